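#' Derive the seed of one replicate from a master seed
#'
#' A fixed, documented derivation: replicate `r` uses child seed
#' `(masterSeed + r * 48271) mod (2^31 - 1)`. The multiplier and the prime
#' modulus guarantee distinct child seeds for all replicate indices below
#' the modulus, every derived seed stays within 32-bit integer range, and
#' any single replicate can be reproduced in isolation by calling
#' `set.seed(replicateSeed(masterSeed, r))` before simulating it.
#'
#' @param masterSeed integer master seed of the experiment.
#' @param replicate replicate index (1-based); vectorised.
#' @return integer child seed(s).
#' @examples
#' replicateSeed(20130617, 1:3)
#' @export
replicateSeed <- function(masterSeed, replicate) {
  if (any(replicate < 1) || any(replicate != floor(replicate)))
    stop("'replicate' must be a positive integer index")
  m <- 2147483647  # 2^31 - 1, prime
  as.integer((as.numeric(masterSeed) %% m + (replicate %% m) * 48271) %% m)
}

#' Run a Monte Carlo ensemble of multitype trajectories
#'
#' Simulates `nReplicates` independent trajectories of the multitype
#' self-regulating process, each on its own seed substream derived from
#' `masterSeed` via [replicateSeed()]. The ensemble is a pure function of
#' `(x0, params, nGenerations, nReplicates, masterSeed)`: rerunning with
#' the same arguments reproduces the count array bit for bit.
#'
#' @param x0 length-k vector of non-negative integer initial counts.
#' @param params a [MultitypeParams-class].
#' @param nGenerations positive integer generations per replicate.
#' @param nReplicates positive integer number of replicates.
#' @param masterSeed integer master seed.
#' @param cap total-population cap per replicate (default 1e12); a cap
#'   violation is re-thrown with the offending replicate index attached.
#' @param cltThreshold passed to the offspring sampler.
#' @param progress if `TRUE`, log a line every 10% of replicates.
#' @return a [BranchingEnsemble-class].
#' @examples
#' ens <- runEnsemble(c(10000, 0, 0), section5Params(), nGenerations = 50,
#'                    nReplicates = 10, masterSeed = 1)
#' dim(counts(ens))
#' @export
runEnsemble <- function(x0, params, nGenerations, nReplicates, masterSeed,
                        cap = 1e12, cltThreshold = Inf, progress = FALSE) {
  stopifnot(is(params, "MultitypeParams"))
  if (nReplicates < 1) stop("'nReplicates' must be at least 1")
  k <- nGenotypes(params)
  arr <- array(0, dim = c(nReplicates, nGenerations + 1L, k))
  tick <- max(1L, floor(nReplicates / 10))
  for (r in seq_len(nReplicates)) {
    tr <- tryCatch(
      simulateMultitype(x0, params, nGenerations,
                        seed = replicateSeed(masterSeed, r),
                        cap = cap, cltThreshold = cltThreshold),
      error = function(e) stop("replicate ", r, ": ", conditionMessage(e),
                               call. = FALSE))
    arr[r, , ] <- tr
    if (progress && r %% tick == 0L)
      message(sprintf("replicate %d/%d done", r, nReplicates))
  }
  new("BranchingEnsemble", counts = arr, params = params,
      x0 = as.numeric(x0), masterSeed = as.integer(masterSeed),
      seedDerivation = "child = (master + r*48271) mod (2^31-1); set.seed(child) per replicate")
}

#' Quantile trajectories of an ensemble
#'
#' Per-generation, per-genotype empirical quantiles across replicates,
#' computed by linear interpolation between order statistics
#' (`stats::quantile` type 7). By default extinct replicates contribute
#' their zeros, so the quantiles describe the unconditional process;
#' `includeExtinct = FALSE` conditions each generation on replicates whose
#' total population is still positive there.
#'
#' @param ens a [BranchingEnsemble-class].
#' @param levels quantile levels strictly inside (0, 1); default
#'   `c(0.05, 0.25, 0.5, 0.75, 0.95)`.
#' @param includeExtinct include extinct replicates as zeros (default
#'   `TRUE`).
#' @return a [QuantileTrajectory-class].
#' @examples
#' ens <- runEnsemble(c(10000, 0, 0), section5Params(), 50, 10, masterSeed = 1)
#' q <- quantileTrajectories(ens)
#' q@values[51, 1, 3]  # genotype-1 median at generation 50
#' @export
quantileTrajectories <- function(ens, levels = c(0.05, 0.25, 0.5, 0.75, 0.95),
                                 includeExtinct = TRUE) {
  stopifnot(is(ens, "BranchingEnsemble"))
  if (!length(levels) || any(levels <= 0) || any(levels >= 1))
    stop("'levels' must lie strictly inside (0, 1)")
  levels <- sort(levels)
  a <- ens@counts
  d <- dim(a)
  if (d[1L] == 0L) stop("empty ensemble")
  vals <- array(NA_real_, dim = c(d[2L], d[3L], length(levels)))
  if (includeExtinct) {
    for (g in seq_len(d[2L]))
      vals[g, , ] <- t(apply(a[, g, , drop = FALSE], 3L, stats::quantile,
                             probs = levels, type = 7, names = FALSE))
  } else {
    totals <- apply(a, c(1L, 2L), sum)
    for (g in seq_len(d[2L])) {
      alive <- totals[, g] > 0
      if (!any(alive)) { vals[g, , ] <- 0; next }
      sub <- a[alive, g, , drop = FALSE]
      vals[g, , ] <- t(apply(sub, 3L, stats::quantile,
                             probs = levels, type = 7, names = FALSE))
    }
  }
  new("QuantileTrajectory", values = vals, levels = levels,
      includeExtinct = includeExtinct,
      estimator = "linear interpolation of order statistics (type 7)")
}

#' First generation at which a genotype appears
#'
#' For each replicate, the smallest generation \eqn{t} with at least one
#' individual of the genotype, or `NA` if it never appears. Genotypes
#' present in the initial population return 0.
#'
#' @param ens a [BranchingEnsemble-class].
#' @param genotype genotype index.
#' @return integer vector, one entry per replicate (`NA` = never appeared).
#' @examples
#' ens <- runEnsemble(c(10000, 0, 0), section5Params(), 50, 10, masterSeed = 1)
#' table(firstAppearance(ens, 3), useNA = "always")  # genotype 3 never appears
#' @export
firstAppearance <- function(ens, genotype) {
  stopifnot(is(ens, "BranchingEnsemble"))
  k <- dim(ens@counts)[3L]
  if (length(genotype) != 1L || genotype < 1 || genotype > k)
    stop("'genotype' must be a single index in 1..", k)
  apply(ens@counts[, , genotype, drop = FALSE], 1L, function(v) {
    i <- which(v >= 1)
    if (length(i)) as.integer(i[1L] - 1L) else NA_integer_
  })
}

#' Extinction probability at a generation
#'
#' Fraction of replicates whose total population is 0 at the given
#' generation, with its binomial standard error.
#'
#' @param ens a [BranchingEnsemble-class].
#' @param generation generation index (0-based, up to `nGenerations`).
#' @return list with `estimate`, `se` and `nReplicates`.
#' @examples
#' p <- MultitypeParams(0.5, 2, 1e-3, matrix(1))
#' ens <- runEnsemble(1, p, 50, 200, masterSeed = 1)
#' extinctionProbability(ens, 50)$estimate
#' @export
extinctionProbability <- function(ens, generation) {
  stopifnot(is(ens, "BranchingEnsemble"))
  ng <- nGenerations(ens)
  if (generation < 0 || generation > ng)
    stop("'generation' must be in 0..", ng)
  totals <- apply(ens@counts[, generation + 1L, , drop = FALSE], 1L, sum)
  n <- length(totals)
  p <- mean(totals == 0)
  list(estimate = p, se = sqrt(p * (1 - p) / n), nReplicates = n)
}

#' Compare a deterministic trajectory with ensemble quantiles
#'
#' Per-generation, per-genotype comparison table of the embedded
#' deterministic prediction (DET) against the ensemble median (Q50):
#' absolute and relative gap, and a flag marking generations where DET
#' falls outside the central quantile band of the ensemble (the lowest and
#' highest levels present in `q`, e.g. [Q05, Q95]). A DET trajectory that
#' is a good measure of central tendency for the process stays inside the
#' band; the preset mutation-selection experiment is a case where it does
#' not.
#'
#' @param det a [DetTrajectory-class].
#' @param q a [QuantileTrajectory-class] over the same generations and
#'   genotypes, containing the 0.5 level.
#' @return a `data.frame` with columns `generation`, `genotype`, `det`,
#'   `q50`, `absGap`, `relGap`, `outsideBand`.
#' @examples
#' p <- section5Params()
#' det <- multitypeDetTrajectory(c(10000, 0, 0), p, 50)
#' ens <- runEnsemble(c(10000, 0, 0), p, 50, 10, masterSeed = 1)
#' rep50 <- detVsStochasticReport(det, quantileTrajectories(ens))
#' subset(rep50, generation == 50)
#' @export
detVsStochasticReport <- function(det, q) {
  stopifnot(is(det, "DetTrajectory"), is(q, "QuantileTrajectory"))
  dS <- det@states
  if (nrow(dS) != dim(q@values)[1L] || ncol(dS) != dim(q@values)[2L])
    stop("deterministic trajectory and quantile summary have mismatched ",
         "generations or genotype counts")
  i50 <- match(0.5, q@levels)
  if (is.na(i50)) stop("quantile summary must contain the 0.5 level")
  lo <- q@values[, , 1L, drop = TRUE]
  hi <- q@values[, , length(q@levels), drop = TRUE]
  q50 <- q@values[, , i50, drop = TRUE]
  nG <- nrow(dS)
  k <- ncol(dS)
  out <- data.frame(
    generation = rep(0:(nG - 1L), times = k),
    genotype = rep(seq_len(k), each = nG),
    det = as.vector(dS),
    q50 = as.vector(q50),
    absGap = as.vector(abs(dS - q50)),
    relGap = as.vector(abs(dS - q50) / pmax(1, abs(q50))),
    outsideBand = as.vector(dS < lo | dS > hi))
  out
}
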