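#' Parameters of the one-type self-regulating branching process
#'
#' Bundles the three parameters of the single-type process: the Poisson
#' offspring mean \eqn{\lambda}, the Weibull shape \eqn{\alpha} and the
#' inverse carrying capacity \eqn{\beta}. Each offspring produced in
#' generation \eqn{t} survives to reproduce with probability
#' \eqn{S(x) = \exp[-(\beta x)^\alpha]} where \eqn{x = X(t)} is the parental
#' population size. \eqn{\beta = 0} is admitted and recovers the classical
#' Galton-Watson process (all offspring survive).
#'
#' @slot lambda positive real, expected offspring per individual per
#'   generation.
#' @slot alpha positive real, Weibull shape.
#' @slot beta non-negative real, inverse carrying capacity; the population
#'   scale at which survival decays sharply is \eqn{1/\beta}.
#'
#' @seealso [OneTypeParams()], [stepOneType()], [oneTypeMap()]
#' @export
setClass("OneTypeParams",
  representation(lambda = "numeric", alpha = "numeric", beta = "numeric"),
  validity = function(object) {
    msg <- NULL
    for (s in c("lambda", "alpha", "beta")) {
      v <- slot(object, s)
      if (length(v) != 1L || !is.finite(v))
        msg <- c(msg, sprintf("'%s' must be a single finite number", s))
    }
    if (is.null(msg)) {
      if (object@lambda <= 0) msg <- c(msg, "'lambda' must be positive")
      if (object@alpha <= 0) msg <- c(msg, "'alpha' must be positive")
      if (object@beta < 0) msg <- c(msg, "'beta' must be non-negative")
    }
    if (is.null(msg)) TRUE else msg
  })

#' Construct one-type process parameters
#'
#' @param lambda positive Poisson offspring mean.
#' @param alpha positive Weibull shape (default 2, the value used throughout
#'   the worked experiments).
#' @param beta non-negative inverse carrying capacity; 0 gives the
#'   Galton-Watson special case.
#' @return a validated [OneTypeParams-class] object.
#' @examples
#' OneTypeParams(lambda = 1.05, alpha = 2, beta = 1e-6)
#' @export
OneTypeParams <- function(lambda, alpha = 2, beta = 0) {
  new("OneTypeParams", lambda = as.numeric(lambda), alpha = as.numeric(alpha),
      beta = as.numeric(beta))
}

setMethod("show", "OneTypeParams", function(object) {
  cat("OneTypeParams: lambda =", object@lambda,
      " alpha =", object@alpha, " beta =", format(object@beta), "\n")
  if (object@beta == 0) {
    cat("  (beta = 0: Galton-Watson special case, no density regulation)\n")
  } else {
    cat("  carrying-capacity scale 1/beta =", format(1 / object@beta), "\n")
  }
})

# row-sum tolerance for mutation matrices; generous enough that rows built
# from off-diagonal entries spanning ~17 orders of magnitude still validate
.MUTATION_ROWSUM_TOL <- 1e-12

#' Row-stochastic mutation probability matrix
#'
#' A square matrix whose entry \eqn{(i, j)} is \eqn{\mu_{ij}}, the
#' conditional probability that a genotype-\eqn{i} parent produces a
#' genotype-\eqn{j} offspring. Every row must sum to 1 (within 1e-12) and
#' all entries must lie in \eqn{[0, 1]}: each row is the probability vector
#' of the multinomial law splitting a parent's offspring among genotypes.
#'
#' @seealso [MutationMatrix()], [completeMutationMatrix()]
#' @export
setClass("MutationMatrix", contains = "matrix",
  validity = function(object) {
    m <- object@.Data
    if (!is.numeric(m) || nrow(m) != ncol(m))
      return("mutation matrix must be a square numeric matrix")
    if (any(!is.finite(m)) || any(m < 0) || any(m > 1))
      return("all mutation probabilities must lie in [0, 1]")
    rs <- rowSums(m)
    if (any(abs(rs - 1) > .MUTATION_ROWSUM_TOL))
      return(sprintf("row sums must equal 1 within %g (worst deviation %g)",
                     .MUTATION_ROWSUM_TOL, max(abs(rs - 1))))
    TRUE
  })

#' Construct a mutation probability matrix
#'
#' @param probs a square numeric matrix of probabilities with unit row sums.
#' @return a validated [MutationMatrix-class].
#' @examples
#' MutationMatrix(diag(3))
#' @export
MutationMatrix <- function(probs) {
  new("MutationMatrix", as.matrix(probs))
}

setMethod("show", "MutationMatrix", function(object) {
  cat("MutationMatrix (", nrow(object), "genotypes ):\n")
  print(object@.Data, digits = 6)
})

#' Parameters of the multitype self-regulating branching process
#'
#' Per-genotype Poisson offspring means, Weibull survival parameters, and
#' the mutation probability matrix. Offspring of genotype \eqn{i} produced
#' in generation \eqn{t} survive to reproduce with probability
#' \eqn{S_i(T) = \exp[-(\beta_i T)^{\alpha_i}]} where \eqn{T = T(t)} is the
#' parental-generation total population size, so all genotypes compete for
#' the same resource pool while possibly differing in their ability to do
#' so (the \eqn{\beta_i}) and in reproductive success (the \eqn{\lambda_i}).
#'
#' @slot lambdas positive reals, per-genotype Poisson offspring means.
#' @slot alphas positive reals, per-genotype Weibull shapes.
#' @slot betas non-negative reals, per-genotype inverse carrying capacities.
#' @slot mutation a [MutationMatrix-class] with one row per genotype.
#'
#' @seealso [MultitypeParams()], [stepMultitype()], [section5Params()]
#' @export
setClass("MultitypeParams",
  representation(lambdas = "numeric", alphas = "numeric", betas = "numeric",
                 mutation = "MutationMatrix"),
  validity = function(object) {
    k <- nrow(object@mutation)
    msg <- NULL
    if (length(object@lambdas) != k || length(object@alphas) != k ||
        length(object@betas) != k)
      msg <- c(msg, sprintf(
        "lambdas, alphas and betas must each have length %d (one per genotype)", k))
    if (any(!is.finite(object@lambdas)) || any(object@lambdas <= 0))
      msg <- c(msg, "all lambdas must be positive and finite")
    if (any(!is.finite(object@alphas)) || any(object@alphas <= 0))
      msg <- c(msg, "all alphas must be positive and finite")
    if (any(!is.finite(object@betas)) || any(object@betas < 0))
      msg <- c(msg, "all betas must be non-negative and finite")
    if (is.null(msg)) TRUE else msg
  })

#' Construct multitype process parameters
#'
#' @param lambdas vector of per-genotype Poisson offspring means.
#' @param alphas vector of per-genotype Weibull shapes (recycled if scalar).
#' @param betas vector of per-genotype inverse carrying capacities
#'   (recycled if scalar).
#' @param mutation a [MutationMatrix-class], a plain row-stochastic matrix,
#'   or a matrix with off-diagonal mutation probabilities whose diagonal is
#'   `NA` (completed via [completeMutationMatrix()]).
#' @return a validated [MultitypeParams-class].
#' @examples
#' MultitypeParams(lambdas = c(1.05, 1.05, 1.5), alphas = 2, betas = 1e-6,
#'                 mutation = diag(3))
#' @export
MultitypeParams <- function(lambdas, alphas, betas, mutation) {
  if (!is(mutation, "MutationMatrix")) {
    mutation <- as.matrix(mutation)
    if (anyNA(diag(mutation))) {
      mutation <- completeMutationMatrix(mutation)
    } else {
      mutation <- MutationMatrix(mutation)
    }
  }
  k <- nrow(mutation)
  new("MultitypeParams",
      lambdas = rep_len(as.numeric(lambdas), k),
      alphas = rep_len(as.numeric(alphas), k),
      betas = rep_len(as.numeric(betas), k),
      mutation = mutation)
}

setMethod("show", "MultitypeParams", function(object) {
  k <- nrow(object@mutation)
  cat("MultitypeParams with", k, "genotypes\n")
  cat("  lambdas:", object@lambdas, "\n")
  cat("  alphas: ", object@alphas, "\n")
  cat("  betas:  ", format(object@betas), "\n")
  cat("  mutation matrix:\n")
  print(object@mutation@.Data, digits = 6)
})

#' @rdname mutationMatrix
#' @param object a [MultitypeParams-class].
#' @return `mutationMatrix` returns the [MutationMatrix-class] of the model.
#' @export
setMethod("mutationMatrix", "MultitypeParams",
          function(object) object@mutation)

#' Number of genotypes
#'
#' @param object a multitype parameter, ensemble or trajectory object.
#' @return integer count of genotypes (types) in the model.
#' @export
setMethod("nGenotypes", "MultitypeParams",
          function(object) nrow(object@mutation))

#' One-type stochastic trajectory
#'
#' A single realisation of the one-type process: the population sizes
#' \eqn{X(0), \ldots, X(T)}, optionally the pre-thinning offspring totals
#' \eqn{Y(0), \ldots, Y(T-1)}, and the seed used. Extinction (count 0) is
#' absorbing.
#'
#' @slot counts non-negative integer-valued vector of length
#'   `nGenerations + 1`.
#' @slot offspringTotals offspring totals per generation (length 0 when not
#'   recorded).
#' @slot seed the integer seed that reproduces the trajectory, or
#'   `NA_integer_` when the caller managed the RNG state.
#' @export
setClass("OneTypeTrajectory",
  representation(counts = "numeric", offspringTotals = "numeric",
                 seed = "integer"),
  validity = function(object) {
    x <- object@counts
    if (any(x < 0) || any(x != floor(x)))
      return("counts must be non-negative integers")
    z <- which(x == 0)
    if (length(z) && any(x[seq(min(z), length(x))] != 0))
      return("extinction must be absorbing: counts after the first 0 must be 0")
    TRUE
  })

setMethod("show", "OneTypeTrajectory", function(object) {
  n <- length(object@counts)
  cat("OneTypeTrajectory over", n - 1L, "generations; X(0) =",
      object@counts[1L], "; final X =", object@counts[n], "\n")
  if (any(object@counts == 0)) {
    cat("  extinct at generation", min(which(object@counts == 0)) - 1L, "\n")
  }
})

#' @rdname counts
#' @export
setMethod("counts", "OneTypeTrajectory", function(object) object@counts)

#' Per-generation offspring table of the multitype process
#'
#' The sampled offspring of one generation, cross-classified by parent and
#' offspring genotype: entry \eqn{(i, j)} of `byParent` is \eqn{Y_{ij}}, the
#' number of genotype-\eqn{j} offspring produced by genotype-\eqn{i}
#' parents; `byOffspring` holds the column sums \eqn{Y_j}.
#'
#' @slot byParent k x k matrix of non-negative integer-valued counts.
#' @slot byOffspring length-k vector equal to `colSums(byParent)`.
#' @seealso [sampleOffspring()]
#' @export
setClass("OffspringTable",
  representation(byParent = "matrix", byOffspring = "numeric"),
  validity = function(object) {
    if (!isTRUE(all.equal(colSums(object@byParent), object@byOffspring,
                          check.attributes = FALSE)))
      return("byOffspring must equal the column sums of byParent")
    if (any(object@byParent < 0))
      return("offspring counts must be non-negative")
    TRUE
  })

setMethod("show", "OffspringTable", function(object) {
  cat("OffspringTable (parent genotype x offspring genotype):\n")
  print(object@byParent)
  cat("  totals by offspring genotype:", object@byOffspring, "\n")
})

#' Deterministic trajectory of an embedded difference-equation model
#'
#' States of the embedded deterministic recursion, obtained by iterating
#' the conditional-expectation map of the stochastic process. States are
#' continuous non-negative reals and are never rounded: mutant mass of
#' order 1e-13 and smaller must be carried exactly for rare-mutant
#' dynamics to unfold.
#'
#' @slot states (nGenerations + 1) x k matrix of non-negative reals; row
#'   \eqn{t + 1} is the state at generation \eqn{t} (k = 1 for the one-type
#'   map).
#' @slot convergedAt generation at which convergence was flagged
#'   (successive relative change below 1e-9 for 10 consecutive
#'   generations), or `NA_integer_`.
#' @slot period detected period if a period search was run, else
#'   `NA_integer_`.
#' @seealso [oneTypeDetTrajectory()], [multitypeDetTrajectory()],
#'   [detectPeriod()]
#' @export
setClass("DetTrajectory",
  representation(states = "matrix", convergedAt = "integer",
                 period = "integer"),
  validity = function(object) {
    if (any(!is.finite(object@states)) || any(object@states < 0))
      return("states must be finite non-negative reals")
    TRUE
  })

setMethod("show", "DetTrajectory", function(object) {
  n <- nrow(object@states) - 1L
  k <- ncol(object@states)
  cat("DetTrajectory:", k, if (k == 1L) "component," else "components,",
      n, "generations\n")
  cat("  final state:", format(object@states[n + 1L, ], digits = 6), "\n")
  if (!is.na(object@convergedAt))
    cat("  converged at generation", object@convergedAt, "\n")
  if (!is.na(object@period))
    cat("  detected period:", object@period, "\n")
})

#' @rdname detStates
#' @param object a [DetTrajectory-class].
#' @return `detStates` returns the (nGenerations + 1) x k state matrix.
#' @export
setMethod("detStates", "DetTrajectory", function(object) object@states)

#' @rdname convergedAt
#' @param object a [DetTrajectory-class].
#' @return `convergedAt` returns the generation index at which the
#'   trajectory was flagged converged, or `NA_integer_`.
#' @export
setMethod("convergedAt", "DetTrajectory", function(object) object@convergedAt)

#' @rdname nGenerations
#' @export
setMethod("nGenerations", "DetTrajectory",
          function(object) nrow(object@states) - 1L)

#' @rdname nGenotypes
#' @export
setMethod("nGenotypes", "DetTrajectory", function(object) ncol(object@states))

#' Fixed-point report for the one-type deterministic map
#'
#' Location and local stability of a fixed point of
#' \eqn{h(x) = x \exp[-(\beta x)^\alpha] \lambda}. A fixed point is stable
#' when the derivative magnitude \eqn{|h'(x_f)|} is below 1 (nearby
#' iterates are attracted), unstable above 1, marginal at 1.
#'
#' @slot location the fixed point \eqn{x_f \ge 0}.
#' @slot derivativeMagnitude \eqn{|h'(x_f)|}.
#' @slot classification one of `"stable"`, `"unstable"`, `"marginal"`.
#' @seealso [findFixedPoint()]
#' @export
setClass("FixedPointReport",
  representation(location = "numeric", derivativeMagnitude = "numeric",
                 classification = "character"),
  validity = function(object) {
    if (object@location < 0) return("location must be non-negative")
    if (object@derivativeMagnitude < 0)
      return("derivativeMagnitude must be non-negative")
    if (!object@classification %in% c("stable", "unstable", "marginal"))
      return("classification must be stable, unstable or marginal")
    TRUE
  })

setMethod("show", "FixedPointReport", function(object) {
  cat("FixedPointReport: x_f =", format(object@location, digits = 8),
      " |h'(x_f)| =", format(object@derivativeMagnitude, digits = 6),
      " (", object@classification, ")\n")
})

#' Monte Carlo ensemble of multitype trajectories
#'
#' Holds the full replicate x generation x genotype count array of a Monte
#' Carlo experiment, together with the model parameters, the initial
#' population vector and the master-seed policy, so the ensemble is a pure
#' function of its stored inputs and is bit-reproducible.
#'
#' @slot counts numeric array with dimensions
#'   `c(nReplicates, nGenerations + 1, nGenotypes)`.
#' @slot params the [MultitypeParams-class] used.
#' @slot x0 initial genotype counts.
#' @slot masterSeed the master seed.
#' @slot seedDerivation human-readable description of the replicate-seed
#'   derivation rule.
#' @seealso [runEnsemble()], [quantileTrajectories()]
#' @export
setClass("BranchingEnsemble",
  representation(counts = "array", params = "MultitypeParams",
                 x0 = "numeric", masterSeed = "integer",
                 seedDerivation = "character"),
  validity = function(object) {
    d <- dim(object@counts)
    if (length(d) != 3L)
      return("counts must be a 3-d array (replicate x generation x genotype)")
    if (d[3L] != nGenotypes(object@params))
      return("third dimension of counts must match the number of genotypes")
    if (any(object@counts < 0))
      return("counts must be non-negative")
    TRUE
  })

setMethod("show", "BranchingEnsemble", function(object) {
  d <- dim(object@counts)
  cat("BranchingEnsemble:", d[1L], "replicates x", d[2L] - 1L,
      "generations x", d[3L], "genotypes\n")
  cat("  x0 =", object@x0, "; master seed =", object@masterSeed, "\n")
  fin <- object@counts[, d[2L], , drop = FALSE]
  cat("  final-generation genotype medians:",
      apply(fin, 3L, stats::median), "\n")
})

#' @rdname counts
#' @export
setMethod("counts", "BranchingEnsemble", function(object) object@counts)

#' @rdname modelParams
#' @param object an object carrying model parameters.
#' @return `modelParams` returns the stored parameter object.
#' @export
setMethod("modelParams", "BranchingEnsemble", function(object) object@params)

#' @rdname nReplicates
#' @param object a [BranchingEnsemble-class].
#' @return `nReplicates` returns the number of Monte Carlo replicates.
#' @export
setMethod("nReplicates", "BranchingEnsemble",
          function(object) dim(object@counts)[1L])

#' @rdname nGenerations
#' @param object an ensemble or trajectory object.
#' @return `nGenerations` returns the number of simulated generations
#'   (the stored trajectories have one more time point, generation 0).
#' @export
setMethod("nGenerations", "BranchingEnsemble",
          function(object) dim(object@counts)[2L] - 1L)

#' @rdname nGenotypes
#' @export
setMethod("nGenotypes", "BranchingEnsemble",
          function(object) dim(object@counts)[3L])

#' Quantile trajectories of a Monte Carlo ensemble
#'
#' Per-generation, per-genotype empirical quantiles across replicates
#' (e.g. the Q50 median trajectory). Values are non-decreasing in the
#' quantile level at every (generation, genotype) cell.
#'
#' @slot values numeric array with dimensions
#'   `c(nGenerations + 1, nGenotypes, length(levels))`.
#' @slot levels the quantile levels, strictly inside (0, 1).
#' @slot includeExtinct whether extinct replicates contributed zeros
#'   (`TRUE`, the default convention) or were dropped.
#' @slot estimator short description of the quantile convention used.
#' @seealso [quantileTrajectories()]
#' @export
setClass("QuantileTrajectory",
  representation(values = "array", levels = "numeric",
                 includeExtinct = "logical", estimator = "character"),
  validity = function(object) {
    if (length(dim(object@values)) != 3L)
      return("values must be a 3-d array (generation x genotype x level)")
    if (dim(object@values)[3L] != length(object@levels))
      return("third dimension must match the number of quantile levels")
    if (any(object@levels <= 0) || any(object@levels >= 1))
      return("levels must lie strictly inside (0, 1)")
    if (is.unsorted(object@levels, strictly = TRUE))
      return("levels must be strictly increasing")
    # monotone in level at every cell
    v <- object@values
    if (dim(v)[3L] > 1L) {
      d <- apply(v, c(1L, 2L), function(z) any(diff(z) < 0))
      if (any(d))
        return("quantile values must be non-decreasing in level")
    }
    TRUE
  })

setMethod("show", "QuantileTrajectory", function(object) {
  d <- dim(object@values)
  cat("QuantileTrajectory:", d[1L] - 1L, "generations x", d[2L],
      "genotypes; levels:", object@levels, "\n")
  cat("  extinct replicates",
      if (object@includeExtinct) "included as zeros" else "excluded", "\n")
})

#' @rdname nGenerations
#' @export
setMethod("nGenerations", "QuantileTrajectory",
          function(object) dim(object@values)[1L] - 1L)

#' @rdname nGenotypes
#' @export
setMethod("nGenotypes", "QuantileTrajectory",
          function(object) dim(object@values)[2L])
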