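#' Sample the total number of offspring of a generation
#'
#' The total number of offspring produced by `x` individuals, each with an
#' independent Poisson(`lambda`) offspring count, is by superposition a
#' single Poisson(`x * lambda`) variable, so one aggregated draw replaces
#' `x` per-individual draws exactly (not approximately).
#'
#' For extremely large means a normal approximation can be enabled via
#' `cltThreshold`: when `x * lambda` exceeds it, the draw is a rounded
#' normal with matching mean and variance, truncated at zero. The default
#' threshold is `Inf`, i.e. exact Poisson sampling always.
#'
#' @param x non-negative integer, number of reproducing individuals.
#' @param lambda positive Poisson offspring mean.
#' @param cltThreshold mean above which a rounded-normal approximation is
#'   used instead of exact Poisson sampling (opt-in; default `Inf`).
#' @return one non-negative integer-valued draw; 0 when `x = 0`.
#' @seealso [sampleOffspringTotalPerIndividual()] for the per-individual
#'   reference sampler used in distributional-equivalence tests.
#' @examples
#' set.seed(1)
#' sampleOffspringTotal(1000, 1.05)
#' @export
sampleOffspringTotal <- function(x, lambda, cltThreshold = Inf) {
  if (length(x) != 1L || is.na(x) || x < 0 || x != floor(x))
    stop("'x' must be a single non-negative integer")
  if (length(lambda) != 1L || is.na(lambda) || lambda <= 0)
    stop("'lambda' must be a single positive number")
  if (x == 0) return(0)
  mu <- x * lambda
  if (mu > cltThreshold) {
    return(max(0, round(stats::rnorm(1L, mean = mu, sd = sqrt(mu)))))
  }
  if (mu > 2^31) {
    stop("offspring mean ", format(mu), " exceeds exact-sampling range; ",
         "set 'cltThreshold' to enable the normal approximation")
  }
  stats::rpois(1L, mu)
}

#' Per-individual reference sampler for the offspring total
#'
#' Draws one Poisson(`lambda`) offspring count per individual and returns
#' the sum, exactly as the process is defined. Distributionally identical
#' to [sampleOffspringTotal()]; kept as an independent sampling route for
#' equivalence tests.
#'
#' @inheritParams sampleOffspringTotal
#' @return one non-negative integer-valued draw.
#' @export
sampleOffspringTotalPerIndividual <- function(x, lambda) {
  if (length(x) != 1L || is.na(x) || x < 0 || x != floor(x))
    stop("'x' must be a single non-negative integer")
  if (length(lambda) != 1L || is.na(lambda) || lambda <= 0)
    stop("'lambda' must be a single positive number")
  if (x == 0) return(0)
  sum(stats::rpois(x, lambda))
}

#' Density-dependent Weibull survival probability
#'
#' Probability that an offspring produced in a generation with (parental)
#' population size `x` survives to reproduce:
#' \eqn{S(x) = \exp[-(\beta x)^\alpha]}. Strictly decreasing in `x` when
#' \eqn{\beta > 0}; identically 1 when \eqn{\beta = 0} (every offspring
#' survives, the Galton-Watson case). With \eqn{\alpha = 1} this is
#' exponential survival. Vectorised over `x`.
#'
#' @param x non-negative population size(s); in the multitype model, the
#'   total population size.
#' @param alpha positive Weibull shape.
#' @param beta non-negative inverse carrying capacity.
#' @return survival probabilities in \eqn{[0, 1]}.
#' @examples
#' survivalProbability(1e6, alpha = 2, beta = 1e-6)  # exp(-1)
#' @export
survivalProbability <- function(x, alpha, beta) {
  if (any(is.na(x)) || any(x < 0)) stop("'x' must be non-negative")
  if (length(alpha) != 1L || is.na(alpha) || alpha <= 0)
    stop("'alpha' must be a single positive number")
  if (length(beta) != 1L || is.na(beta) || beta < 0)
    stop("'beta' must be a single non-negative number")
  exp(-(beta * x)^alpha)
}

#' One generation of the one-type self-regulating process
#'
#' Given the parental count `x`, draws the offspring total
#' \eqn{Y \sim} Poisson(\eqn{x\lambda}) and thins it binomially with the
#' survival probability evaluated at the parental count:
#' \eqn{X' \sim} Binomial(\eqn{Y}, \eqn{S(x)}). The conditional mean is
#' \eqn{E[X' \mid x] = x\,S(x)\,\lambda}, which is what the embedded
#' deterministic map iterates.
#'
#' @param x non-negative integer parental count.
#' @param params a [OneTypeParams-class].
#' @param cltThreshold passed to [sampleOffspringTotal()].
#' @return the next-generation count (non-negative integer-valued).
#' @examples
#' set.seed(1)
#' stepOneType(10000, OneTypeParams(1.05, 2, 1e-6))
#' @export
stepOneType <- function(x, params, cltThreshold = Inf) {
  stopifnot(is(params, "OneTypeParams"))
  if (x == 0) return(0)
  y <- sampleOffspringTotal(x, params@lambda, cltThreshold = cltThreshold)
  if (y == 0) return(0)
  s <- survivalProbability(x, params@alpha, params@beta)
  stats::rbinom(1L, y, s)
}

#' Simulate a one-type trajectory
#'
#' Iterates [stepOneType()] from `x0` for `nGenerations` generations.
#' Extinction is absorbing: once the count hits 0 the remainder of the
#' trajectory is 0. Counts above `cap` abort with an error rather than
#' risking loss of integer precision.
#'
#' @param x0 positive integer initial count.
#' @param params a [OneTypeParams-class].
#' @param nGenerations positive integer number of generations.
#' @param seed optional integer; when supplied, `set.seed(seed)` is called
#'   so the trajectory is reproducible in isolation and the seed is stored
#'   in the result.
#' @param recordOffspring if `TRUE`, also record the pre-thinning offspring
#'   totals \eqn{Y(t)}.
#' @param cap hard upper bound on any count (default 1e12); exceeding it is
#'   an error.
#' @param cltThreshold passed to [sampleOffspringTotal()].
#' @return a [OneTypeTrajectory-class] of length `nGenerations + 1`.
#' @examples
#' traj <- simulateOneType(10000, OneTypeParams(1.05, 2, 1e-6), 100, seed = 7)
#' counts(traj)[1:5]
#' @export
simulateOneType <- function(x0, params, nGenerations, seed = NULL,
                            recordOffspring = FALSE, cap = 1e12,
                            cltThreshold = Inf) {
  stopifnot(is(params, "OneTypeParams"))
  if (length(x0) != 1L || is.na(x0) || x0 < 1 || x0 != floor(x0))
    stop("'x0' must be a single positive integer")
  if (nGenerations < 1) stop("'nGenerations' must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(nGenerations)
  out <- numeric(n + 1L)
  out[1L] <- x0
  ys <- if (recordOffspring) numeric(n) else numeric(0)
  x <- x0
  s <- 1
  lastX <- -1
  for (t in seq_len(n)) {
    if (x == 0) break
    y <- sampleOffspringTotal(x, params@lambda, cltThreshold = cltThreshold)
    if (recordOffspring) ys[t] <- y
    if (y > 0) {
      if (x != lastX) {  # survival depends only on the parental count
        s <- survivalProbability(x, params@alpha, params@beta)
        lastX <- x
      }
      x <- stats::rbinom(1L, y, s)
    } else {
      x <- 0
    }
    if (x > cap)
      stop("population count ", format(x), " exceeded the cap ", format(cap),
           " at generation ", t)
    out[t + 1L] <- x
  }
  new("OneTypeTrajectory", counts = out, offspringTotals = ys,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Galton-Watson mean population size
#'
#' Closed-form unconditional expectation of the Galton-Watson process
#' (the \eqn{\beta = 0} special case): \eqn{\eta(t) = x_0 \lambda^t}.
#' Supercritical (\eqn{\lambda > 1}) means grow without bound, critical
#' means stay at \eqn{x_0}, subcritical means decay to 0. Used as an
#' oracle for the simulator in the undamped regime.
#'
#' @param x0 positive initial count.
#' @param lambda positive offspring mean.
#' @param t non-negative generation index (vectorised).
#' @return \eqn{x_0 \lambda^t}.
#' @examples
#' gwMean(1, 2, 3)  # 8
#' @export
gwMean <- function(x0, lambda, t) {
  if (any(t < 0)) stop("'t' must be non-negative")
  if (x0 < 1) stop("'x0' must be positive")
  if (lambda <= 0) stop("'lambda' must be positive")
  x0 * lambda^t
}
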