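# relative change below which, sustained over .CONV_RUN consecutive
# generations, a deterministic trajectory is flagged converged
.CONV_TOL <- 1e-9
.CONV_RUN <- 10L
# deterministic components below this are clamped to zero (double-precision
# underflow would zero them silently anyway)
.UNDERFLOW <- 1e-300

#' The one-type embedded deterministic map
#'
#' The conditional-expectation map of the one-type process,
#' \eqn{h(x) = x \exp[-(\beta x)^\alpha] \lambda}: one deterministic step
#' equals the expected value of one stochastic step from the point state
#' `x`. Extended by \eqn{h(x) = 0} for \eqn{x \le 0} so the map is
#' continuous on the whole line. With \eqn{\beta = 0} it reduces to the
#' linear Galton-Watson mean map \eqn{\lambda x}. Vectorised over `x`.
#'
#' @param x non-negative real state(s).
#' @param params a [OneTypeParams-class].
#' @return \eqn{h(x)}, non-negative real(s).
#' @examples
#' oneTypeMap(1e5, OneTypeParams(1.05, 2, 1e-6))
#' @export
oneTypeMap <- function(x, params) {
  stopifnot(is(params, "OneTypeParams"))
  ifelse(x <= 0, 0,
         x * exp(-(params@beta * x)^params@alpha) * params@lambda)
}

# flag the first generation at which .CONV_RUN consecutive relative
# changes fall below .CONV_TOL; states is (n+1) x k
.flagConvergence <- function(states) {
  n <- nrow(states) - 1L
  if (n < .CONV_RUN) return(NA_integer_)
  prev <- states[seq_len(n), , drop = FALSE]
  nxt <- states[seq_len(n) + 1L, , drop = FALSE]
  rel <- abs(nxt - prev) / pmax(1, abs(prev))
  small <- apply(rel <= .CONV_TOL, 1L, all)
  r <- rle(small)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= .CONV_RUN)
  if (!length(hit)) return(NA_integer_)
  first <- hit[1L]
  # generation index at which the qualifying run completes
  as.integer(ends[first] - r$lengths[first] + .CONV_RUN)
}

#' Iterate the one-type deterministic model
#'
#' Iterates [oneTypeMap()] from `x0`, producing the embedded deterministic
#' trajectory \eqn{\hat X(0..n)}. States are continuous reals and never
#' rounded. Convergence is flagged when the relative change stays below
#' 1e-9 for 10 consecutive generations.
#'
#' @param x0 positive real initial state.
#' @param params a [OneTypeParams-class].
#' @param nGenerations positive integer.
#' @return a [DetTrajectory-class] with a single component.
#' @examples
#' tr <- oneTypeDetTrajectory(1e4, OneTypeParams(1.05, 2, 1e-6), 300)
#' tail(detStates(tr), 1)
#' @export
oneTypeDetTrajectory <- function(x0, params, nGenerations) {
  stopifnot(is(params, "OneTypeParams"))
  if (x0 <= 0) stop("'x0' must be positive")
  if (nGenerations < 1) stop("'nGenerations' must be at least 1")
  n <- as.integer(nGenerations)
  states <- matrix(0, n + 1L, 1L)
  states[1L, 1L] <- x <- x0
  for (t in seq_len(n)) {
    x <- oneTypeMap(x, params)
    if (x < .UNDERFLOW) x <- 0
    states[t + 1L, 1L] <- x
  }
  new("DetTrajectory", states = states,
      convergedAt = .flagConvergence(states), period = NA_integer_)
}

#' Locate and classify the fixed point of the one-type map
#'
#' For \eqn{\lambda > 1} and \eqn{\beta > 0} the map
#' \eqn{h(x) = x e^{-(\beta x)^\alpha} \lambda} has the unique positive
#' fixed point \eqn{x_f = (\ln \lambda)^{1/\alpha} / \beta} (where survival
#' exactly offsets the offspring surplus, \eqn{e^{-(\beta x_f)^\alpha}
#' \lambda = 1}). The derivative there is \eqn{h'(x_f) = 1 - \alpha \ln
#' \lambda}, so the fixed point is stable iff
#' \eqn{|1 - \alpha \ln \lambda| < 1}. For \eqn{\lambda \le 1} (or
#' \eqn{\beta = 0}) only the trivial fixed point 0 exists and is classified
#' by \eqn{|h'(0)| = \lambda}.
#'
#' The closed form is cross-checked internally against a bisection root of
#' \eqn{h(x) - x} and the analytic derivative against a central difference;
#' disagreement beyond 1e-9 relative is an error.
#'
#' @param params a [OneTypeParams-class].
#' @return a [FixedPointReport-class].
#' @examples
#' findFixedPoint(OneTypeParams(1.05, 2, 1e-6))
#' @export
findFixedPoint <- function(params) {
  stopifnot(is(params, "OneTypeParams"))
  lam <- params@lambda
  if (lam <= 1 || params@beta == 0) {
    cls <- if (lam < 1) "stable" else if (lam > 1) "unstable" else "marginal"
    return(new("FixedPointReport", location = 0,
               derivativeMagnitude = lam, classification = cls))
  }
  a <- params@alpha
  b <- params@beta
  xf <- log(lam)^(1 / a) / b
  # cross-check the closed form by bisection on g(x) = h(x) - x
  g <- function(x) oneTypeMap(x, params) - x
  root <- stats::uniroot(g, lower = xf / 10, upper = min(10 / b, xf * 10),
                         tol = 1e-12 * xf)$root
  if (abs(root - xf) > 1e-9 * max(1, xf))
    stop("closed-form fixed point disagrees with the bisection root: ",
         format(xf), " vs ", format(root))
  dmag <- abs(1 - a * log(lam))
  # cross-check the analytic derivative by central differences
  hstep <- xf * 1e-6
  dnum <- (oneTypeMap(xf + hstep, params) - oneTypeMap(xf - hstep, params)) /
    (2 * hstep)
  if (abs(abs(dnum) - dmag) > 1e-4 * max(1, dmag))
    stop("analytic derivative magnitude disagrees with central difference: ",
         format(dmag), " vs ", format(abs(dnum)))
  cls <- if (dmag < 1) "stable" else if (dmag > 1) "unstable" else "marginal"
  new("FixedPointReport", location = xf, derivativeMagnitude = dmag,
      classification = cls)
}

#' Detect the period of a deterministic trajectory
#'
#' Empirical period detection: the smallest \eqn{p \le pMax} such that
#' \eqn{|x(t + p) - x(t)| \le tol \cdot \max(1, |x(t)|)} componentwise for
#' every post-burn-in \eqn{t}. A converged trajectory has period 1; an
#' irregular (possibly chaotic) trajectory has no period and `NA_integer_`
#' is returned. This is an empirical search, not a formal chaos
#' diagnostic.
#'
#' @param traj a [DetTrajectory-class] or a numeric vector/matrix of
#'   states.
#' @param burnIn non-negative number of initial generations to discard
#'   before testing (default 100).
#' @param tol positive relative tolerance (default 1e-6).
#' @param pMax largest period searched (default 64).
#' @return the detected period as an integer, or `NA_integer_`.
#' @examples
#' tr <- oneTypeDetTrajectory(1e4, OneTypeParams(1.05, 2, 1e-6), 1000)
#' detectPeriod(tr)  # 1: converged to the stable fixed point
#' @export
detectPeriod <- function(traj, burnIn = 100L, tol = 1e-6, pMax = 64L) {
  states <- if (is(traj, "DetTrajectory")) traj@states else
    as.matrix(traj)
  if (tol <= 0) stop("'tol' must be positive")
  if (burnIn < 0) stop("'burnIn' must be non-negative")
  n <- nrow(states)
  if (n < burnIn + 2L * pMax + 1L)
    stop("trajectory too short: need more than burnIn + 2*pMax states")
  post <- states[(burnIn + 1L):n, , drop = FALSE]
  m <- nrow(post)
  for (p in seq_len(pMax)) {
    a <- post[seq_len(m - p), , drop = FALSE]
    b <- post[(p + 1L):m, , drop = FALSE]
    if (all(abs(b - a) <= tol * pmax(1, abs(a))))
      return(as.integer(p))
  }
  NA_integer_
}

#' One step of the multitype embedded deterministic model
#'
#' The conditional-expectation step of the multitype process: with
#' \eqn{\hat T = \sum_i \hat X_i}, component \eqn{j} of the next state is
#' \eqn{\sum_i \hat X_i \, S_i(\hat T) \, \lambda_i \, \mu_{ij}} — the
#' state vector times the density-dependent mean matrix whose row \eqn{i}
#' is \eqn{S_i(\hat T) \lambda_i (\mu_{i1}, \ldots, \mu_{ik})}. Values are
#' continuous and never rounded. With all \eqn{\beta_i = 0} the recursion
#' is linear with matrix \eqn{A_{ij} = \lambda_i \mu_{ij}}, the mean matrix
#' of the multitype Galton-Watson process.
#'
#' @param state length-k vector of non-negative reals.
#' @param params a [MultitypeParams-class].
#' @return length-k vector of non-negative reals.
#' @examples
#' multitypeDetStep(c(10000, 0, 0), section5Params())
#' @export
multitypeDetStep <- function(state, params) {
  stopifnot(is(params, "MultitypeParams"))
  k <- nGenotypes(params)
  state <- as.numeric(state)
  if (length(state) != k || any(is.na(state)) || any(state < 0))
    stop("'state' must be a length-", k, " vector of non-negative reals")
  total <- sum(state)
  if (total == 0) return(numeric(k))
  s <- exp(-(params@betas * total)^params@alphas)
  out <- as.vector((state * s * params@lambdas) %*% params@mutation@.Data)
  out[out < .UNDERFLOW] <- 0
  out
}

#' Iterate the multitype embedded deterministic model
#'
#' Iterates [multitypeDetStep()] from `x0`. Convergence is flagged when
#' all components' relative change stays below 1e-9 for 10 consecutive
#' generations.
#'
#' @param x0 length-k vector of non-negative reals, not all zero.
#' @param params a [MultitypeParams-class].
#' @param nGenerations positive integer.
#' @return a [DetTrajectory-class].
#' @examples
#' tr <- multitypeDetTrajectory(c(10000, 0, 0), section5Params(), 300)
#' detStates(tr)[151, 3]  # genotype-3 mass at generation 150
#' @export
multitypeDetTrajectory <- function(x0, params, nGenerations) {
  stopifnot(is(params, "MultitypeParams"))
  k <- nGenotypes(params)
  x0 <- as.numeric(x0)
  if (length(x0) != k || any(is.na(x0)) || any(x0 < 0))
    stop("'x0' must be a length-", k, " vector of non-negative reals")
  if (sum(x0) == 0) stop("'x0' must not be all zero")
  if (nGenerations < 1) stop("'nGenerations' must be at least 1")
  n <- as.integer(nGenerations)
  states <- matrix(0, n + 1L, k)
  states[1L, ] <- x <- x0
  lamMu <- params@lambdas * params@mutation@.Data
  betas <- params@betas
  alphas <- params@alphas
  for (t in seq_len(n)) {
    total <- sum(x)
    if (total == 0) break
    s <- exp(-(betas * total)^alphas)
    x <- as.vector((x * s) %*% lamMu)
    x[x < .UNDERFLOW] <- 0
    states[t + 1L, ] <- x
  }
  colnames(states) <- paste0("genotype", seq_len(k))
  new("DetTrajectory", states = states,
      convergedAt = .flagConvergence(states), period = NA_integer_)
}
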