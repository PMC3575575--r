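#' Complete a mutation matrix from its off-diagonal entries
#'
#' Mutation experiments are usually specified by the off-diagonal mutation
#' probabilities only; the diagonal (no-mutation) entries are then
#' determined by the requirement that each row sum to 1. This constructor
#' sets each diagonal entry to 1 minus the row's off-diagonal sum. Any
#' value already present on the diagonal of the input (including `NA`) is
#' ignored.
#'
#' @param offDiagonal square numeric matrix; off-diagonal entries are
#'   mutation probabilities, diagonal entries are ignored.
#' @return a validated [MutationMatrix-class].
#' @examples
#' completeMutationMatrix(matrix(c(NA, 1e-6, 0,
#'                                 1e-12, NA, 1e-14,
#'                                 1e-15, 1e-17, NA), 3, 3, byrow = TRUE))
#' @export
completeMutationMatrix <- function(offDiagonal) {
  m <- as.matrix(offDiagonal)
  if (nrow(m) != ncol(m)) stop("'offDiagonal' must be a square matrix")
  diag(m) <- 0
  if (any(is.na(m)) || any(m < 0) || any(m > 1))
    stop("off-diagonal mutation probabilities must lie in [0, 1]")
  rs <- rowSums(m)
  if (any(rs > 1 + .MUTATION_ROWSUM_TOL)) {
    bad <- which(rs > 1 + .MUTATION_ROWSUM_TOL)[1L]
    stop("off-diagonal probabilities in row ", bad, " sum to ",
         format(rs[bad]), " which exceeds 1")
  }
  diag(m) <- pmax(0, 1 - rs)
  MutationMatrix(m)
}

#' Sample one generation's offspring table
#'
#' Draws the full parent-genotype x offspring-genotype offspring table for
#' one generation. The process definition has each genotype-\eqn{i} parent
#' produce a Poisson(\eqn{\lambda_i}) brood which is split multinomially
#' among offspring genotypes with the mutation row \eqn{p_i}; by Poisson
#' splitting, the aggregated cell counts \eqn{Y_{ij}} are then independent
#' Poisson(\eqn{X_i \lambda_i \mu_{ij}}) variables, which is what this
#' sampler draws — an exact identity, not an approximation.
#'
#' @param pop length-k vector of non-negative integer genotype counts.
#' @param params a [MultitypeParams-class].
#' @param cltThreshold cell mean above which a rounded-normal approximation
#'   is used (opt-in; default `Inf`, exact Poisson sampling).
#' @return an [OffspringTable-class].
#' @seealso [sampleOffspringPerIndividual()] for the per-individual
#'   reference route.
#' @examples
#' p <- section5Params()
#' set.seed(1)
#' sampleOffspring(c(10000, 0, 0), p)
#' @export
sampleOffspring <- function(pop, params, cltThreshold = Inf) {
  stopifnot(is(params, "MultitypeParams"))
  k <- nGenotypes(params)
  pop <- .checkPop(pop, k)
  mu <- pop * params@lambdas * params@mutation@.Data  # (i,j) = X_i lam_i mu_ij
  y <- .rpoisMatrix(mu, cltThreshold)
  new("OffspringTable", byParent = y, byOffspring = colSums(y))
}

# Poisson draws for a matrix of means, with optional normal approximation
# for very large means and an explicit error instead of rpois's silent NA.
.rpoisMatrix <- function(mu, cltThreshold) {
  d <- dim(mu)
  v <- as.vector(mu)
  y <- numeric(length(v))
  big <- v > cltThreshold
  if (any(big)) {
    y[big] <- pmax(0, round(stats::rnorm(sum(big), v[big], sqrt(v[big]))))
    v[big] <- 0
  }
  if (any(v > 2^31))
    stop("offspring mean ", format(max(v)), " exceeds exact-sampling range; ",
         "set 'cltThreshold' to enable the normal approximation")
  small <- !big
  y[small] <- stats::rpois(sum(small), v[small])
  array(y, dim = d)
}

.checkPop <- function(pop, k) {
  pop <- as.numeric(pop)
  if (length(pop) != k)
    stop("'pop' must have one count per genotype (length ", k, ")")
  if (any(is.na(pop)) || any(pop < 0) || any(pop != floor(pop)))
    stop("genotype counts must be non-negative integers")
  pop
}

#' Per-individual reference sampler for the offspring table
#'
#' Samples the offspring table exactly as the process is defined: each
#' parent of genotype \eqn{i} draws an independent Poisson(\eqn{\lambda_i})
#' brood size which is split among offspring genotypes by a multinomial
#' draw with probability row \eqn{p_i} (realised as successive conditional
#' binomials, the standard multinomial decomposition). Distributionally
#' identical to [sampleOffspring()]; kept as an independent route for
#' equivalence tests. Intended for small populations — cost is linear in
#' the number of parents.
#'
#' @inheritParams sampleOffspring
#' @return an [OffspringTable-class].
#' @export
sampleOffspringPerIndividual <- function(pop, params) {
  stopifnot(is(params, "MultitypeParams"))
  k <- nGenotypes(params)
  pop <- .checkPop(pop, k)
  M <- params@mutation@.Data
  y <- matrix(0, k, k)
  for (i in seq_len(k)) {
    ni <- pop[i]
    if (ni == 0) next
    broods <- stats::rpois(ni, params@lambdas[i])
    rem <- broods
    pRem <- 1
    for (j in seq_len(k)) {
      pj <- M[i, j]
      if (j < k) {
        cond <- if (pRem > 0) pj / pRem else 0
        zj <- stats::rbinom(ni, rem, min(1, cond))
        rem <- rem - zj
        pRem <- pRem - pj
      } else {
        zj <- rem
      }
      y[i, j] <- y[i, j] + sum(zj)
    }
  }
  new("OffspringTable", byParent = y, byOffspring = colSums(y))
}

#' Genotype-specific survival probability
#'
#' Survival probability of genotype-`genotype` offspring given the
#' parental-generation total population size:
#' \eqn{S_i(T) = \exp[-(\beta_i T)^{\alpha_i}]}. All genotypes face the
#' same total \eqn{T}, so differing \eqn{\beta_i} model differential
#' ability to compete for the shared resource pool.
#'
#' @param total non-negative total population size \eqn{T(t)}.
#' @param params a [MultitypeParams-class].
#' @param genotype genotype index or indices in `1..k` (default: all).
#' @return survival probabilities in \eqn{[0, 1]}.
#' @examples
#' genotypeSurvival(1e6, section5Params(), 1)  # exp(-1)
#' @export
genotypeSurvival <- function(total, params,
                             genotype = seq_len(nGenotypes(params))) {
  stopifnot(is(params, "MultitypeParams"))
  if (length(total) != 1L || is.na(total) || total < 0)
    stop("'total' must be a single non-negative number")
  k <- nGenotypes(params)
  if (any(genotype < 1) || any(genotype > k))
    stop("'genotype' must be in 1..", k)
  exp(-(params@betas[genotype] * total)^params@alphas[genotype])
}

#' One generation of the multitype self-regulating process
#'
#' Records the parental total \eqn{T(t)}, samples the offspring table, and
#' thins the genotype-\eqn{j} offspring total \eqn{Y_j} with an independent
#' Binomial(\eqn{Y_j}, \eqn{S_j(T(t))}) survival draw. Survival is always
#' evaluated at the parental-generation total, never at the offspring
#' count: offspring compete under the density their parents created.
#'
#' @inheritParams sampleOffspring
#' @return length-k vector of next-generation genotype counts.
#' @examples
#' set.seed(1)
#' stepMultitype(c(10000, 0, 0), section5Params())
#' @export
stepMultitype <- function(pop, params, cltThreshold = Inf) {
  stopifnot(is(params, "MultitypeParams"))
  k <- nGenotypes(params)
  pop <- .checkPop(pop, k)
  total <- sum(pop)
  if (total == 0) return(numeric(k))
  tab <- sampleOffspring(pop, params, cltThreshold = cltThreshold)
  s <- exp(-(params@betas * total)^params@alphas)
  .rbinomVec(tab@byOffspring, s)
}

# rbinom that tolerates sizes above .Machine$integer.max via a normal
# approximation (exact binomial otherwise); sizes that large only arise
# when the CLT offspring path is enabled.
.rbinomVec <- function(size, prob) {
  out <- numeric(length(size))
  big <- size > .Machine$integer.max
  if (any(big)) {
    m <- size[big] * prob[big]
    v <- m * (1 - prob[big])
    out[big] <- pmin(size[big], pmax(0, round(stats::rnorm(sum(big), m, sqrt(v)))))
  }
  sm <- !big
  out[sm] <- stats::rbinom(sum(sm), size[sm], prob[sm])
  out
}

#' Simulate a multitype trajectory
#'
#' Iterates [stepMultitype()] from the initial genotype-count vector `x0`.
#' Extinction of the whole population (total 0) is absorbing. The result is
#' a `(nGenerations + 1) x k` matrix whose row \eqn{t + 1} is the genotype
#' count vector at generation \eqn{t}.
#'
#' @param x0 length-k vector of non-negative integer initial counts, at
#'   least one positive.
#' @param params a [MultitypeParams-class].
#' @param nGenerations positive integer.
#' @param seed optional integer seed (`set.seed` is called when supplied).
#' @param cap hard cap on the total population (default 1e12); exceeding it
#'   aborts with an error.
#' @param cltThreshold passed to the offspring sampler.
#' @return numeric matrix, `nGenerations + 1` rows, one column per genotype.
#' @examples
#' tr <- simulateMultitype(c(10000, 0, 0), section5Params(), 50, seed = 7)
#' tail(tr, 2)
#' @export
simulateMultitype <- function(x0, params, nGenerations, seed = NULL,
                              cap = 1e12, cltThreshold = Inf) {
  stopifnot(is(params, "MultitypeParams"))
  k <- nGenotypes(params)
  x0 <- .checkPop(x0, k)
  if (sum(x0) < 1) stop("'x0' must contain at least one individual")
  if (nGenerations < 1) stop("'nGenerations' must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(nGenerations)
  lamMu <- params@lambdas * params@mutation@.Data
  alphas <- params@alphas
  betas <- params@betas
  out <- matrix(0, n + 1L, k)
  out[1L, ] <- x <- x0
  for (t in seq_len(n)) {
    total <- sum(x)
    if (total == 0) break
    y <- .rpoisMatrix(x * lamMu, cltThreshold)
    x <- .rbinomVec(colSums(y), exp(-(betas * total)^alphas))
    if (sum(x) > cap)
      stop("total population ", format(sum(x)), " exceeded the cap ",
           format(cap), " at generation ", t)
    out[t + 1L, ] <- x
  }
  colnames(out) <- paste0("genotype", seq_len(k))
  out
}
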