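# Two-sample chi-square comparison of two integer-valued samples: bins are
# chosen from the pooled sample so every expected cell count is adequate,
# then a standard chi-square test of homogeneity is applied.
chisqTwoSample <- function(a, b, nBins = 12L) {
  pooled <- c(a, b)
  brks <- unique(stats::quantile(pooled, probs = seq(0, 1, length.out = nBins + 1L),
                                 type = 1))
  brks[1L] <- -Inf
  brks[length(brks)] <- Inf
  ta <- table(cut(a, brks))
  tb <- table(cut(b, brks))
  suppressWarnings(stats::chisq.test(rbind(as.vector(ta), as.vector(tb))))
}

# Joint two-sample chi-square for a pair of integer margins: each margin is
# cut at pooled quartiles and the cross-classification compared.
chisqTwoSampleJoint <- function(a1, a2, b1, b2, nBins = 4L) {
  cutBy <- function(x, pooled) {
    brks <- unique(stats::quantile(pooled, seq(0, 1, length.out = nBins + 1L),
                                   type = 1))
    brks[1L] <- -Inf
    brks[length(brks)] <- Inf
    cut(x, brks)
  }
  p1 <- c(a1, b1)
  p2 <- c(a2, b2)
  ca <- table(interaction(cutBy(a1, p1), cutBy(a2, p2)))
  cb <- table(interaction(cutBy(b1, p1), cutBy(b2, p2)))
  keep <- (ca + cb) > 0
  suppressWarnings(stats::chisq.test(rbind(as.vector(ca[keep]),
                                           as.vector(cb[keep]))))
}

# Small neutral three-genotype model: identical rates, symmetric mutation.
neutralParams <- function(lambda = 1.1, beta = 1e-3, eps = 0.1) {
  M <- matrix(eps / 2, 3, 3)
  diag(M) <- 1 - eps
  MultitypeParams(lambdas = lambda, alphas = 2, betas = beta, mutation = M)
}
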