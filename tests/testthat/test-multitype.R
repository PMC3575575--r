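test_that("mutation matrices are validated and diagonal-completed", {
  expect_s4_class(MutationMatrix(diag(3)), "MutationMatrix")
  expect_error(MutationMatrix(matrix(c(0.5, 0.4, 0.2, 0.8), 2)), "row sums")
  expect_error(MutationMatrix(matrix(c(1.5, -0.5, 0, 1), 2, byrow = TRUE)),
               "\\[0, 1\\]")

  m <- completeMutationMatrix(matrix(c(NA, 1e-6, 0,
                                       1e-12, NA, 1e-14,
                                       1e-15, 1e-17, NA), 3, byrow = TRUE))
  expect_equal(m[1, 1], 1 - 1e-6)
  expect_equal(rowSums(m@.Data), rep(1, 3))

  expect_equal(completeMutationMatrix(matrix(0, 3, 3))@.Data, diag(3))
  expect_error(completeMutationMatrix(matrix(c(NA, 0.6, 0.6,
                                               0, NA, 0,
                                               0, 0, NA), 3, byrow = TRUE)),
               "exceeds 1")
})

test_that("offspring tables conserve counts and respect structure", {
  p <- section5Params()
  zero <- sampleOffspring(c(0, 0, 0), p)
  expect_true(all(zero@byParent == 0))

  pid <- MultitypeParams(c(1.2, 1.2, 1.2), 2, 0, diag(3))
  set.seed(71)
  for (i in 1:20) {
    tab <- sampleOffspring(c(30, 10, 5), pid)
    # identity mutation: no off-diagonal offspring
    expect_true(all(tab@byParent[upper.tri(tab@byParent)] == 0))
    expect_true(all(tab@byParent[lower.tri(tab@byParent)] == 0))
    expect_equal(colSums(tab@byParent), tab@byOffspring)
  }
})

test_that("aggregated Poisson-splitting matches per-individual sampling", {
  M <- matrix(c(0.9, 0.1, 0,
                0, 1, 0,
                0, 0, 1), 3, byrow = TRUE)
  p <- MultitypeParams(c(1.05, 1, 1), 2, 0, M)
  set.seed(81)
  n <- 5e3
  pop <- c(20, 0, 0)
  agg11 <- agg12 <- ind11 <- ind12 <- numeric(n)
  for (i in seq_len(n)) {
    ta <- sampleOffspring(pop, p)
    ti <- sampleOffspringPerIndividual(pop, p)
    agg11[i] <- ta@byParent[1, 1]; agg12[i] <- ta@byParent[1, 2]
    ind11[i] <- ti@byParent[1, 1]; ind12[i] <- ti@byParent[1, 2]
  }
  expect_gt(chisqTwoSampleJoint(agg11, agg12, ind11, ind12)$p.value, 0.01)
})

test_that("genotype survival uses the shared total with per-genotype rates", {
  p <- section5Params()
  expect_equal(genotypeSurvival(1e6, p, 1), exp(-1))
  expect_equal(genotypeSurvival(0, p), rep(1, 3))
  # equal betas/alphas: identical survival for all genotypes
  expect_equal(length(unique(genotypeSurvival(54321, p))), 1L)
  expect_error(genotypeSurvival(100, p, 4), "1..3")
  # differing betas: the better competitor survives more
  p2 <- MultitypeParams(c(1, 1), 2, c(1e-6, 1e-5), diag(2))
  s <- genotypeSurvival(1e5, p2)
  expect_gt(s[1], s[2])
})

test_that("multitype step obeys the expectation-matrix row law", {
  p <- section5Params()
  expect_equal(stepMultitype(c(0, 0, 0), p), c(0, 0, 0))
  set.seed(91)
  n <- 2000
  x1 <- 1e5
  draws <- matrix(0, n, 3)
  for (i in seq_len(n)) draws[i, ] <- stepMultitype(c(x1, 0, 0), p)
  s1 <- genotypeSurvival(x1, p, 1)
  target11 <- x1 * s1 * 1.05 * (1 - 1e-6)
  se <- sd(draws[, 1]) / sqrt(n)
  expect_lt(abs(mean(draws[, 1]) - target11), 3 * se)
  # genotype-2 offspring arise at rate X1 * lambda1 * mu12 before thinning
  target12 <- x1 * s1 * 1.05 * 1e-6
  se2 <- sd(draws[, 2]) / sqrt(n)
  expect_lt(abs(mean(draws[, 2]) - target12), 3 * se2 + 1e-3)
})

test_that("with no regulation and no mutation each genotype is GW", {
  p <- MultitypeParams(c(1.2, 0.8, 1), 2, 0, diag(3))
  set.seed(101)
  n <- 2000
  x0 <- c(50, 50, 50)
  finals <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    tr <- simulateMultitype(x0, p, 5)
    finals[i, ] <- tr[6, ]
  }
  for (g in 1:3) {
    target <- gwMean(50, p@lambdas[g], 5)
    se <- sd(finals[, g]) / sqrt(n)
    expect_lt(abs(mean(finals[, g]) - target), 3 * se)
  }
})

test_that("multitype trajectories have the contracted shape", {
  p <- section5Params()
  tr <- simulateMultitype(c(10000, 0, 0), p, 300, seed = 5)
  expect_equal(dim(tr), c(301L, 3L))
  expect_true(all(tr >= 0) && all(tr == floor(tr)))
  expect_error(simulateMultitype(c(0, 0, 0), p, 10), "at least one")
})

test_that("k = 1 multitype reduces to the one-type process", {
  p1 <- MultitypeParams(1.05, 2, 1e-4, matrix(1))
  pOne <- OneTypeParams(1.05, 2, 1e-4)
  set.seed(111)
  n <- 2000
  mt <- vapply(seq_len(n), function(i) {
    x <- 500
    for (t in 1:5) x <- stepMultitype(x, p1)[1]
    x
  }, numeric(1))
  ot <- vapply(seq_len(n), function(i) {
    x <- 500
    for (t in 1:5) x <- stepOneType(x, pOne)
    x
  }, numeric(1))
  se <- sqrt(var(mt) / n + var(ot) / n)
  expect_lt(abs(mean(mt) - mean(ot)), 3 * se)
  expect_gt(chisqTwoSample(mt, ot)$p.value, 0.01)
})

test_that("neutral symmetric model has exchangeable genotype marginals", {
  p <- neutralParams()
  set.seed(121)
  n <- 1000
  finals <- matrix(0, n, 3)
  for (i in seq_len(n)) finals[i, ] <- simulateMultitype(c(40, 40, 40), p, 10)[11, ]
  for (g in 2:3) {
    se <- sqrt(var(finals[, 1]) / n + var(finals[, g]) / n)
    expect_lt(abs(mean(finals[, 1]) - mean(finals[, g])), 3 * se)
  }
})

test_that("rare-mutation flux matches its expectation", {
  # measurable magnitude: mean genotype-3 offspring = X2 * lambda2 * mu23
  M <- completeMutationMatrix(matrix(c(NA, 1e-6, 0,
                                       1e-12, NA, 1e-6,
                                       1e-15, 1e-17, NA), 3, byrow = TRUE))
  p <- MultitypeParams(c(1.05, 1.05, 1.5), 2, 1e-6, M)
  set.seed(131)
  n <- 2000
  x2 <- 1e6
  y23 <- vapply(seq_len(n), function(i)
    sampleOffspring(c(0, x2, 0), p)@byParent[2, 3], numeric(1))
  target <- x2 * 1.05 * 1e-6
  se <- sd(y23) / sqrt(n)
  expect_lt(abs(mean(y23) - target), 3 * se)

  # at the preset magnitude (mu23 = 1e-14) events are essentially impossible
  p5 <- section5Params()
  y <- vapply(seq_len(1000), function(i)
    sampleOffspring(c(0, 1e6, 0), p5)@byParent[2, 3], numeric(1))
  expect_true(all(y == 0))
})
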