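test_that("the one-type map has the stated closed form and extensions", {
  p <- OneTypeParams(1.05, 2, 1e-6)
  expect_equal(oneTypeMap(0, p), 0)
  expect_equal(oneTypeMap(-5, p), 0)  # continuity extension
  pGW <- OneTypeParams(1.7, 2, 0)
  expect_equal(oneTypeMap(c(1, 10, 100), pGW), 1.7 * c(1, 10, 100))
  xf <- findFixedPoint(p)@location
  expect_equal(oneTypeMap(xf, p), xf, tolerance = 1e-12)
})

test_that("one-type deterministic trajectories converge as the theory says", {
  p <- OneTypeParams(1.05, 2, 1e-6)
  tr <- oneTypeDetTrajectory(1e4, p, 400)
  s <- detStates(tr)[, 1]
  expect_true(all(diff(s) > 0 | abs(diff(s)) < 1e-6))  # monotone approach
  expect_equal(s[401], 2.2088e5, tolerance = 1e-3)
  expect_false(is.na(convergedAt(tr)))

  sub <- oneTypeDetTrajectory(100, OneTypeParams(0.9, 2, 1e-6), 200)
  ss <- detStates(sub)[, 1]
  expect_true(all(diff(ss) < 0 | ss[-1] == 0))
  expect_lt(ss[201], 1e-6)

  # starting exactly at the fixed point stays there
  xf <- findFixedPoint(p)@location
  cons <- oneTypeDetTrajectory(xf, p, 50)
  expect_equal(detStates(cons)[, 1], rep(xf, 51), tolerance = 1e-9)
})

test_that("fixed-point closed form agrees with a root-finding oracle", {
  fp <- findFixedPoint(OneTypeParams(1.05, 2, 1e-6))
  expect_equal(fp@location, 2.2088e5, tolerance = 1e-4)
  expect_equal(fp@derivativeMagnitude, 0.9024, tolerance = 1e-4)
  expect_equal(fp@classification, "stable")
  expect_equal(findFixedPoint(OneTypeParams(1.5, 2, 1e-6))@location,
               6.3676e5, tolerance = 1e-4)
  sub <- findFixedPoint(OneTypeParams(0.9, 2, 1e-6))
  expect_equal(sub@location, 0)
  expect_equal(sub@classification, "stable")

  # independent uniroot oracle across the parameter grid
  for (lam in c(1.2, 2, 5, 10)) {
    for (a in c(0.5, 1, 2, 4)) {
      for (b in c(1e-3, 1e-6)) {
        p <- OneTypeParams(lam, a, b)
        xf <- findFixedPoint(p)@location
        g <- function(x) oneTypeMap(x, p) - x
        oracle <- uniroot(g, lower = xf * 0.2, upper = xf * 5,
                          tol = 1e-13 * xf)$root
        expect_lt(abs(xf - oracle) / oracle, 1e-9)
      }
    }
  }
})

test_that("the stability criterion predicts the fate of nearby iterates", {
  for (lam in c(1.2, 2, 5, 10)) {
    for (a in c(0.5, 1, 2, 4)) {
      for (b in c(1e-3, 1e-6)) {
        p <- OneTypeParams(lam, a, b)
        fp <- findFixedPoint(p)
        if (abs(fp@derivativeMagnitude - 1) < 0.1) next  # marginal, slow
        x <- 1.01 * fp@location
        for (t in 1:3000) x <- oneTypeMap(x, p)
        tail50 <- numeric(50)
        for (t in 1:50) { x <- oneTypeMap(x, p); tail50[t] <- x }
        dev <- max(abs(tail50 - fp@location)) / fp@location
        if (fp@classification == "stable") {
          expect_lt(dev, 1e-6)
        } else {
          expect_gt(dev, 1e-3)
        }
      }
    }
  }
})

test_that("period detection identifies fixed points and oscillations", {
  p <- OneTypeParams(1.05, 2, 1e-6)
  tr <- oneTypeDetTrajectory(1e4, p, 1000)
  # burn-in must clear the transient (contraction ~0.9 per generation)
  expect_identical(detectPeriod(tr, burnIn = 600), 1L)
  expect_identical(detectPeriod(matrix(rep(7, 500), ncol = 1)), 1L)

  # large lambda: unstable fixed point, period >= 2 or irregular
  pu <- OneTypeParams(exp(1.5), 2, 1e-6)
  expect_gt(findFixedPoint(pu)@derivativeMagnitude, 1)
  tru <- oneTypeDetTrajectory(1e4, pu, 10000)
  per <- detectPeriod(tru, burnIn = 5000)
  expect_true(is.na(per) || per >= 2L)

  expect_error(detectPeriod(matrix(1:10, ncol = 1)), "too short")
})

test_that("multitype deterministic step reduces and linearises correctly", {
  p <- section5Params()
  expect_equal(multitypeDetStep(c(0, 0, 0), p), c(0, 0, 0))

  # k = 1 equals the one-type map
  p1 <- MultitypeParams(1.3, 2, 1e-5, matrix(1))
  pOne <- OneTypeParams(1.3, 2, 1e-5)
  for (x in c(1, 100, 1e4, 1e5))
    expect_equal(multitypeDetStep(x, p1), oneTypeMap(x, pOne))

  # betas 0: linear recursion with matrix A = diag(lambda) %*% M
  M <- matrix(c(0.9, 0.1, 0, 0.05, 0.9, 0.05, 0, 0.2, 0.8), 3, byrow = TRUE)
  pl <- MultitypeParams(c(1.2, 0.9, 1.5), 2, 0, M)
  x <- c(10, 20, 30)
  A <- diag(c(1.2, 0.9, 1.5)) %*% M
  expect_equal(multitypeDetStep(x, pl), as.vector(x %*% A))
})

test_that("one deterministic step equals the stochastic conditional mean", {
  p <- section5Params()
  set.seed(141)
  for (state in list(c(1e4, 0, 0), c(1e5, 100, 0), c(2e5, 50, 10))) {
    n <- 3000
    draws <- matrix(0, n, 3)
    for (i in seq_len(n)) draws[i, ] <- stepMultitype(state, p)
    target <- multitypeDetStep(state, p)
    for (g in 1:3) {
      se <- sd(draws[, g]) / sqrt(n)
      # the additive slack covers targets far below one individual (the
      # genotype-3 mean can be ~1e-12), where every draw is exactly 0
      expect_lt(abs(mean(draws[, g]) - target[g]), 3 * se + 1e-6)
    }
  }
})

test_that("deterministic trajectories are scale-equivariant in beta", {
  p <- OneTypeParams(1.3, 2, 1e-4)
  pScaled <- OneTypeParams(1.3, 2, 1e-4 / 4)  # c = 4, exact in binary
  x <- c(1, 17, 1000, 54321)
  expect_identical(oneTypeMap(4 * x, pScaled), 4 * oneTypeMap(x, p))
  t1 <- detStates(oneTypeDetTrajectory(100, p, 200))
  t2 <- detStates(oneTypeDetTrajectory(400, pScaled, 200))
  expect_identical(t2, 4 * t1)
})

test_that("the preset deterministic run shows the genotype-3 takeover", {
  tr <- multitypeDetTrajectory(c(10000, 0, 0), section5Params(), 300)
  s <- detStates(tr)
  expect_gt(s[151, 3], 6e5)
  expect_gte(max(s[, 1]), 2e5)
  expect_lt(max(s[, 2]), 50)
  expect_false(is.na(convergedAt(tr)))
  expect_error(multitypeDetTrajectory(c(0, 0, 0), section5Params(), 10),
               "all zero")
})
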