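test_that("replicate seeds are distinct, in range and reproducible", {
  s <- replicateSeed(101, 1:10000)
  expect_false(any(duplicated(s)))
  expect_true(all(s >= 0 & s < 2^31))
  expect_identical(replicateSeed(101, 5), replicateSeed(101, 5))
  expect_error(replicateSeed(101, 0), "positive")
})

test_that("ensembles are bit-reproducible and seed-sensitive", {
  p <- section5Params()
  e1 <- runEnsemble(c(10000, 0, 0), p, 30, 5, masterSeed = 7)
  e2 <- runEnsemble(c(10000, 0, 0), p, 30, 5, masterSeed = 7)
  expect_identical(counts(e1), counts(e2))
  e3 <- runEnsemble(c(10000, 0, 0), p, 30, 5, masterSeed = 8)
  expect_false(identical(counts(e1), counts(e3)))
  expect_equal(nReplicates(e1), 5L)
  expect_equal(nGenerations(e1), 30L)
  expect_equal(nGenotypes(e1), 3L)
})

test_that("per-replicate substreams behave independently", {
  p <- MultitypeParams(1, 2, 0, matrix(1))
  ens <- runEnsemble(50, p, 1, 1000, masterSeed = 3)
  g1 <- counts(ens)[, 2, 1]
  ct <- cor.test(g1[seq(1, 999, 2)], g1[seq(2, 1000, 2)])
  expect_gt(ct$p.value, 0.01)
})

test_that("quantile trajectories interpolate order statistics correctly", {
  p <- neutralParams()
  # hand-built ensemble: replicate r holds constant count r for genotype 1
  arr <- array(0, c(3, 4, 3))
  for (r in 1:3) arr[r, , 1] <- r
  ens <- new("BranchingEnsemble", counts = arr, params = p,
             x0 = c(1, 0, 0), masterSeed = 1L, seedDerivation = "manual")
  q <- quantileTrajectories(ens, levels = c(0.25, 0.5, 0.75))
  expect_equal(q@values[, 1, 2], rep(2, 4))  # Q50 of {1,2,3}
  expect_equal(q@values[, 1, 1], rep(1.5, 4))  # type-7 interpolation

  # all replicates identical: every quantile equals the common trajectory
  tr <- simulateMultitype(c(100, 0, 0), p, 10, seed = 4)
  arr2 <- array(0, c(5, 11, 3))
  for (r in 1:5) arr2[r, , ] <- tr
  ens2 <- new("BranchingEnsemble", counts = arr2, params = p,
              x0 = c(100, 0, 0), masterSeed = 1L, seedDerivation = "manual")
  q2 <- quantileTrajectories(ens2)
  for (l in seq_along(q2@levels))
    expect_equal(q2@values[, , l], unname(tr))
})

test_that("quantiles are monotone in level on simulated ensembles", {
  ens <- runEnsemble(c(200, 0, 0), neutralParams(), 20, 40, masterSeed = 9)
  q <- quantileTrajectories(ens)
  v <- q@values
  for (l in 2:dim(v)[3])
    expect_true(all(v[, , l] >= v[, , l - 1]))
})

test_that("extinct replicates shift quantiles exactly when present", {
  p <- MultitypeParams(0.5, 2, 1e-3, matrix(1))  # subcritical
  ens <- runEnsemble(1, p, 20, 200, masterSeed = 11)
  ext <- extinctionProbability(ens, 20)
  expect_gt(ext$estimate, 0.9)
  qIn <- quantileTrajectories(ens, levels = 0.9, includeExtinct = TRUE)
  qEx <- quantileTrajectories(ens, levels = 0.9, includeExtinct = FALSE)
  gen <- 3  # some replicates extinct, some alive
  expect_false(isTRUE(all.equal(qIn@values[gen, , ], qEx@values[gen, , ])))
  expect_gte(qEx@values[gen, 1, 1], qIn@values[gen, 1, 1])
})

test_that("first appearance reports initial presence, arrival and absence", {
  p <- neutralParams(eps = 0.4)
  ens <- runEnsemble(c(50, 0, 0), p, 10, 20, masterSeed = 13)
  expect_true(all(firstAppearance(ens, 1) == 0L))
  fa2 <- firstAppearance(ens, 2)
  expect_true(all(fa2[!is.na(fa2)] >= 1))

  # unreachable genotype: no inflow and absent initially
  M <- matrix(c(1, 0, 0, 0, 1, 0, 0, 0, 1), 3)
  pUnreach <- MultitypeParams(c(1.1, 1, 1), 2, 1e-3, M)
  ens2 <- runEnsemble(c(50, 0, 0), pUnreach, 10, 20, masterSeed = 14)
  expect_true(all(is.na(firstAppearance(ens2, 3))))
})

test_that("extinction probability has the trivial endpoints", {
  p <- MultitypeParams(5, 2, 1e-3, matrix(1))  # strongly supercritical
  ens <- runEnsemble(100, p, 5, 30, masterSeed = 15)
  expect_equal(extinctionProbability(ens, 0)$estimate, 0)
  pDead <- MultitypeParams(0.1, 2, 1e-3, matrix(1))
  ens2 <- runEnsemble(1, pDead, 40, 30, masterSeed = 16)
  expect_equal(extinctionProbability(ens2, 40)$estimate, 1)
  expect_error(extinctionProbability(ens, 99), "0..5")
})

test_that("the DET-vs-Q50 report flags exactly the right rows", {
  p <- neutralParams()
  arr <- array(5, c(4, 11, 3))
  ens <- new("BranchingEnsemble", counts = arr, params = p,
             x0 = c(5, 5, 5), masterSeed = 1L, seedDerivation = "manual")
  q <- quantileTrajectories(ens)
  det <- new("DetTrajectory", states = matrix(5, 11, 3),
             convergedAt = 1L, period = NA_integer_)
  rep0 <- detVsStochasticReport(det, q)
  expect_true(all(rep0$absGap == 0))
  expect_false(any(rep0$outsideBand))

  detFar <- new("DetTrajectory", states = matrix(50, 11, 3),
                convergedAt = 1L, period = NA_integer_)
  repFar <- detVsStochasticReport(detFar, q)
  expect_true(all(repFar$outsideBand))
  expect_true(all(repFar$absGap == 45))

  detBad <- new("DetTrajectory", states = matrix(5, 7, 3),
                convergedAt = 1L, period = NA_integer_)
  expect_error(detVsStochasticReport(detBad, q), "mismatched")
})
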