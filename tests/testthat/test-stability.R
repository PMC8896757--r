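test_that("featurize counts match a brute-force tally and conserve length", {
  s <- TESequence("p", c(4, 5), c(2, 2))
  rec <- featurize(s)
  expect_equal(unlist(rec[paste0("n", 1:8)]),
    c(0, 0, 0, 1, 1, 0, 0, 0),
    ignore_attr = TRUE
  )
  expect_equal(unlist(rec[paste0("d", 1:8)]), c(0, 2, rep(0, 6)),
    ignore_attr = TRUE
  )
  expect_identical(rec$length, 2L)

  r <- randomTESequence(200, 31)
  rec <- featurize(r)
  tally <- vapply(1:8, function(k) sum(nativeLabels(r) == k), 0)
  expect_equal(unlist(rec[paste0("n", 1:8)]), tally, ignore_attr = TRUE)

  set.seed(32)
  perm <- sample.int(200)
  rPerm <- TESequence("p", nativeLabels(r)[perm], denaturedLabels(r)[perm])
  expect_equal(featurize(rPerm)[-1], featurize(r)[-1], ignore_attr = TRUE)
})

test_that("predictDG evaluates the additive model exactly", {
  s <- randomTESequence(60, 33)
  rec <- featurize(s)
  # all-zero weights with Z = 1: no entropic penalty, prediction 0
  expect_equal(predictDG(rec, StabilityModel(rep(0, 8), rep(0, 8), 1)), 0)
  # unit native weights, Z = 1: counts sum to the length
  expect_equal(
    predictDG(rec, StabilityModel(rep(1, 8), rep(0, 8), 1)), 60
  )
  # random model vs a hand-expanded 17-term sum
  set.seed(34)
  m <- StabilityModel(rnorm(8), rnorm(8), Z = exp(runif(1, 0, 3)))
  manual <- 0
  for (i in 1:8) manual <- manual + m@wNative[i] * rec[[paste0("n", i)]]
  for (j in 1:8) manual <- manual + m@wDenatured[j] * rec[[paste0("d", j)]]
  manual <- manual - rec$length * 0.0083145 * 298.15 * log(m@Z)
  expect_equal(predictDG(rec, m), manual, tolerance = 1e-12)
  expect_error(StabilityModel(rep(0, 8), rep(0, 8), Z = -2), "positive")
})

test_that("RT and the Z = 20 per-residue penalty take their closed forms", {
  k <- thermoConstants()
  expect_equal(k$R * k$T, 2.4790, tolerance = 1e-3)
  expect_equal(k$R * k$T * log(20), 7.43, tolerance = 0.01)
})

test_that("predictions are linear in counts and add over concatenation", {
  a <- featurize(randomTESequence(40, 35, "a"))
  b <- featurize(randomTESequence(25, 36, "b"))
  ab <- a
  for (col in c(paste0("n", 1:8), paste0("d", 1:8), "length")) {
    ab[[col]] <- a[[col]] + b[[col]]
  }
  m <- defaultStabilityTruth()
  expect_equal(
    predictDG(ab, m), predictDG(a, m) + predictDG(b, m),
    tolerance = 1e-10
  )
})

test_that("the gauge transformation changes no prediction", {
  rec <- genStabilityRecords(n = 20, seed = 37)
  m <- defaultStabilityTruth()
  for (shift in list(c(1, 0), c(0, -2), c(3.7, 1.3))) {
    m2 <- gaugeTransform(m, shift[1], shift[2])
    expect_lt(max(abs(predictDG(rec, m2) - predictDG(rec, m))), 1e-9)
  }
})

test_that("noiseless synthetic records are fit back exactly", {
  rec <- genStabilityRecords(n = 12, noiseSD = 0, seed = 38)
  fit <- fitStabilityModel(rec, seed = 39)
  expect_lt(max(abs(predictDG(rec, fit) - rec$dG_exp)), 1e-6)
  # deterministic given the seed
  fit2 <- fitStabilityModel(rec, seed = 39)
  expect_identical(nativeWeights(fit), nativeWeights(fit2))
  expect_identical(zParameter(fit), zParameter(fit2))
  expect_error(fitStabilityModel(rec[1:2, ]), "at least 3")
})

test_that("gauge fixing zeroes the weight-block means, predictions intact", {
  rec <- genStabilityRecords(n = 12, noiseSD = 0, seed = 38)
  free <- fitStabilityModel(rec, seed = 40)
  pinned <- fitStabilityModel(rec, seed = 40, gauge = TRUE)
  expect_equal(mean(nativeWeights(pinned)), 0, tolerance = 1e-9)
  expect_equal(mean(denaturedWeights(pinned)), 0, tolerance = 1e-9)
  expect_lt(max(abs(predictDG(rec, pinned) - predictDG(rec, free))), 1e-6)
})

test_that("noisy fits generalize with held-out RMSE near the noise floor", {
  sigma <- 2
  train <- genStabilityRecords(n = 35, noiseSD = sigma, seed = 41)
  test <- genStabilityRecords(n = 60, noiseSD = sigma, seed = 42)
  fit <- fitStabilityModel(train, seed = 43)
  rmse <- sqrt(mean((predictDG(test, fit) - test$dG_exp)^2))
  expect_gte(rmse, sigma / 2)
  expect_lte(rmse, 2 * sigma)
})

test_that("leave-one-out bookkeeping is exact and noiseless folds agree", {
  # n - 1 training records must exceed the 15 identifiable weight directions
  # for held-out predictions to be pinned by the data
  rec <- genStabilityRecords(n = 20, noiseSD = 0, seed = 44)
  loo <- looBootstrap(rec, seed = 45)
  expect_length(loo$models, 20L)
  expect_identical(loo$heldout$fold, 1:20)
  # each fold excludes its record: refitting without it must match the
  # fold's held-out prediction
  expect_lt(max(abs(loo$heldout$dG_pred - rec$dG_exp)), 1e-4)
  zs <- vapply(loo$models, zParameter, 0)
  expect_gte(zParameter(loo$average), min(zs))
  expect_lte(zParameter(loo$average), max(zs))
  expect_error(looBootstrap(rec[1:3, ]), "at least 4")
})

test_that("classification separates synthetic structured from disordered", {
  expect_identical(classifyStructured(c(-20, 5)), c("structured", "disordered"))
  train <- genStabilityRecords(n = 35, noiseSD = 2, seed = 46)
  fit <- fitStabilityModel(train, seed = 47)
  test <- genStabilityRecords(n = 100, noiseSD = 2, lengthMatched = TRUE,
    seed = 48
  )
  # pairs share lengths
  expect_identical(test$length[seq(1, 99, 2)], test$length[seq(2, 100, 2)])
  pred <- classifyStructured(predictDG(test, fit))
  acc <- mean(pred == test$class)
  expect_lt(
    binom.test(sum(pred == test$class), 100, 0.5, "greater")$p.value, 0.01
  )
  expect_gt(acc, 0.7)
})
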