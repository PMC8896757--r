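test_that("proteome frequencies pool residue counts, not protein means", {
  one <- proteomeTEFrequencies(
    list(TESequence("p1", c(4, 4, 5, 5), c(1, 1, 1, 1))),
    list(organism_id = "o1", kingdom = "bacteria")
  )
  expect_equal(
    teFrequencies(one)[1, ], c(0, 0, 0, .5, .5, 0, 0, 0),
    ignore_attr = TRUE
  )

  # lengths 1 and 3: pooled result weights residues 1:3
  two <- proteomeTEFrequencies(
    list(
      TESequence("p1", 1, 1),
      TESequence("p2", c(2, 2, 2), c(2, 2, 2))
    ),
    list(organism_id = "o2", kingdom = "archaea")
  )
  expect_equal(
    teFrequencies(two)[1, ], c(1, 3, 0, 0, 0, 0, 0, 0) / 4,
    ignore_attr = TRUE
  )
  # the per-protein alternative averages the two compositions instead
  twoMean <- proteomeTEFrequencies(
    list(
      TESequence("p1", 1, 1),
      TESequence("p2", c(2, 2, 2), c(2, 2, 2))
    ),
    list(organism_id = "o2", kingdom = "archaea"),
    perProtein = TRUE
  )
  expect_equal(
    teFrequencies(twoMean)[1, ], c(.5, .5, 0, 0, 0, 0, 0, 0),
    ignore_attr = TRUE
  )

  # pooled count check against a brute-force tally over random proteins
  seqs <- lapply(1:5, function(i) randomTESequence(10 * i, 100 + i, paste0("p", i)))
  prof <- proteomeTEFrequencies(seqs,
    list(organism_id = "o3", kingdom = "eukaryote")
  )
  all <- unlist(lapply(seqs, nativeLabels))
  expect_equal(
    teFrequencies(prof)[1, ], tabulate(all, 8) / length(all),
    ignore_attr = TRUE
  )
  expect_equal(sum(teFrequencies(prof)), 1, tolerance = 1e-12)
  expect_error(
    proteomeTEFrequencies(list(), list(organism_id = "x", kingdom = "bacteria")),
    "empty"
  )
})

test_that("UPGMA matches closed forms and the textbook oracle", {
  # n = 2: single join; patristic distance = the Euclidean distance, each
  # leaf at half that height
  p2 <- randomProfiles(2, seed = 1)
  tr2 <- upgmaCluster(p2)
  d <- dist(teFrequencies(p2))
  expect_equal(as.numeric(ape::cophenetic.phylo(tr2)[1, 2]),
    as.numeric(d),
    tolerance = 1e-12
  )
  expect_equal(tr2$edge.length, rep(as.numeric(d) / 2, 2), tolerance = 1e-12)

  # identical pair joins first at height 0
  f <- teFrequencies(randomProfiles(2, seed = 2))
  p3 <- ProteomeProfiles(rbind(f, f[1, ]), data.frame(
    organism_id = c("a", "b", "adup"), kingdom = "bacteria"
  ))
  coph3 <- ape::cophenetic.phylo(upgmaCluster(p3))
  expect_equal(coph3["a", "adup"], 0, tolerance = 1e-12)

  # 6 random profiles vs the quadratic-time oracle
  p6 <- randomProfiles(6, seed = 3)
  coph <- ape::cophenetic.phylo(upgmaCluster(p6))
  D <- as.matrix(dist(teFrequencies(p6)))
  oracle <- upgmaOracleCophenetic(D)
  expect_equal(coph[rownames(oracle), colnames(oracle)], oracle,
    tolerance = 1e-9
  )

  expect_error(
    ProteomeProfiles(f, data.frame(
      organism_id = c("a", "a"), kingdom = "bacteria"
    )),
    "duplicate"
  )
})

test_that("UPGMA trees are ultrametric over all leaf triples", {
  p <- randomProfiles(10, seed = 4)
  coph <- ape::cophenetic.phylo(upgmaCluster(p))
  n <- nrow(coph)
  for (i in 1:(n - 2)) {
    for (j in (i + 1):(n - 1)) {
      for (k in (j + 1):n) {
        trio <- sort(c(coph[i, j], coph[i, k], coph[j, k]), decreasing = TRUE)
        expect_lt(trio[1] - trio[2], 1e-9)
      }
    }
  }
})

test_that("PCA matches an explicit covariance eigensolve", {
  p <- randomProfiles(20, seed = 5)
  pca <- pcaDecompose(p)
  x <- teFrequencies(p)
  xc <- scale(x, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(xc) / (nrow(x) - 1), symmetric = TRUE)
  expect_equal(
    explainedVariance(pca), ev$values / sum(ev$values),
    tolerance = 1e-9
  )
  # loadings agree up to sign with the eigenvectors
  for (i in 1:7) {
    expect_equal(abs(sum(pcaLoadings(pca)[, i] * ev$vectors[, i])), 1,
      tolerance = 1e-8
    )
  }
  # sign convention: largest-magnitude entry positive
  for (i in 1:8) {
    l <- pcaLoadings(pca)[, i]
    expect_gte(l[which.max(abs(l))], 0)
  }
  # completeness and reconstruction with all components retained
  expect_equal(sum(explainedVariance(pca)), 1, tolerance = 1e-9)
  expect_lt(max(abs(pcaReconstruct(pca) - x)), 1e-8)
  # compositional closure leaves (at least) one near-zero eigenvalue
  expect_lt(explainedVariance(pca)[8], 1e-12)
})

test_that("PCA handles rank-1 variation and rejects constant input", {
  base <- rep(1 / 8, 8)
  dir <- c(3, -1, -1, -1, 0, 0, 0, 0) / 8
  freq <- t(vapply(seq(-0.1, 0.1, length.out = 6), function(a) base + a * dir,
    numeric(8)
  ))
  p <- ProteomeProfiles(freq, data.frame(
    organism_id = letters[1:6], kingdom = "bacteria"
  ))
  pca <- pcaDecompose(p, nComponents = 2)
  expect_equal(explainedVariance(pca)[1], 1, tolerance = 1e-9)
  u <- dir / sqrt(sum(dir^2))
  expect_equal(abs(sum(pcaLoadings(pca)[, 1] * u)), 1, tolerance = 1e-8)

  same <- ProteomeProfiles(matrix(base, 4, 8, byrow = TRUE), data.frame(
    organism_id = letters[1:4], kingdom = "bacteria"
  ))
  expect_error(pcaDecompose(same), "variance")
})

test_that("fractionMostStable defaults to TE8 and honors the stable set", {
  f <- rbind(c(rep(0, 7), 1), rep(1 / 8, 8))
  p <- ProteomeProfiles(f, data.frame(
    organism_id = c("a", "b"), kingdom = "bacteria"
  ))
  expect_equal(fractionMostStable(p), c(1, 0.125), ignore_attr = TRUE)
  expect_equal(fractionMostStable(p, c(7, 8)), c(1, 0.25),
    ignore_attr = TRUE
  )
})

test_that("a noiseless linear trait regresses with |r| = 1", {
  p <- randomProfiles(30, seed = 6)
  pca <- pcaDecompose(p)
  tempTrait <- 10 + 2.5 * pcaScores(pca)[, 1]
  p2 <- ProteomeProfiles(teFrequencies(p), within(organismMeta(p), {
    growth_temp <- tempTrait
  }))
  r <- regressPCTrait(pcaDecompose(p2), p2, "growth_temp", 1)
  expect_equal(r$pearson_r, 1, tolerance = 1e-9)
  expect_equal(r$slope, 2.5, tolerance = 1e-9)
  expect_lt(r$p_value, 1e-20)
})

test_that("null trait regressions are calibrated and slopes recovered", {
  # type-I error of the zero-slope test at alpha = 0.05
  nrep <- 300L
  rejections <- 0L
  set.seed(77)
  for (i in seq_len(nrep)) {
    n <- 100L
    freq <- t(vapply(seq_len(n), function(.) {
      g <- rgamma(8, 2)
      g / sum(g)
    }, numeric(8)))
    p <- ProteomeProfiles(freq, data.frame(
      organism_id = sprintf("o%03d", 1:n), kingdom = "bacteria",
      growth_temp = rnorm(n)
    ))
    r <- regressPCTrait(pcaDecompose(p, nComponents = 2), p, "growth_temp", 1)
    if (r$p_value < 0.05) rejections <- rejections + 1L
  }
  expect_gt(rejections / nrep, 0.02)
  expect_lt(rejections / nrep, 0.09)

  # planted slope recovered within 3 standard errors
  set.seed(88)
  p <- randomProfiles(100, seed = 8)
  pca <- pcaDecompose(p)
  y <- 5 + 0.4 * pcaScores(pca)[, 1] + rnorm(100, 0, 0.05)
  p2 <- ProteomeProfiles(teFrequencies(p), within(organismMeta(p), {
    growth_temp <- y
  }))
  r <- regressPCTrait(pcaDecompose(p2), p2, "growth_temp", 1)
  expect_lt(abs(r$slope - 0.4), 3 * r$slope_se)
})

test_that("organisms missing the trait are dropped and counted", {
  p <- randomProfiles(10, seed = 9, growth_temp = c(rnorm(7), NA, NA, NA))
  r <- regressPCTrait(pcaDecompose(p), p, "growth_temp", 1)
  expect_identical(r$n, 7L)
  expect_identical(r$n_dropped, 3L)
  pAllNA <- randomProfiles(10, seed = 10)
  expect_error(
    regressPCTrait(pcaDecompose(pAllNA), pAllNA, "growth_temp", 1),
    "missing"
  )
})

test_that("kingdom slope interaction test has power and holds its level", {
  simKingdoms <- function(slopeB, slopeE, n = 100L, noise = 0.5) {
    x <- rnorm(2L * n)
    kingdom <- rep(c("bacteria", "eukaryote"), each = n)
    slope <- ifelse(kingdom == "bacteria", slopeB, slopeE)
    y <- slope * x + rnorm(2L * n, 0, noise)
    # embed the score directly: frequencies vary along one direction
    dir <- c(1, -1, 0, 0, 0, 0, 0, 0) / 50
    freq <- matrix(rep(1 / 8, 8), 2L * n, 8, byrow = TRUE) +
      outer(x / max(abs(x)), dir)
    freq <- freq / rowSums(freq)
    p <- ProteomeProfiles(freq, data.frame(
      organism_id = sprintf("o%04d", seq_len(2L * n)), kingdom = kingdom,
      growth_temp = y
    ))
    kingdomSlopeTest(pcaDecompose(p, nComponents = 2), p, "growth_temp", 1)
  }
  set.seed(123)
  nullHits <- sum(vapply(1:100, function(i) {
    simKingdoms(1, 1)$interaction_p_value < 0.05
  }, TRUE))
  expect_lte(nullHits, 10L) # level held in >= 90% of replicates

  powerHits <- sum(vapply(1:100, function(i) {
    simKingdoms(1, 0.2)$interaction_p_value < 0.05
  }, TRUE))
  expect_gte(powerHits, 90L)

  oneKing <- randomProfiles(10, seed = 11,
    kingdoms = rep("bacteria", 10), growth_temp = rnorm(10)
  )
  expect_error(
    kingdomSlopeTest(pcaDecompose(oneKing), oneKing, "growth_temp", 1),
    "one kingdom"
  )
})
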