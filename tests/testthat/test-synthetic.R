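test_that("generated center tables honor separation and ordering", {
  for (sep in c(5, 10, 25)) {
    ctrs <- genCenterTable(separation = sep)
    expect_true(validObject(ctrs))
    # exhaustive pairwise weighted-Manhattan separation
    for (state in c("native", "denatured")) {
      m <- slot(ctrs, state)
      w <- if (state == "native") c(1, 1, 1, 3) else c(1, 1, 1, 1)
      for (i in 1:7) {
        for (j in (i + 1):8) {
          expect_gte(sum(w * abs(m[i, ] - m[j, ])), sep - 1e-9)
        }
      }
    }
    expect_true(all(diff(nativeCenters(ctrs)[, 1]) < 0))
  }
  expect_error(genCenterTable(0), "positive")
})

test_that("descriptor generation is seeded and recovers truth", {
  ctrs <- genCenterTable()
  a <- genProteinTD(50, ctrs, seed = 61)
  b <- genProteinTD(50, ctrs, seed = 61)
  expect_identical(a$td@native, b$td@native)
  expect_identical(nativeLabels(a$truth), nativeLabels(b$truth))

  # zero scatter: assignment recovers truth exactly
  g0 <- genProteinTD(500, ctrs, scatterSD = 0, seed = 62)
  te0 <- annotateProtein(g0$td, ctrs)
  expect_identical(nativeLabels(te0), nativeLabels(g0$truth))
  expect_identical(denaturedLabels(te0), denaturedLabels(g0$truth))

  # scatter at a tenth of the separation: >= 99% recovery over 1e4 residues
  g <- genProteinTD(10000, ctrs, scatterSD = 1, seed = 63)
  te <- annotateProtein(g$td, ctrs)
  expect_gte(mean(nativeLabels(te) == nativeLabels(g$truth)), 0.99)
  expect_gte(mean(denaturedLabels(te) == denaturedLabels(g$truth)), 0.99)
})

test_that("proteome sets are deterministic with coherent ground truth", {
  s1 <- genProteomeSet(nPerKingdom = 2, nProteins = 3,
    lengthRange = c(30, 50), seed = 64
  )
  s2 <- genProteomeSet(nPerKingdom = 2, nProteins = 3,
    lengthRange = c(30, 50), seed = 64
  )
  expect_identical(s1$meta, s2$meta)
  expect_identical(
    s1$organisms[[1]]$tdTables[[1]]@native,
    s2$organisms[[1]]$tdTables[[1]]@native
  )
  expect_identical(names(s1$organisms), s1$meta$organism_id)
  expect_setequal(unique(s1$meta$kingdom),
    c("bacteria", "archaea", "eukaryote")
  )
  expect_true(all(s1$meta$disorder_fraction >= 0 &
    s1$meta$disorder_fraction <= 1))
  for (org in s1$organisms) {
    expect_equal(sum(org$targetFreq), 1, tolerance = 1e-12)
    expect_length(org$tdTables, 3L)
  }
})

test_that("zero trait noise makes the planted disorder axis near-perfect", {
  ctrs <- genCenterTable()
  set <- genProteomeSet(
    nPerKingdom = 12, nProteins = 8, lengthRange = c(60, 120),
    traitNoise = c(growth_temp = 0, disorder_fraction = 0),
    centers = ctrs, seed = 65
  )
  profs <- combineProfiles(lapply(names(set$organisms), function(o) {
    seqs <- lapply(set$organisms[[o]]$tdTables, annotateProtein,
      centers = ctrs
    )
    proteomeTEFrequencies(seqs, set$meta[set$meta$organism_id == o, ])
  }))
  pca <- pcaDecompose(profs)
  r <- regressPCTrait(pca, profs, "disorder_fraction", 1)
  expect_gt(abs(r$pearson_r), 0.9)
  # the planted slope couples disorder positively to the stability contrast;
  # the recovered association must carry that sign on the aligned axis
  stabAxis <- sum(pcaLoadings(pca)[, 1] * (((1:8) - 4.5) / 3.5))
  expect_equal(sign(r$slope * stabAxis), 1)
})

test_that("ss-label generation is seeded and independence is calibrated", {
  te <- rep(1:8, 100)
  a <- genSSLabels(te, seed = 66)
  b <- genSSLabels(te, seed = 66)
  expect_identical(a$codes, b$codes)

  # all-zero planted matrix: chi-square p-values roughly uniform
  set.seed(67)
  flat <- matrix(0, 4, 8)
  pvals <- vapply(1:40, function(i) {
    te <- sample.int(8, 4000, replace = TRUE)
    ss <- genSSLabels(te, enrichment = flat)
    suppressWarnings(chisq.test(table(ss$classes, te))$p.value)
  }, 0)
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("non-normalizable planted patterns are rejected", {
  E <- matrix(NA_real_, 4, 8)
  E[1, ] <- 2 # helix enriched e^2-fold everywhere: row mass > 1
  te <- rep(1:8, 50)
  expect_error(genSSLabels(te, enrichment = E), "non-normalizable")
})

test_that("stability records generator is seeded and respects its truth", {
  r1 <- genStabilityRecords(n = 10, seed = 68)
  r2 <- genStabilityRecords(n = 10, seed = 68)
  expect_identical(r1$dG_exp, r2$dG_exp)
  expect_true(all(rowSums(r1[paste0("n", 1:8)]) == r1$length))
  expect_true(all(rowSums(r1[paste0("d", 1:8)]) == r1$length))
  # zero noise: stored dG equals the generating model's prediction
  r0 <- genStabilityRecords(n = 10, noiseSD = 0, seed = 69)
  expect_equal(r0$dG_exp, predictDG(r0, attr(r0, "truth")), tolerance = 1e-10)
})
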