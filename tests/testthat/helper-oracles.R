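# Independent oracles, coded from the definitions, never from package
# internals.

# exhaustive weighted-Manhattan nearest center; ties to the lowest index
bruteAssign <- function(td, centers, weights) {
  d <- vapply(seq_len(nrow(centers)), function(k) {
    sum(weights * abs(centers[k, ] - td))
  }, 0)
  which.min(d)
}

# textbook quadratic-time UPGMA: returns the cophenetic matrix under the
# convention that two leaves' cophenetic distance is the average pairwise
# distance between the two clusters at their merge
upgmaOracleCophenetic <- function(D) {
  n <- nrow(D)
  labels <- rownames(D)
  clusters <- as.list(seq_len(n))
  sizes <- rep(1L, n)
  act <- rep(TRUE, n)
  W <- D
  coph <- matrix(0, n, n, dimnames = list(labels, labels))
  for (step in seq_len(n - 1L)) {
    best <- c(NA, NA)
    bestD <- Inf
    ids <- which(act)
    for (a in seq_along(ids)) {
      for (b in seq_len(a - 1L)) {
        i <- ids[b]; j <- ids[a]
        if (W[i, j] < bestD) {
          bestD <- W[i, j]
          best <- c(i, j)
        }
      }
    }
    i <- best[1L]; j <- best[2L]
    for (x in clusters[[i]]) {
      for (y in clusters[[j]]) {
        coph[x, y] <- coph[y, x] <- bestD
      }
    }
    for (k in which(act)) {
      if (k != i && k != j) {
        W[i, k] <- W[k, i] <-
          (sizes[i] * W[i, k] + sizes[j] * W[j, k]) / (sizes[i] + sizes[j])
      }
    }
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    act[j] <- FALSE
  }
  coph
}

# profiles built directly from Dirichlet frequency draws (no protein
# sampling), for decomposition/regression tests
randomProfiles <- function(n, seed, kingdoms = NULL, alpha = rep(2, 8),
                           growth_temp = NA_real_,
                           disorder_fraction = NA_real_) {
  set.seed(seed)
  freq <- t(vapply(seq_len(n), function(i) {
    g <- rgamma(8, shape = alpha)
    g / sum(g)
  }, numeric(8)))
  if (is.null(kingdoms)) {
    kingdoms <- rep(c("bacteria", "archaea", "eukaryote"), length.out = n)
  }
  ProteomeProfiles(freq, data.frame(
    organism_id = sprintf("org%03d", seq_len(n)),
    kingdom = kingdoms,
    growth_temp = growth_temp,
    disorder_fraction = disorder_fraction
  ))
}

randomTESequence <- function(L, seed, id = "p") {
  set.seed(seed)
  TESequence(id, sample.int(8, L, replace = TRUE),
    sample.int(8, L, replace = TRUE)
  )
}
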