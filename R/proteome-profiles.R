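#' Summarize a proteome as a TE frequency profile
#'
#' Pools the residue-level TE counts of all proteins of one organism and
#' divides by the total residue count (a pooled frequency, not a mean of
#' per-protein frequencies; set `perProtein = TRUE` for the alternative).
#'
#' @param teSeqs list of [TESequence-class] objects (>= 1 protein).
#' @param meta single-row data.frame or list with `organism_id`, `kingdom`
#'   and optional `growth_temp`, `disorder_fraction`.
#' @param denatured include the denatured-track frequencies too.
#' @param perProtein average per-protein frequency vectors instead of
#'   pooling counts.
#' @return A one-organism [ProteomeProfiles-class].
#' @examples
#' seqs <- list(TESequence("p1", c(4, 4, 5, 5), c(2, 2, 2, 2)))
#' prof <- proteomeTEFrequencies(seqs, list(organism_id = "o1",
#'   kingdom = "bacteria"))
#' teFrequencies(prof)
#' @export
proteomeTEFrequencies <- function(teSeqs, meta, denatured = TRUE,
                                  perProtein = FALSE) {
  if (length(teSeqs) == 0L) stop("empty proteome", call. = FALSE)
  stopifnot(all(vapply(teSeqs, is, TRUE, "TESequence")))
  counts <- lapply(teSeqs, teCounts)
  natM <- do.call(rbind, lapply(counts, `[[`, "native"))
  denM <- do.call(rbind, lapply(counts, `[[`, "denatured"))
  toFreq <- function(m) {
    if (perProtein) {
      colMeans(m / rowSums(m))
    } else {
      colSums(m) / sum(m)
    }
  }
  meta <- as.list(meta)
  metaRow <- data.frame(
    organism_id = as.character(meta$organism_id),
    kingdom = tolower(as.character(meta$kingdom)),
    growth_temp = if (is.null(meta$growth_temp)) NA_real_ else
      as.numeric(meta$growth_temp),
    disorder_fraction = if (is.null(meta$disorder_fraction)) NA_real_ else
      as.numeric(meta$disorder_fraction),
    stringsAsFactors = FALSE
  )
  new("ProteomeProfiles",
    freq = matrix(toFreq(natM), 1L, 8L,
      dimnames = list(metaRow$organism_id, NULL)
    ),
    denaturedFreq = if (denatured) {
      matrix(toFreq(denM), 1L, 8L, dimnames = list(metaRow$organism_id, NULL))
    } else {
      NULL
    },
    nProteins = length(teSeqs),
    nResidues = as.integer(sum(natM)),
    meta = metaRow
  )
}

#' Combine per-organism profiles into one object
#'
#' @param ... [ProteomeProfiles-class] objects, or a single list of them.
#' @return A stacked [ProteomeProfiles-class].
#' @export
combineProfiles <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1L]]) && !is(xs[[1L]], "ProteomeProfiles")) {
    xs <- xs[[1L]]
  }
  stopifnot(length(xs) >= 1L, all(vapply(xs, is, TRUE, "ProteomeProfiles")))
  den <- lapply(xs, slot, "denaturedFreq")
  haveDen <- !vapply(den, is.null, TRUE)
  new("ProteomeProfiles",
    freq = do.call(rbind, lapply(xs, slot, "freq")),
    denaturedFreq = if (all(haveDen)) do.call(rbind, den) else NULL,
    nProteins = unlist(lapply(xs, slot, "nProteins")),
    nResidues = unlist(lapply(xs, slot, "nResidues")),
    meta = do.call(rbind, lapply(xs, slot, "meta"))
  )
}

#' UPGMA clustering of proteome TE profiles
#'
#' Agglomerative average-linkage (UPGMA) clustering of the native TE
#' frequency vectors under Euclidean distance. The returned tree is rooted
#' and ultrametric; node heights follow the convention that a node sits at
#' half the average pairwise distance between the clusters it joins, so the
#' patristic (cophenetic) distance between two leaves equals the UPGMA
#' average distance between their clusters.
#'
#' @param profiles a [ProteomeProfiles-class] with >= 2 organisms.
#' @return An [ape::phylo] tree with one tip per organism, serializable with
#'   [ape::write.tree()].
#' @export
upgmaCluster <- function(profiles) {
  stopifnot(is(profiles, "ProteomeProfiles"))
  validObject(profiles)
  if (nrow(profiles@freq) < 2L) {
    stop("UPGMA needs at least two proteomes", call. = FALSE)
  }
  if (anyDuplicated(profiles@meta$organism_id)) {
    stop("duplicate organism_id", call. = FALSE)
  }
  m <- profiles@freq
  rownames(m) <- profiles@meta$organism_id
  hc <- hclust(dist(m, method = "euclidean"), method = "average")
  ape::as.phylo(hc)
}

#' Principal component decomposition of TE frequency profiles
#'
#' Mean-centered (not variance-scaled) PCA of the native TE frequency matrix,
#' optionally with the denatured frequencies appended as eight further
#' columns. Because frequencies sum to one, the covariance is rank-deficient
#' (rank <= 7 per state); the trailing near-zero eigenvalue is retained as-is.
#' Loading signs follow the convention that each component's largest-magnitude
#' entry is positive.
#'
#' @param profiles a [ProteomeProfiles-class] with >= 3 organisms.
#' @param states `"native"` (8 columns) or `"both"` (16 columns; requires
#'   denatured frequencies).
#' @param nComponents components to retain; default all `min(n - 1, p)`.
#' @return A [TEPCA-class] object.
#' @export
pcaDecompose <- function(profiles, states = c("native", "both"),
                         nComponents = NULL) {
  stopifnot(is(profiles, "ProteomeProfiles"))
  states <- match.arg(states)
  x <- profiles@freq
  if (states == "both") {
    if (is.null(profiles@denaturedFreq)) {
      stop("profiles carry no denatured frequencies", call. = FALSE)
    }
    x <- cbind(x, profiles@denaturedFreq)
  }
  n <- nrow(x)
  if (n < 3L) stop("PCA needs at least three proteomes", call. = FALSE)
  if (sum(apply(x, 2L, var)) <= 1e-20) {
    stop("zero total variance: all profiles are identical", call. = FALSE)
  }
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  k <- if (is.null(nComponents)) {
    min(n - 1L, length(pc$sdev))
  } else {
    as.integer(nComponents)
  }
  if (k > length(pc$sdev) || k > n - 1L) {
    stop("cannot retain more components than min(n - 1, p)", call. = FALSE)
  }
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  sco <- pc$x[, seq_len(k), drop = FALSE]
  for (i in seq_len(k)) {
    if (load[which.max(abs(load[, i])), i] < 0) {
      load[, i] <- -load[, i]
      sco[, i] <- -sco[, i]
    }
  }
  rownames(sco) <- profiles@meta$organism_id
  new("TEPCA",
    loadings = unname(load) * 1, explainedVarianceRatio = evr[seq_len(k)],
    center = unname(pc$center), scores = sco, states = states
  )
}

#' Reconstruct (centered) profiles from a TEPCA
#'
#' @param pca a [TEPCA-class].
#' @return The reconstructed data matrix `scores %*% t(loadings) + center`,
#'   exact when all components were retained.
#' @export
pcaReconstruct <- function(pca) {
  stopifnot(is(pca, "TEPCA"))
  sweep(pca@scores %*% t(pca@loadings), 2L, pca@center, `+`)
}

#' Fraction of a proteome in the most stable environments
#'
#' By default the native TE8 frequency; the set of environments counted as
#' "most stable" is configurable (e.g. `c(7, 8)`).
#'
#' @param profiles a [ProteomeProfiles-class].
#' @param stableSet integer TE indices to sum, default `8`.
#' @return Numeric vector, one fraction per organism.
#' @examples
#' # uniform usage gives 1/8 for the default set
#' @export
fractionMostStable <- function(profiles, stableSet = 8L) {
  stopifnot(is(profiles, "ProteomeProfiles"))
  stableSet <- as.integer(stableSet)
  stopifnot(all(stableSet >= 1L), all(stableSet <= 8L))
  rowSums(profiles@freq[, stableSet, drop = FALSE])
}

.traitVector <- function(profiles, trait) {
  switch(trait,
    growth_temp = profiles@meta$growth_temp,
    disorder_fraction = profiles@meta$disorder_fraction,
    fraction_most_stable = fractionMostStable(profiles),
    stop("unknown trait: ", trait, call. = FALSE)
  )
}

#' Regress an organism trait on a principal component
#'
#' Ordinary least squares of the trait on the scores of one component.
#' Organisms missing the trait are dropped and counted.
#'
#' @param pca a [TEPCA-class] computed from `profiles`.
#' @param profiles the matching [ProteomeProfiles-class].
#' @param trait `"growth_temp"`, `"disorder_fraction"` or
#'   `"fraction_most_stable"`.
#' @param pcIndex which component (1-based).
#' @return List with `slope` (trait units per score unit), `intercept`,
#'   `pearson_r`, `p_value` (two-sided, zero slope), `slope_se`, `n` used and
#'   `n_dropped`.
#' @export
regressPCTrait <- function(pca, profiles,
                           trait = c(
                             "growth_temp", "disorder_fraction",
                             "fraction_most_stable"
                           ),
                           pcIndex = 1L) {
  stopifnot(is(pca, "TEPCA"), is(profiles, "ProteomeProfiles"))
  trait <- match.arg(trait)
  y <- .traitVector(profiles, trait)
  x <- pca@scores[, pcIndex]
  keep <- !is.na(y)
  if (sum(keep) == 0L) stop("trait '", trait, "' missing for every organism",
    call. = FALSE
  )
  if (sum(keep) < 3L) {
    stop("need at least three organisms with trait '", trait, "'",
      call. = FALSE
    )
  }
  fit <- lm(y[keep] ~ x[keep])
  # noiseless traits are legitimate input; silence the perfect-fit warning
  sm <- suppressWarnings(summary(fit))
  list(
    trait = trait, pcIndex = as.integer(pcIndex),
    slope = unname(coef(fit)[2L]),
    intercept = unname(coef(fit)[1L]),
    slope_se = sm$coefficients[2L, 2L],
    pearson_r = unname(cor(x[keep], y[keep])),
    p_value = sm$coefficients[2L, 4L],
    n = sum(keep), n_dropped = sum(!keep)
  )
}

#' Test for kingdom-specific trait slopes
#'
#' ANCOVA with a full kingdom-by-score interaction: the trait is regressed on
#' the component score, kingdom, and their interaction; the interaction
#' p-value (F test against the additive model) asks whether any kingdom's
#' slope differs. Per-kingdom slopes are reported alongside.
#'
#' @inheritParams regressPCTrait
#' @return List with `interaction_p_value`, named `slopes` and `slope_se`
#'   per kingdom, and `n` per kingdom.
#' @export
kingdomSlopeTest <- function(pca, profiles,
                             trait = c(
                               "growth_temp", "disorder_fraction",
                               "fraction_most_stable"
                             ),
                             pcIndex = 1L) {
  stopifnot(is(pca, "TEPCA"), is(profiles, "ProteomeProfiles"))
  trait <- match.arg(trait)
  y <- .traitVector(profiles, trait)
  x <- pca@scores[, pcIndex]
  king <- profiles@meta$kingdom
  keep <- !is.na(y) & !is.na(king)
  d <- data.frame(y = y[keep], x = x[keep], kingdom = factor(king[keep]))
  tabk <- table(d$kingdom)
  if (nlevels(d$kingdom) < 2L) {
    stop(
      "only one kingdom present; use regressPCTrait() for a single-group fit",
      call. = FALSE
    )
  }
  if (any(tabk < 3L)) {
    stop("each kingdom needs at least three trait-bearing organisms",
      call. = FALSE
    )
  }
  full <- lm(y ~ x * kingdom, data = d)
  reduced <- lm(y ~ x + kingdom, data = d)
  pInt <- anova(reduced, full)[2L, "Pr(>F)"]
  slopes <- vapply(levels(d$kingdom), function(kg) {
    unname(coef(lm(y ~ x, data = d[d$kingdom == kg, ]))[2L])
  }, 0)
  slopeSE <- vapply(levels(d$kingdom), function(kg) {
    summary(lm(y ~ x, data = d[d$kingdom == kg, ]))$coefficients[2L, 2L]
  }, 0)
  list(
    trait = trait, pcIndex = as.integer(pcIndex),
    interaction_p_value = pInt,
    slopes = slopes, slope_se = slopeSE,
    n = as.integer(tabk)
  )
}
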