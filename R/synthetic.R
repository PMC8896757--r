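## Synthetic-data generators. Every upstream input of the pipeline
## (descriptor tables, cluster centers, proteome sets with organism traits,
## secondary-structure labels, stability records) can be generated with
## known ground truth, fully determined by a seed, so that each analysis
## stage has a recovery test that needs no external downloads.

# stability contrast over the TE ladder, scaled to [-1, 1]
.TE_STABILITY_CONTRAST <- ((1:8) - 4.5) / 3.5

# alternating "fine structure" contrast (a hydrophobicity-like axis
# orthogonal to the stability ladder)
.TE_ALT_CONTRAST <- rep(c(-1, 1), 4L)

# background TE usage: peaked at the median-stability environments TE4/TE5,
# rarest at the extremes TE1/TE8 (roughly the universal usage shape)
.TE_BASE_COMPOSITION <- c(0.04, 0.09, 0.16, 0.21, 0.21, 0.16, 0.09, 0.04)

.dirichlet <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

.tiltComposition <- function(base, stabilityTilt, altTilt) {
  m <- base * exp(
    stabilityTilt * .TE_STABILITY_CONTRAST + altTilt * .TE_ALT_CONTRAST
  )
  m / sum(m)
}

#' Generate a synthetic TE cluster-center table
#'
#' Builds a deterministic ladder of eight native and eight denatured centers
#' whose native mean dG is strictly decreasing with the environment index
#' (TE1 least stable, TE8 most stable) and whose pairwise separation under
#' the assignment metric is at least `separation`. Adjacent centers differ
#' mostly in dG with smaller enthalpy offsets; the native entropy column is
#' flat so that its triple metric weight does not amplify scatter.
#'
#' @param separation minimum pairwise weighted-Manhattan distance between
#'   centers of the same state, kJ/mol; default 10.
#' @param nativeWeights,denaturedWeights metric weights, defaults
#'   `c(1, 1, 1, 3)` and `c(1, 1, 1, 1)`.
#' @return A [TECenters-class] object.
#' @examples
#' genCenterTable()
#' @export
genCenterTable <- function(separation = 10,
                           nativeWeights = c(1, 1, 1, 3),
                           denaturedWeights = c(1, 1, 1, 1)) {
  if (!is.finite(separation) || separation <= 0) {
    stop("'separation' must be a positive distance in kJ/mol", call. = FALSE)
  }
  # per-step displacement; |dir| weighted by the metric sums to 1, so each
  # ladder step moves exactly `separation` in the weighted metric
  dirN <- c(-0.7, 0.15, -0.15, 0)
  dirD <- c(-0.6, 0.2, 0.1, 0.1)
  scaleDir <- function(dir, w) dir / sum(w * abs(dir))
  dirN <- scaleDir(dirN, nativeWeights)
  dirD <- scaleDir(dirD, denaturedWeights)
  steps <- (0:7)
  nat <- t(vapply(steps, function(s) {
    c(5, -25, -18, 12) + s * separation * dirN
  }, numeric(4L)))
  den <- t(vapply(steps, function(s) {
    c(8, -15, -12, 20) + s * separation * dirD
  }, numeric(4L)))
  TECenters(nat, den,
    nativeWeights = nativeWeights, denaturedWeights = denaturedWeights
  )
}

#' Generate a synthetic per-residue descriptor table with known TE truth
#'
#' Each residue's native (denatured) 4-vector is its true environment's
#' center plus isotropic Gaussian scatter of standard deviation `scatterSD`
#' kJ/mol per component.
#'
#' @param length protein length (>= 1).
#' @param centers a [TECenters-class]; default [genCenterTable()].
#' @param trueNative,trueDenatured optional true label vectors (1..8); drawn
#'   uniformly when NULL.
#' @param scatterSD Gaussian scatter, kJ/mol; default 1.
#' @param proteinId identifier for the generated protein.
#' @param seed optional integer seed (the caller's RNG stream is restored).
#' @return List with `td` (a [TDTable-class]) and `truth` (the generating
#'   [TESequence-class]).
#' @export
genProteinTD <- function(length, centers = genCenterTable(),
                         trueNative = NULL, trueDenatured = NULL,
                         scatterSD = 1, proteinId = "synthetic",
                         seed = NULL) {
  stopifnot(length >= 1L, scatterSD >= 0)
  L <- as.integer(length)
  .withSeed(seed, {
    if (is.null(trueNative)) trueNative <- sample.int(8L, L, replace = TRUE)
    if (is.null(trueDenatured)) {
      trueDenatured <- sample.int(8L, L, replace = TRUE)
    }
    truth <- TESequence(proteinId, trueNative, trueDenatured)
    nat <- centers@native[truth@nativeLabels, , drop = FALSE] +
      matrix(rnorm(4L * L, 0, scatterSD), L, 4L)
    den <- centers@denatured[truth@denaturedLabels, , drop = FALSE] +
      matrix(rnorm(4L * L, 0, scatterSD), L, 4L)
    aa <- sample(names(kyteDoolittle()), L, replace = TRUE)
    list(td = TDTable(proteinId, aa, nat, den), truth = truth)
  })
}

#' Generate a synthetic multi-kingdom proteome set with planted traits
#'
#' Each organism's native TE usage target is drawn from its kingdom's
#' Dirichlet distribution (base composition peaked at TE4/TE5, tilted along
#' a stability contrast for bacteria vs eukaryotes and along an alternating
#' contrast for archaea); proteins are sampled to match and emitted as
#' descriptor tables. Growth temperature is planted as a linear function of
#' the alternating contrast of the organism's target composition, and
#' disorder fraction as a linear function of the stability contrast, each
#' plus Gaussian noise; the planted slopes are returned as ground truth.
#'
#' @param nPerKingdom organisms per kingdom, default 30.
#' @param kingdoms kingdoms to simulate.
#' @param nProteins proteins per organism, default 20.
#' @param lengthRange protein length range, default `c(80, 200)`.
#' @param precision Dirichlet concentration (larger = tighter kingdoms),
#'   default 400.
#' @param stabilityTilts named log-tilts along the stability contrast.
#' @param altTilts named log-tilts along the alternating contrast.
#' @param traitSlopes planted slopes: growth temp in degrees C per unit of
#'   alternating contrast; disorder per unit of stability contrast.
#' @param traitNoise Gaussian noise sd for the two traits.
#' @param centers a [TECenters-class] used for descriptor generation.
#' @param scatterSD descriptor scatter, kJ/mol.
#' @param seed integer seed.
#' @return List with `organisms` (per organism: `tdTables`, `truth` TE
#'   sequences, `targetFreq`), `meta` (metadata data.frame) and
#'   `groundTruth` (kingdom compositions, contrasts and planted slopes).
#' @export
genProteomeSet <- function(nPerKingdom = 30L, kingdoms = .KINGDOMS,
                           nProteins = 20L, lengthRange = c(80L, 200L),
                           precision = 400,
                           stabilityTilts = c(
                             bacteria = -0.8, archaea = 0, eukaryote = 0.8
                           ),
                           altTilts = c(
                             bacteria = 0, archaea = 0.35, eukaryote = 0
                           ),
                           traitSlopes = c(
                             growth_temp = 60, disorder_fraction = 0.35
                           ),
                           traitNoise = c(
                             growth_temp = 4, disorder_fraction = 0.03
                           ),
                           centers = genCenterTable(), scatterSD = 1,
                           seed = 1L) {
  stopifnot(all(kingdoms %in% .KINGDOMS), nPerKingdom >= 1L)
  kingMeans <- lapply(kingdoms, function(kg) {
    .tiltComposition(.TE_BASE_COMPOSITION, stabilityTilts[[kg]], altTilts[[kg]])
  })
  names(kingMeans) <- kingdoms
  .withSeed(seed, {
    organisms <- list()
    metaRows <- list()
    idx <- 0L
    for (kg in kingdoms) {
      for (i in seq_len(nPerKingdom)) {
        idx <- idx + 1L
        orgId <- sprintf("%s_%02d", substr(kg, 1L, 3L), i)
        p <- .dirichlet(precision * kingMeans[[kg]])
        lens <- sample(lengthRange[1L]:lengthRange[2L], nProteins,
          replace = TRUE
        )
        tdTables <- vector("list", nProteins)
        truths <- vector("list", nProteins)
        for (j in seq_len(nProteins)) {
          nat <- sample.int(8L, lens[j], replace = TRUE, prob = p)
          den <- sample.int(8L, lens[j], replace = TRUE,
            prob = .TE_BASE_COMPOSITION
          )
          g <- genProteinTD(lens[j],
            centers = centers, trueNative = nat,
            trueDenatured = den, scatterSD = scatterSD,
            proteinId = sprintf("%s_p%03d", orgId, j)
          )
          tdTables[[j]] <- g$td
          truths[[j]] <- g$truth
        }
        altScore <- sum(p * .TE_ALT_CONTRAST)
        stabScore <- sum(p * .TE_STABILITY_CONTRAST)
        gt <- 20 + traitSlopes[["growth_temp"]] * altScore +
          rnorm(1L, 0, traitNoise[["growth_temp"]])
        disf <- 0.25 + traitSlopes[["disorder_fraction"]] * stabScore +
          rnorm(1L, 0, traitNoise[["disorder_fraction"]])
        disf <- min(max(disf, 0), 1)
        organisms[[orgId]] <- list(
          tdTables = tdTables, truth = truths, targetFreq = p
        )
        metaRows[[orgId]] <- data.frame(
          organism_id = orgId, kingdom = kg, growth_temp = gt,
          disorder_fraction = disf, stringsAsFactors = FALSE
        )
      }
    }
    list(
      organisms = organisms,
      meta = do.call(rbind, c(metaRows, list(make.row.names = FALSE))),
      groundTruth = list(
        kingdomCompositions = kingMeans,
        stabilityContrast = .TE_STABILITY_CONTRAST,
        altContrast = .TE_ALT_CONTRAST,
        traitSlopes = traitSlopes, traitNoise = traitNoise,
        traitIntercepts = c(growth_temp = 20, disorder_fraction = 0.25)
      )
    )
  })
}

#' Default planted secondary-structure enrichment pattern
#'
#' Helix enriched (log-odds +0.5) in the two most stable native TEs and
#' depleted (-0.5) in the two least stable; coil the mirror image. NA cells
#' are free: the generator adjusts them to keep the construction exactly
#' consistent with the planted cells.
#'
#' @return 4 x 8 matrix of planted log-odds with NA for free cells.
#' @export
defaultPlantedEnrichment <- function() {
  m <- matrix(NA_real_, 4L, 8L,
    dimnames = list(.SS_CLASSES, paste0("TE", 1:8))
  )
  m["helix", c(1L, 2L)] <- -0.5
  m["helix", c(7L, 8L)] <- 0.5
  m["coil", c(1L, 2L)] <- 0.5
  m["coil", c(7L, 8L)] <- -0.5
  m
}

# Solve for per-residue class conditionals P(j | k) such that
#   ln[ P(j|k) / P'(j) ] equals the planted value exactly at every planted
# cell, where P'(j) is the realized class marginal under the TE frequencies
# q, and free (NA) cells share row/column compensation factors. Returns the
# conditional matrix and the full realized score matrix.
.plantedConditionals <- function(E, q, baseProbs, maxIter = 1000L,
                                 tol = 1e-13) {
  planted <- !is.na(E)
  use <- q > 0
  alpha <- numeric(4L)
  beta <- numeric(8L)
  expE <- ifelse(planted, exp(E), 0)
  for (it in seq_len(maxIter)) {
    old <- c(alpha, beta)
    for (j in 1:4) {
      freeK <- which(!planted[j, ] & use)
      if (!length(freeK)) next
      sPl <- sum(q[planted[j, ] & use] * expE[j, planted[j, ] & use])
      if (sPl >= 1) {
        stop("planted enrichment row '", .SS_CLASSES[j],
          "' is non-normalizable (planted mass >= 1)",
          call. = FALSE
        )
      }
      alpha[j] <- log((1 - sPl) / sum(q[freeK] * exp(beta[freeK])))
    }
    for (k in which(use)) {
      freeJ <- which(!planted[, k])
      if (!length(freeJ)) next
      sPl <- sum(baseProbs[planted[, k]] * expE[planted[, k], k])
      if (sPl >= 1) {
        stop("planted enrichment column TE", k,
          " is non-normalizable (planted mass >= 1)",
          call. = FALSE
        )
      }
      beta[k] <- log((1 - sPl) / sum(baseProbs[freeJ] * exp(alpha[freeJ])))
    }
    if (max(abs(c(alpha, beta) - old)) < tol) break
  }
  scores <- matrix(NA_real_, 4L, 8L,
    dimnames = list(.SS_CLASSES, paste0("TE", 1:8))
  )
  cond <- matrix(0, 4L, 8L, dimnames = dimnames(scores))
  for (k in which(use)) {
    s <- ifelse(planted[, k], E[, k], alpha + beta[k])
    pk <- baseProbs * exp(s)
    if (abs(sum(pk) - 1) > 1e-8) {
      stop("planted enrichment pattern is infeasible: column TE", k,
        " cannot be normalized consistently with the planted scores",
        call. = FALSE
      )
    }
    cond[, k] <- pk / sum(pk)
    scores[, k] <- s
  }
  # realized class marginals equal baseProbs by construction; verify
  marg <- as.numeric(cond[, use, drop = FALSE] %*% q[use])
  if (max(abs(marg - baseProbs)) > 1e-8) {
    stop("planted enrichment pattern is infeasible for these TE frequencies",
      call. = FALSE
    )
  }
  list(cond = cond, scores = scores)
}

#' Generate secondary-structure labels with planted TE enrichment
#'
#' Samples a DSSP code for every residue of a TE sequence so that the
#' class-vs-TE log-odds matrix of the generating distribution matches the
#' planted values exactly (free NA cells absorb the compensation needed to
#' keep the construction consistent; the full realized score matrix is
#' returned as ground truth).
#'
#' @param teSeq a [TESequence-class], or an integer vector of native TE
#'   labels.
#' @param enrichment 4 x 8 planted log-odds matrix with NA for free cells;
#'   default [defaultPlantedEnrichment()]. An all-zero matrix yields
#'   class/TE independence.
#' @param baseClassProbs length-4 class marginals (helix, strand, turn,
#'   coil); default `c(0.35, 0.22, 0.12, 0.31)`.
#' @param seed optional integer seed.
#' @return List with `codes` (DSSP characters), `classes` (factor),
#'   `trueScores` (the realized 4 x 8 log-odds matrix of the generating
#'   distribution; NA for TEs absent from the input) and `conditionals`.
#' @export
genSSLabels <- function(teSeq, enrichment = defaultPlantedEnrichment(),
                        baseClassProbs = c(0.35, 0.22, 0.12, 0.31),
                        seed = NULL) {
  te <- if (is(teSeq, "TESequence")) teSeq@nativeLabels else as.integer(teSeq)
  stopifnot(all(te >= 1L), all(te <= 8L))
  if (abs(sum(baseClassProbs) - 1) > 1e-9 || any(baseClassProbs <= 0)) {
    stop("'baseClassProbs' must be positive and sum to 1", call. = FALSE)
  }
  q <- tabulate(te, nbins = 8L) / length(te)
  sol <- .plantedConditionals(as.matrix(enrichment), q, baseClassProbs)
  codeSets <- list(
    helix = c(H = 0.7, G = 0.2, I = 0.1),
    strand = c(E = 0.85, B = 0.15),
    turn = c(T = 0.5, S = 0.5),
    coil = c(`-` = 1)
  )
  .withSeed(seed, {
    classes <- integer(length(te))
    for (k in which(q > 0)) {
      idx <- which(te == k)
      classes[idx] <- sample.int(4L, length(idx),
        replace = TRUE, prob = sol$cond[, k]
      )
    }
    codes <- character(length(te))
    for (j in 1:4) {
      idx <- which(classes == j)
      cs <- codeSets[[j]]
      codes[idx] <- sample(names(cs), length(idx),
        replace = TRUE, prob = cs
      )
    }
    list(
      codes = codes,
      classes = factor(.SS_CLASSES[classes], levels = .SS_CLASSES),
      trueScores = sol$scores,
      conditionals = sol$cond
    )
  })
}

#' Default ground-truth stability model for synthetic records
#'
#' Flat denatured weights, a native weight ladder that rewards the stable
#' environments, and Z = 20 unfolded conformations per residue; chosen so a
#' typical structured composition nets a realistic two-state stability of a
#' few tenths of a kJ/mol per residue.
#'
#' @return A [StabilityModel-class].
#' @export
defaultStabilityTruth <- function() {
  StabilityModel(
    wNative = c(2, 1.5, 1, 0.5, 0, -1, -2, -3),
    wDenatured = rep(7.7, 8L),
    Z = 20
  )
}

#' Generate synthetic stability records
#'
#' Native TE compositions are drawn from class-specific Dirichlet
#' distributions (structured enriched toward the stable end of the ladder,
#' disordered toward the unstable end); denatured compositions from the
#' background shape. Experimental stabilities are the additive-model
#' predictions under `truth` plus Gaussian noise.
#'
#' @param n number of records; must be even when `lengthMatched`.
#' @param truth generating [StabilityModel-class].
#' @param noiseSD Gaussian noise on dG_exp, kJ/mol; default 2.
#' @param lengthRange protein length range, default `c(50, 400)`.
#' @param classes per-record class labels; default all `"structured"`, or
#'   alternating structured/disordered pairs when `lengthMatched`.
#' @param lengthMatched generate structured/disordered pairs of identical
#'   length (for discrimination experiments).
#' @param classTilt log-tilt of the class compositions along the stability
#'   contrast, default 0.9.
#' @param precision Dirichlet concentration for per-protein compositions.
#' @param seed integer seed.
#' @return data.frame of records (see [featurize()]) with attribute
#'   `"truth"` carrying the generating model.
#' @export
genStabilityRecords <- function(n = 35L, truth = defaultStabilityTruth(),
                                noiseSD = 2, lengthRange = c(50L, 400L),
                                classes = NULL, lengthMatched = FALSE,
                                classTilt = 0.9, precision = 50,
                                seed = 1L) {
  stopifnot(n >= 1L)
  if (lengthMatched && n %% 2L != 0L) {
    stop("'n' must be even for length-matched pairs", call. = FALSE)
  }
  if (is.null(classes)) {
    classes <- if (lengthMatched) {
      rep(c("structured", "disordered"), n / 2L)
    } else {
      rep("structured", n)
    }
  }
  stopifnot(length(classes) == n,
    all(classes %in% c("structured", "disordered"))
  )
  mClass <- list(
    structured = .tiltComposition(.TE_BASE_COMPOSITION, classTilt, 0),
    disordered = .tiltComposition(.TE_BASE_COMPOSITION, -classTilt, 0)
  )
  .withSeed(seed, {
    lens <- sample(lengthRange[1L]:lengthRange[2L], n, replace = TRUE)
    if (lengthMatched) {
      lens[seq(2L, n, 2L)] <- lens[seq(1L, n, 2L)]
    }
    rows <- lapply(seq_len(n), function(i) {
      p <- .dirichlet(precision * mClass[[classes[i]]])
      natC <- as.integer(rmultinom(1L, lens[i], p))
      denC <- as.integer(rmultinom(1L, lens[i], .TE_BASE_COMPOSITION))
      rec <- data.frame(
        protein_id = sprintf("%s_%03d", substr(classes[i], 1L, 4L), i),
        matrix(natC, 1L), matrix(denC, 1L),
        length = lens[i], dG_exp = NA_real_, class = classes[i],
        stringsAsFactors = FALSE
      )
      names(rec) <- .RECORD_COLS
      rec
    })
    records <- do.call(rbind, rows)
    records$dG_exp <- predictDG(records, truth) + rnorm(n, 0, noiseSD)
    attr(records, "truth") <- truth
    records
  })
}
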