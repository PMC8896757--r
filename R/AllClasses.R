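setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' TECenters: the cluster centers defining the TE alphabet
#'
#' Holds the eight native-state and eight denatured-state cluster centers in
#' thermodynamic-descriptor space, together with the per-term weights of the
#' Manhattan assignment metric. Native centers are ordered by mean stability:
#' TE1 has the least negative mean \eqn{\Delta G} (least stable), TE8 the most
#' negative (most stable). The native metric triple-weights the conformational
#' entropy term by default; the denatured metric uses unit weights.
#'
#' @slot native 8 x 4 numeric matrix of native centers (kJ/mol), columns
#'   `dG`, `dHap`, `dHpol`, `TdS`.
#' @slot denatured 8 x 4 numeric matrix of denatured centers (kJ/mol).
#' @slot nativeWeights nonnegative length-4 weights, default `c(1, 1, 1, 3)`.
#' @slot denaturedWeights nonnegative length-4 weights, default `c(1, 1, 1, 1)`.
#' @exportClass TECenters
setClass("TECenters",
  representation(
    native = "matrix",
    denatured = "matrix",
    nativeWeights = "numeric",
    denaturedWeights = "numeric"
  )
)

setValidity("TECenters", function(object) {
  msg <- character()
  for (nm in c("native", "denatured")) {
    m <- slot(object, nm)
    if (!all(dim(m) == c(8L, 4L))) {
      msg <- c(msg, sprintf("'%s' centers must be an 8 x 4 matrix", nm))
    } else if (!all(is.finite(m))) {
      msg <- c(msg, sprintf("'%s' centers must be finite", nm))
    }
  }
  for (nm in c("nativeWeights", "denaturedWeights")) {
    w <- slot(object, nm)
    if (length(w) != 4L || any(!is.finite(w)) || any(w < 0) || all(w == 0)) {
      msg <- c(msg, sprintf(
        "'%s' must be 4 nonnegative finite values, not all zero", nm
      ))
    }
  }
  if (length(msg) == 0L) {
    dg <- object@native[, 1L]
    if (any(diff(dg) > 0)) {
      msg <- c(msg, paste(
        "native center mean dG must be non-increasing with environment index",
        "(TE1 least stable, TE8 most stable)"
      ))
    }
  }
  if (length(msg)) msg else TRUE
})

#' TDTable: per-residue thermodynamic descriptors of one protein
#'
#' Paired native and denatured 4-vectors \{\eqn{\Delta G},
#' \eqn{\Delta H_{apolar}}, \eqn{\Delta H_{polar}}, \eqn{T\Delta S_{conf}}\}
#' for every residue of a protein, in kJ/mol. Residue positions are the
#' consecutive 1-based row indices.
#'
#' @slot proteinId single identifier string.
#' @slot aa character vector of one-letter amino-acid codes, length L.
#' @slot native L x 4 numeric matrix of native-state descriptors.
#' @slot denatured L x 4 numeric matrix of denatured-state descriptors.
#' @exportClass TDTable
setClass("TDTable",
  representation(
    proteinId = "character",
    aa = "character",
    native = "matrix",
    denatured = "matrix"
  )
)

setValidity("TDTable", function(object) {
  msg <- character()
  L <- length(object@aa)
  if (length(object@proteinId) != 1L || !nzchar(object@proteinId)) {
    msg <- c(msg, "'proteinId' must be a single non-empty string")
  }
  if (L < 1L) msg <- c(msg, "a TDTable must contain at least one residue")
  for (nm in c("native", "denatured")) {
    m <- slot(object, nm)
    if (nrow(m) != L || ncol(m) != 4L) {
      msg <- c(msg, sprintf("'%s' must be an L x 4 matrix", nm))
    } else if (!all(is.finite(m))) {
      msg <- c(msg, sprintf("all '%s' descriptor entries must be finite", nm))
    }
  }
  if (length(msg)) msg else TRUE
})

#' TESequence: per-residue TE labels of one protein
#'
#' The native and denatured thermodynamic-environment tracks of a protein:
#' two aligned integer label vectors in 1..8, one label per residue.
#'
#' @slot proteinId single identifier string.
#' @slot nativeLabels integer vector, values in 1..8.
#' @slot denaturedLabels integer vector, values in 1..8, same length.
#' @exportClass TESequence
setClass("TESequence",
  representation(
    proteinId = "character",
    nativeLabels = "integer",
    denaturedLabels = "integer"
  )
)

setValidity("TESequence", function(object) {
  msg <- character()
  if (length(object@proteinId) != 1L || !nzchar(object@proteinId)) {
    msg <- c(msg, "'proteinId' must be a single non-empty string")
  }
  n <- object@nativeLabels
  d <- object@denaturedLabels
  if (length(n) < 1L) msg <- c(msg, "label tracks must have length >= 1")
  if (length(n) != length(d)) {
    msg <- c(msg, "native and denatured tracks must have identical length")
  }
  if (anyNA(n) || anyNA(d) || any(c(n, d) < 1L) || any(c(n, d) > 8L)) {
    msg <- c(msg, "TE labels must be integers in 1..8")
  }
  if (length(msg)) msg else TRUE
})

#' ProteomeProfiles: TE usage frequency vectors for a set of organisms
#'
#' Each row is one proteome summarized as the pooled per-residue frequency of
#' the eight native TEs (and optionally the eight denatured TEs), together
#' with organism metadata.
#'
#' @slot freq n x 8 matrix of native TE frequencies; each row sums to 1.
#' @slot denaturedFreq optional n x 8 matrix of denatured TE frequencies.
#' @slot nProteins integer vector, proteins pooled per organism.
#' @slot nResidues integer vector, residues pooled per organism.
#' @slot meta data.frame with columns `organism_id`, `kingdom`,
#'   `growth_temp` (deg C, may be NA), `disorder_fraction` (in `[0,1]`, may
#'   be NA).
#' @exportClass ProteomeProfiles
setClass("ProteomeProfiles",
  representation(
    freq = "matrix",
    denaturedFreq = "matrixOrNULL",
    nProteins = "integer",
    nResidues = "integer",
    meta = "data.frame"
  )
)

.checkFreqMatrix <- function(m, what) {
  msg <- character()
  if (ncol(m) != 8L) msg <- c(msg, sprintf("'%s' must have 8 columns", what))
  if (any(!is.finite(m)) || any(m < 0)) {
    msg <- c(msg, sprintf("'%s' entries must be finite and >= 0", what))
  } else if (any(abs(rowSums(m) - 1) > 1e-9)) {
    msg <- c(msg, sprintf("every row of '%s' must sum to 1 (tol 1e-9)", what))
  }
  msg
}

setValidity("ProteomeProfiles", function(object) {
  msg <- .checkFreqMatrix(object@freq, "freq")
  n <- nrow(object@freq)
  if (!is.null(object@denaturedFreq)) {
    msg <- c(msg, .checkFreqMatrix(object@denaturedFreq, "denaturedFreq"))
    if (nrow(object@denaturedFreq) != n) {
      msg <- c(msg, "'denaturedFreq' must have one row per organism")
    }
  }
  if (nrow(object@meta) != n) {
    msg <- c(msg, "'meta' must have one row per organism")
  }
  need <- c("organism_id", "kingdom", "growth_temp", "disorder_fraction")
  if (!all(need %in% names(object@meta))) {
    msg <- c(msg, sprintf(
      "'meta' must contain columns %s", paste(need, collapse = ", ")
    ))
  } else {
    if (anyDuplicated(object@meta$organism_id)) {
      msg <- c(msg, "duplicate organism_id in 'meta'")
    }
    king <- object@meta$kingdom
    if (!all(is.na(king) | king %in% .KINGDOMS)) {
      msg <- c(msg, sprintf(
        "kingdom must be one of %s", paste(.KINGDOMS, collapse = ", ")
      ))
    }
    disf <- object@meta$disorder_fraction
    if (any(!is.na(disf) & (disf < 0 | disf > 1))) {
      msg <- c(msg, "disorder_fraction must lie in [0, 1]")
    }
  }
  if (length(object@nProteins) != n || length(object@nResidues) != n) {
    msg <- c(msg, "'nProteins' and 'nResidues' must have one entry per organism")
  }
  if (length(msg)) msg else TRUE
})

#' TEPCA: principal component decomposition of TE frequency profiles
#'
#' @slot loadings p x k matrix of orthonormal component loadings (p = 8 for
#'   native-only input, 16 when denatured frequencies are appended).
#' @slot explainedVarianceRatio nonincreasing fractions of total variance.
#' @slot center length-p column means removed before decomposition.
#' @slot scores n x k matrix of organism coordinates.
#' @slot states `"native"` or `"both"`.
#' @exportClass TEPCA
setClass("TEPCA",
  representation(
    loadings = "matrix",
    explainedVarianceRatio = "numeric",
    center = "numeric",
    scores = "matrix",
    states = "character"
  )
)

setValidity("TEPCA", function(object) {
  msg <- character()
  L <- object@loadings
  k <- ncol(L)
  if (length(object@explainedVarianceRatio) != k) {
    msg <- c(msg, "one explained-variance ratio per retained component")
  } else {
    evr <- object@explainedVarianceRatio
    if (any(evr < -1e-12) || any(evr > 1 + 1e-12) || any(diff(evr) > 1e-12)) {
      msg <- c(msg, "explained-variance ratios must be nonincreasing in [0,1]")
    }
    if (sum(evr) > 1 + 1e-9) {
      msg <- c(msg, "explained-variance ratios must sum to at most 1")
    }
  }
  gram <- crossprod(L)
  if (max(abs(gram - diag(k))) > 1e-8) {
    msg <- c(msg, "loadings must be mutually orthonormal (tol 1e-8)")
  }
  if (length(object@center) != nrow(L)) {
    msg <- c(msg, "'center' length must match the loading dimension")
  }
  if (ncol(object@scores) != k) {
    msg <- c(msg, "'scores' must have one column per retained component")
  }
  if (length(msg)) msg else TRUE
})

#' LogOddsMatrix: secondary-structure enrichment per native TE
#'
#' Log-odds scores \eqn{\ln[(N_{j|k}/N_k)/(N_j/N)]} for the 4 secondary
#' structure classes (rows: helix, strand, turn, coil) against the 8 native
#' TEs (columns), with the joint count table they were computed from. Cells
#' whose class or TE marginal is zero are undefined (NA); cells with positive
#' marginals but zero joint count score -Inf unless a pseudocount was used.
#'
#' @slot scores 4 x 8 numeric matrix, natural-log units.
#' @slot counts 4 x 8 matrix of joint residue counts.
#' @slot nTotal total residues scored.
#' @slot nClass length-4 class marginals.
#' @slot nTE length-8 TE marginals.
#' @slot pseudocount pseudocount added to each joint cell (0 = none).
#' @exportClass LogOddsMatrix
setClass("LogOddsMatrix",
  representation(
    scores = "matrix",
    counts = "matrix",
    nTotal = "numeric",
    nClass = "numeric",
    nTE = "numeric",
    pseudocount = "numeric"
  )
)

setValidity("LogOddsMatrix", function(object) {
  msg <- character()
  if (!all(dim(object@scores) == c(4L, 8L))) {
    msg <- c(msg, "'scores' must be 4 x 8")
  }
  if (!all(dim(object@counts) == c(4L, 8L))) {
    msg <- c(msg, "'counts' must be 4 x 8")
  } else {
    if (abs(sum(object@counts) - object@nTotal) > 1e-9) {
      msg <- c(msg, "joint counts must sum to nTotal")
    }
    if (max(abs(rowSums(object@counts) - object@nClass)) > 1e-9 ||
        max(abs(colSums(object@counts) - object@nTE)) > 1e-9) {
      msg <- c(msg, "marginals must be consistent with the joint counts")
    }
  }
  if (length(msg)) msg else TRUE
})

#' StabilityModel: additive TE model of global protein stability
#'
#' Predicts the standard-condition global stability of a protein (kJ/mol,
#' more negative = more stable) as a weighted sum over its native and
#' denatured TE counts minus a uniform per-residue conformational entropy
#' penalty \eqn{L\,R\,T\ln Z}, where Z is the effective number of unfolded
#' conformations available per residue.
#'
#' @slot wNative length-8 weights, kJ/mol per residue.
#' @slot wDenatured length-8 weights, kJ/mol per residue.
#' @slot Z conformations per residue, > 0.
#' @slot temperature kelvin, default 298.15.
#' @slot gasConstant kJ/(mol K), default 0.0083145.
#' @slot diagnostics list of fit diagnostics (may be empty).
#' @exportClass StabilityModel
setClass("StabilityModel",
  representation(
    wNative = "numeric",
    wDenatured = "numeric",
    Z = "numeric",
    temperature = "numeric",
    gasConstant = "numeric",
    diagnostics = "list"
  )
)

setValidity("StabilityModel", function(object) {
  msg <- character()
  if (length(object@wNative) != 8L || length(object@wDenatured) != 8L ||
      anyNA(object@wNative) || anyNA(object@wDenatured)) {
    msg <- c(msg, "weight vectors must be 8 finite values each")
  }
  if (length(object@Z) != 1L || !is.finite(object@Z) || object@Z <= 0) {
    msg <- c(msg, "'Z' must be a single positive number")
  }
  if (length(object@temperature) != 1L || object@temperature <= 0) {
    msg <- c(msg, "'temperature' must be positive (kelvin)")
  }
  if (length(msg)) msg else TRUE
})
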