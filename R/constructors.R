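#' Construct a TECenters object
#'
#' @param native,denatured 8 x 4 numeric matrices (rows TE1..TE8, columns
#'   dG, dHap, dHpol, TdS, kJ/mol).
#' @param nativeWeights,denaturedWeights nonnegative length-4 metric weights.
#'   The native default triple-weights the conformational entropy term.
#' @return A [TECenters-class] object.
#' @examples
#' ctrs <- genCenterTable()
#' nativeCenters(ctrs)[1:2, ]
#' @export
TECenters <- function(native, denatured,
                      nativeWeights = c(1, 1, 1, 3),
                      denaturedWeights = c(1, 1, 1, 1)) {
  native <- .asTDMatrix(native)
  denatured <- .asTDMatrix(denatured)
  new("TECenters",
    native = native, denatured = denatured,
    nativeWeights = as.numeric(nativeWeights),
    denaturedWeights = as.numeric(denaturedWeights)
  )
}

.asTDMatrix <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  colnames(m) <- .TD_NAMES
  m
}

#' Construct a TDTable object
#'
#' @param proteinId identifier string.
#' @param aa character vector of one-letter amino-acid codes.
#' @param native,denatured L x 4 numeric matrices of thermodynamic
#'   descriptors (kJ/mol), columns dG, dHap, dHpol, TdS.
#' @return A [TDTable-class] object.
#' @export
TDTable <- function(proteinId, aa, native, denatured) {
  new("TDTable",
    proteinId = as.character(proteinId), aa = toupper(as.character(aa)),
    native = .asTDMatrix(native), denatured = .asTDMatrix(denatured)
  )
}

#' Construct a TESequence object
#'
#' @param proteinId identifier string.
#' @param nativeLabels,denaturedLabels integer label vectors in 1..8, equal
#'   length.
#' @return A [TESequence-class] object.
#' @examples
#' TESequence("p1", c(4, 4, 5), c(2, 2, 2))
#' @export
TESequence <- function(proteinId, nativeLabels, denaturedLabels) {
  new("TESequence",
    proteinId = as.character(proteinId),
    nativeLabels = as.integer(nativeLabels),
    denaturedLabels = as.integer(denaturedLabels)
  )
}

#' Construct a StabilityModel object
#'
#' @param wNative,wDenatured length-8 weights (kJ/mol per residue).
#' @param Z conformations per residue (> 0).
#' @param temperature kelvin; default 298.15 (25 degrees C).
#' @param gasConstant kJ/(mol K).
#' @param diagnostics optional list of fit diagnostics.
#' @return A [StabilityModel-class] object.
#' @examples
#' m <- StabilityModel(rep(0, 8), rep(0, 8), Z = 1)
#' @export
StabilityModel <- function(wNative, wDenatured, Z,
                           temperature = .TSTD, gasConstant = .RGAS,
                           diagnostics = list()) {
  new("StabilityModel",
    wNative = as.numeric(wNative), wDenatured = as.numeric(wDenatured),
    Z = as.numeric(Z), temperature = as.numeric(temperature),
    gasConstant = as.numeric(gasConstant), diagnostics = diagnostics
  )
}

#' Construct a ProteomeProfiles object from a frequency matrix
#'
#' Convenience constructor for profiles that were not pooled from TE
#' sequences in this session (e.g. external tables or simulation studies).
#'
#' @param freq n x 8 matrix of native TE frequencies, rows summing to 1.
#' @param meta data.frame with `organism_id` and `kingdom` columns;
#'   `growth_temp` and `disorder_fraction` are added as NA when absent.
#' @param denaturedFreq optional n x 8 denatured frequency matrix.
#' @param nProteins,nResidues optional per-organism pooling sizes.
#' @return A [ProteomeProfiles-class] object.
#' @export
ProteomeProfiles <- function(freq, meta, denaturedFreq = NULL,
                             nProteins = NA_integer_,
                             nResidues = NA_integer_) {
  freq <- as.matrix(freq)
  meta <- as.data.frame(meta)
  n <- nrow(freq)
  if (is.null(meta$growth_temp)) meta$growth_temp <- NA_real_
  if (is.null(meta$disorder_fraction)) meta$disorder_fraction <- NA_real_
  rownames(freq) <- meta$organism_id
  new("ProteomeProfiles",
    freq = freq,
    denaturedFreq = if (is.null(denaturedFreq)) NULL else
      as.matrix(denaturedFreq),
    nProteins = rep_len(as.integer(nProteins), n),
    nResidues = rep_len(as.integer(nResidues), n),
    meta = meta
  )
}

## ------------------------------------------------------------------ accessors

#' @rdname TECenters
#' @param object,x a TECenters object.
#' @export
setGeneric("nativeCenters", function(object) standardGeneric("nativeCenters"))
#' @rdname TECenters
#' @export
setMethod("nativeCenters", "TECenters", function(object) object@native)

#' @rdname TECenters
#' @export
setGeneric("denaturedCenters", function(object) {
  standardGeneric("denaturedCenters")
})
#' @rdname TECenters
#' @export
setMethod("denaturedCenters", "TECenters", function(object) object@denatured)

#' @rdname TESequence
#' @param object a TESequence object.
#' @export
setGeneric("proteinId", function(object) standardGeneric("proteinId"))
#' @rdname TESequence
#' @export
setMethod("proteinId", "TESequence", function(object) object@proteinId)
#' @rdname TDTable
#' @param object a TDTable object.
#' @export
setMethod("proteinId", "TDTable", function(object) object@proteinId)

#' @rdname TESequence
#' @export
setGeneric("nativeLabels", function(object) standardGeneric("nativeLabels"))
#' @rdname TESequence
#' @export
setMethod("nativeLabels", "TESequence", function(object) object@nativeLabels)

#' @rdname TESequence
#' @export
setGeneric("denaturedLabels", function(object) {
  standardGeneric("denaturedLabels")
})
#' @rdname TESequence
#' @export
setMethod("denaturedLabels", "TESequence", function(object) {
  object@denaturedLabels
})

#' Length of a TESequence or TDTable (number of residues)
#'
#' @param x a TESequence or TDTable.
#' @export
setMethod("length", "TESequence", function(x) length(x@nativeLabels))
#' @rdname length-TESequence-method
#' @export
setMethod("length", "TDTable", function(x) length(x@aa))

#' @rdname ProteomeProfiles-class
#' @param object a ProteomeProfiles object.
#' @export
setGeneric("teFrequencies", function(object) standardGeneric("teFrequencies"))
#' @rdname ProteomeProfiles-class
#' @export
setMethod("teFrequencies", "ProteomeProfiles", function(object) object@freq)

#' @rdname ProteomeProfiles-class
#' @export
setGeneric("denaturedFrequencies", function(object) {
  standardGeneric("denaturedFrequencies")
})
#' @rdname ProteomeProfiles-class
#' @export
setMethod("denaturedFrequencies", "ProteomeProfiles", function(object) {
  object@denaturedFreq
})

#' @rdname ProteomeProfiles-class
#' @export
setGeneric("organismMeta", function(object) standardGeneric("organismMeta"))
#' @rdname ProteomeProfiles-class
#' @export
setMethod("organismMeta", "ProteomeProfiles", function(object) object@meta)

#' @rdname TEPCA-class
#' @param object a TEPCA object.
#' @export
setGeneric("pcaScores", function(object) standardGeneric("pcaScores"))
#' @rdname TEPCA-class
#' @export
setMethod("pcaScores", "TEPCA", function(object) object@scores)

#' @rdname TEPCA-class
#' @export
setGeneric("pcaLoadings", function(object) standardGeneric("pcaLoadings"))
#' @rdname TEPCA-class
#' @export
setMethod("pcaLoadings", "TEPCA", function(object) object@loadings)

#' @rdname TEPCA-class
#' @export
setGeneric("explainedVariance", function(object) {
  standardGeneric("explainedVariance")
})
#' @rdname TEPCA-class
#' @export
setMethod("explainedVariance", "TEPCA", function(object) {
  object@explainedVarianceRatio
})

#' @rdname LogOddsMatrix-class
#' @param object a LogOddsMatrix object.
#' @export
setGeneric("oddsScores", function(object) standardGeneric("oddsScores"))
#' @rdname LogOddsMatrix-class
#' @export
setMethod("oddsScores", "LogOddsMatrix", function(object) object@scores)

#' @rdname LogOddsMatrix-class
#' @export
setGeneric("jointCounts", function(object) standardGeneric("jointCounts"))
#' @rdname LogOddsMatrix-class
#' @export
setMethod("jointCounts", "LogOddsMatrix", function(object) object@counts)

#' @rdname StabilityModel
#' @export
setGeneric("nativeWeights", function(object) standardGeneric("nativeWeights"))
#' @rdname StabilityModel
#' @export
setMethod("nativeWeights", "StabilityModel", function(object) object@wNative)

#' @rdname StabilityModel
#' @export
setGeneric("denaturedWeights", function(object) {
  standardGeneric("denaturedWeights")
})
#' @rdname StabilityModel
#' @export
setMethod("denaturedWeights", "StabilityModel", function(object) {
  object@wDenatured
})

#' @rdname StabilityModel
#' @export
setGeneric("zParameter", function(object) standardGeneric("zParameter"))
#' @rdname StabilityModel
#' @export
setMethod("zParameter", "StabilityModel", function(object) object@Z)

## ------------------------------------------------------------------ show

setMethod("show", "TECenters", function(object) {
  cat("TECenters: 8 native + 8 denatured cluster centers (kJ/mol)\n")
  cat(sprintf(
    "  native dG range: %.2f (TE1) .. %.2f (TE8)\n",
    object@native[1, 1], object@native[8, 1]
  ))
  cat(sprintf(
    "  metric weights: native (%s), denatured (%s)\n",
    paste(format(object@nativeWeights), collapse = ", "),
    paste(format(object@denaturedWeights), collapse = ", ")
  ))
})

setMethod("show", "TDTable", function(object) {
  cat(sprintf(
    "TDTable '%s': %d residues, native + denatured 4-vectors (kJ/mol)\n",
    object@proteinId, length(object@aa)
  ))
})

setMethod("show", "TESequence", function(object) {
  L <- length(object@nativeLabels)
  trunc <- function(v) {
    s <- paste(v[seq_len(min(L, 40L))], collapse = "")
    if (L > 40L) paste0(s, "...") else s
  }
  cat(sprintf("TESequence '%s' (%d residues)\n", object@proteinId, L))
  cat("  native:    ", trunc(object@nativeLabels), "\n", sep = "")
  cat("  denatured: ", trunc(object@denaturedLabels), "\n", sep = "")
})

setMethod("show", "ProteomeProfiles", function(object) {
  cat(sprintf(
    "ProteomeProfiles: %d organisms (%s)%s\n",
    nrow(object@freq),
    paste(sprintf(
      "%d %s", tabulate(factor(object@meta$kingdom, .KINGDOMS), 3L), .KINGDOMS
    ), collapse = ", "),
    if (is.null(object@denaturedFreq)) "" else ", denatured tracks present"
  ))
})

setMethod("show", "TEPCA", function(object) {
  cat(sprintf(
    "TEPCA (%s states): %d components, variance shares %s\n",
    object@states, ncol(object@loadings),
    paste(sprintf("%.1f%%", 100 * object@explainedVarianceRatio),
      collapse = " "
    )
  ))
})

setMethod("show", "LogOddsMatrix", function(object) {
  cat(sprintf(
    "LogOddsMatrix: 4 SS classes x 8 native TEs, N = %g residues\n",
    object@nTotal
  ))
  print(round(object@scores, 3))
})

setMethod("show", "StabilityModel", function(object) {
  rt <- object@gasConstant * object@temperature
  cat("StabilityModel (additive TE stability model)\n")
  cat("  wNative:    ", paste(sprintf("%.3f", object@wNative), collapse = " "),
    "\n",
    sep = ""
  )
  cat("  wDenatured: ",
    paste(sprintf("%.3f", object@wDenatured), collapse = " "), "\n",
    sep = ""
  )
  cat(sprintf(
    "  Z = %.3f conformations/residue; per-residue penalty RT ln Z = %.3f kJ/mol\n",
    object@Z, rt * log(object@Z)
  ))
})
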