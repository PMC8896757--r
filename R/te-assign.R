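## TE assignment: each residue's 4-vector of thermodynamic descriptors is
## mapped to the environment whose cluster center is closest under a weighted
## Manhattan metric. The native metric triple-weights the conformational
## entropy term; the denatured metric is unweighted. Ties go to the lowest
## environment index so assignment is deterministic.

# td: n x 4 matrix; centers: 8 x 4; weights: length 4.
# Returns integer labels (lowest index wins ties).
.assignTE <- function(td, centers, weights) {
  if (any(!is.finite(td))) {
    stop("thermodynamic descriptors must be finite", call. = FALSE)
  }
  d <- matrix(0, nrow(td), 8L)
  for (k in seq_len(8L)) {
    dev <- abs(td - matrix(centers[k, ], nrow(td), 4L, byrow = TRUE))
    d[, k] <- dev %*% weights
  }
  max.col(-d, ties.method = "first")
}

.asTDRow <- function(td) {
  if (is.null(dim(td))) {
    if (length(td) != 4L) stop("a TD vector has exactly 4 entries",
      call. = FALSE
    )
    td <- matrix(as.numeric(td), 1L, 4L)
  }
  td
}

#' Assign a native thermodynamic environment
#'
#' Maps a native-state thermodynamic descriptor 4-vector (dG, dHap, dHpol,
#' TdS, kJ/mol) to the native TE whose cluster center is nearest under the
#' weighted Manhattan metric (default weights 1, 1, 1, 3: the conformational
#' entropy deviation counts three-fold). Ties resolve to the lowest index.
#'
#' @param td numeric 4-vector, or an n x 4 matrix for vectorized use.
#' @param centers a [TECenters-class] object.
#' @return Integer label(s) in 1..8.
#' @examples
#' ctrs <- genCenterTable()
#' assignNativeTE(nativeCenters(ctrs)[5, ], ctrs) # 5
#' @export
assignNativeTE <- function(td, centers) {
  stopifnot(is(centers, "TECenters"))
  .assignTE(.asTDRow(td), centers@native, centers@nativeWeights)
}

#' Assign a denatured thermodynamic environment
#'
#' As [assignNativeTE()] but against the denatured centers with unit metric
#' weights.
#'
#' @inheritParams assignNativeTE
#' @return Integer label(s) in 1..8.
#' @export
assignDenaturedTE <- function(td, centers) {
  stopifnot(is(centers, "TECenters"))
  .assignTE(.asTDRow(td), centers@denatured, centers@denaturedWeights)
}

#' Relabel a protein's residues as TE sequences
#'
#' Applies the native and denatured TE assignment residue-wise to a
#' [TDTable-class], producing the protein's two TE tracks.
#'
#' @param tdTable a [TDTable-class] object.
#' @param centers a [TECenters-class] object.
#' @return A [TESequence-class] with one native and one denatured label per
#'   residue.
#' @export
annotateProtein <- function(tdTable, centers) {
  stopifnot(is(tdTable, "TDTable"), is(centers, "TECenters"))
  TESequence(
    proteinId = tdTable@proteinId,
    nativeLabels = assignNativeTE(tdTable@native, centers),
    denaturedLabels = assignDenaturedTE(tdTable@denatured, centers)
  )
}

#' Count TE usage in a TE sequence
#'
#' @param teSeq a [TESequence-class].
#' @return List with integer 8-vectors `native` and `denatured`; each sums to
#'   the protein length.
#' @examples
#' teCounts(TESequence("p", c(4, 4, 5), c(1, 1, 1)))$native
#' @export
teCounts <- function(teSeq) {
  stopifnot(is(teSeq, "TESequence"))
  list(
    native = tabulate(teSeq@nativeLabels, nbins = 8L),
    denatured = tabulate(teSeq@denaturedLabels, nbins = 8L)
  )
}
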