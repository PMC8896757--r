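#' Group DSSP codes into four secondary-structure classes
#'
#' H, G, I map to helix; E, B to strand; T, S to turn; anything else
#' (including blanks and gap characters) to coil.
#'
#' @param codes character vector of single-character DSSP codes.
#' @return Factor with levels helix, strand, turn, coil.
#' @examples
#' groupDSSP(c("H", "G", "B", "-"))
#' @export
groupDSSP <- function(codes) {
  codes <- as.character(codes)
  cls <- rep("coil", length(codes))
  cls[codes %in% c("H", "G", "I")] <- "helix"
  cls[codes %in% c("E", "B")] <- "strand"
  cls[codes %in% c("T", "S")] <- "turn"
  factor(cls, levels = .SS_CLASSES)
}

#' Log-odds enrichment of secondary structure within native TEs
#'
#' For each of the 4 x 8 (class, TE) categories the score is
#' \deqn{\ln\frac{N_{j|k}/N_k}{N_j/N}}
#' the log of how much more often class j occurs inside TE k than overall.
#' Cells whose class or TE marginal is zero are undefined and reported NA;
#' cells with positive marginals but zero joint count score -Inf unless a
#' positive `pseudocount` (e.g. 0.5) is supplied, in which case it is added
#' to every joint cell and the marginals are recomputed accordingly.
#'
#' @param ss secondary-structure labels: DSSP codes, class names, or a
#'   factor from [groupDSSP()]; aligned with `te`.
#' @param te native TE labels (integers 1..8) aligned with `ss`.
#' @param pseudocount nonnegative value added to each joint cell; default 0.
#' @return A [LogOddsMatrix-class] object.
#' @examples
#' lom <- logOdds(c("H", "H", "E", "-"), c(8, 8, 8, 1))
#' oddsScores(lom)["helix", 8]
#' @export
logOdds <- function(ss, te, pseudocount = 0) {
  if (length(ss) != length(te)) {
    stop("'ss' and 'te' labels must be aligned and of equal length",
      call. = FALSE
    )
  }
  if (length(ss) < 1L) stop("need at least one residue", call. = FALSE)
  stopifnot(pseudocount >= 0)
  if (is.factor(ss) || all(as.character(ss) %in% .SS_CLASSES)) {
    cls <- factor(as.character(ss), levels = .SS_CLASSES)
  } else {
    cls <- groupDSSP(ss)
  }
  te <- as.integer(te)
  if (anyNA(te) || any(te < 1L) || any(te > 8L)) {
    stop("TE labels must be integers in 1..8", call. = FALSE)
  }
  counts <- table(cls, factor(te, levels = 1:8))
  counts <- matrix(as.numeric(counts), 4L, 8L,
    dimnames = list(.SS_CLASSES, paste0("TE", 1:8))
  )
  .logOddsFromCounts(counts, pseudocount)
}

#' Log-odds scores from a precomputed joint count table
#'
#' @param counts 4 x 8 matrix of joint (class, TE) counts, rows in the order
#'   helix, strand, turn, coil.
#' @inheritParams logOdds
#' @return A [LogOddsMatrix-class] object.
#' @export
logOddsFromCounts <- function(counts, pseudocount = 0) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(4L, 8L)) || any(counts < 0)) {
    stop("'counts' must be a nonnegative 4 x 8 matrix", call. = FALSE)
  }
  dimnames(counts) <- list(.SS_CLASSES, paste0("TE", 1:8))
  .logOddsFromCounts(counts, pseudocount)
}

.logOddsFromCounts <- function(counts, pseudocount) {
  work <- counts + pseudocount
  N <- sum(work)
  nClass <- rowSums(work)
  nTE <- colSums(work)
  scores <- log(work * N) - log(outer(nClass, nTE))
  undef <- outer(nClass == 0, nTE == 0, `|`)
  scores[undef] <- NA_real_
  new("LogOddsMatrix",
    scores = scores, counts = counts,
    nTotal = sum(counts), nClass = rowSums(counts), nTE = colSums(counts),
    pseudocount = pseudocount
  )
}

#' Write a log-odds score matrix (and counts) to TSV
#'
#' @param lom a [LogOddsMatrix-class].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
writeLogOdds <- function(lom, path) {
  stopifnot(is(lom, "LogOddsMatrix"))
  out <- data.frame(
    class = rownames(lom@scores), lom@scores,
    check.names = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
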