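#' Kyte-Doolittle hydropathy scale
#'
#' @return Named numeric vector of per-residue hydropathy values for the 20
#'   standard amino acids (positive = hydrophobic).
#' @export
kyteDoolittle <- function() {
  c(
    A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
    L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
  )
}

# centered moving average; windows shrink symmetrically at the termini
# (position p averages over [p - h, p + h] intersected with 1..L).
.slidingMean <- function(x, window) {
  L <- length(x)
  if (window %% 2L != 1L) stop("window length must be odd", call. = FALSE)
  if (window > L) stop("window longer than the sequence", call. = FALSE)
  h <- (window - 1L) %/% 2L
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(L) - h, 1L)
  hi <- pmin(seq_len(L) + h, L)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Sliding-window hydropathy profile of a sequence
#'
#' Centered moving average of per-residue hydropathy over an odd window
#' (default 17 residues). Terminal windows shrink symmetrically rather than
#' padding.
#'
#' @param seq amino-acid sequence: single string or character vector of
#'   one-letter codes.
#' @param scale named per-residue values; default [kyteDoolittle()].
#' @param window odd window length `<=` sequence length; `window = 1`
#'   returns the raw scale values.
#' @return data.frame with `position`, `raw` and `windowed` columns.
#' @examples
#' hydropathyProfile("MKVL", window = 1)$raw
#' @export
hydropathyProfile <- function(seq, scale = kyteDoolittle(), window = 17L) {
  if (length(seq) == 1L && nchar(seq) > 1L) {
    seq <- strsplit(seq, "")[[1L]]
  }
  seq <- toupper(seq)
  unknown <- which(!seq %in% names(scale))
  if (length(unknown)) {
    stop(sprintf(
      "residue '%s' at position %d has no value in the hydropathy scale",
      seq[unknown[1L]], unknown[1L]
    ), call. = FALSE)
  }
  raw <- unname(scale[seq])
  data.frame(
    position = seq_along(raw), raw = raw,
    windowed = .slidingMean(raw, as.integer(window))
  )
}

#' Positionwise TE difference between a wild-type/mutant pair
#'
#' The raw track is the signed native-TE index difference (mutant minus wild
#' type) at each position, in environment steps; an optional windowed track
#' applies the same shrinking centered moving average as
#' [hydropathyProfile()]. Swapping the two sequences negates every delta.
#'
#' @param wt,mut [TESequence-class] objects of equal length.
#' @param window optional odd window length for a smoothed track.
#' @return data.frame with `position`, `raw_delta` and, when `window` is
#'   given, `window_mean`.
#' @export
teDeltaProfile <- function(wt, mut, window = NULL) {
  stopifnot(is(wt, "TESequence"), is(mut, "TESequence"))
  if (length(wt) != length(mut)) {
    stop("wild-type and mutant TE sequences differ in length", call. = FALSE)
  }
  delta <- as.numeric(mut@nativeLabels - wt@nativeLabels)
  out <- data.frame(position = seq_along(delta), raw_delta = delta)
  if (!is.null(window)) {
    out$window_mean <- .slidingMean(delta, as.integer(window))
  }
  out
}

#' Distribution of substitution consequences over mutant pairs
#'
#' For each wild-type/mutant pair, sums the signed native-TE change over the
#' mutated position plus a flank of neighbors on each side (local stability
#' effects of a substitution land at the site and its sequence neighbors;
#' default flank 3), then pools the per-pair totals into a summary.
#'
#' @param pairs list of lists/tuples, each with elements `wt`
#'   ([TESequence-class]), `mut` ([TESequence-class], same length) and
#'   `position` (1-based mutated site).
#' @param flank neighbors included on each side of the site, default 3.
#' @return List with `mean`, `variance` (sample variance; NA for a single
#'   pair), `histogram` (a table of per-pair totals) and `per_pair` values.
#' @export
substitutionEffectDistribution <- function(pairs, flank = 3L) {
  if (length(pairs) < 1L) stop("need at least one pair", call. = FALSE)
  flank <- as.integer(flank)
  vals <- vapply(pairs, function(p) {
    wt <- p$wt
    mut <- p$mut
    stopifnot(is(wt, "TESequence"), is(mut, "TESequence"))
    if (length(wt) != length(mut)) {
      stop("pair sequences differ in length", call. = FALSE)
    }
    pos <- as.integer(p$position)
    if (pos < 1L || pos > length(wt)) {
      stop(sprintf("mutated position %d out of range 1..%d", pos, length(wt)),
        call. = FALSE
      )
    }
    win <- max(1L, pos - flank):min(length(wt), pos + flank)
    sum(mut@nativeLabels[win] - wt@nativeLabels[win])
  }, 0)
  list(
    mean = mean(vals),
    variance = if (length(vals) > 1L) var(vals) else NA_real_,
    histogram = table(vals),
    per_pair = vals
  )
}
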