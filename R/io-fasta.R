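#' Read amino-acid sequences from a FASTA file
#'
#' Thin validating wrapper around [Biostrings::readBStringSet()]. Sequences
#' are uppercased and returned in file order.
#'
#' @param path FASTA file.
#' @return A [Biostrings::AAStringSet] named by record header.
#' @export
readFastaSequences <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop(sprintf("malformed FASTA in '%s': %s", path, conditionMessage(e)),
        call. = FALSE
      )
    }
  )
  if (length(set) == 0L) {
    stop(sprintf("no FASTA records in '%s'", path), call. = FALSE)
  }
  empty <- Biostrings::width(set) == 0L
  if (any(empty)) {
    stop(sprintf(
      "empty sequence body for record '%s' in '%s'",
      names(set)[which(empty)[1L]], path
    ), call. = FALSE)
  }
  Biostrings::AAStringSet(toupper(as.character(set)))
}

#' Write TE sequences as a two-track FASTA file
#'
#' Each protein contributes two records, `<id> native` and `<id> denatured`,
#' whose bodies are the TE labels written as the digit characters 1-8.
#'
#' @param teSeqs a [TESequence-class] or list of them.
#' @param path output file.
#' @return Invisibly, `path`.
#' @seealso [readTESequence()] for the matching reader.
#' @export
writeTESequence <- function(teSeqs, path) {
  if (is(teSeqs, "TESequence")) teSeqs <- list(teSeqs)
  stopifnot(length(teSeqs) >= 1L, all(vapply(teSeqs, is, TRUE, "TESequence")))
  bodies <- unlist(lapply(teSeqs, function(s) {
    validObject(s)
    c(
      paste(s@nativeLabels, collapse = ""),
      paste(s@denaturedLabels, collapse = "")
    )
  }))
  ids <- unlist(lapply(teSeqs, function(s) {
    paste(s@proteinId, c("native", "denatured"))
  }))
  set <- Biostrings::BStringSet(bodies)
  names(set) <- ids
  Biostrings::writeXStringSet(set, filepath = path, width = 80L)
  invisible(path)
}

#' Read TE sequences from a two-track FASTA file
#'
#' @param path file written by [writeTESequence()].
#' @return A list of [TESequence-class] objects, in file order.
#' @export
readTESequence <- function(path) {
  set <- Biostrings::readBStringSet(path)
  hdr <- strsplit(names(set), " ", fixed = TRUE)
  ids <- vapply(hdr, `[`, "", 1L)
  track <- vapply(hdr, function(h) h[length(h)], "")
  if (length(set) %% 2L != 0L ||
      !all(track[c(TRUE, FALSE)] == "native" &
        track[c(FALSE, TRUE)] == "denatured")) {
    stop(sprintf(
      "'%s' is not a native/denatured TE track file", path
    ), call. = FALSE)
  }
  lapply(seq_len(length(set) / 2L), function(i) {
    nat <- as.character(set[[2L * i - 1L]])
    den <- as.character(set[[2L * i]])
    lab <- function(s, rec) {
      v <- as.integer(strsplit(s, "")[[1L]])
      if (anyNA(v) || any(v < 1L) || any(v > 8L)) {
        stop(sprintf(
          "record '%s' in '%s' contains characters outside 1-8",
          rec, path
        ), call. = FALSE)
      }
      v
    }
    TESequence(ids[2L * i - 1L],
      nativeLabels = lab(nat, names(set)[2L * i - 1L]),
      denaturedLabels = lab(den, names(set)[2L * i])
    )
  })
}
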