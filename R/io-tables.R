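## Tab-separated table dialects. All energies are kJ/mol internally; center
## tables supplied in kcal/mol are converted on load. Readers reject rather
## than repair malformed input and report the offending file and line
## (line numbers count the header as line 1).

.TD_COLS <- c(
  "position", "aa", "dG_N", "dHap_N", "dHpol_N", "TdS_N",
  "dG_D", "dHap_D", "dHpol_D", "TdS_D"
)

.readTSV <- function(path, what) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- tryCatch(
    read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
      check.names = FALSE, na.strings = NULL, blank.lines.skip = FALSE
    ),
    error = function(e) {
      stop(sprintf("cannot read %s table '%s': %s", what, path,
        conditionMessage(e)
      ), call. = FALSE)
    }
  )
  tab
}

.numericColumn <- function(tab, col, path) {
  x <- tab[[col]]
  bad <- !grepl("^\\s*-?(\\d+\\.?\\d*|\\.\\d+)([eE][+-]?\\d+)?\\s*$", x)
  if (any(bad)) {
    stop(sprintf(
      "'%s' line %d: non-numeric value '%s' in column '%s'",
      path, which(bad)[1L] + 1L, x[which(bad)[1L]], col
    ), call. = FALSE)
  }
  as.numeric(x)
}

#' Read a per-residue thermodynamic descriptor table
#'
#' The dialect is tab-separated with a header row and the ten columns
#' `position`, `aa`, `dG_N`, `dHap_N`, `dHpol_N`, `TdS_N`, `dG_D`, `dHap_D`,
#' `dHpol_D`, `TdS_D` (energies in kJ/mol). Positions must be consecutive
#' starting at 1.
#'
#' @param path input file.
#' @param proteinId identifier for the protein; defaults to the file name
#'   without extension.
#' @return A [TDTable-class] object.
#' @export
readTDTable <- function(path, proteinId = NULL) {
  tab <- .readTSV(path, "TD")
  if (!identical(names(tab), .TD_COLS)) {
    stop(sprintf(
      "'%s': expected columns %s", path, paste(.TD_COLS, collapse = ", ")
    ), call. = FALSE)
  }
  if (nrow(tab) < 1L) stop(sprintf("'%s': no residue rows", path),
    call. = FALSE
  )
  pos <- .numericColumn(tab, "position", path)
  bad <- which(pos != seq_len(nrow(tab)))
  if (length(bad)) {
    stop(sprintf(
      "'%s' line %d: positions must be consecutive 1..L (found %g, expected %d)",
      path, bad[1L] + 1L, pos[bad[1L]], bad[1L]
    ), call. = FALSE)
  }
  vals <- vapply(.TD_COLS[-(1:2)], function(col) {
    .numericColumn(tab, col, path)
  }, numeric(nrow(tab)))
  vals <- matrix(vals, nrow = nrow(tab))
  if (is.null(proteinId)) {
    proteinId <- sub("\\.[^.]*$", "", basename(path))
  }
  TDTable(proteinId, tab$aa,
    native = vals[, 1:4, drop = FALSE],
    denatured = vals[, 5:8, drop = FALSE]
  )
}

#' Write a thermodynamic descriptor table
#'
#' Inverse of [readTDTable()]; energies are printed to three decimals.
#'
#' @param tdTable a [TDTable-class].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
writeTDTable <- function(tdTable, path) {
  stopifnot(is(tdTable, "TDTable"))
  validObject(tdTable)
  fmt <- function(m) apply(m, 2L, sprintf, fmt = "%.3f")
  out <- data.frame(
    position = seq_along(tdTable@aa), aa = tdTable@aa,
    fmt(tdTable@native), fmt(tdTable@denatured),
    check.names = FALSE
  )
  names(out) <- .TD_COLS
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an organism metadata table
#'
#' Tab-separated with header columns `organism_id`, `kingdom`,
#' `growth_temp` (degrees C) and `disorder_fraction` (in `[0,1]`); trait
#' cells may be blank and are kept missing, never imputed. Kingdoms are
#' lowercased and must be one of bacteria, archaea, eukaryote.
#'
#' @param path input file.
#' @return data.frame with one row per organism.
#' @export
readMetadataTable <- function(path) {
  tab <- .readTSV(path, "metadata")
  need <- c("organism_id", "kingdom", "growth_temp", "disorder_fraction")
  if (!all(need %in% names(tab))) {
    stop(sprintf(
      "'%s': expected columns %s", path, paste(need, collapse = ", ")
    ), call. = FALSE)
  }
  kingdom <- tolower(trimws(tab$kingdom))
  bad <- which(!kingdom %in% .KINGDOMS)
  if (length(bad)) {
    stop(sprintf(
      "'%s' line %d: unknown kingdom '%s' (must be one of %s)",
      path, bad[1L] + 1L, tab$kingdom[bad[1L]],
      paste(.KINGDOMS, collapse = ", ")
    ), call. = FALSE)
  }
  numOrNA <- function(col, lo = -Inf, hi = Inf) {
    x <- trimws(tab[[col]])
    out <- rep(NA_real_, length(x))
    present <- nzchar(x) & toupper(x) != "NA"
    if (any(present)) {
      sub <- tab[present, , drop = FALSE]
      sub[[col]] <- x[present]
      out[present] <- .numericColumn(sub, col, path)
    }
    if (any(!is.na(out) & (out < lo | out > hi))) {
      stop(sprintf("'%s': %s out of range [%g, %g]", path, col, lo, hi),
        call. = FALSE
      )
    }
    out
  }
  data.frame(
    organism_id = tab$organism_id,
    kingdom = kingdom,
    growth_temp = numOrNA("growth_temp"),
    disorder_fraction = numOrNA("disorder_fraction", 0, 1),
    stringsAsFactors = FALSE
  )
}

#' Read a TE cluster-center table
#'
#' Tab-separated with header columns `state` (N or D), `env` (1-8), `dG`,
#' `dHap`, `dHpol`, `TdS`. Exactly eight N and eight D rows are required.
#' Values supplied in kcal/mol are converted to kJ/mol on load.
#'
#' @param path input file.
#' @param units `"kJ"` (default) or `"kcal"`.
#' @param nativeWeights,denaturedWeights metric weights passed to
#'   [TECenters()].
#' @return A [TECenters-class] object.
#' @export
readCenterTable <- function(path, units = c("kJ", "kcal"),
                            nativeWeights = c(1, 1, 1, 3),
                            denaturedWeights = c(1, 1, 1, 1)) {
  units <- match.arg(units)
  tab <- .readTSV(path, "center")
  need <- c("state", "env", "dG", "dHap", "dHpol", "TdS")
  if (!all(need %in% names(tab))) {
    stop(sprintf(
      "'%s': expected columns %s", path, paste(need, collapse = ", ")
    ), call. = FALSE)
  }
  env <- .numericColumn(tab, "env", path)
  vals <- vapply(c("dG", "dHap", "dHpol", "TdS"), function(col) {
    .numericColumn(tab, col, path)
  }, numeric(nrow(tab)))
  vals <- matrix(vals, nrow = nrow(tab))
  if (units == "kcal") vals <- vals * .KCAL_TO_KJ
  pick <- function(state) {
    sel <- tab$state == state
    if (sum(sel) != 8L || !setequal(env[sel], 1:8)) {
      stop(sprintf(
        "'%s': need exactly one row per environment 1-8 for state %s",
        path, state
      ), call. = FALSE)
    }
    vals[sel, , drop = FALSE][order(env[sel]), , drop = FALSE]
  }
  TECenters(pick("N"), pick("D"),
    nativeWeights = nativeWeights, denaturedWeights = denaturedWeights
  )
}

#' Write a TE cluster-center table
#'
#' @param centers a [TECenters-class].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
writeCenterTable <- function(centers, path) {
  stopifnot(is(centers, "TECenters"))
  out <- data.frame(
    state = rep(c("N", "D"), each = 8L),
    env = rep(1:8, 2L),
    rbind(centers@native, centers@denatured),
    check.names = FALSE
  )
  names(out)[3:6] <- c("dG", "dHap", "dHpol", "TdS")
  out[3:6] <- lapply(out[3:6], sprintf, fmt = "%.4f")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write stability-record tables
#'
#' Tab-separated with header columns `protein_id`, `n1`..`n8` (native TE
#' counts), `d1`..`d8` (denatured TE counts), `length`, `dG_exp` (kJ/mol,
#' may be blank) and `class` (structured, disordered, or blank).
#'
#' @param path file path.
#' @return `readStabilityRecords` returns a data.frame of records.
#' @export
readStabilityRecords <- function(path) {
  tab <- .readTSV(path, "stability-record")
  need <- c(
    "protein_id", paste0("n", 1:8), paste0("d", 1:8), "length", "dG_exp",
    "class"
  )
  if (!all(need %in% names(tab))) {
    stop(sprintf(
      "'%s': expected columns %s", path, paste(need, collapse = ", ")
    ), call. = FALSE)
  }
  out <- data.frame(protein_id = tab$protein_id, stringsAsFactors = FALSE)
  for (col in c(paste0("n", 1:8), paste0("d", 1:8), "length")) {
    out[[col]] <- .numericColumn(tab, col, path)
  }
  dg <- trimws(tab$dG_exp)
  out$dG_exp <- ifelse(nzchar(dg) & toupper(dg) != "NA", suppressWarnings(
    as.numeric(dg)
  ), NA_real_)
  cls <- trimws(tab$class)
  cls[!nzchar(cls) | toupper(cls) == "NA"] <- NA_character_
  if (any(!is.na(cls) & !cls %in% c("structured", "disordered"))) {
    stop(sprintf(
      "'%s': class must be 'structured' or 'disordered'", path
    ), call. = FALSE)
  }
  out$class <- cls
  .validateRecords(out, requireDG = FALSE)
  out
}

#' @rdname readStabilityRecords
#' @param records a stability-record data.frame (see [featurize()]).
#' @export
writeStabilityRecords <- function(records, path) {
  .validateRecords(records, requireDG = FALSE)
  out <- records
  out$dG_exp <- ifelse(is.na(out$dG_exp), "", sprintf("%.4f", out$dG_exp))
  out$class <- ifelse(is.na(out$class), "", out$class)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a fitted stability model to JSON
#'
#' @param model a [StabilityModel-class].
#' @param path output JSON file.
#' @return Invisibly, `path`.
#' @export
writeStabilityModel <- function(model, path) {
  stopifnot(is(model, "StabilityModel"))
  validObject(model)
  obj <- list(
    wNative = model@wNative, wDenatured = model@wDenatured,
    Z = model@Z, temperature = model@temperature,
    gasConstant = model@gasConstant,
    generator = "thermoenv", class = "StabilityModel"
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
    pretty = TRUE
  )
  invisible(path)
}

#' @rdname writeStabilityModel
#' @export
readStabilityModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  StabilityModel(obj$wNative, obj$wDenatured, obj$Z,
    temperature = obj$temperature, gasConstant = obj$gasConstant
  )
}

#' Read and write proteome profile tables
#'
#' Tab-separated with columns `organism_id`, `kingdom`, `growth_temp`,
#' `disorder_fraction`, `nat1`..`nat8`, optionally `den1`..`den8`,
#' `n_proteins`, `n_residues`.
#'
#' @param path file path.
#' @return `readProteomeProfiles` returns a [ProteomeProfiles-class].
#' @export
readProteomeProfiles <- function(path) {
  tab <- .readTSV(path, "profile")
  natCols <- paste0("nat", 1:8)
  denCols <- paste0("den", 1:8)
  need <- c("organism_id", "kingdom", natCols, "n_proteins", "n_residues")
  if (!all(need %in% names(tab))) {
    stop(sprintf(
      "'%s': expected at least columns %s", path, paste(need, collapse = ", ")
    ), call. = FALSE)
  }
  num <- function(cols) {
    m <- vapply(cols, function(col) .numericColumn(tab, col, path),
      numeric(nrow(tab))
    )
    matrix(m, nrow = nrow(tab), dimnames = list(tab$organism_id, NULL))
  }
  meta <- data.frame(
    organism_id = tab$organism_id, kingdom = tolower(tab$kingdom),
    growth_temp = if ("growth_temp" %in% names(tab)) {
      suppressWarnings(as.numeric(tab$growth_temp))
    } else {
      NA_real_
    },
    disorder_fraction = if ("disorder_fraction" %in% names(tab)) {
      suppressWarnings(as.numeric(tab$disorder_fraction))
    } else {
      NA_real_
    },
    stringsAsFactors = FALSE
  )
  den <- if (all(denCols %in% names(tab))) num(denCols) else NULL
  new("ProteomeProfiles",
    freq = num(natCols), denaturedFreq = den,
    nProteins = suppressWarnings(as.integer(tab$n_proteins)),
    nResidues = suppressWarnings(as.integer(tab$n_residues)),
    meta = meta
  )
}

#' @rdname readProteomeProfiles
#' @param profiles a [ProteomeProfiles-class].
#' @export
writeProteomeProfiles <- function(profiles, path) {
  stopifnot(is(profiles, "ProteomeProfiles"))
  validObject(profiles)
  out <- data.frame(
    organism_id = profiles@meta$organism_id,
    kingdom = profiles@meta$kingdom,
    growth_temp = profiles@meta$growth_temp,
    disorder_fraction = profiles@meta$disorder_fraction,
    profiles@freq, check.names = FALSE
  )
  names(out)[5:12] <- paste0("nat", 1:8)
  if (!is.null(profiles@denaturedFreq)) {
    den <- as.data.frame(profiles@denaturedFreq)
    names(den) <- paste0("den", 1:8)
    out <- cbind(out, den)
  }
  out$n_proteins <- profiles@nProteins
  out$n_residues <- profiles@nResidues
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
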