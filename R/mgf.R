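#' Read a Mascot Generic Format (MGF) peak-list file
#'
#' Parses centroided MS/MS spectra from MGF text. Each `BEGIN IONS` /
#' `END IONS` block must carry a `TITLE` (unique within the file) and
#' `PEPMASS`; `CHARGE` is optional. Peak lines are `m/z intensity` pairs.
#' Blank lines and lines starting with `#` are ignored. Peaks are returned
#' sorted by ascending m/z; zero-intensity peaks are retained.
#'
#' @param path Path to an MGF file.
#' @return A tibble with one row per spectrum: `title`, `precursor_mz`,
#'   `precursor_charge` (integer, `NA` if absent) and `peaks`, a list-column
#'   of tibbles with columns `mz` and `intensity`.
#' @seealso [write_mgf()]
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) abort(sprintf("MGF file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  n_lines <- length(lines)
  spectra <- list()
  i <- 1L
  while (i <= n_lines) {
    line <- trimws(lines[[i]])
    if (!nzchar(line) || startsWith(line, "#")) { i <- i + 1L; next }
    if (line != "BEGIN IONS") {
      abort(sprintf("MGF parse error at line %d: expected BEGIN IONS, got '%s'.", i, line))
    }
    start_line <- i
    i <- i + 1L
    title <- NA_character_; pmz <- NA_real_; pz <- NA_integer_
    mzs <- numeric(0); ints <- numeric(0)
    closed <- FALSE
    while (i <= n_lines) {
      line <- trimws(lines[[i]])
      if (!nzchar(line) || startsWith(line, "#")) { i <- i + 1L; next }
      if (line == "END IONS") { closed <- TRUE; i <- i + 1L; break }
      if (grepl("=", line, fixed = TRUE)) {
        key <- toupper(sub("=.*$", "", line))
        val <- sub("^[^=]*=", "", line)
        if (key == "TITLE") title <- val
        if (key == "PEPMASS") pmz <- as.numeric(strsplit(trimws(val), "[ \t]+")[[1]][1])
        if (key == "CHARGE") pz <- as.integer(gsub("[^0-9]", "", val))
      } else {
        parts <- strsplit(line, "[ \t]+")[[1]]
        vals <- suppressWarnings(as.numeric(parts[1:2]))
        if (length(parts) < 2 || anyNA(vals)) {
          abort(sprintf("MGF parse error at line %d: non-numeric peak line '%s'.", i, line))
        }
        mzs <- c(mzs, vals[1]); ints <- c(ints, vals[2])
      }
      i <- i + 1L
    }
    if (!closed) {
      abort(sprintf("MGF parse error: block starting at line %d has no END IONS.", start_line))
    }
    ord <- order(mzs)
    spectra[[length(spectra) + 1L]] <- tibble(
      title = title, precursor_mz = pmz, precursor_charge = pz,
      peaks = list(tibble(mz = mzs[ord], intensity = ints[ord]))
    )
  }
  out <- dplyr::bind_rows(spectra)
  if (nrow(out) == 0) {
    return(tibble(
      title = character(), precursor_mz = numeric(),
      precursor_charge = integer(), peaks = list()
    ))
  }
  dup <- out$title[duplicated(out$title)]
  if (length(dup) > 0) {
    abort(sprintf(
      "Duplicate spectrum TITLE(s) in %s: %s", path,
      paste(unique(dup), collapse = ", ")
    ))
  }
  out
}

#' Write spectra to a Mascot Generic Format (MGF) file
#'
#' Inverse of [read_mgf()]: m/z and intensity values are written with five
#' decimal places, so a write/read round trip reproduces the input at that
#' precision. The `CHARGE` line is omitted for spectra with unknown charge.
#'
#' @param spectra A spectra tibble as returned by [read_mgf()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  out <- character(0)
  for (k in seq_len(nrow(spectra))) {
    pk <- spectra$peaks[[k]]
    block <- c(
      "BEGIN IONS",
      paste0("TITLE=", spectra$title[[k]]),
      paste0("PEPMASS=", sprintf("%.5f", spectra$precursor_mz[[k]])),
      if (!is.na(spectra$precursor_charge[[k]])) {
        paste0("CHARGE=", spectra$precursor_charge[[k]], "+")
      },
      if (nrow(pk) > 0) sprintf("%.5f %.5f", pk$mz, pk$intensity),
      "END IONS",
      ""
    )
    out <- c(out, block)
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a glycopeptide-spectrum-match (GSM) table
#'
#' Reads a tab-separated table linking spectrum titles to identified
#' glycopeptides. Required columns: `title`, `glycopeptide_id`. Optional:
#' `label` (manual fucosylation class, one of `none`, `core`, `outer`,
#' `dual`; may be empty) and `source` (free text, e.g. IgG / AGP / plasma;
#' also used for train/test splits). Lines starting with `#` are ignored.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `title`, `glycopeptide_id`, `label`
#'   (factor, `NA` allowed) and `source`.
#' @export
read_gsm_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("GSM table not found: %s", path))
  tbl <- readr::read_tsv(
    path, comment = "#", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  required <- c("title", "glycopeptide_id")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "GSM table %s is missing required column(s): %s",
      path, paste(missing_cols, collapse = ", ")
    ))
  }
  if (!"label" %in% names(tbl)) tbl$label <- NA_character_
  if (!"source" %in% names(tbl)) tbl$source <- NA_character_
  tbl$label[!is.na(tbl$label) & tbl$label == ""] <- NA_character_
  tbl$label <- as_fuco_factor(tbl$label)
  tibble::as_tibble(tbl[, c("title", "glycopeptide_id", "label", "source")])
}

#' Write a GSM table
#'
#' @param gsm A GSM tibble (see [read_gsm_table()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_gsm_table <- function(gsm, path) {
  out <- gsm
  out$label <- as.character(out$label)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
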