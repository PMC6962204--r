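#' Peak-matching parameters
#'
#' Parameters for diagnostic-ion matching: an absolute m/z tolerance
#' (default +/-0.02 Da) and a minimum signal-to-noise ratio (default 3),
#' where the noise level of a spectrum is estimated as the median intensity
#' of its nonzero peaks.
#'
#' @param tolerance Absolute m/z tolerance in Da (> 0).
#' @param snr_min Minimum peak intensity as a multiple of the noise estimate
#'   (>= 0). Set to 0 to disable the S/N gate (e.g. for noiseless synthetic
#'   spectra, where no noise floor exists to estimate).
#' @return A list of class `fuco_params`.
#' @export
extraction_params <- function(tolerance = 0.02, snr_min = 3) {
  if (tolerance <= 0) abort("`tolerance` must be > 0.")
  if (snr_min < 0) abort("`snr_min` must be >= 0.")
  structure(list(tolerance = tolerance, snr_min = snr_min),
            class = "fuco_params")
}

#' Noise level of a spectrum
#'
#' The noise estimate used by the S/N gate: the median intensity of all
#' peaks with nonzero intensity. An empty or all-zero spectrum has noise 0,
#' so every peak passes the gate.
#'
#' @param peaks A tibble with columns `mz` and `intensity`.
#' @return A single non-negative number.
#' @export
estimate_noise <- function(peaks) {
  pos <- peaks$intensity[peaks$intensity > 0]
  if (length(pos) == 0) return(0)
  stats::median(pos)
}

#' Match the best peak for a target m/z
#'
#' Among peaks within `tolerance` of `target_mz` whose intensity reaches
#' `snr_min` times the spectrum noise, returns the most intense (ties broken
#' by lower m/z). Returns a zero-row tibble when nothing qualifies.
#'
#' @param peaks A peak tibble (`mz`, `intensity`).
#' @param target_mz Target m/z.
#' @param params An [extraction_params()] object.
#' @param noise Optional precomputed noise level; defaults to
#'   [estimate_noise()] of `peaks`.
#' @return A one- or zero-row tibble with columns `mz` and `intensity`.
#' @export
match_peak <- function(peaks, target_mz, params = extraction_params(),
                       noise = NULL) {
  noise <- noise %||% estimate_noise(peaks)
  hit <- peaks[abs(peaks$mz - target_mz) <= params$tolerance &
                 peaks$intensity >= params$snr_min * noise, , drop = FALSE]
  if (nrow(hit) == 0) return(hit)
  hit <- hit[order(-hit$intensity, hit$mz), , drop = FALSE]
  hit[1, , drop = FALSE]
}

#' Diagnostic-ion feature vector of one spectrum
#'
#' Matches the 14 diagnostic B/Y fragment ions of a glycopeptide in one
#' spectrum and reports each ion's relative intensity: matched peak
#' intensity divided by the base-peak (most intense peak) intensity of the
#' whole spectrum. Unmatched ions get 0; an empty spectrum yields 14 zeros.
#' All values are therefore in \[0, 1\] and invariant to a global intensity
#' rescaling of the spectrum.
#'
#' @param peaks A peak tibble (`mz`, `intensity`).
#' @param peptide The peptide sequence (for Y-ion m/z).
#' @param params An [extraction_params()] object.
#' @param charge Fragment charge state used for the panel m/z (default 1).
#' @return A named numeric vector of length 14 in feature order
#'   (`ion_labels()`).
#' @export
spectrum_features <- function(peaks, peptide, params = extraction_params(),
                              charge = 1L) {
  feats <- setNames(numeric(length(ION_LABELS)), ION_LABELS)
  if (nrow(peaks) == 0) return(feats)
  base <- max(peaks$intensity)
  if (base <= 0) return(feats)
  noise <- estimate_noise(peaks)
  ions <- diagnostic_ions(peptide, charge = charge)
  for (k in seq_len(nrow(ions))) {
    hit <- match_peak(peaks, ions$mz[[k]], params, noise = noise)
    if (nrow(hit) == 1) feats[[ions$ion[[k]]]] <- hit$intensity[[1]] / base
  }
  feats
}

#' Feature matrix for a set of GSMs
#'
#' Joins a GSM table to its spectra by title and computes the 14-ion
#' relative-intensity feature vector for every glycopeptide-spectrum match.
#'
#' @param gsm A GSM tibble (`title`, `glycopeptide_id`, optionally `label`,
#'   `source`).
#' @param spectra A spectra tibble from [read_mgf()] or
#'   [generate_dataset()].
#' @param params An [extraction_params()] object.
#' @return A tibble with the GSM columns followed by the 14 feature columns
#'   named after `ion_labels()`.
#' @export
extract_features <- function(gsm, spectra, params = extraction_params()) {
  feat_cols <- tibble::as_tibble(
    matrix(numeric(0), nrow = 0, ncol = 14, dimnames = list(NULL, ION_LABELS))
  )
  if (nrow(gsm) == 0) return(dplyr::bind_cols(gsm, feat_cols))
  missing_titles <- setdiff(gsm$title, spectra$title)
  if (length(missing_titles) > 0) {
    abort(sprintf(
      "GSM title(s) not found in the spectra: %s",
      paste(head(missing_titles, 10), collapse = ", ")
    ))
  }
  peps <- parse_glycopeptide_id(gsm$glycopeptide_id)$peptide
  idx <- match(gsm$title, spectra$title)
  rows <- lapply(seq_len(nrow(gsm)), function(k) {
    spectrum_features(spectra$peaks[[idx[[k]]]], peps[[k]], params)
  })
  feats <- tibble::as_tibble(do.call(rbind, rows))
  dplyr::bind_cols(gsm, feats)
}

feature_matrix <- function(features) {
  missing_cols <- setdiff(ION_LABELS, names(features))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "Feature table is missing ion column(s): %s",
      paste(missing_cols, collapse = ", ")
    ))
  }
  as.matrix(features[, ION_LABELS, drop = FALSE])
}
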