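## Synthetic GSM generator. Spectra encode the diagnostic-ion pairing logic
## of CID glycopeptide spectra: core fucosylation puts the fucose on the
## peptide-bearing Y ions (Y1F..Y4F present, no fucosylated B ions), outer
## fucosylation puts it on the glycan-only B ions (B2F/B3F, plus B3SF when
## sialylated, no fucosylated Y ions), dual shows both and none shows
## neither.

## Baseline (unscaled) intensities per ion, loosely following CID
## glycopeptide spectra: Y ions dominate, oxonium B ions are moderate,
## fucosylated partners run at ~60% of their parent ion.
.DEFAULT_ION_INTENSITY <- c(
  B2 = 400, B2F = 240, B3 = 200, B3F = 120, B3S = 300, B3SF = 180,
  Y1 = 1000, Y1F = 600, Y2 = 700, Y2F = 420, Y3 = 500, Y3F = 300,
  Y4 = 600, Y4F = 360
)

## Per-ion dropout: the probability that a nominally present diagnostic ion
## is missing from the spectrum. Detectability is ion-specific: the Y1
## anchor ion is essentially always observed, while minor oxonium species
## (B3, B3F) are flaky.
.DEFAULT_ION_DROPOUT <- c(
  B2 = 0.02, B2F = 0.05, B3 = 0.15, B3F = 0.15, B3S = 0.05, B3SF = 0.03,
  Y1 = 0.01, Y1F = 0.02, Y2 = 0.02, Y2F = 0.10, Y3 = 0.05, Y3F = 0.10,
  Y4 = 0.03, Y4F = 0.05
)

#' Class template for synthetic spectra
#'
#' Describes how one fucosylation class manifests in a synthetic spectrum:
#' which of the 14 diagnostic ions are present (fucosylated Y ions for
#' `core`, fucosylated B ions for `outer`, both for `dual`, none for
#' `none`), their log-normal intensity law, a per-ion dropout probability,
#' Gaussian m/z jitter, and a bed of low-intensity noise peaks kept below
#' the S/N gate.
#'
#' @param label One of `none`, `core`, `outer`, `dual`.
#' @param ion_intensity Named vector of median intensities per ion
#'   (log-normal `exp(meanlog)`).
#' @param intensity_sdlog Log-scale SD of ion intensities.
#' @param dropout_prob Probability that a nominally present ion is omitted;
#'   either a single number or a named per-ion vector (the default).
#' @param mz_jitter_sd SD (Da) of the Gaussian m/z jitter, truncated to half
#'   the matching tolerance.
#' @param n_noise_peaks Number of random noise peaks per spectrum.
#' @param noise_meanlog,noise_sdlog Log-normal parameters of the noise-peak
#'   intensities.
#' @param dual_attenuation Multiplier on fucosylated-ion intensities (or
#'   split fractions, with `fuc_split > 0`) of the `dual` template (< 1
#'   creates harder, attenuated dual spectra).
#' @param fuc_split Mean fraction of an (ion, ion+Fuc) pair's intensity
#'   carried by the fucosylated partner when both are present (Beta-
#'   distributed per pair; 0 disables intensity sharing and draws the
#'   fucosylated ion from its own law).
#' @param antenna_effect Strength of the antenna-dependent fragment yields:
#'   glycan-only B-ion intensities scale with (antennae / 2) ^ effect and
#'   the small Y ions (Y1/Y2 and partners) inversely, reflecting that
#'   oxonium yield grows with the number of LacNAc antennae while the
#'   relative share of small Y ions shrinks. 0 disables.
#' @return A list of class `fuco_template`.
#' @export
class_template <- function(label,
                           ion_intensity = .DEFAULT_ION_INTENSITY,
                           intensity_sdlog = 0.4,
                           dropout_prob = .DEFAULT_ION_DROPOUT,
                           mz_jitter_sd = 0.005,
                           n_noise_peaks = 60,
                           noise_meanlog = log(8),
                           noise_sdlog = 0.4,
                           dual_attenuation = 1,
                           fuc_split = 0.35,
                           antenna_effect = 1) {
  label <- match.arg(label, FUCO_CLASSES)
  structure(
    list(label = label, ion_intensity = ion_intensity,
         intensity_sdlog = intensity_sdlog, dropout_prob = dropout_prob,
         mz_jitter_sd = mz_jitter_sd, n_noise_peaks = n_noise_peaks,
         noise_meanlog = noise_meanlog, noise_sdlog = noise_sdlog,
         dual_attenuation = dual_attenuation, fuc_split = fuc_split,
         antenna_effect = antenna_effect),
    class = "fuco_template"
  )
}

#' @rdname class_template
#' @details `noiseless_template()` is the degenerate variant used for
#'   closure testing: zero dropout, zero jitter and zero noise peaks, so the
#'   spectrum contains exactly the template's diagnostic ions at their
#'   theoretical m/z.
#' @export
noiseless_template <- function(label) {
  class_template(label, dropout_prob = 0, mz_jitter_sd = 0, n_noise_peaks = 0)
}

## Which of the 14 ions a template/composition pair puts in the spectrum.
template_present_ions <- function(label, n_hex, n_hexnac, n_fuc, n_sia) {
  ions <- c("B2", "Y1", "Y2")
  if (n_hex >= 2) ions <- c(ions, "B3")
  if (n_hex >= 1 && n_hexnac >= 2) ions <- c(ions, "Y3")
  if (n_hex >= 2 && n_hexnac >= 2) ions <- c(ions, "Y4")
  if (n_sia >= 1) ions <- c(ions, "B3S")
  if (label %in% c("core", "dual")) {
    ions <- c(ions, intersect(c("Y1F", "Y2F", "Y3F", "Y4F"),
                              paste0(ions, "F")))
  }
  if (label %in% c("outer", "dual")) {
    ions <- c(ions, intersect(c("B2F", "B3F", "B3SF"), paste0(ions, "F")))
  }
  intersect(ION_LABELS, ions)
}

check_template_consistency <- function(label, n_fuc) {
  min_fuc <- switch(label, none = 0L, core = 1L, outer = 1L, dual = 2L)
  if (n_fuc < min_fuc) {
    abort(sprintf(
      "Template '%s' requires a composition with at least %d fucose(s); got %d.",
      label, min_fuc, n_fuc
    ))
  }
}

generate_gsm_impl <- function(template, peptide, n_hex, n_hexnac, n_fuc,
                              n_sia, title, source = "synthetic",
                              tolerance = 0.02) {
  check_template_consistency(template$label, n_fuc)
  ions <- diagnostic_ions(peptide)
  present <- template_present_ions(template$label, n_hex, n_hexnac, n_fuc, n_sia)
  drop_p <- template$dropout_prob
  if (!is.null(names(drop_p))) {
    drop_p <- ifelse(present %in% names(drop_p), drop_p[present], 0)
  }
  keep <- present[runif(length(present)) >= drop_p]
  ion_rows <- ions[ions$ion %in% keep, , drop = FALSE]

  scale <- rep(1, nrow(ion_rows))
  if (template$label == "dual" && template$dual_attenuation != 1) {
    scale[grepl("F$", ion_rows$ion)] <- template$dual_attenuation
  }
  base_intensity <- template$ion_intensity[ion_rows$ion]
  if (template$antenna_effect > 0) {
    antennae <- max(1L, n_hexnac - 2L)
    s_ant <- (antennae / 2)^template$antenna_effect
    is_b <- !fragment_specs()$includes_peptide[match(ion_rows$ion, ION_LABELS)]
    is_small_y <- ion_rows$ion %in% c("Y1", "Y1F", "Y2", "Y2F")
    base_intensity[is_b] <- base_intensity[is_b] * s_ant
    base_intensity[is_small_y] <- base_intensity[is_small_y] / s_ant
  }
  intensity <- scale * rlnorm(
    nrow(ion_rows),
    meanlog = log(base_intensity),
    sdlog = template$intensity_sdlog
  )
  # Fucosylation splits each fragment population between the parent ion and
  # its fucosylated partner: when both members of an (X, XF) pair are in the
  # spectrum, a shared split fraction reallocates the pair's intensity.
  if (template$fuc_split > 0) {
    f_ions <- ion_rows$ion[grepl("F$", ion_rows$ion)]
    for (fi in f_ions) {
      parent <- sub("F$", "", fi)
      pi_idx <- match(parent, ion_rows$ion)
      fi_idx <- match(fi, ion_rows$ion)
      if (!is.na(pi_idx)) {
        fs <- template$fuc_split
        phi <- min(0.9, scale[fi_idx] * stats::rbeta(1, 8 * fs, 8 * (1 - fs)))
        total <- intensity[pi_idx]
        intensity[fi_idx] <- phi * total
        intensity[pi_idx] <- (1 - phi) * total
      }
    }
  }
  jitter <- numeric(nrow(ion_rows))
  if (template$mz_jitter_sd > 0) {
    lim <- tolerance / 2
    jitter <- rnorm(nrow(ion_rows), 0, template$mz_jitter_sd)
    while (any(abs(jitter) >= lim)) {
      bad <- abs(jitter) >= lim
      jitter[bad] <- rnorm(sum(bad), 0, template$mz_jitter_sd)
    }
  }
  mzs <- ion_rows$mz + jitter
  ints <- intensity
  if (template$n_noise_peaks > 0) {
    mzs <- c(mzs, runif(template$n_noise_peaks, 150, 2000))
    ints <- c(ints, rlnorm(template$n_noise_peaks,
                           template$noise_meanlog, template$noise_sdlog))
  }
  ord <- order(mzs)
  gp_mass <- peptide_mass(peptide) + glycan_mass(n_hex, n_hexnac, n_fuc, n_sia)
  gp_id <- format_glycopeptide_id(peptide, n_hex, n_hexnac, n_fuc, n_sia)
  list(
    spectrum = tibble(
      title = title,
      precursor_mz = (gp_mass + 2 * .MONO_MASSES[["proton"]]) / 2,
      precursor_charge = 2L,
      peaks = list(tibble(mz = mzs[ord], intensity = ints[ord]))
    ),
    gsm = tibble(
      title = title, glycopeptide_id = gp_id,
      label = factor(template$label, levels = FUCO_CLASSES),
      source = source
    )
  )
}

#' Generate one synthetic glycopeptide-spectrum match
#'
#' Places peaks at the theoretical m/z of the template's present diagnostic
#' ions (with truncated Gaussian jitter and log-normal intensities), adds
#' sub-S/N noise peaks, and returns the spectrum together with its labelled
#' GSM record. Deterministic given `seed`.
#'
#' @param template A [class_template()].
#' @param glycopeptide_id Glycopeptide identifier `PEPTIDE_h_n_f_s`; its
#'   composition must be consistent with the template (core/outer need at
#'   least one fucose, dual at least two).
#' @param seed Integer seed.
#' @param title Spectrum title (must be unique within a dataset).
#' @param source Free-text source tag.
#' @param tolerance Matching tolerance the jitter truncation is tied to.
#' @return A list with elements `spectrum` (one-row spectra tibble) and
#'   `gsm` (one-row GSM tibble carrying the true label).
#' @export
generate_gsm <- function(template, glycopeptide_id, seed = 1L,
                         title = paste0("syn_", glycopeptide_id, "_", seed),
                         source = "synthetic", tolerance = 0.02) {
  gp <- parse_glycopeptide_id(glycopeptide_id)
  withr::with_seed(as.integer(seed), {
    generate_gsm_impl(template, gp$peptide, gp$n_hex, gp$n_hexnac,
                      gp$n_fuc, gp$n_sia, title, source, tolerance)
  })
}

#' Default peptide pool and composition families
#'
#' `default_peptide_pool()` returns tryptic N-glycopeptide backbones of
#' well-characterised plasma glycoproteins (alpha-2-HS-glycoprotein, AGP,
#' IgG, hemopexin). `default_composition_grid()` returns the complex-type
#' glycan composition families the generator draws from, one row per
#' (antennarity, sialylation) combination, without fucose counts (fucose is
#' set by the class).
#'
#' @return A character vector / a tibble with columns `n_hex`, `n_hexnac`,
#'   `n_sia`, `antennarity`.
#' @export
default_peptide_pool <- function() {
  c("VCQDCPLLAPLNDTR", "NEEYNK", "EEQYNSTYR", "ENGTVSR",
    "SWPAVGNCSSALR", "EEQFNSTFR")
}

#' @rdname default_peptide_pool
#' @export
default_composition_grid <- function() {
  base <- tibble(
    n_hex    = c(4L, 5L, 6L, 7L, 6L),
    n_hexnac = c(3L, 4L, 5L, 6L, 3L),
    max_sia  = c(1L, 2L, 3L, 4L, 1L)
  )
  out <- tidyr::unnest(
    dplyr::mutate(base, n_sia = purrr::map(.data$max_sia, ~0:.x)),
    "n_sia"
  )
  out$antennarity <- antennarity_class(out$n_hex, out$n_hexnac)
  dplyr::select(out, "n_hex", "n_hexnac", "n_sia", "antennarity")
}

## Largest-remainder apportionment of n over the class mix.
apportion_counts <- function(n, class_mix) {
  raw <- n * class_mix / sum(class_mix)
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    ord <- order(raw - counts, decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
  }
  as.integer(counts)
}

#' Generate a labelled synthetic dataset
#'
#' Draws a class-labelled population of synthetic GSMs. The class mix
#' defaults to 39/25/21/16% (none/core/outer/dual), echoing the manual
#' class proportions of a curated standard-protein training set, and glycan
#' antennarity correlates with class: outer- and dual-fucosylated GSMs draw
#' tri/tetra-antennary compositions with probability `antennarity_bias`,
#' while none/core draw mono/bi/hybrid ones. Fucose counts follow the
#' class (0 for none, 1 for core/outer, 2 for dual).
#'
#' @param n Total number of GSMs (ignored when `n_per_class` is given).
#' @param n_per_class If not `NULL`, generate exactly this many GSMs of each
#'   of the four classes.
#' @param class_mix Numeric weights over (none, core, outer, dual).
#' @param peptides Peptide pool to sample backbones from.
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @param antennarity_bias Probability that a GSM's composition family is
#'   drawn from its class-typical antennarity group.
#' @param test_fraction Fraction of GSMs tagged `source = "test"` (the rest
#'   are `"train"`); 0 tags everything `"synthetic"`.
#' @param template_args Named list of overrides passed to
#'   [class_template()] for every class.
#' @return A list with `spectra` (spectra tibble) and `gsm` (GSM tibble with
#'   true labels).
#' @export
generate_dataset <- function(n = 400, n_per_class = NULL,
                             class_mix = c(none = 0.39, core = 0.25,
                                           outer = 0.21, dual = 0.16),
                             peptides = default_peptide_pool(),
                             seed = 1L, antennarity_bias = 0.8,
                             test_fraction = 0, template_args = list()) {
  if (length(peptides) == 0) abort("Peptide pool must be non-empty.")
  counts <- if (!is.null(n_per_class)) {
    if (n_per_class < 1) abort("`n_per_class` must be >= 1.")
    rep(as.integer(n_per_class), 4)
  } else {
    apportion_counts(n, class_mix)
  }
  labels <- rep(FUCO_CLASSES, counts)
  templates <- lapply(FUCO_CLASSES, function(cl) {
    do.call(class_template, c(list(label = cl), template_args))
  })
  names(templates) <- FUCO_CLASSES
  comp <- default_composition_grid()
  hi <- comp[comp$antennarity == "tri_tetra", , drop = FALSE]
  lo <- comp[comp$antennarity %in% c("mono", "bi", "hybrid"), , drop = FALSE]

  withr::with_seed(as.integer(seed), {
    out <- vector("list", length(labels))
    for (k in seq_along(labels)) {
      cl <- labels[[k]]
      pool <- if (cl %in% c("outer", "dual")) {
        if (runif(1) < antennarity_bias) hi else lo
      } else {
        if (runif(1) < antennarity_bias) lo else hi
      }
      row <- pool[sample.int(nrow(pool), 1), ]
      n_fuc <- switch(cl, none = 0L, core = 1L, outer = 1L, dual = 2L)
      pep <- sample(peptides, 1)
      src <- if (test_fraction > 0) {
        if (runif(1) < test_fraction) "test" else "train"
      } else "synthetic"
      out[[k]] <- generate_gsm_impl(
        templates[[cl]], pep, row$n_hex, row$n_hexnac, n_fuc, row$n_sia,
        title = sprintf("syn_%05d", k), source = src
      )
    }
    list(
      spectra = dplyr::bind_rows(purrr::map(out, "spectrum")),
      gsm = dplyr::bind_rows(purrr::map(out, "gsm"))
    )
  })
}

#' Rule-based oracle classifier
#'
#' Classifies a feature vector by the diagnostic-ion pairing rule: evidence
#' of a fucosylated glycan-only B ion (B2F, B3F or B3SF above `threshold`)
#' indicates outer fucosylation, evidence of a fucosylated peptide-bearing Y
#' ion (Y1F..Y4F) indicates core fucosylation, both indicate dual, and
#' neither indicates none. This oracle is independent of the trained models
#' and serves as the generator's ground-truth contract.
#'
#' @param features A feature tibble (or named numeric vector) with the 14
#'   ion columns.
#' @param threshold Relative intensity a fucosylated ion must exceed to
#'   count as evidence (default 0: any nonzero signal).
#' @return A factor with levels `fuco_classes()`.
#' @export
oracle_classify <- function(features, threshold = 0) {
  if (is.numeric(features) && is.null(dim(features))) {
    features <- tibble::as_tibble(as.list(features))
  }
  x <- feature_matrix(features)
  b_ev <- apply(x[, c("B2F", "B3F", "B3SF"), drop = FALSE] > threshold, 1, any)
  y_ev <- apply(x[, c("Y1F", "Y2F", "Y3F", "Y4F"), drop = FALSE] > threshold, 1, any)
  cls <- dplyr::case_when(
    b_ev & y_ev ~ "dual",
    b_ev ~ "outer",
    y_ev ~ "core",
    TRUE ~ "none"
  )
  factor(cls, levels = FUCO_CLASSES)
}
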