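#' Parse glycopeptide identifiers
#'
#' Glycopeptide identifications are written as `PEPTIDE_h_n_f_s`, the peptide
#' sequence followed by four underscore-separated glycan counts in the order
#' hexose, N-acetylhexosamine, fucose, sialic acid. For example
#' `VCQDCPLLAPLNDTR_5_4_1_2` is a disialylated, monofucosylated bi-antennary
#' glycopeptide. Identifiers are taken as given; the N-X-S/T sequon is not
#' validated.
#'
#' @param id Character vector of glycopeptide identifiers.
#' @return A tibble with one row per identifier and columns
#'   `glycopeptide_id`, `peptide`, `n_hex`, `n_hexnac`, `n_fuc`, `n_sia`.
#' @seealso [format_glycopeptide_id()] for the inverse.
#' @export
#' @examples
#' parse_glycopeptide_id("VCQDCPLLAPLNDTR_5_4_1_2")
parse_glycopeptide_id <- function(id) {
  rows <- lapply(id, function(x) {
    if (is.na(x) || !nzchar(x)) abort("Glycopeptide identifier is empty.")
    tokens <- strsplit(x, "_", fixed = TRUE)[[1]]
    if (length(tokens) != 5) {
      abort(sprintf(
        "Malformed glycopeptide identifier '%s': expected PEPTIDE plus 4 glycan counts, got %d token(s).",
        x, length(tokens)
      ))
    }
    pep <- tokens[1]
    if (!nzchar(pep)) {
      abort(sprintf("Malformed glycopeptide identifier '%s': empty peptide token.", x))
    }
    if (!grepl("^[A-Z]+$", pep) || !all(strsplit(pep, "")[[1]] %in% names(.AA_MASSES))) {
      abort(sprintf(
        "Malformed glycopeptide identifier '%s': peptide token '%s' contains non-standard residues.",
        x, pep
      ))
    }
    counts <- tokens[2:5]
    bad <- counts[!grepl("^[0-9]+$", counts)]
    if (length(bad) > 0) {
      abort(sprintf(
        "Malformed glycopeptide identifier '%s': non-integer glycan count token '%s'.",
        x, bad[1]
      ))
    }
    n <- as.integer(counts)
    tibble(
      glycopeptide_id = x, peptide = pep,
      n_hex = n[1], n_hexnac = n[2], n_fuc = n[3], n_sia = n[4]
    )
  })
  dplyr::bind_rows(rows)
}

#' @rdname parse_glycopeptide_id
#' @param peptide,n_hex,n_hexnac,n_fuc,n_sia Components to format (vectors
#'   recycled to a common length).
#' @export
format_glycopeptide_id <- function(peptide, n_hex, n_hexnac, n_fuc, n_sia) {
  paste(peptide, n_hex, n_hexnac, n_fuc, n_sia, sep = "_")
}

#' Theoretical m/z of a glycopeptide fragment
#'
#' Computes the m/z of a glycosidic-bond fragment from its glycan residue
#' composition. B-series (oxonium) fragments carry glycan only; Y-series
#' fragments additionally carry the intact peptide. The singly protonated
#' default reproduces the canonical oxonium values, e.g. Hex-HexNAc at
#' m/z 366.1 and Hex-HexNAc-Fuc at m/z 512.2.
#'
#' @param n_hex,n_hexnac,n_fuc,n_sia Glycan residue counts of the fragment.
#' @param peptide Peptide sequence for Y-series fragments, or `NULL` for
#'   B-series (glycan-only) fragments.
#' @param charge Positive integer charge state (default 1; the diagnostic
#'   ions are matched singly charged).
#' @param fixed_mods Fixed modifications passed to [peptide_mass()].
#' @return Numeric m/z.
#' @export
#' @examples
#' fragment_mz(n_hex = 1, n_hexnac = 1)              # B2 oxonium, 366.14
#' fragment_mz(n_hexnac = 1, peptide = "NEEYNK")     # Y1 ion
fragment_mz <- function(n_hex = 0, n_hexnac = 0, n_fuc = 0, n_sia = 0,
                        peptide = NULL, charge = 1L,
                        fixed_mods = .DEFAULT_FIXED_MODS) {
  if (charge < 1) abort("Fragment charge must be a positive integer.")
  neutral <- glycan_mass(n_hex, n_hexnac, n_fuc, n_sia)
  if (!is.null(peptide)) neutral <- neutral + peptide_mass(peptide, fixed_mods)
  (neutral + charge * .MONO_MASSES[["proton"]]) / charge
}

#' The fixed 14-ion diagnostic fragment panel
#'
#' `fragment_specs()` returns the glycan composition and peptide flag of each
#' of the 14 diagnostic fragments: six glycan-only B ions (B2, B2F, B3, B3F,
#' B3S, B3SF) and eight peptide-bearing Y ions (Y1..Y4 and their fucosylated
#' partners Y1F..Y4F). `diagnostic_ions()` evaluates their theoretical m/z
#' for a given peptide. Each fucosylated partner sits exactly one fucose
#' residue mass (146.0579 Da) above its parent ion.
#'
#' @return `fragment_specs()`: a 14-row tibble with columns `ion`, `n_hex`,
#'   `n_hexnac`, `n_fuc`, `n_sia`, `includes_peptide`.
#' @export
#' @examples
#' fragment_specs()
fragment_specs <- function() {
  tibble(
    ion    = ION_LABELS,
    n_hex  = c(1L, 1L, 2L, 2L, 1L, 1L, 0L, 0L, 0L, 0L, 1L, 1L, 2L, 2L),
    n_hexnac = c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L, 2L),
    n_fuc  = c(0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L),
    n_sia  = c(0L, 0L, 0L, 0L, 1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
    includes_peptide = c(rep(FALSE, 6), rep(TRUE, 8))
  )
}

#' @rdname fragment_specs
#' @param peptide Single peptide sequence (required for the Y-series m/z).
#' @param charge Charge state, default 1.
#' @param fixed_mods Fixed modifications passed to [peptide_mass()].
#' @return `diagnostic_ions()`: a 14-row tibble with columns `ion` and `mz`,
#'   in fixed feature order.
#' @export
#' @examples
#' diagnostic_ions("NEEYNK")
diagnostic_ions <- function(peptide, charge = 1L,
                            fixed_mods = .DEFAULT_FIXED_MODS) {
  if (missing(peptide) || is.null(peptide)) {
    abort("Y-series fragments require a peptide sequence.")
  }
  specs <- fragment_specs()
  pep_mass <- peptide_mass(peptide, fixed_mods)
  neutral <- glycan_mass(specs$n_hex, specs$n_hexnac, specs$n_fuc, specs$n_sia) +
    ifelse(specs$includes_peptide, pep_mass, 0)
  tibble(ion = specs$ion, mz = (neutral + charge * .MONO_MASSES[["proton"]]) / charge)
}

#' Antennarity class of a glycan composition
#'
#' Heuristic grouping of N-glycan compositions by branching. Antennae are
#' counted as HexNAc beyond the two chitobiose-core GlcNAcs
#' (`antennae = n_hexnac - 2`); a mannose excess (`n_hex >= antennae + 4`)
#' with at least one antenna flags a hybrid type. Remaining compositions are
#' `mono` (1 antenna), `bi` (2), `tri_tetra` (3-4), or `other`.
#'
#' @param n_hex,n_hexnac Integer vectors of hexose and HexNAc counts.
#' @return Character vector with values in
#'   `c("mono", "bi", "tri_tetra", "hybrid", "other")`.
#' @export
#' @examples
#' antennarity_class(5, 4)  # bi
#' antennarity_class(6, 5)  # tri_tetra
antennarity_class <- function(n_hex, n_hexnac) {
  antennae <- n_hexnac - 2L
  dplyr::case_when(
    antennae >= 1 & n_hex >= antennae + 4 ~ "hybrid",
    antennae == 1 ~ "mono",
    antennae == 2 ~ "bi",
    antennae %in% c(3, 4) ~ "tri_tetra",
    TRUE ~ "other"
  )
}
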