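## Monoisotopic mass model: monosaccharide residues, amino-acid residues,
## water and the proton. All values in Da, residue (dehydrated) masses.

.MONO_MASSES <- c(
  hex    = 162.0528234,   # hexose (Glc/Gal/Man)
  hexnac = 203.0793725,   # N-acetylhexosamine (GlcNAc/GalNAc)
  fuc    = 146.0579088,   # deoxyhexose (fucose)
  neuac  = 291.0954165,   # N-acetylneuraminic acid (sialic acid)
  proton =   1.0072765,
  water  =  18.0105646
)

.AA_MASSES <- c(
  G =  57.021464, A =  71.037114, S =  87.032028, P =  97.052764,
  V =  99.068414, T = 101.047679, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)

.DEFAULT_FIXED_MODS <- c(C = 57.021464)  # carbamidomethyl (iodoacetamide)

#' Monoisotopic mass constants
#'
#' `monosaccharide_masses()` returns the monoisotopic residue masses (Da) of
#' the four carbohydrate building blocks of N-glycans — hexose (`hex`),
#' N-acetylhexosamine (`hexnac`), fucose (`fuc`) and N-acetylneuraminic acid
#' (`neuac`) — plus the proton and water masses used in fragment m/z
#' arithmetic. `amino_acid_masses()` returns the 20 standard amino-acid
#' residue masses.
#'
#' @return A tibble with columns `name` and `mass_da`.
#' @export
#' @examples
#' monosaccharide_masses()
monosaccharide_masses <- function() {
  tibble(name = names(.MONO_MASSES), mass_da = unname(.MONO_MASSES))
}

#' @rdname monosaccharide_masses
#' @export
amino_acid_masses <- function() {
  tibble(name = names(.AA_MASSES), mass_da = unname(.AA_MASSES))
}

#' Monoisotopic neutral mass of a peptide
#'
#' Sum of amino-acid residue masses plus one water, with fixed modifications
#' added per matching residue. The default fixed modification is
#' carbamidomethylation of cysteine (+57.02146 Da), matching iodoacetamide
#' alkylation.
#'
#' @param peptide Character vector of peptide sequences (uppercase, standard
#'   20 amino-acid letters).
#' @param fixed_mods Named numeric vector of per-residue mass additions (Da);
#'   names are single residue letters.
#' @return Numeric vector of neutral monoisotopic masses (Da).
#' @export
#' @examples
#' peptide_mass("NEEYNK")
#' peptide_mass("C", fixed_mods = NULL)
peptide_mass <- function(peptide, fixed_mods = .DEFAULT_FIXED_MODS) {
  vapply(peptide, function(p) {
    if (is.na(p) || !nzchar(p)) {
      abort("Peptide sequence must be a non-empty string.")
    }
    aa <- strsplit(p, "")[[1]]
    unknown <- setdiff(unique(aa), names(.AA_MASSES))
    if (length(unknown) > 0) {
      abort(sprintf(
        "Unknown amino-acid residue(s) in '%s': %s",
        p, paste(unknown, collapse = ", ")
      ))
    }
    m <- sum(.AA_MASSES[aa]) + .MONO_MASSES[["water"]]
    if (length(fixed_mods) > 0) {
      for (res in names(fixed_mods)) {
        m <- m + fixed_mods[[res]] * sum(aa == res)
      }
    }
    m
  }, numeric(1), USE.NAMES = FALSE)
}

glycan_mass <- function(n_hex = 0, n_hexnac = 0, n_fuc = 0, n_sia = 0) {
  n_hex * .MONO_MASSES[["hex"]] + n_hexnac * .MONO_MASSES[["hexnac"]] +
    n_fuc * .MONO_MASSES[["fuc"]] + n_sia * .MONO_MASSES[["neuac"]]
}
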