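test_that("glycopeptide identifiers parse with the Hex_HexNAc_Fuc_Sia suffix order", {
  gp <- parse_glycopeptide_id("VCQDCPLLAPLNDTR_5_4_1_2")
  expect_equal(gp$peptide, "VCQDCPLLAPLNDTR")
  expect_equal(unlist(gp[, c("n_hex", "n_hexnac", "n_fuc", "n_sia")]),
               c(n_hex = 5L, n_hexnac = 4L, n_fuc = 1L, n_sia = 2L))

  gp2 <- parse_glycopeptide_id("EEQYNSTYR_5_4_2_1")
  expect_equal(gp2$n_fuc, 2L)
  expect_equal(gp2$n_sia, 1L)

  gp3 <- parse_glycopeptide_id("A_0_0_0_0")
  expect_equal(gp3$peptide, "A")
  expect_true(all(gp3[, c("n_hex", "n_hexnac", "n_fuc", "n_sia")] == 0))
})

test_that("malformed identifiers fail with the offending token named", {
  expect_error(parse_glycopeptide_id("PEPTIDE_1_2_3"), "token")
  expect_error(parse_glycopeptide_id("PEPTIDE_1_2_3_x"), "x")
  expect_error(parse_glycopeptide_id("_1_2_3_4"), "empty peptide")
  expect_error(parse_glycopeptide_id("PEP1IDE_1_2_3_4"), "non-standard")
})

test_that("parse and format round-trip on generated identifiers", {
  withr::with_seed(11, {
    for (i in 1:25) {
      pep <- paste(sample(c("A", "C", "N", "K", "R", "S", "T", "G", "Y"),
                          sample(4:12, 1), replace = TRUE), collapse = "")
      counts <- sample(0:9, 4, replace = TRUE)
      id <- format_glycopeptide_id(pep, counts[1], counts[2], counts[3], counts[4])
      gp <- parse_glycopeptide_id(id)
      expect_equal(gp$glycopeptide_id, id)
      expect_equal(
        format_glycopeptide_id(gp$peptide, gp$n_hex, gp$n_hexnac,
                               gp$n_fuc, gp$n_sia),
        id
      )
    }
  })
})

test_that("peptide masses match independent monoisotopic values", {
  expect_equal(peptide_mass("G", fixed_mods = NULL), 75.03203, tolerance = 1e-7)
  # Cys + default carbamidomethyl, frozen from an independent mass oracle
  expect_equal(peptide_mass("C"), 178.04121, tolerance = 1e-7)
  expect_error(peptide_mass(""), "non-empty")
  expect_error(peptide_mass("AXA"), "X")
})

test_that("fragment m/z arithmetic is additive and anchored", {
  # glycan-free fragment carries only the proton
  expect_equal(fragment_mz(), 1.00728, tolerance = 1e-5)
  # additivity: adding residues shifts m/z by exactly their residue masses
  masses <- tibble::deframe(monosaccharide_masses())
  base <- fragment_mz(1, 1)
  expect_equal(fragment_mz(2, 1) - base, masses[["hex"]])
  expect_equal(fragment_mz(1, 2) - base, masses[["hexnac"]])
  expect_equal(fragment_mz(1, 1, 1) - base, masses[["fuc"]])
  expect_equal(fragment_mz(1, 1, 0, 1) - base, masses[["neuac"]])
  # Y-type arithmetic includes the peptide neutral mass
  expect_equal(
    fragment_mz(n_hexnac = 1, peptide = "G", fixed_mods = NULL),
    279.11868, tolerance = 1e-5
  )
  # doubly charged halves the proton-adjusted mass
  z2 <- fragment_mz(1, 1, charge = 2)
  expect_equal(2 * z2 - 2 * 1.00728, fragment_mz(1, 1) - 1.00728,
               tolerance = 1e-5)
  expect_error(fragment_mz(1, 1, charge = 0), "positive")
})

test_that("the diagnostic panel has 14 ions in fixed order with fucose-paired spacing", {
  ions <- diagnostic_ions("NEEYNK")
  expect_equal(ions$ion, ion_labels())
  expect_equal(nrow(ions), 14)
  fuc <- tibble::deframe(monosaccharide_masses())[["fuc"]]
  for (parent in c("B2", "B3", "B3S", "Y1", "Y2", "Y3", "Y4")) {
    expect_equal(
      ions$mz[ions$ion == paste0(parent, "F")] - ions$mz[ions$ion == parent],
      fuc, tolerance = 1e-9
    )
  }
  specs <- fragment_specs()
  expect_false(any(specs$includes_peptide[1:6]))
  expect_true(all(specs$includes_peptide[7:14]))
  expect_true(all(specs$n_fuc[grepl("F$", specs$ion)] == 1))
  expect_error(diagnostic_ions(NULL), "peptide")
})

test_that("antennarity classes follow the branching heuristic", {
  expect_equal(antennarity_class(5, 4), "bi")
  expect_equal(antennarity_class(6, 5), "tri_tetra")
  expect_equal(antennarity_class(4, 3), "mono")
  expect_equal(antennarity_class(0, 2), "other")
  # mannose excess with at least one antenna is hybrid, not mono
  expect_equal(antennarity_class(6, 3), "hybrid")
  expect_equal(antennarity_class(c(5, 7), c(4, 6)), c("bi", "tri_tetra"))
})
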