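# Mass scale, modification registry, proteoform masses.

test_that("residue masses match elemental-composition values", {
  # frozen against an independent mass calculator (pyteomics) on the
  # residue formulas C2H3NO, C6H12N2O, C6H7N3O
  expect_equal(residue_mass("G"), 57.02146372057, tolerance = 1e-9)
  expect_equal(residue_mass("K"), 128.094963014, tolerance = 1e-9)
  expect_equal(residue_mass("H"), 137.05891185845, tolerance = 1e-9)
  expect_length(residue_table()$residues, 20L)
  expect_true(all(residue_table()$residues > 0))
  expect_error(residue_mass("B"), "unknown residue")
})

test_that("registry reproduces the search-space deltas and caps", {
  ac <- modification_delta("Acetyl")
  expect_equal(ac$delta, 42.010565, tolerance = 1e-6)
  expect_identical(ac$targets, "K")
  expect_identical(ac$mod_class, "common")
  expect_identical(ac$max_count, 5L)

  ph <- modification_delta("Phospho")
  expect_equal(ph$delta, 79.966331, tolerance = 1e-6)
  expect_setequal(ph$targets, c("S", "T"))
  expect_identical(ph$max_count, 2L)

  ct <- modification_delta("CtermLigationOffset")
  expect_equal(ct$delta, 76.1001, tolerance = 1e-9)
  expect_identical(ct$mod_class, "fixed")
  expect_true(is.na(ct$max_count))

  expect_error(modification_delta("Crotonyl"), "unregistered")
})

test_that("shipped YAML registry agrees with the built-in defaults", {
  path <- system.file("extdata", "modifications.yaml", package = "midtail")
  expect_true(nzchar(path))
  reg <- read_modification_registry(path)
  def <- default_modifications()
  expect_setequal(reg$name, def$name)
  i <- match(def$name, reg$name)
  expect_equal(reg$delta[i], def$delta, tolerance = 1e-4)
  expect_identical(reg$targets[i], def$targets)
  expect_identical(reg$mod_class[i], def$mod_class)
})

test_that("proteoform neutral mass matches an independent oracle", {
  # unmodified tagged H3.1 tail: peptide 3644.0571234 Da (pyteomics on the
  # surrogate sequence) + TMT 229.162932 + C-terminal offset 76.1001
  p <- proteoform("H3.1")
  expect_equal(proteoform_neutral_mass(p), 3949.3201554371, tolerance = 1e-8)

  # additivity: one acetyl adds exactly its delta
  pa <- proteoform("H3.1", "K9ac")
  expect_equal(proteoform_neutral_mass(pa) - proteoform_neutral_mass(p),
               42.010565, tolerance = 1e-6)

  # H3.3 differs from H3.1 by Ser - Ala at position 31
  expect_equal(proteoform_neutral_mass(proteoform("H3.3")) -
                 proteoform_neutral_mass(p),
               15.99491461956, tolerance = 1e-8)
})

test_that("proteoform mass is invariant to mod ordering and add/remove", {
  set.seed(11)
  for (rep in 1:20) {
    p <- random_proteoform()
    if (!nrow(p$mods)) next
    perm <- sample(nrow(p$mods))
    p2 <- proteoform(p$base_id, p$mods[perm, c("position", "name")])
    expect_identical(proteoform_id(p), proteoform_id(p2))
    expect_equal(proteoform_neutral_mass(p), proteoform_neutral_mass(p2))
    # removing the first mod subtracts exactly its delta
    less <- proteoform(p$base_id, p$mods[-1, c("position", "name")])
    expect_equal(proteoform_neutral_mass(p) - proteoform_neutral_mass(less),
                 p$mods$delta[1], tolerance = 1e-9)
  }
})

test_that("proteoform invariants are enforced", {
  expect_error(proteoform("H3.1", "G12(Acetyl)"), "targets")
  expect_error(proteoform("H3.1", "K9(Acetyl);K9(Methyl)"), "at most one")
  expect_error(proteoform("H3.1", "S10(Phospho);T11(Phospho);T22(Phospho)"),
               "more than 2 Phospho")
  expect_error(proteoform("H3.1", "K4(Propionyl);K9(Propionyl)"),
               "more than 1")
  expect_error(
    proteoform("H3.1",
               "K4ac;K9ac;K14ac;K18ac;K23ac;R2me1;T3ph"),
    "more than 6 common")
  expect_error(proteoform("H3.1", "K9(TMT6plex)"), "fixed modification")
})

test_that("proteoform ids follow the field's naming convention", {
  expect_identical(proteoform_id(proteoform("H3.1")), "H3")
  expect_identical(
    proteoform_id(proteoform("H3.1", "K14ac;K27me2;K9ac;K23ac")),
    "H3K9acK14acK23acK27me2")
  expect_identical(proteoform_id(proteoform("H3.3", "K27me3")),
                   "H3.3K27me3")
})

test_that("ppm error is the signed relative deviation in ppm", {
  expect_equal(ppm_error(500, 500.005), 10)
  expect_equal(ppm_error(500, 500.010), 20)
  expect_equal(ppm_error(1000, 1000), 0)
  expect_error(ppm_error(0, 1), "> 0")
})
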