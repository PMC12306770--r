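test_that("formula masses match hand-computed atomic sums", {
  # glycine C2H5NO2 from atomic monoisotopic masses
  gly <- 2 * 12 + 5 * 1.00782503207 + 14.0030740048 + 2 * 15.9949146196
  expect_equal(formula_mass("C2H5NO2"), gly, tolerance = 1e-9)
  expect_equal(formula_mass("C6H12O6"), 180.0634, tolerance = 1e-4)
  expect_error(formula_mass("C6X2"), "unsupported element")
})

test_that("peptide enumeration matches the combinatorial counts", {
  pep <- enumerate_peptides(max_len = 4)
  # compositions: multisets of size 1..4 over 20 residues
  expect_equal(nrow(pep), 20 + 210 + 1540 + 8855)
  expect_equal(nrow(pep), 10625)
  expect_equal(sum(pep$n_sequences), 20 + 20^2 + 20^3 + 20^4)
  expect_equal(sum(pep$n_sequences), 168420)
  expect_equal(anyDuplicated(pep$label), 0L)

  expect_equal(pep$mass[pep$label == "G"], 57.02146 + 18.010565,
               tolerance = 1e-4)
  expect_equal(pep$mass[pep$label == "GG"], 132.05349, tolerance = 1e-4)
})

test_that("peptide masses are additive over residues", {
  pep <- enumerate_peptides(max_len = 4)
  res <- amino_acid_residues()
  lookup <- stats::setNames(res$residue_mass, res$residue)
  withr::with_seed(33, idx <- sample(nrow(pep), 100))
  for (i in idx) {
    parts <- strsplit(pep$label[i], "")[[1]]
    expect_lt(abs(pep$mass[i] - (sum(lookup[parts]) + water_mass)), 1e-4)
  }
})

test_that("amino-sugar masses follow condensation arithmetic", {
  sug <- sugar_masses()
  hexn <- sug$mass[sug$label == "hexosamine"]
  hexnac <- sug$mass[sug$label == "N-acetylhexosamine"]
  expect_equal(hexn, 179.07937, tolerance = 1e-4)
  expect_equal(hexnac, 221.08994, tolerance = 1e-4)
  expect_equal(sug$mass[sug$label == "N-acetylhexosamine dimer"],
               2 * 221.08994 - 18.010565, tolerance = 1e-4)
  # every dimer weighs less than the sum of its monomers (water loss)
  dimers <- sug[grepl("dimer", sug$label), ]
  expect_true(all(dimers$mass < 2 * max(hexn, hexnac)))
})

test_that("adduct arithmetic identifies known ions", {
  cat <- mass_catalog()
  gg <- annotate_ions(133.06077, mode = "positive", catalog = cat)
  expect_true("GG" %in% gg$label)
  expect_lt(min(abs(gg$ppm_error[gg$label == "GG"])), 1)

  dimer <- annotate_ions(423.16204, mode = "negative", catalog = cat)
  expect_true("N-acetylhexosamine dimer" %in% dimer$label)

  none <- annotate_ions(1000.00000, mode = "negative", catalog = cat)
  expect_equal(nrow(none), 0L)

  expect_error(annotate_ions(100, catalog = cat, ppm_tol = 0), "positive")
})

test_that("positive and negative adducts of one neutral differ by two protons", {
  neutral <- 221.08994
  expect_equal((neutral + proton_mass) - (neutral - proton_mass),
               2 * proton_mass)
})

test_that("annotation equals a brute-force linear scan on random m/z values", {
  cat <- mass_catalog(max_len = 2)
  withr::with_seed(44, {
    mzs <- c(
      runif(800, 50, 700),
      # half near true catalog lines so matches actually occur
      sample(cat$mass, 200, replace = TRUE) - proton_mass +
        runif(200, -3e-3, 3e-3)
    )
  })
  got <- annotate_ions(mzs, mode = "negative", catalog = cat, ppm_tol = 5)
  want <- oracle_annotate(mzs, "negative", cat, ppm_tol = 5)
  key <- function(ion, label) paste(ion, label)
  got_key <- key(match(got$mz, mzs), got$label)
  want_key <- key(want$ion, want$label)
  expect_setequal(got_key, want_key)
})

test_that("tightening the tolerance only removes matches", {
  cat <- mass_catalog(max_len = 2)
  withr::with_seed(45, mzs <- runif(300, 50, 700))
  at5 <- annotate_ions(mzs, mode = "negative", catalog = cat, ppm_tol = 5)
  at3 <- annotate_ions(mzs, mode = "negative", catalog = cat, ppm_tol = 3)
  expect_true(all(
    paste(at3$mz, at3$label) %in% paste(at5$mz, at5$label)
  ))
  expect_lte(nrow(at3), nrow(at5))
})

test_that("class-prediction filtering applies all three thresholds", {
  rows <- tibble::tibble(
    feature = 1:5,
    intensity_explained = c(0.6, 0.4, 0.7, 0.9, 0.5),
    isotope_score = c(6, 9, NA, 4, 5),
    class_probability = c(0.80, 0.99, 0.75, 0.9, 0.749)
  )
  kept <- filter_class_predictions(rows)
  # (0.6, 6, 0.80) kept; (0.4, 9, 0.99) fails intensity; (0.7, absent, 0.75)
  # kept since the isotope rule applies only if present and 0.75 is
  # inclusive; (0.9, 4, 0.9) fails isotope; (0.5, 5, 0.749) fails class prob
  expect_equal(kept$feature, c(1L, 3L))
  expect_error(
    filter_class_predictions(dplyr::mutate(rows, class_probability = 1.2)),
    "\\[0, 1\\]"
  )
})

test_that("user compound tables join the catalog via formula parsing", {
  user <- data.frame(label = c("glucose", "pyruvate"),
                     formula = c("C6H12O6", "C3H4O3"))
  cat <- mass_catalog(peptides = FALSE, sugars = FALSE, user = user)
  expect_equal(nrow(cat), 2L)
  hit <- annotate_ions(179.0556, mode = "negative", catalog = cat)
  expect_equal(hit$label, "glucose")
})
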