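test_that("carbon budget closes to 100 and derives the exudate share", {
  b <- carbon_budget(33, 4.1, 11)
  expect_equal(b$co2_pct, 51.9)
  expect_equal(b$eps_share_of_exudate, 100 * 4.1 / 15.1)
  expect_equal(round(b$eps_share_of_exudate, 1), 27.2)

  b2 <- carbon_budget(36, 4.5, 14)
  expect_equal(b2$co2_pct, 45.5)
  expect_equal(round(b2$eps_share_of_exudate, 1), 24.3)

  both <- carbon_budget(c(33, 36), c(4.1, 4.5), c(11, 14))
  expect_equal(both$biomass_pct + both$eps_pct + both$lmw_pct + both$co2_pct,
               c(100, 100))

  expect_error(carbon_budget(90, 8, 5), "exceed 100")
  expect_error(carbon_budget(-1, 4, 11), "non-negative")
  expect_warning(zero <- carbon_budget(0, 0, 0), "undefined")
  expect_equal(zero$co2_pct, 100)
  expect_true(is.na(zero$eps_share_of_exudate))
})

test_that("budget tidiers reshape without losing the balance", {
  b <- carbon_budget(c(33, 36), c(4.1, 4.5), c(11, 14))
  long <- tidy(b)
  expect_equal(
    as.vector(tapply(long$percent, long$.row, sum)), c(100, 100)
  )
  g <- glance(b)
  expect_equal(c(g$co2_min, g$co2_max), c(45.5, 51.9))
})

test_that("EPS yield converts between mg/g and percent", {
  y <- eps_yield(90, 2)
  expect_equal(y$yield_mg_per_g, 45)
  expect_equal(y$yield_pct, 4.5)
  expect_equal(eps_yield(0, 1)$yield_mg_per_g, 0)
  expect_equal(eps_yield(c(40, 70), 1)$yield_pct, c(4, 7))
  expect_error(eps_yield(10, 0), "positive")
})

test_that("polymer ranges add elementwise", {
  r <- combined_polymer_fraction(c(13, 23), c(9, 36))
  expect_equal(c(r$low, r$high), c(22, 59))
  r0 <- combined_polymer_fraction(c(0, 0), c(9, 36))
  expect_equal(c(r0$low, r0$high), c(9, 36))
  expect_lte(r$low, r$high)
  expect_error(combined_polymer_fraction(c(23, 13), c(9, 36)), "low <= high")
})

test_that("monosaccharide weight fractions are MW-weighted and sum to one", {
  one <- monosaccharide_mass_fractions(
    data.frame(sugar = "glucose", conc_um = 5)
  )
  expect_equal(one$weight_fraction, 1)

  two <- monosaccharide_mass_fractions(
    data.frame(sugar = c("glucose", "N-acetylglucosamine"),
               conc_um = c(10, 10))
  )
  expect_equal(two$weight_fraction, c(0.4489, 0.5511), tolerance = 1e-4)

  multi <- monosaccharide_mass_fractions(
    data.frame(
      sample = rep(c("s1", "s2"), each = 2),
      sugar = rep(c("glucose", "fucose"), 2),
      conc_um = c(1, 2, 3, 4)
    )
  )
  sums <- tapply(multi$weight_fraction, multi$sample, sum)
  expect_true(all(abs(sums - 1) < 1e-12))

  expect_error(
    monosaccharide_mass_fractions(
      data.frame(sugar = "glucose", conc_um = 0)
    ),
    "zero"
  )
  expect_error(
    monosaccharide_mass_fractions(
      data.frame(sugar = "unobtainium", conc_um = 1)
    ),
    "unknown molecular weight"
  )
})

test_that("anhydro masses are the free sugar minus one water", {
  free <- monosaccharide_masses()
  anh <- monosaccharide_masses(anhydro = TRUE)
  expect_equal(free$mass - anh$mass, rep(water_mass, nrow(free)))
  expect_equal(nrow(free), 17L)
})

test_that("mock medium keeps sugars above the inclusion threshold", {
  sugars <- data.frame(
    sugar = c("galactose", "galacturonic acid", "glucosamine", "glucose",
              "rhamnose"),
    conc_um = c(13, 17, 22, 20, 0.5)
  )
  recipe <- mock_medium(sugars)
  expect_setequal(
    recipe$component,
    c("galactose", "galacturonic acid", "glucosamine", "glucose",
      "bovine serum albumin")
  )
  expect_equal(recipe$amount[recipe$component == "bovine serum albumin"], 150)
  expect_false("rhamnose" %in% recipe$component)

  sugars_only <- mock_medium(sugars, protein_mg_per_l = 0)
  expect_false("bovine serum albumin" %in% sugars_only$component)
  expect_error(mock_medium(sugars, protein_mg_per_l = -1), "non-negative")
})

test_that("Coble peaks integrate their rectangular windows", {
  ex <- seq(250, 450, by = 5)
  em <- seq(300, 600, by = 5)
  uniform <- eem_grid(ex, em, matrix(3, length(ex), length(em)))
  peaks <- coble_peaks(uniform)
  expect_equal(peaks$value, c(3, 3))

  # signal confined to the M window leaves peak C at zero
  vals <- matrix(0, length(ex), length(em))
  vals[ex >= 290 & ex <= 310, em >= 370 & em <= 410] <- 7
  m_only <- eem_grid(ex, em, vals)
  peaks2 <- coble_peaks(m_only)
  expect_equal(peaks2$value[peaks2$peak == "M"], 7)
  expect_equal(peaks2$value[peaks2$peak == "C"], 0)

  # linearity: scaling the grid scales both peaks
  peaks3 <- coble_peaks(eem_grid(ex, em, 2.5 * vals))
  expect_equal(peaks3$value, 2.5 * peaks2$value)

  # window counts on the 5-nm grid: (5 ex) x (9 em)
  expect_equal(peaks$n_points, c(5 * 9, 9 * 9))

  small <- eem_grid(seq(300, 400, 5), seq(350, 500, 5),
                    matrix(1, 21, 31))
  expect_error(coble_peaks(small), "outside")
})

test_that("EEM grids round-trip through the wide CSV reader", {
  ex <- seq(250, 450, by = 5)
  em <- seq(300, 600, by = 5)
  withr::with_seed(66, vals <- matrix(runif(length(ex) * length(em)),
                                      length(ex), length(em)))
  g <- eem_grid(ex, em, vals)
  path <- withr::local_tempfile(fileext = ".csv")
  wide <- cbind(excitation = ex, as.data.frame(vals))
  names(wide)[-1] <- em
  readr::write_csv(as.data.frame(wide), path)
  back <- read_eem_csv(path)
  expect_equal(back$fluorescence, g$fluorescence, tolerance = 1e-12)
})
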