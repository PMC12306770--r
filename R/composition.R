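#' Monoisotopic masses of the quantified monosaccharide standards
#'
#' The 17 monosaccharide standards quantified after acid hydrolysis of EPS
#' polysaccharides, with molecular formulas and neutral monoisotopic masses.
#'
#' @param anhydro Return anhydro (in-chain) masses, i.e. the free
#'   monosaccharide minus one water? Default `FALSE` (free monosaccharide).
#' @return A tibble with columns `sugar`, `formula`, `mass` (Da).
#' @export
monosaccharide_masses <- function(anhydro = FALSE) {
  tab <- tibble(
    sugar = c(
      "galacturonic acid", "glucuronic acid", "mannuronic acid",
      "guluronic acid", "xylose", "arabinose", "ribose",
      "fucose", "rhamnose",
      "glucose", "galactose", "mannose",
      "glucosamine", "galactosamine",
      "N-acetylglucosamine", "N-acetylgalactosamine", "N-acetylmannosamine"
    ),
    formula = c(
      rep("C6H10O7", 4L), rep("C5H10O5", 3L), rep("C6H12O5", 2L),
      rep("C6H12O6", 3L), rep("C6H13NO5", 2L), rep("C8H15NO6", 3L)
    )
  )
  tab$mass <- formula_mass(tab$formula)
  if (anhydro) {
    tab$mass <- tab$mass - water_mass
  }
  tab
}

#' Weight fractions of monosaccharides from molar concentrations
#'
#' Converts per-sugar molar concentrations (from hydrolysed EPS
#' polysaccharides) into mass fractions: `fraction_i = c_i * MW_i /
#' sum_j(c_j * MW_j)`. Fractions sum to 1 within each sample.
#'
#' @param concentrations A data frame with columns `sugar` and `conc_um`
#'   (micromolar), optionally `sample` (fractions are computed per sample)
#'   and `mw` (g/mol; looked up from [monosaccharide_masses()] when absent).
#' @param masses Lookup table of sugar masses used when `mw` is absent.
#' @return The input with `mw` and `weight_fraction` columns appended.
#' @examples
#' monosaccharide_mass_fractions(
#'   data.frame(sugar = c("glucose", "N-acetylglucosamine"),
#'              conc_um = c(10, 10))
#' )
#' @export
monosaccharide_mass_fractions <- function(concentrations,
                                          masses = monosaccharide_masses()) {
  concentrations <- as_tibble(concentrations)
  if (!all(c("sugar", "conc_um") %in% names(concentrations))) {
    abort("need 'sugar' and 'conc_um' columns")
  }
  if (any(concentrations$conc_um < 0, na.rm = TRUE)) {
    abort("concentrations must be non-negative")
  }
  if (!"sample" %in% names(concentrations)) {
    concentrations$sample <- "sample"
    drop_sample <- TRUE
  } else {
    drop_sample <- FALSE
  }
  if (!"mw" %in% names(concentrations)) {
    concentrations$mw <- masses$mass[match(concentrations$sugar, masses$sugar)]
  }
  if (any(is.na(concentrations$mw))) {
    missing_sugars <- unique(
      concentrations$sugar[is.na(concentrations$mw)]
    )
    abort(paste(
      "unknown molecular weight for:",
      paste(missing_sugars, collapse = ", ")
    ))
  }
  out <- concentrations |>
    group_by(.data$sample) |>
    mutate(
      weight_fraction = {
        w <- .data$conc_um * .data$mw
        if (sum(w, na.rm = TRUE) <= 0) {
          abort("all concentrations are zero in at least one sample")
        }
        w / sum(w, na.rm = TRUE)
      }
    ) |>
    ungroup()
  if (drop_sample) {
    out$sample <- NULL
  }
  out
}

#' Formulate a mock EPS medium
#'
#' Builds a defined medium reconstructing the measurable protein and
#' monosaccharide content of an EPS, to test whether those components
#' suffice to explain growth on the real polymer. Sugars are included only at
#' concentrations greater than the threshold (default 1 uM); protein is
#' supplied as bovine serum albumin.
#'
#' @param sugars A data frame with columns `sugar` and `conc_um` (uM).
#' @param protein_mg_per_l Protein concentration, mg/L (default 150; 0 gives
#'   a sugars-only recipe). Must be non-negative.
#' @param include_threshold_um Minimum sugar concentration, uM; sugars at or
#'   below it are excluded. Default 1.
#' @return A tibble recipe with columns `component`, `amount`, `unit`.
#' @examples
#' mock_medium(
#'   data.frame(sugar = c("galactose", "galacturonic acid", "glucosamine",
#'                        "glucose"),
#'              conc_um = c(13, 17, 22, 20))
#' )
#' @export
mock_medium <- function(sugars, protein_mg_per_l = 150,
                        include_threshold_um = 1) {
  sugars <- as_tibble(sugars)
  if (!all(c("sugar", "conc_um") %in% names(sugars))) {
    abort("sugars need 'sugar' and 'conc_um' columns")
  }
  if (include_threshold_um < 0) {
    abort("include_threshold_um must be non-negative")
  }
  if (protein_mg_per_l < 0) {
    abort("protein_mg_per_l must be non-negative")
  }
  kept <- filter(sugars, .data$conc_um > include_threshold_um)
  recipe <- tibble(
    component = kept$sugar, amount = kept$conc_um, unit = "uM"
  )
  if (protein_mg_per_l > 0) {
    recipe <- bind_rows(recipe, tibble(
      component = "bovine serum albumin", amount = protein_mg_per_l,
      unit = "mg/L"
    ))
  }
  recipe
}
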