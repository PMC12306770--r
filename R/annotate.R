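#' Annotate ions by exact mass against a catalog
#'
#' Matches observed m/z values to neutral monoisotopic masses in a catalog
#' under a single protonation adduct: \eqn{[M-H]^-} in negative mode,
#' \eqn{[M+H]^+} in positive mode. A catalog entry matches when the relative
#' deviation between the observed m/z and the entry's theoretical adduct m/z
#' is within `ppm_tol` parts per million. Matches are putative: isomers (and
#' the isobaric Leu/Ile pair) are indistinguishable by exact mass.
#'
#' @param ions A data frame with an `mz` column (other columns are carried
#'   through), or a bare numeric vector of m/z values.
#' @param mode `"negative"` or `"positive"` ionization.
#' @param catalog A catalog from [mass_catalog()] (or any data frame with
#'   `label`, `mass`, `source`).
#' @param ppm_tol Mass tolerance in ppm (default 5). Must be positive.
#' @return A tibble with one row per (ion, matching catalog entry):
#'   the input columns plus `label`, `source`, `catalog_mass`, `theoretical_mz`
#'   and `ppm_error` (signed, observed minus theoretical). Within each ion,
#'   matches are sorted by absolute ppm error. Ions without matches are absent.
#' @examples
#' annotate_ions(133.06077, mode = "positive", catalog = mass_catalog())
#' @export
annotate_ions <- function(ions, mode = c("negative", "positive"),
                          catalog = mass_catalog(), ppm_tol = 5) {
  mode <- match.arg(mode)
  if (!is.numeric(ppm_tol) || length(ppm_tol) != 1L || ppm_tol <= 0) {
    abort("ppm_tol must be a single positive number")
  }
  if (is.numeric(ions)) {
    ions <- tibble(mz = as.numeric(ions))
  }
  ions <- as_tibble(ions)
  if (!"mz" %in% names(ions)) {
    abort("ions must have an 'mz' column")
  }
  catalog <- arrange(as_tibble(catalog), .data$mass)
  shift <- if (mode == "negative") -proton_mass else proton_mass
  theo_mz <- catalog$mass + shift
  ord <- order(theo_mz)
  theo_sorted <- theo_mz[ord]

  hit_rows <- vector("list", nrow(ions))
  for (i in seq_len(nrow(ions))) {
    mz <- ions$mz[[i]]
    half <- ppm_tol * 1e-6
    lo <- findInterval(mz / (1 + half), theo_sorted) + 1L
    hi <- findInterval(mz * (1 + half), theo_sorted)
    if (hi < lo) next
    cand <- ord[lo:hi]
    ppm <- (mz - theo_mz[cand]) / theo_mz[cand] * 1e6
    keep <- abs(ppm) <= ppm_tol
    if (!any(keep)) next
    cand <- cand[keep]
    ppm <- ppm[keep]
    o <- order(abs(ppm), catalog$mass[cand])
    hit_rows[[i]] <- tibble(
      .ion_row = i,
      label = catalog$label[cand][o],
      source = catalog$source[cand][o],
      catalog_mass = catalog$mass[cand][o],
      theoretical_mz = theo_mz[cand][o],
      ppm_error = ppm[o]
    )
  }
  hits <- bind_rows(hit_rows)
  if (nrow(hits) == 0L) {
    return(tibble(
      ions[0, , drop = FALSE],
      label = character(), source = character(),
      catalog_mass = numeric(), theoretical_mz = numeric(),
      ppm_error = numeric()
    ))
  }
  out <- dplyr::bind_cols(
    ions[hits$.ion_row, , drop = FALSE],
    hits[, setdiff(names(hits), ".ion_row")]
  )
  as_tibble(out)
}

#' Filter MS2 compound-class predictions
#'
#' Applies the quality filter used for fragmentation-based compound-class
#' predictions: a row is retained when the fraction of spectrum intensity
#' explained is at least 0.5, the isotope score (when present) is at least 5,
#' and the most specific class probability is at least 0.75.
#'
#' @param rows A data frame with columns `intensity_explained` (in `[0, 1]`),
#'   `isotope_score` (numeric, `NA` when no isotope pattern was scored) and
#'   `class_probability` (in `[0, 1]`). Other columns are carried through.
#' @param min_intensity_explained,min_isotope_score,min_class_probability
#'   Filter thresholds; defaults 0.5, 5 and 0.75.
#' @return The retained rows, as a tibble.
#' @export
filter_class_predictions <- function(rows,
                                     min_intensity_explained = 0.5,
                                     min_isotope_score = 5,
                                     min_class_probability = 0.75) {
  rows <- as_tibble(rows)
  needed <- c("intensity_explained", "isotope_score", "class_probability")
  missing_cols <- setdiff(needed, names(rows))
  if (length(missing_cols) > 0L) {
    abort(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  }
  bad_prob <- function(p) any(!is.na(p) & (p < 0 | p > 1))
  if (bad_prob(rows$intensity_explained) || bad_prob(rows$class_probability)) {
    abort("probabilities must lie within [0, 1]")
  }
  filter(
    rows,
    .data$intensity_explained >= min_intensity_explained,
    is.na(.data$isotope_score) | .data$isotope_score >= min_isotope_score,
    .data$class_probability >= min_class_probability
  )
}
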