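#' Carbon mass-balance of a chitin-fed culture
#'
#' Partitions the input substrate carbon into biomass, EPS, low-molecular-
#' weight (LMW) metabolites and a CO2 remainder (carbon unaccounted for after
#' the three measured fractions is attributed to respiration). Also derives
#' the EPS share of the exuded carbon, `eps / (eps + lmw)` — the headline
#' quantity for how much of a degrader's exudate is polymeric.
#'
#' @param biomass_pct,eps_pct,lmw_pct Percent of input substrate carbon
#'   recovered in each measured fraction. Vectors are recycled to a common
#'   length so range endpoints can be computed in one call. All entries must
#'   be non-negative and sum to at most 100 within each row.
#' @return An object of class `carbon_budget`: a tibble with columns
#'   `biomass_pct`, `eps_pct`, `lmw_pct`, `co2_pct` (the remainder, closing
#'   the balance to exactly 100) and `eps_share_of_exudate` (percent; `NA`
#'   with a warning when no carbon was exuded).
#' @examples
#' carbon_budget(biomass_pct = c(33, 36), eps_pct = c(4.1, 4.5),
#'               lmw_pct = c(11, 14))
#' @export
carbon_budget <- function(biomass_pct, eps_pct, lmw_pct) {
  n <- max(length(biomass_pct), length(eps_pct), length(lmw_pct))
  biomass_pct <- rep_len(as.numeric(biomass_pct), n)
  eps_pct <- rep_len(as.numeric(eps_pct), n)
  lmw_pct <- rep_len(as.numeric(lmw_pct), n)
  if (any(c(biomass_pct, eps_pct, lmw_pct) < 0)) {
    abort("carbon fractions must be non-negative")
  }
  total <- biomass_pct + eps_pct + lmw_pct
  if (any(total > 100)) {
    abort("measured fractions exceed 100% of input carbon")
  }
  exuded <- eps_pct + lmw_pct
  share <- ifelse(exuded > 0, 100 * eps_pct / exuded, NA_real_)
  if (any(exuded == 0)) {
    warn("no exuded carbon: EPS share of exudate is undefined")
  }
  out <- tibble(
    biomass_pct = biomass_pct, eps_pct = eps_pct, lmw_pct = lmw_pct,
    co2_pct = 100 - total, eps_share_of_exudate = share
  )
  class(out) <- c("carbon_budget", class(out))
  out
}

#' @describeIn carbon_budget Long tibble (fraction, percent) per budget row.
#' @param x A `carbon_budget`.
#' @param ... Unused.
#' @method tidy carbon_budget
#' @export
tidy.carbon_budget <- function(x, ...) {
  as_tibble(x) |>
    mutate(.row = dplyr::row_number()) |>
    tidyr::pivot_longer(
      c("biomass_pct", "eps_pct", "lmw_pct", "co2_pct"),
      names_to = "fraction", values_to = "percent"
    ) |>
    mutate(fraction = sub("_pct$", "", .data$fraction)) |>
    select(".row", "fraction", "percent", "eps_share_of_exudate")
}

#' @describeIn carbon_budget One-row summary across budget rows: ranges of
#'   the CO2 remainder and of the EPS share of exudate.
#' @method glance carbon_budget
#' @export
glance.carbon_budget <- function(x, ...) {
  tibble(
    n = nrow(x),
    co2_min = min(x$co2_pct), co2_max = max(x$co2_pct),
    eps_share_min = min(x$eps_share_of_exudate, na.rm = TRUE),
    eps_share_max = max(x$eps_share_of_exudate, na.rm = TRUE)
  )
}

#' EPS yield from consumed chitin
#'
#' @param dried_eps_mg Dried EPS recovered, mg. Non-negative.
#' @param chitin_consumed_g Chitin consumed, g. Must be positive.
#' @return A tibble with `yield_mg_per_g` (mg EPS per g chitin) and
#'   `yield_pct` (the same yield as percent dry mass, i.e. mg/g divided by
#'   10).
#' @examples
#' eps_yield(90, 2) # 45 mg/g = 4.5%
#' @export
eps_yield <- function(dried_eps_mg, chitin_consumed_g) {
  if (any(chitin_consumed_g <= 0)) {
    abort("chitin_consumed_g must be positive")
  }
  if (any(dried_eps_mg < 0)) {
    abort("dried_eps_mg must be non-negative")
  }
  y <- dried_eps_mg / chitin_consumed_g
  tibble(yield_mg_per_g = y, yield_pct = y / 10)
}

#' Combine measured polymer mass-fraction ranges
#'
#' Adds a protein and a polysaccharide mass-fraction range elementwise, giving
#' the combined share of EPS accounted for by the two hydrolysable polymer
#' classes.
#'
#' @param protein_range,polysaccharide_range Length-2 numeric vectors
#'   `c(low, high)` in percent (g/g), `low <= high`.
#' @return A tibble with `low` and `high` of the combined range.
#' @examples
#' combined_polymer_fraction(c(13, 23), c(9, 36)) # 22-59%
#' @export
combined_polymer_fraction <- function(protein_range, polysaccharide_range) {
  for (r in list(protein_range, polysaccharide_range)) {
    if (length(r) != 2L || r[1] > r[2]) {
      abort("ranges must be c(low, high) with low <= high")
    }
  }
  tibble(
    low = protein_range[1] + polysaccharide_range[1],
    high = protein_range[2] + polysaccharide_range[2]
  )
}
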