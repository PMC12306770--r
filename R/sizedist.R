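#' Default m/z bin edges for size distributions
#'
#' The acquisition window starts at 50 m/z; subsequent edges run every
#' 200 m/z up to the 1,800 m/z detection limit, so the top bin is
#' 1,600-1,800.
#'
#' @return Numeric vector of ascending bin edges.
#' @export
default_mz_bins <- function() {
  c(50, seq(200, 1800, by = 200))
}

.bin_mz <- function(mz, bin_edges) {
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    abort("bin_edges must be strictly ascending")
  }
  # half-open [low, high) bins; a final Inf edge yields an unbounded top bin
  idx <- findInterval(mz, bin_edges, left.open = FALSE)
  idx[mz >= bin_edges[length(bin_edges)]] <- NA_integer_
  idx[idx == 0L] <- NA_integer_
  idx
}

.bin_labels <- function(bin_edges) {
  lo <- bin_edges[-length(bin_edges)]
  hi <- bin_edges[-1]
  sprintf(
    "[%s, %s)", format(lo, trim = TRUE),
    ifelse(is.finite(hi), format(hi, trim = TRUE), "Inf")
  )
}

#' Category fractions per m/z bin
#'
#' Computes, for each m/z size bin, the fraction of categorized ions falling
#' into each of the three temporal categories. Fractions within a bin sum to
#' 1; bins containing no categorized ions are absent from the output.
#'
#' @param result An [classify_table()] result (`ion_categories`), or a tibble
#'   with columns `mz` and `category`.
#' @param bin_edges Ascending bin edges defining half-open bins
#'   `[low, high)`; default [default_mz_bins()]. The last edge may be `Inf`.
#' @return A tibble with columns `bin`, `bin_low`, `bin_high`, `category`,
#'   `n` and `fraction`.
#' @export
mz_category_distribution <- function(result, bin_edges = default_mz_bins()) {
  ions <- if (inherits(result, "ion_categories")) result$ions else
    as_tibble(result)
  if (!all(c("mz", "category") %in% names(ions))) {
    abort("need 'mz' and 'category' columns")
  }
  ions <- filter(
    ions, .data$category %in% c("decreased", "bell", "increased")
  )
  ions$bin <- .bin_mz(ions$mz, bin_edges)
  ions <- filter(ions, !is.na(.data$bin))
  if (nrow(ions) == 0L) {
    return(tibble(
      bin = character(), bin_low = numeric(), bin_high = numeric(),
      category = character(), n = integer(), fraction = numeric()
    ))
  }
  labs <- .bin_labels(bin_edges)
  ions |>
    mutate(category = factor(.data$category,
                             levels = c("decreased", "bell", "increased"))) |>
    group_by(.data$bin) |>
    dplyr::count(.data$category, .drop = FALSE) |>
    mutate(fraction = .data$n / sum(.data$n)) |>
    ungroup() |>
    mutate(
      bin_low = bin_edges[.data$bin],
      bin_high = bin_edges[.data$bin + 1L],
      bin = labs[.data$bin],
      category = as.character(.data$category)
    ) |>
    select("bin", "bin_low", "bin_high", "category", "n", "fraction")
}

#' Align ion features across digests
#'
#' Clusters feature lists by m/z and retention-time proximity: two features
#' belong to the same cluster when their relative m/z difference is within
#' `ppm_tol` ppm of their mean m/z and their retention times differ by at
#' most `rt_tol` minutes, with the relation closed transitively
#' (single linkage). Output is deterministic: clusters are numbered by their
#' lowest member in ascending (m/z, retention time) order, so permuting the
#' input rows or digests only permutes row order.
#'
#' @param features A feature table (one row per ion and digest) with columns
#'   `mz`, `rt_min`, `digest`, and `mode` (see [ion_features()]); or a
#'   `digest_dataset`.
#' @param ppm_tol Pairwise m/z tolerance in ppm (default 8).
#' @param rt_tol Pairwise retention-time tolerance in minutes (default 0.1).
#' @param allow_mixed_mode Features from both ionization modes may never
#'   co-elute into one cluster; mixing modes in one call is an error unless
#'   this is `TRUE` (in which case modes are still aligned separately).
#' @return The input tibble with an integer `cluster` column appended.
#' @export
align_ions <- function(features, ppm_tol = 8, rt_tol = 0.1,
                       allow_mixed_mode = FALSE) {
  if (inherits(features, "digest_dataset")) {
    features <- ion_features(features)
  }
  features <- as_tibble(features)
  if (!all(c("mz", "rt_min") %in% names(features))) {
    abort("features need 'mz' and 'rt_min' columns")
  }
  if (ppm_tol <= 0 || rt_tol <= 0) {
    abort("ppm_tol and rt_tol must be positive")
  }
  modes <- if ("mode" %in% names(features)) unique(features$mode) else "all"
  if (length(modes) > 1L && !allow_mixed_mode) {
    abort("features mix ionization modes; set allow_mixed_mode = TRUE to align each mode separately")
  }
  n <- nrow(features)
  if (n == 0L) {
    features$cluster <- integer()
    return(features)
  }

  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union_ <- function(i, j) {
    ri <- find(i)
    rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }

  mode_vec <- if ("mode" %in% names(features)) features$mode else
    rep("all", n)
  for (md in unique(mode_vec)) {
    rows <- which(mode_vec == md)
    ord <- rows[order(features$mz[rows], features$rt_min[rows])]
    mzs <- features$mz[ord]
    rts <- features$rt_min[ord]
    m <- length(ord)
    for (a in seq_len(m)) {
      b <- a + 1L
      while (b <= m && (mzs[b] - mzs[a]) <= ppm_tol * 1e-6 * mzs[b]) {
        mean_mz <- (mzs[a] + mzs[b]) / 2
        if (abs(mzs[b] - mzs[a]) / mean_mz <= ppm_tol * 1e-6 &&
            abs(rts[b] - rts[a]) <= rt_tol) {
          union_(ord[a], ord[b])
        }
        b <- b + 1L
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  # deterministic numbering: clusters ordered by their minimal (mz, rt) member
  rep_order <- order(features$mz, features$rt_min)
  first_seen <- rep_order[!duplicated(roots[rep_order])]
  cluster_id <- setNames(seq_along(first_seen), roots[first_seen])
  features$cluster <- unname(cluster_id[as.character(roots)])
  features
}

#' Cross-digest sharing of ions by m/z bin
#'
#' Given aligned features (typically restricted to the "increased" category,
#' i.e. terminal digestion products), computes per m/z bin the fraction of
#' aligned ions detected in more than one digest. An aligned ion (cluster) is
#' "shared" when its members span at least two digests; its m/z is the mean
#' member m/z. Bins without ions are absent from the output.
#'
#' @param aligned Output of [align_ions()] (needs `cluster`, `mz`, `digest`).
#' @param bin_edges Ascending half-open bin edges; the default covers
#'   50-1,400 in 200 m/z steps with an unbounded `[1400, Inf)` top bin, so
#'   "ions above 1,400 m/z" form one bin.
#' @return A tibble with `bin`, `bin_low`, `bin_high`, `n_ions`, `n_shared`
#'   and `shared_fraction`.
#' @export
sharing_by_mz <- function(aligned,
                          bin_edges = c(50, seq(200, 1400, by = 200), Inf)) {
  aligned <- as_tibble(aligned)
  if (!all(c("cluster", "mz", "digest") %in% names(aligned))) {
    abort("aligned features need 'cluster', 'mz' and 'digest' columns")
  }
  clusters <- aligned |>
    group_by(.data$cluster) |>
    summarise(
      mz = mean(.data$mz),
      shared = dplyr::n_distinct(.data$digest) >= 2L,
      .groups = "drop"
    )
  clusters$bin <- .bin_mz(clusters$mz, bin_edges)
  clusters <- filter(clusters, !is.na(.data$bin))
  labs <- .bin_labels(bin_edges)
  clusters |>
    group_by(.data$bin) |>
    summarise(
      n_ions = dplyr::n(),
      n_shared = sum(.data$shared),
      shared_fraction = mean(.data$shared),
      .groups = "drop"
    ) |>
    mutate(
      bin_low = bin_edges[.data$bin],
      bin_high = bin_edges[.data$bin + 1L],
      bin = labs[.data$bin]
    ) |>
    select("bin", "bin_low", "bin_high", "n_ions", "n_shared",
           "shared_fraction")
}
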