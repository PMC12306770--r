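#' Parameters of the temporal-profile classifier
#'
#' @param tau_increase log2 fold-change threshold (final vs. initial
#'   timepoint) at or above which an ion is "increased". Default 10, the
#'   selection rule used for terminal digestion products.
#' @param tau_decrease Magnitude of the log2 fold-change threshold at or
#'   below minus which an ion is "decreased". Default 1 (a 2-fold drop).
#' @param bell_prominence Fold by which the smoothed interior maximum must
#'   exceed both endpoints for a "bell" call. Default 2.
#' @param floor_quantile Quantile of the nonzero intensities (per digest)
#'   used as the imputation floor for missing/zero values. Default 0.01.
#' @param smooth_window Odd width of the moving-median smoother applied
#'   before bell detection (robustness against single-timepoint spikes).
#'   Default 3; 1 disables smoothing.
#' @return An object of class `classifier_params`.
#' @export
classifier_params <- function(tau_increase = 10, tau_decrease = 1,
                              bell_prominence = 2, floor_quantile = 0.01,
                              smooth_window = 3) {
  if (tau_increase <= 0 || tau_decrease <= 0 || bell_prominence <= 0) {
    abort("thresholds must be positive")
  }
  if (floor_quantile < 0 || floor_quantile > 1) {
    abort("floor_quantile must lie within [0, 1]")
  }
  smooth_window <- as.integer(smooth_window)
  if (smooth_window < 1L || smooth_window %% 2L == 0L) {
    abort("smooth_window must be an odd integer >= 1")
  }
  structure(
    list(
      tau_increase = tau_increase, tau_decrease = tau_decrease,
      bell_prominence = bell_prominence, floor_quantile = floor_quantile,
      smooth_window = smooth_window
    ),
    class = "classifier_params"
  )
}

#' @export
print.classifier_params <- function(x, ...) {
  cat(
    "<classifier_params> increased: log2FC >= ", x$tau_increase,
    "; decreased: log2FC <= -", x$tau_decrease,
    "; bell: interior max >= ", x$bell_prominence,
    "x endpoints (median window ", x$smooth_window,
    "); floor quantile ", x$floor_quantile, "\n",
    sep = ""
  )
  invisible(x)
}

#' Classify one ion temporal profile
#'
#' Assigns one of the three temporal categories observed during sequential
#' EPS digestion, in fixed rule order:
#' \enumerate{
#'   \item \strong{increased} — `log2(I_end / I_0) >= tau_increase`
#'     (accumulating terminal product; large fold changes arise from
#'     censored near-zero baselines imputed at the floor);
#'   \item \strong{bell} — the median-smoothed interior maximum is at least
#'     `bell_prominence` times both endpoints (transient intermediate);
#'   \item \strong{decreased} — `log2(I_end / I_0) <= -tau_decrease`
#'     (consumed substrate);
#'   \item \strong{unclassified} otherwise.
#' }
#' Missing and zero intensities are imputed at `floor` before ratios are
#' formed.
#'
#' @param intensity Numeric intensities (may contain `NA`).
#' @param hours Timepoints in hours; must contain at least 3 values
#'   including 0 and the final time `end_hour`.
#' @param params A [classifier_params()].
#' @param floor Imputation floor. Defaults to the `floor_quantile` quantile
#'   of the profile's own nonzero intensities (in table context the floor is
#'   computed per digest instead; see [classify_table()]).
#' @param end_hour The experiment's final timepoint (default `max(hours)`).
#' @return A single string: `"increased"`, `"bell"`, `"decreased"` or
#'   `"unclassified"`.
#' @examples
#' classify_profile(c(1, 8, 1), c(0, 12, 24)) # "bell"
#' classify_profile(c(100, 30, 3), c(0, 12, 24)) # "decreased"
#' @export
classify_profile <- function(intensity, hours, params = classifier_params(),
                             floor = NULL, end_hour = max(hours)) {
  if (length(intensity) != length(hours)) {
    abort("intensity and hours must have equal length")
  }
  o <- order(hours)
  hours <- hours[o]
  intensity <- as.numeric(intensity)[o]
  if (length(hours) < 3L) {
    abort("a profile needs at least 3 timepoints")
  }
  if (!0 %in% hours || !end_hour %in% hours) {
    abort("profile must include t = 0 and the final timepoint")
  }
  if (is.null(floor)) {
    nz <- intensity[!is.na(intensity) & intensity > 0]
    if (length(nz) == 0L) {
      return("unclassified")
    }
    floor <- quantile(nz, params$floor_quantile, names = FALSE)
  }
  x <- intensity
  x[is.na(x) | x <= 0] <- floor
  i0 <- x[hours == 0][1]
  iend <- x[hours == end_hour][1]
  l2fc <- log2(iend / i0)
  if (l2fc >= params$tau_increase) {
    return("increased")
  }
  smooth <- if (params$smooth_window > 1L && length(x) > params$smooth_window) {
    runmed(x, params$smooth_window, endrule = "keep")
  } else {
    x
  }
  interior <- smooth[seq(2L, length(smooth) - 1L)]
  if (max(interior) >= params$bell_prominence * max(smooth[1], smooth[length(smooth)])) {
    return("bell")
  }
  if (l2fc <= -params$tau_decrease) {
    return("decreased")
  }
  "unclassified"
}

#' Classify every ion in a multi-digest ion table
#'
#' Classifies each (ion, digest) profile with [classify_profile()], using a
#' per-digest imputation floor (the `floor_quantile` quantile of that
#' digest's nonzero intensities). An ion's overall category is assigned when
#' the rule fires in at least one digest; conflicting calls across digests
#' are resolved by the precedence increased > bell > decreased.
#'
#' Profiles are completed to the digest's full timepoint grid before
#' classification, so timepoints censored below the detection floor count as
#' missing rather than absent.
#'
#' @param ions A long ion table (`ion_id`, `digest`, `hours`, `intensity`,
#'   optionally `mz`), or a `digest_dataset`.
#' @param params A [classifier_params()].
#' @return An object of class `ion_categories`: a list with `ions` (per-ion
#'   tibble: `ion_id`, `mz`, `category`), `per_digest` (per ion and digest),
#'   `counts` (overall count per category), `digest_counts`, and `params`.
#'   An empty table yields zero counts.
#' @export
classify_table <- function(ions, params = classifier_params()) {
  if (inherits(ions, "digest_dataset")) {
    ions <- ions$ions
  }
  ions <- as_tibble(ions)
  categories <- c("decreased", "bell", "increased")
  if (nrow(ions) == 0L) {
    return(structure(
      list(
        ions = tibble(ion_id = character(), mz = numeric(),
                      category = character()),
        per_digest = tibble(ion_id = character(), digest = character(),
                            category = character()),
        counts = setNames(rep(0L, 4L), c(categories, "unclassified")),
        digest_counts = tibble(digest = character(), category = character(),
                               n = integer()),
        params = params
      ),
      class = "ion_categories"
    ))
  }
  per_digest_rows <- list()
  for (d in unique(ions$digest)) {
    sub <- ions[ions$digest == d, ]
    grid <- sort(unique(sub$hours))
    if (!0 %in% grid || length(grid) < 3L) {
      abort(paste0("digest ", d, " lacks t = 0 or has fewer than 3 timepoints"))
    }
    end_hour <- max(grid)
    nz <- sub$intensity[!is.na(sub$intensity) & sub$intensity > 0]
    if (length(nz) == 0L) {
      abort(paste0("digest ", d, " has no nonzero intensities"))
    }
    floor_d <- quantile(nz, params$floor_quantile, names = FALSE)
    full <- tidyr::complete(
      sub[, c("ion_id", "hours", "intensity")],
      ion_id = unique(sub$ion_id), hours = grid,
      fill = list(intensity = NA_real_)
    )
    cls <- full |>
      group_by(.data$ion_id) |>
      summarise(
        category = classify_profile(
          .data$intensity, .data$hours, params,
          floor = floor_d, end_hour = end_hour
        ),
        .groups = "drop"
      )
    cls$digest <- d
    per_digest_rows[[d]] <- cls
  }
  per_digest <- bind_rows(per_digest_rows)[, c("ion_id", "digest", "category")]

  prec <- c(increased = 3L, bell = 2L, decreased = 1L, unclassified = 0L)
  overall <- per_digest |>
    group_by(.data$ion_id) |>
    summarise(
      category = names(prec)[match(max(prec[.data$category]), prec)],
      .groups = "drop"
    )
  mz_tbl <- if ("mz" %in% names(ions)) {
    ions |>
      group_by(.data$ion_id) |>
      summarise(mz = mean(.data$mz), .groups = "drop")
  } else {
    tibble(ion_id = unique(ions$ion_id), mz = NA_real_)
  }
  overall <- left_join(overall, mz_tbl, by = "ion_id")[,
    c("ion_id", "mz", "category")]

  counts <- setNames(rep(0L, 4L), c(categories, "unclassified"))
  tab <- table(overall$category)
  counts[names(tab)] <- as.integer(tab)
  digest_counts <- per_digest |>
    filter(.data$category != "unclassified") |>
    dplyr::count(.data$digest, .data$category)

  structure(
    list(
      ions = overall, per_digest = per_digest, counts = counts,
      digest_counts = digest_counts, params = params
    ),
    class = "ion_categories"
  )
}

#' @export
print.ion_categories <- function(x, ...) {
  cat("<ion_categories> ", nrow(x$ions), " ions: ", sep = "")
  cat(paste(names(x$counts), x$counts, sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn classify_table Per-ion categories as a tibble.
#' @param x An `ion_categories` object.
#' @param ... Unused.
#' @method tidy ion_categories
#' @export
tidy.ion_categories <- function(x, ...) {
  x$ions
}

#' @describeIn classify_table One-row summary with the overall category
#'   counts (`n_ions` counts categorized ions only).
#' @method glance ion_categories
#' @export
glance.ion_categories <- function(x, ...) {
  tibble(
    n_ions = sum(x$counts[c("decreased", "bell", "increased")]),
    n_decreased = x$counts[["decreased"]],
    n_bell = x$counts[["bell"]],
    n_increased = x$counts[["increased"]],
    n_unclassified = x$counts[["unclassified"]]
  )
}
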