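#' Generate a synthetic multi-digest ion time-series dataset
#'
#' Simulates every chain in the scenario, converts stage masses to m/z under
#' the scenario's ionization adduct (\eqn{[M-H]^-} or \eqn{[M+H]^+}), drops
#' ions outside the acquisition m/z window, applies multiplicative log-normal
#' intensity noise, and censors intensities below the detection floor to
#' missing. Shared terminal products carry the same ion id across digests, as
#' in an aligned LC-MS feature table; observed m/z and retention time receive
#' small per-digest measurement jitter so that cross-digest alignment is
#' non-trivial.
#'
#' The same seed reproduces the output exactly. With `noise_cv = 0` the
#' planted trajectories are noiseless and the default classifier recovers
#' every planted category.
#'
#' @param scenario A [digest_scenario()].
#' @param mz_jitter_ppm Standard deviation of per-digest m/z measurement
#'   error, ppm (default 0.8).
#' @param rt_jitter_min Standard deviation of per-digest retention-time
#'   error, minutes (default 0.01).
#' @return An object of class `digest_dataset`: a list with
#'   \describe{
#'     \item{ions}{long tibble with columns `ion_id`, `digest`, `mz`,
#'       `rt_min`, `mode`, `hours`, `intensity` (`NA` below the detection
#'       floor).}
#'     \item{truth}{tibble `ion_id`, `true_category` for every ion that made
#'       it into the table.}
#'     \item{scenario}{the input scenario.}
#'   }
#' @export
generate_dataset <- function(scenario, mz_jitter_ppm = 0.8,
                             rt_jitter_min = 0.01) {
  if (!inherits(scenario, "digest_scenario")) {
    abort("scenario must come from digest_scenario()")
  }
  shift <- if (scenario$mode == "negative") -proton_mass else proton_mass
  sp <- scenario$species
  sdlog <- sqrt(log1p(scenario$noise_cv^2))

  rows <- withr::with_seed(scenario$seed, {
    out <- list()
    for (d in scenario$digests) {
      for (entry in scenario$chains[[d]]) {
        sim <- simulate_chain(entry$chain, scenario$timepoints)
        n_stage <- length(entry$chain$stage_masses)
        for (s in seq_len(n_stage)) {
          id <- entry$ion_ids[s]
          info <- sp[sp$ion_id == id, ]
          mz_theo <- info$mass + shift
          # instrument acquisition window: ions outside are never reported
          if (mz_theo < scenario$mz_window[1] ||
              mz_theo > scenario$mz_window[2]) {
            next
          }
          mz_obs <- mz_theo * (1 + rnorm(1, 0, mz_jitter_ppm * 1e-6))
          rt_obs <- info$rt_min + rnorm(1, 0, rt_jitter_min)
          amount <- sim$amount[sim$stage == s]
          intensity <- if (scenario$noise_cv > 0) {
            amount * exp(rnorm(length(amount), -sdlog^2 / 2, sdlog))
          } else {
            amount
          }
          intensity[intensity < scenario$detection_floor] <- NA_real_
          out[[length(out) + 1L]] <- tibble(
            ion_id = id, digest = d, mz = mz_obs, rt_min = rt_obs,
            mode = scenario$mode, hours = scenario$timepoints,
            intensity = intensity
          )
        }
      }
    }
    out
  })
  ions <- bind_rows(rows)
  truth <- sp |>
    filter(.data$ion_id %in% unique(ions$ion_id)) |>
    select("ion_id", "true_category")
  structure(
    list(ions = ions, truth = truth, scenario = scenario),
    class = "digest_dataset"
  )
}

#' @export
print.digest_dataset <- function(x, ...) {
  cat(
    "<digest_dataset> ", dplyr::n_distinct(x$ions$ion_id), " ions, ",
    dplyr::n_distinct(x$ions$digest), " digests, ",
    nrow(x$ions), " rows\n",
    sep = ""
  )
  invisible(x)
}

#' @describeIn generate_dataset Extract the long ion table from a dataset.
#' @param x A `digest_dataset`.
#' @param ... Unused.
#' @method tidy digest_dataset
#' @export
tidy.digest_dataset <- function(x, ...) {
  x$ions
}

#' One feature row per ion and digest
#'
#' Collapses a long ion table to its feature list: one row per
#' (`ion_id`, `digest`) with m/z, retention time and mode — the unit on which
#' cross-digest alignment operates.
#'
#' @param ions A long ion table (or a `digest_dataset`).
#' @return A tibble with columns `ion_id`, `digest`, `mz`, `rt_min`, `mode`.
#' @export
ion_features <- function(ions) {
  if (inherits(ions, "digest_dataset")) {
    ions <- ions$ions
  }
  distinct(
    as_tibble(ions),
    .data$ion_id, .data$digest, .data$mz, .data$rt_min, .data$mode
  )
}

#' Write a dataset to plain-text files
#'
#' Writes `ions.csv` (long format: `ion_id`, `digest`, `mz`, `rt_min`,
#' `mode`, `hours`, `intensity`) and the ground-truth side-car `truth.csv`
#' (`ion_id`, `true_category`) into a directory.
#'
#' @param dataset A `digest_dataset`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir) {
  if (!inherits(dataset, "digest_dataset")) {
    abort("dataset must come from generate_dataset()")
  }
  if (!dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
  }
  paths <- c(
    ions = file.path(dir, "ions.csv"),
    truth = file.path(dir, "truth.csv")
  )
  readr::write_csv(dataset$ions, paths[["ions"]])
  readr::write_csv(dataset$truth, paths[["truth"]])
  invisible(paths)
}
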