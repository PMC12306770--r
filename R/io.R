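#' Read a long-format ion table from CSV
#'
#' Expects the columns `ion_id`, `digest`, `mz`, `rt_min`, `mode`, `hours`,
#' `intensity` (empty intensity cells become `NA`, i.e. below the detection
#' floor).
#'
#' @param path Path to the CSV file.
#' @return A validated ion-table tibble.
#' @export
read_ion_table <- function(path) {
  ions <- readr::read_csv(
    path,
    col_types = readr::cols(
      ion_id = readr::col_character(),
      digest = readr::col_character(),
      mz = readr::col_double(),
      rt_min = readr::col_double(),
      mode = readr::col_character(),
      hours = readr::col_double(),
      intensity = readr::col_double()
    )
  )
  validate_ion_table(ions)
}

#' Read an ion table in the supplementary spreadsheet layout
#'
#' Reads an XLSX sheet whose header follows the supplementary-data layout
#' (`m/z`, `retention_time`, `Degrader`, `hours`, `mode`, `annotation`,
#' `intensity`) and renames it to the package's long ion-table columns. An
#' `ion_id` is synthesised from (`m/z`, `retention_time`, mode) when absent.
#'
#' @param path Path to an `.xlsx` file.
#' @param sheet Sheet name or index (default first).
#' @return A validated ion-table tibble (with an extra `annotation` column
#'   when present in the sheet).
#' @export
read_ion_xlsx <- function(path, sheet = 1) {
  if (!requireNamespace("readxl", quietly = TRUE)) {
    abort("read_ion_xlsx() needs the readxl package")
  }
  raw <- readxl::read_xlsx(path, sheet = sheet)
  nm <- names(raw)
  ren <- c(
    "m/z" = "mz", "retention_time" = "rt_min", "Degrader" = "digest",
    "hours" = "hours", "mode" = "mode", "annotation" = "annotation",
    "intensity" = "intensity"
  )
  hit <- nm %in% names(ren)
  names(raw)[hit] <- ren[nm[hit]]
  needed <- c("mz", "rt_min", "digest", "hours", "mode", "intensity")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0L) {
    abort(paste("sheet lacks columns:", paste(missing_cols, collapse = ", ")))
  }
  if (!"ion_id" %in% names(raw)) {
    raw$ion_id <- sprintf(
      "ion_%s", as.integer(factor(paste(
        sprintf("%.5f", raw$mz), sprintf("%.3f", raw$rt_min), raw$mode
      )))
    )
  }
  validate_ion_table(as_tibble(raw))
}

#' Validate a long ion table
#'
#' Checks the ion-table invariants: required columns present, positive m/z,
#' hours within `[0, 24]`, non-negative intensities, and uniqueness of
#' (`ion_id`, `digest`, `hours`).
#'
#' @param ions A data frame.
#' @return The table, invisibly coerced to a tibble, on success; otherwise
#'   an error.
#' @export
validate_ion_table <- function(ions) {
  ions <- as_tibble(ions)
  needed <- c("ion_id", "digest", "mz", "rt_min", "mode", "hours", "intensity")
  missing_cols <- setdiff(needed, names(ions))
  if (length(missing_cols) > 0L) {
    abort(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  }
  if (any(ions$mz <= 0, na.rm = TRUE)) {
    abort("mz must be positive")
  }
  if (any(ions$hours < 0 | ions$hours > 24, na.rm = TRUE)) {
    abort("hours must lie within [0, 24]")
  }
  if (any(ions$intensity < 0, na.rm = TRUE)) {
    abort("intensities must be non-negative (missing = NA)")
  }
  key <- paste(ions$ion_id, ions$digest, ions$hours)
  if (anyDuplicated(key)) {
    abort("(ion_id, digest, hours) must be unique")
  }
  ions
}

#' Read a species-by-sample abundance table from CSV
#'
#' Expects species in the first column (named `species` or otherwise renamed
#' to it) and one numeric column per sample; each sample is renormalized to
#' relative abundances summing to 1.
#'
#' @param path Path to the CSV file.
#' @return A wide tibble: `species` plus sample columns.
#' @export
read_abundance_csv <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  names(tab)[1] <- "species"
  normalize_abundance(tab)
}
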