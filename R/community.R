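#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' \eqn{BC(u, v) = \sum_i |u_i - v_i| / \sum_i (u_i + v_i)}: 0 for identical
#' communities, 1 for communities with disjoint support. Symmetric in its
#' arguments.
#'
#' @param u,v Non-negative abundance vectors over the same species universe.
#' @return A single dissimilarity in `[0, 1]`.
#' @examples
#' bray_curtis(c(0.7, 0.3, 0), c(0.2, 0.3, 0.5)) # 0.5
#' @export
bray_curtis <- function(u, v) {
  if (length(u) != length(v)) {
    abort("u and v must cover the same species universe")
  }
  if (any(u < 0) || any(v < 0)) {
    abort("abundances must be non-negative")
  }
  denom <- sum(u + v)
  if (denom == 0) {
    abort("both communities are empty (all-zero vectors)")
  }
  sum(abs(u - v)) / denom
}

#' Pairwise Bray-Curtis dissimilarities across samples
#'
#' @param table A wide abundance table: a `species` column plus one numeric
#'   column per sample.
#' @param species_col Name of the species column (default `"species"`).
#' @return A tibble of sample pairs with their dissimilarity.
#' @export
bray_curtis_pairs <- function(table, species_col = "species") {
  table <- as_tibble(table)
  samples <- setdiff(names(table), species_col)
  if (length(samples) < 2L) {
    abort("need at least two sample columns")
  }
  combs <- utils::combn(samples, 2L)
  tibble(
    sample_1 = combs[1L, ],
    sample_2 = combs[2L, ],
    bray_curtis = apply(combs, 2L, function(p) {
      bray_curtis(table[[p[1]]], table[[p[2]]])
    })
  )
}

#' Normalize an abundance table to relative abundances
#'
#' Renormalizes each sample column to sum to 1 (per-sample sums in `(0, 1]`
#' are accepted on input, e.g. after filtering out rare taxa).
#'
#' @param table A wide table: `species` column plus numeric sample columns.
#' @param species_col Name of the species column.
#' @return The renormalized tibble.
#' @export
normalize_abundance <- function(table, species_col = "species") {
  table <- as_tibble(table)
  samples <- setdiff(names(table), species_col)
  for (s in samples) {
    x <- table[[s]]
    if (any(x < 0, na.rm = TRUE)) {
      abort("abundances must be non-negative")
    }
    tot <- sum(x, na.rm = TRUE)
    if (tot <= 0) {
      abort(paste0("sample ", s, " sums to zero"))
    }
    table[[s]] <- x / tot
  }
  table
}

#' Log2 fold changes of species abundances versus the inoculum
#'
#' For each species and condition, `log2(a_condition / max(a_inoculum,
#' floor))`. The floor guards against division by zero for species
#' undetected in the inoculum; its default, 1/30,000, corresponds to a
#' detection limit of one read at a filtered depth of ~30,000 reads per
#' sample. Species undetected in a condition are masked (`NA` with
#' `absent = TRUE`), not zero-filled: absence carries no finite fold change.
#'
#' @param table Wide relative-abundance table (`species` column plus one
#'   column per sample, including the inoculum).
#' @param inoculum Name of the inoculum sample column.
#' @param floor Inoculum abundance floor (> 0).
#' @param species_col Name of the species column.
#' @return A tibble of class `fold_change_matrix` in long form: `species`,
#'   `condition`, `log2_fc`, `absent`.
#' @export
fold_changes <- function(table, inoculum, floor = 1 / 30000,
                         species_col = "species") {
  table <- as_tibble(table)
  if (!inoculum %in% names(table)) {
    abort(paste0("unknown inoculum sample: ", inoculum))
  }
  if (floor <= 0) {
    abort("floor must be positive")
  }
  conditions <- setdiff(names(table), c(species_col, inoculum))
  if (length(conditions) == 0L) {
    abort("no condition samples besides the inoculum")
  }
  base <- pmax(table[[inoculum]], floor)
  rows <- purrr::map(conditions, function(cond) {
    a <- table[[cond]]
    tibble(
      species = table[[species_col]],
      condition = cond,
      log2_fc = ifelse(a > 0, log2(a / base), NA_real_),
      absent = a == 0
    )
  })
  out <- bind_rows(rows)
  class(out) <- c("fold_change_matrix", class(out))
  out
}

#' Ward clustering of species fold-change profiles
#'
#' Agglomeratively clusters species by their log2 fold-change profiles
#' across conditions using Ward's minimum-variance criterion on Euclidean
#' distances (each merge minimizes the increase in within-cluster sum of
#' squares). Masked cells (species absent from a condition) are imputed at
#' the matrix minimum before distances, preserving the "absent = strongly
#' depleted" ordering of a fold-change heatmap.
#'
#' @param fc A [fold_changes()] result, or any long tibble with `species`,
#'   `condition`, `log2_fc` (and optionally `absent`).
#' @param impute `"minimum"` (default, matrix minimum) or a single number to
#'   impute masked cells with.
#' @return An object of class `ward_clustering`: a list with `hclust` (the
#'   merge tree, heights on the Ward scale of [stats::hclust()] method
#'   `"ward.D2"`), `order` (leaf order), `labels`, and `data` (the imputed
#'   species-by-condition matrix).
#' @export
ward_cluster <- function(fc, impute = "minimum") {
  fc <- as_tibble(fc)
  if (!all(c("species", "condition", "log2_fc") %in% names(fc))) {
    abort("need 'species', 'condition' and 'log2_fc' columns")
  }
  wide <- tidyr::pivot_wider(
    fc[, c("species", "condition", "log2_fc")],
    names_from = "condition", values_from = "log2_fc"
  )
  mat <- as.matrix(wide[, -1, drop = FALSE])
  rownames(mat) <- wide$species
  if (nrow(mat) < 2L) {
    abort("need at least 2 species rows to cluster")
  }
  all_masked <- rowSums(!is.na(mat)) == 0L
  if (any(all_masked)) {
    abort(paste(
      "species with no finite fold change in any condition:",
      paste(rownames(mat)[all_masked], collapse = ", ")
    ))
  }
  fill <- if (identical(impute, "minimum")) {
    min(mat, na.rm = TRUE)
  } else if (is.numeric(impute) && length(impute) == 1L) {
    impute
  } else {
    abort("impute must be \"minimum\" or a single number")
  }
  mat[is.na(mat)] <- fill
  hc <- hclust(dist(mat), method = "ward.D2")
  structure(
    list(hclust = hc, order = hc$order, labels = rownames(mat), data = mat),
    class = "ward_clustering"
  )
}

#' @export
print.ward_clustering <- function(x, ...) {
  cat(
    "<ward_clustering> ", length(x$labels), " species, leaf order: ",
    paste(x$labels[x$order], collapse = ", "), "\n",
    sep = ""
  )
  invisible(x)
}

#' @describeIn ward_cluster Merge table: one row per agglomeration step with
#'   the (negative = leaf) member indices and the merge height.
#' @param x A `ward_clustering`.
#' @param ... Unused.
#' @method tidy ward_clustering
#' @export
tidy.ward_clustering <- function(x, ...) {
  tibble(
    step = seq_len(nrow(x$hclust$merge)),
    member_1 = x$hclust$merge[, 1],
    member_2 = x$hclust$merge[, 2],
    height = x$hclust$height
  )
}

#' @describeIn ward_cluster Export the merge tree as a newick string (or
#'   file, when `path` is given).
#' @param path Optional file path to write to.
#' @export
as_newick <- function(x, path = NULL) {
  if (!inherits(x, "ward_clustering")) {
    abort("x must be a ward_clustering")
  }
  phy <- ape::as.phylo(x$hclust)
  if (is.null(path)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = path)
    invisible(path)
  }
}

#' Top abundant species per sample with an "other" remainder
#'
#' @param table Wide relative-abundance table (`species` plus sample
#'   columns).
#' @param n Number of top species per sample (ties broken by species name,
#'   ascending). `n >= ` the species count returns all species with zero
#'   remainder.
#' @param species_col Name of the species column.
#' @return A long tibble `sample`, `species`, `abundance` with one `"other"`
#'   row per sample holding `1 - sum(top n)` (for tables normalized to 1).
#' @export
top_taxa <- function(table, n = 6, species_col = "species") {
  if (n < 1) {
    abort("n must be at least 1")
  }
  table <- as_tibble(table)
  samples <- setdiff(names(table), species_col)
  rows <- purrr::map(samples, function(s) {
    d <- tibble(species = table[[species_col]], abundance = table[[s]])
    d <- arrange(d, dplyr::desc(.data$abundance), .data$species)
    top <- head(d, n)
    bind_rows(
      tibble(sample = s, top),
      tibble(
        sample = s, species = "other",
        abundance = sum(d$abundance) - sum(top$abundance)
      )
    )
  })
  bind_rows(rows)
}
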