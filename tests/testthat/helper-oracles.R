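# Independent brute-force oracles used to cross-check the package's
# implementations on small inputs.

# All-pairs single-linkage clustering under the ppm/RT tolerance, closed
# transitively by breadth-first search over the pair graph.
oracle_align <- function(features, ppm_tol = 8, rt_tol = 0.1) {
  n <- nrow(features)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      mean_mz <- (features$mz[i] + features$mz[j]) / 2
      same_mode <- !("mode" %in% names(features)) ||
        features$mode[i] == features$mode[j]
      if (same_mode &&
          abs(features$mz[i] - features$mz[j]) / mean_mz <= ppm_tol * 1e-6 &&
          abs(features$rt_min[i] - features$rt_min[j]) <= rt_tol) {
        adj[i, j] <- TRUE
      }
    }
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue) > 0L) {
      v <- queue[1L]
      queue <- queue[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# Linear scan over every catalog entry for every m/z value.
oracle_annotate <- function(mz_values, mode, catalog, ppm_tol = 5) {
  shift <- if (mode == "negative") -1.007276 else 1.007276
  out <- list()
  for (i in seq_along(mz_values)) {
    mz <- mz_values[i]
    for (j in seq_len(nrow(catalog))) {
      theo <- catalog$mass[j] + shift
      ppm <- (mz - theo) / theo * 1e6
      if (abs(ppm) <= ppm_tol) {
        out[[length(out) + 1L]] <- data.frame(
          ion = i, label = catalog$label[j], ppm_error = ppm
        )
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(ion = integer(), label = character(),
                      ppm_error = numeric()))
  }
  do.call(rbind, out)
}

# Exhaustive greedy Ward agglomeration: at each step merge the pair of
# clusters whose union minimizes the increase in within-cluster sum of
# squares. Returns the member sets formed at each step and the
# ward.D2-scale heights sqrt(2 * delta-ESS).
oracle_ward <- function(mat) {
  ess <- function(idx) {
    sub <- mat[idx, , drop = FALSE]
    ctr <- colMeans(sub)
    sum(sweep(sub, 2L, ctr)^2)
  }
  clusters <- as.list(seq_len(nrow(mat)))
  merges <- list()
  heights <- numeric()
  while (length(clusters) > 1L) {
    best <- NULL
    best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        d <- ess(c(clusters[[i]], clusters[[j]])) -
          ess(clusters[[i]]) - ess(clusters[[j]])
        if (d < best_d - 1e-12) {
          best_d <- d
          best <- c(i, j)
        }
      }
    }
    merged <- sort(c(clusters[[best[1L]]], clusters[[best[2L]]]))
    clusters <- c(clusters[-best], list(merged))
    merges[[length(merges) + 1L]] <- merged
    heights <- c(heights, sqrt(2 * best_d))
  }
  list(merges = merges, heights = heights)
}

# Member sets formed at each step of an hclust tree.
hclust_merge_sets <- function(hc) {
  sets <- vector("list", nrow(hc$merge))
  members <- function(m) {
    if (m < 0) -m else sets[[m]]
  }
  for (i in seq_len(nrow(hc$merge))) {
    sets[[i]] <- sort(c(members(hc$merge[i, 1L]), members(hc$merge[i, 2L])))
  }
  sets
}

# Clustering equality up to label permutation.
same_partition <- function(a, b) {
  identical(
    as.integer(factor(a, levels = unique(a))),
    as.integer(factor(b, levels = unique(b)))
  )
}
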