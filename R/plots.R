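.category_scale <- function() {
  ggplot2::scale_fill_manual(
    values = c(
      decreased = "#4477AA", bell = "#CCBB44", increased = "#EE6677",
      unclassified = "grey70"
    ),
    name = NULL
  )
}

#' @method autoplot ion_categories
#' @export
autoplot.ion_categories <- function(object, ...) {
  ggplot2::ggplot(
    object$digest_counts,
    ggplot2::aes(x = .data$digest, y = .data$n, fill = .data$category)
  ) +
    ggplot2::geom_col(position = "dodge") +
    .category_scale() +
    ggplot2::labs(x = NULL, y = "ions") +
    ggplot2::theme_minimal()
}

#' Plot category fractions across m/z bins
#'
#' Stacked-bar view of a [mz_category_distribution()] table: per size bin,
#' the share of ions that decreased, peaked transiently, or accumulated.
#'
#' @param dist Output of [mz_category_distribution()].
#' @return A ggplot object.
#' @export
plot_size_distribution <- function(dist) {
  dist$bin <- factor(dist$bin, levels = unique(dist$bin[order(dist$bin_low)]))
  ggplot2::ggplot(
    dist,
    ggplot2::aes(x = .data$bin, y = .data$fraction, fill = .data$category)
  ) +
    ggplot2::geom_col() +
    .category_scale() +
    ggplot2::labs(x = "m/z bin", y = "fraction of ions") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot cross-digest sharing across m/z bins
#'
#' @param sharing Output of [sharing_by_mz()].
#' @return A ggplot object.
#' @export
plot_sharing <- function(sharing) {
  sharing$bin <- factor(
    sharing$bin, levels = unique(sharing$bin[order(sharing$bin_low)])
  )
  ggplot2::ggplot(
    sharing,
    ggplot2::aes(x = .data$bin, y = .data$shared_fraction)
  ) +
    ggplot2::geom_col(fill = "#66CCEE") +
    ggplot2::labs(x = "m/z bin", y = "fraction detected in >1 digest") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot stage trajectories of a simulated chain
#'
#' @param sim Output of [simulate_chain()].
#' @param log_y Log-scale the amount axis? Default `FALSE`.
#' @return A ggplot object.
#' @export
plot_chain_trajectories <- function(sim, log_y = FALSE) {
  sim$stage_label <- sprintf(
    "stage %d (%.1f Da)", sim$stage, sim$stage_mass
  )
  p <- ggplot2::ggplot(
    sim,
    ggplot2::aes(x = .data$hours, y = .data$amount,
                 colour = .data$stage_label)
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "hours", y = "amount", colour = NULL) +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' @method autoplot carbon_budget
#' @export
autoplot.carbon_budget <- function(object, ...) {
  long <- tidy(object)
  long$fraction <- factor(
    long$fraction, levels = c("biomass", "eps", "lmw", "co2")
  )
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = factor(.data$.row), y = .data$percent,
                 fill = .data$fraction)
  ) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(
      biomass = "#228833", eps = "#4477AA", lmw = "#66CCEE", co2 = "grey70"
    ), name = NULL) +
    ggplot2::labs(x = "budget", y = "% of input carbon") +
    ggplot2::theme_minimal()
}

#' @method autoplot ward_clustering
#' @export
autoplot.ward_clustering <- function(object, ...) {
  hc <- object$hclust
  n <- length(object$labels)
  # leaf x positions in dendrogram order; internal-node positions and segment
  # coordinates derived from the merge table
  xpos <- numeric(n)
  xpos[hc$order] <- seq_len(n)
  node_x <- numeric(nrow(hc$merge))
  node_h <- hc$height
  segs <- vector("list", nrow(hc$merge))
  coord <- function(m) {
    if (m < 0) c(xpos[-m], 0) else c(node_x[m], node_h[m])
  }
  for (i in seq_len(nrow(hc$merge))) {
    a <- coord(hc$merge[i, 1])
    b <- coord(hc$merge[i, 2])
    node_x[i] <- (a[1] + b[1]) / 2
    segs[[i]] <- tibble(
      x = c(a[1], a[1], b[1]),
      xend = c(a[1], b[1], b[1]),
      y = c(a[2], node_h[i], node_h[i]),
      yend = c(node_h[i], node_h[i], b[2])
    )
  }
  segs <- bind_rows(segs)
  leaves <- tibble(x = xpos, label = object$labels)
  ggplot2::ggplot(segs) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$x, xend = .data$xend, y = .data$y, yend = .data$yend
    )) +
    ggplot2::scale_x_continuous(
      breaks = leaves$x, labels = leaves$label
    ) +
    ggplot2::labs(x = NULL, y = "Ward merge height") +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.x = ggplot2::element_text(angle = 90, hjust = 1, vjust = 0.5),
      panel.grid.major.x = ggplot2::element_blank()
    )
}
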