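#' Plot a windowed statistic track
#'
#' Line plot of window values along the chromosome (one facet per
#' statistic when tracks are row-bound), with optional dashed genome-wide
#' threshold lines and shaded called regions.
#'
#' @param object a stat-track tibble (several may be combined with
#'   `dplyr::bind_rows()`).
#' @param thresholds optional named numeric vector of per-statistic
#'   thresholds.
#' @param regions optional [call_sweeps()] regions to shade.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.stat_track <- function(object, thresholds = NULL, regions = NULL, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
                      mid_mb = (.data$start0 + .data$end) / 2 / 1e6)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mid_mb, y = .data$value))
  if (!is.null(regions) && nrow(regions)) {
    p <- p + ggplot2::geom_rect(
      data = tibble::as_tibble(regions),
      ggplot2::aes(xmin = .data$start0 / 1e6, xmax = .data$end / 1e6),
      ymin = -Inf, ymax = Inf, inherit.aes = FALSE,
      fill = "goldenrod", alpha = 0.25
    )
  }
  p <- p + ggplot2::geom_line(linewidth = 0.4, na.rm = TRUE)
  if (!is.null(thresholds)) {
    thr <- tibble::tibble(stat = names(thresholds), thr = unname(thresholds))
    thr <- dplyr::semi_join(thr, df, by = "stat")
    p <- p + ggplot2::geom_hline(data = thr,
                                 ggplot2::aes(yintercept = .data$thr),
                                 linetype = "dashed", colour = "firebrick")
  }
  p + ggplot2::facet_wrap(~stat, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Position (Mb)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a median-joining haplotype network
#'
#' Force-directed layout; observed haplotypes drawn with area proportional
#' to their chromosome count (coloured by major group when an assignment
#' is given), median vectors as small open points; link labels give the
#' mutational distance.
#'
#' @param object an [mj_network()].
#' @param groups optional [assign_major_groups()] result for colouring.
#' @param layout_seed seed for the layout (layout only; statistics are
#'   unaffected).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.mj_network <- function(object, groups = NULL, layout_seed = 42, ...) {
  set.seed(layout_seed)
  xy <- igraph::layout_with_fr(object$graph)
  nodes <- dplyr::mutate(object$nodes, x = xy[, 1], y = xy[, 2])
  if (!is.null(groups)) {
    nodes <- dplyr::left_join(nodes, groups[c("haplotype", "group")],
                              by = "haplotype")
  } else {
    nodes$group <- "haplotype"
  }
  idx <- setNames(seq_len(nrow(nodes)), nodes$haplotype)
  edges <- dplyr::mutate(object$edges,
                         x = nodes$x[idx[.data$from]], y = nodes$y[idx[.data$from]],
                         xend = nodes$x[idx[.data$to]], yend = nodes$y[idx[.data$to]])
  obs <- dplyr::filter(nodes, !.data$is_median)
  med <- dplyr::filter(nodes, .data$is_median)
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          colour = "grey50") +
    ggplot2::geom_text(data = edges,
                       ggplot2::aes(x = (.data$x + .data$xend) / 2,
                                    y = (.data$y + .data$yend) / 2,
                                    label = .data$weight),
                       size = 3, colour = "grey30") +
    ggplot2::geom_point(data = obs,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     size = .data$total, colour = .data$group)) +
    ggplot2::geom_text(data = obs,
                       ggplot2::aes(x = .data$x, y = .data$y, label = .data$haplotype),
                       vjust = -1.2, size = 3)
  if (nrow(med)) {
    p <- p + ggplot2::geom_point(data = med,
                                 ggplot2::aes(x = .data$x, y = .data$y),
                                 shape = 21, size = 2, fill = "white")
  }
  p + ggplot2::scale_size_area(max_size = 12) +
    ggplot2::theme_void() +
    ggplot2::labs(size = "Chromosomes", colour = NULL)
}

#' Plot trait distributions by haplotype group
#'
#' Boxplots per group faceted by trait, annotated with the compact letter
#' display (groups sharing a letter do not differ at the chosen alpha).
#'
#' @param object a `trait_association` from [associate_groups()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.trait_association <- function(object, ...) {
  sm <- object$summary
  lab <- dplyr::mutate(sm, y = .data$q3 + 1.6 * (.data$q3 - .data$q1) / 2)
  ggplot2::ggplot(sm, ggplot2::aes(x = .data$group)) +
    ggplot2::geom_boxplot(
      ggplot2::aes(ymin = .data$q1 - 1.5 * (.data$q3 - .data$q1),
                   lower = .data$q1, middle = .data$median,
                   upper = .data$q3,
                   ymax = .data$q3 + 1.5 * (.data$q3 - .data$q1),
                   fill = .data$group),
      stat = "identity", width = 0.6, show.legend = FALSE
    ) +
    ggplot2::geom_text(data = lab,
                       ggplot2::aes(y = .data$y, label = .data$letter),
                       vjust = -0.5, na.rm = TRUE) +
    ggplot2::facet_wrap(~trait, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Stacked haplotype-group frequencies per subpopulation
#'
#' @param freqs output of [haplotype_frequencies()].
#' @return a ggplot.
#' @export
plot_group_frequencies <- function(freqs) {
  df <- dplyr::mutate(freqs, subpop = factor(.data$subpop, levels = c("S", "L", "C")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$subpop, y = .data$prop,
                                   fill = .data$unit)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Subpopulation", y = "Frequency", fill = NULL) +
    ggplot2::theme_minimal()
}
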