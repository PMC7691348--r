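#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_col
#'   geom_histogram geom_vline geom_segment labs theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' Plot a threshold scan
#'
#' Cluster count against candidate threshold, with the chosen plateau
#' midpoint marked.
#'
#' @param object A [estimate_threshold()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.threshold_scan <- function(object, ...) {
  ggplot(object$scan, aes(x = .data$threshold, y = .data$n_clusters)) +
    geom_line(colour = "grey40") +
    geom_point(aes(colour = .data$eligible), size = 1.5) +
    geom_vline(xintercept = object$threshold, linetype = 2) +
    labs(x = "score threshold", y = "clusters",
         colour = "eligible",
         title = sprintf("Threshold scan (chosen %d)", object$threshold)) +
    theme_minimal()
}

#' Plot cluster-size distribution
#'
#' @param object A [cluster_umis()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.umi_clustering <- function(object, ...) {
  ggplot(object$clusters, aes(x = .data$n_reads)) +
    geom_histogram(binwidth = 1, fill = "steelblue", colour = "white") +
    labs(x = "reads per cluster", y = "clusters",
         title = sprintf("%d clusters (threshold %d)",
                         nrow(object$clusters), object$threshold)) +
    theme_minimal()
}

#' Plot simulated clustering efficiency
#'
#' Recollection and homogeneity against error rate, faceted by UMI length.
#'
#' @param object A [simulate_clustering_efficiency()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.clustering_efficiency <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("recollection", "homogeneity"),
                              names_to = "metric")
  ggplot(long, aes(x = .data$error_rate, y = .data$value,
                   colour = .data$metric,
                   linetype = factor(.data$library_size))) +
    geom_line() + geom_point() +
    facet_wrap(~umi_length, labeller = "label_both") +
    labs(x = "per-base error rate", y = NULL,
         linetype = "library size") +
    theme_minimal()
}

#' Plot the support-fraction histogram of consensus candidates
#'
#' True mutations sit near support 1; random read errors pile up near 0.
#' The vertical line is the pass threshold (calls must exceed it). Mixed
#' clusters reveal themselves as mass near 0.5.
#'
#' @param consensus A [call_consensus()] result.
#' @return A ggplot.
#' @export
plot_support_histogram <- function(consensus) {
  ggplot(consensus$calls, aes(x = .data$support, fill = .data$passed)) +
    geom_histogram(binwidth = 0.05, boundary = 0) +
    geom_vline(xintercept = consensus$filters$min_support, linetype = 2) +
    labs(x = "read support fraction", y = "candidate calls") +
    theme_minimal()
}

#' Plot a variant similarity network embedding
#'
#' Variants at their 2-D embedding coordinates, coloured by the round of
#' first occurrence and sized by total count. Requires a network built with
#' `embed = TRUE`.
#'
#' @param object A [build_network()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.variant_network <- function(object, ...) {
  if (!all(c("x", "y") %in% names(object$nodes))) {
    stop("network has no embedding; rebuild with embed = TRUE")
  }
  nodes <- object$nodes
  seg <- object$edges |>
    left_join(select(nodes, "variant_id", "x", "y"),
              by = c(from = "variant_id")) |>
    left_join(select(nodes, "variant_id", xend = "x", yend = "y"),
              by = c(to = "variant_id"))
  ggplot(nodes, aes(x = .data$x, y = .data$y)) +
    geom_segment(data = seg, aes(xend = .data$xend, yend = .data$yend),
                 colour = "grey80", linewidth = 0.3) +
    geom_point(aes(colour = factor(.data$first_round),
                   size = .data$total), alpha = 0.8) +
    labs(colour = "first round", size = "count", x = NULL, y = NULL) +
    theme_minimal()
}

#' Plot positional enrichment (mutational hot-spots)
#'
#' @param enrichment A [positional_enrichment()] tibble.
#' @return A ggplot.
#' @export
plot_enrichment <- function(enrichment) {
  ggplot(enrichment, aes(x = .data$residue, y = .data$enrichment)) +
    geom_segment(aes(xend = .data$residue, yend = 1), colour = "grey60") +
    geom_point(aes(colour = .data$enrichment > 1)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    labs(x = "residue", y = "enrichment (round ratio)", colour = "enriched") +
    theme_minimal()
}
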