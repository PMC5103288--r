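#' Genome-wide window statistic track
#'
#' Manhattan-style track of a windowed statistic (`pi`, `tajima_d` or `fst`)
#' along concatenated scaffolds, faceted by scaffold.
#'
#' @param windows a window tibble from [windowed_diversity()] or
#'   [wc_fst_windows()].
#' @param stat column to plot.
#' @return A ggplot object.
#' @export
plot_windows <- function(windows, stat = c("pi", "tajima_d", "fst")) {
  stat <- match.arg(stat)
  stopifnot(stat %in% names(windows))
  ggplot2::ggplot(windows,
                  ggplot2::aes(x = (.data$start + .data$end) / 2,
                               y = .data[[stat]])) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::facet_wrap(~scaffold, scales = "free_x") +
    ggplot2::labs(x = "window midpoint (bp)", y = stat) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.fst_scan <- function(object, q_threshold = 0.05, ...) {
  res <- object$result
  res$called <- res$qvalue < q_threshold
  ggplot2::ggplot(res, ggplot2::aes(x = log10(pmax(.data$qvalue, 1e-6)),
                                    y = .data$fst,
                                    colour = .data$called)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = log10(q_threshold), linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick"),
                                 name = paste0("q < ", q_threshold)) +
    ggplot2::labs(x = "log10 q-value", y = "posterior locus F_ST") +
    ggplot2::theme_minimal()
}

#' Log-odds bar chart of enriched terms
#'
#' Fig-4b-style horizontal bars of per-term log2 odds with significance
#' stars.
#'
#' @param enrichment output of [fisher_enrichment()] (optionally with a
#'   `group` column for faceting).
#' @param max_terms show at most this many terms (smallest p first).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment, max_terms = 20) {
  enr <- dplyr::filter(as_tibble(enrichment), !is.na(.data$log2_odds))
  enr <- head(enr[order(enr$p), ], max_terms)
  p <- ggplot2::ggplot(enr,
                       ggplot2::aes(x = .data$log2_odds,
                                    y = stats::reorder(.data$term, -.data$p))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars), hjust = -0.3,
                       colour = "firebrick") +
    ggplot2::labs(x = "log2 odds vs background", y = NULL) +
    ggplot2::theme_minimal()
  if ("group" %in% names(enr)) p <- p + ggplot2::facet_wrap(~group)
  p
}

#' Phenotype heatmap in cluster order
#'
#' Tile heatmap of the normalised strain-by-trait matrix with rows and
#' columns in complete-linkage dendrogram order.
#'
#' @param object a `pheno_clust` from [cluster_phenotypes()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.pheno_clust <- function(object, ...) {
  m <- object$ordered_matrix
  df <- tibble(
    strain = factor(rep(rownames(m), times = ncol(m)), levels = rownames(m)),
    trait = factor(rep(colnames(m), each = nrow(m)), levels = colnames(m)),
    value = as.vector(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trait, y = .data$strain,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "normalised") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 5))
}
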