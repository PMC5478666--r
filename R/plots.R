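# ggplot2 views of the main result types. Numeric summaries are the primary
# output; these are convenience graphics for interactive use.

#' Volcano-style plot of site-level results
#'
#' Delta-beta against -log10 of the moderated-test q-value, consensus sites
#' highlighted.
#'
#' @param object A `dm_sites` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dm_sites
#' @export
autoplot.dm_sites <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$delta_beta,
    y = -log10(pmax(.data$q_moderated, 1e-300)),
    colour = .data$consensus
  )) +
    ggplot2::geom_point(alpha = 0.4, size = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = expression(Delta * beta ~ "(receptive - pre-receptive)"),
      y = expression(-log[10] ~ "q (moderated test)"),
      colour = "consensus"
    ) +
    ggplot2::theme_minimal()
}

#' Distribution of beta-values by genomic category
#'
#' Density of per-probe phase-mean beta per category and phase, the numeric
#' counterpart of the usual beanplot figure.
#'
#' @param dist Long tibble from [distribution_by_category()].
#' @return A ggplot.
#' @export
plot_beta_distribution <- function(dist) {
  ggplot2::ggplot(dist, ggplot2::aes(
    x = .data$mean_beta, colour = .data$phase
  )) +
    ggplot2::geom_density() +
    ggplot2::facet_wrap(ggplot2::vars(.data$category)) +
    ggplot2::labs(x = expression(beta), y = "density") +
    ggplot2::theme_minimal()
}

#' DMR counts by chromosome and direction
#'
#' @param object A `dmr_set` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dmr_set
#' @export
autoplot.dmr_set <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$chrom, fill = .data$direction)) +
    ggplot2::geom_bar(position = "dodge") +
    ggplot2::labs(x = NULL, y = "DMRs") +
    ggplot2::theme_minimal()
}

#' Correlation coefficients by gene region
#'
#' Spearman rho of significant records, split by region group, showing the
#' positive/negative balance (negative correlations dominating the 5'
#' region, positive the gene body).
#'
#' @param object A `meth_expr_cor` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot meth_expr_cor
#' @export
autoplot.meth_expr_cor <- function(object, ...) {
  df <- tibble::as_tibble(object)[object$significant, ]
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$region_group, y = .data$rho, colour = .data$sign
  )) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL, y = expression(rho)) +
    ggplot2::theme_minimal()
}
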