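# Plotting: ape-style tree rendering for rate-scaled phylogenies, ggplot2
# for posterior and association displays.

#' Plot a rate-scaled tree
#'
#' Renders the phylogeny with branch lengths equal to rt (time x posterior
#' median rate scalar) and branches coloured by the relative rate scalar, so
#' stretched, warm-coloured lineages are the phenotypically fast ones.
#'
#' @param tree A `phylo` in time units.
#' @param rates A [branch_values()] tibble of rate scalars (kind `"r"`).
#' @param palette Colour ramp endpoints (slow, fast) on log rate.
#' @param ... Passed to [ape::plot.phylo()].
#' @return Invisibly, the scaled tree.
#' @export
plot_rate_tree <- function(tree, rates, palette = c("steelblue", "grey40",
                                                    "firebrick"), ...) {
  r <- match_branch_values(tree, rates)
  scaled <- scale_branches(tree, r)
  lr <- log(pmax(r, 1e-6))
  mx <- max(abs(lr), 1e-6)
  ramp <- grDevices::colorRamp(palette)
  cols <- grDevices::rgb(ramp((lr / mx + 1) / 2), maxColorValue = 255)
  ape::plot.phylo(scaled, edge.color = cols, ...)
  invisible(scaled)
}

#' Posterior summaries of a PGLS fit
#'
#' Density of each coefficient's posterior with the zero line: the mass on
#' the minority side of zero is the p_x statistic.
#'
#' @param object A `pgls_posterior`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pgls_posterior <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$trace[, c(object$summary$term)],
    cols = dplyr::everything(), names_to = "term", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~term, scales = "free") +
    ggplot2::labs(x = "coefficient", y = "posterior density") +
    ggplot2::theme_minimal()
}

#' Association scatterplots for a gene
#'
#' Species-level scatter of the phenotype (and its evolutionary rate)
#' against root-to-tip molecular adaptation, the relationships the two PGLS
#' models quantify.
#'
#' @param object A completed `gene_association`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gene_association <- function(object, ...) {
  if (isTRUE(object$skipped)) stop("gene was skipped; nothing to plot",
                                   call. = FALSE)
  d <- object$data
  long <- dplyr::bind_rows(
    tibble::tibble(x = d$R_dN, y = d$testes_mass_log10,
                   panel = "log10 testes mass ~ log10 R_dN"),
    tibble::tibble(x = d$R_dN, y = d$R_phen,
                   panel = "log10 R_phen ~ log10 R_dN"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5, colour = "firebrick") +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = "log10 R_dN", y = NULL,
                  title = paste0(object$gene, ": ", object$classification)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
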