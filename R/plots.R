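#' Plot a carbon balance as net fluxes
#'
#' Bar chart of net mmol C per metabolite (consumption negative), with the
#' residual X shown as its own bar.
#'
#' @param object a [carbon_balance()] object.
#' @param ... ignored.
#' @return a ggplot.
#' @method autoplot carbon_balance
#' @export
autoplot.carbon_balance <- function(object, ...) {
  df <- object$fluxes %>%
    dplyr::select("metabolite", "net") %>%
    dplyr::bind_rows(tibble::tibble(metabolite = "X (biomass + gases)",
                                    net = -object$X))
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$metabolite,
                                                      .data$net),
                                   y = .data$net,
                                   fill = .data$net > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "net flux (mmol C)",
                  title = "Fermentation carbon balance") +
    ggplot2::theme_minimal()
}

#' Plot fitted pathway fluxes
#'
#' @param object a [fit_flux()] result.
#' @param ... ignored.
#' @return a ggplot of nonzero reaction rates.
#' @method autoplot flux_fit
#' @export
autoplot.flux_fit <- function(object, ...) {
  df <- dplyr::filter(object$fluxes, .data$flux > 1e-9)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$reaction,
                                                      .data$flux),
                                   y = .data$flux)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "flux (mmol)",
                  title = "Fitted pathway fluxes") +
    ggplot2::theme_minimal()
}

#' Plot a bootstrap-annotated tree
#'
#' Base-graphics phylogram (via ape) with bootstrap supports at internal
#' nodes; supports below the threshold are drawn in grey.
#'
#' @param tree an `etf_tree` from [bootstrap_support()].
#' @param ... passed to `ape::plot.phylo`.
#' @return the tree, invisibly.
#' @export
plot_etf_tree <- function(tree, ...) {
  ape::plot.phylo(tree, ...)
  sup <- attr(tree, "support")
  if (!is.null(sup)) {
    thr <- attr(tree, "threshold") %||% 0
    nodes <- as.integer(names(sup))[!is.na(sup)]
    vals <- sup[!is.na(sup)]
    ape::nodelabels(node = nodes, text = sprintf("%.0f", vals),
                    frame = "none", adj = c(1.2, -0.3), cex = 0.7,
                    col = ifelse(vals < thr, "grey60", "black"))
  }
  invisible(tree)
}

#' Tidy a bootstrap-annotated tree into a clade table
#'
#' @param x an `etf_tree`.
#' @param ... ignored.
#' @return tibble with `node`, `support`, `n_tips`, `tips` (list-column).
#' @method tidy etf_tree
#' @export
tidy.etf_tree <- function(x, ...) {
  clades <- tree_clades(x)
  sup <- attr(x, "support")
  tibble::tibble(
    node = as.integer(names(clades)),
    support = unname(sup[names(clades)]),
    n_tips = lengths(clades),
    tips = unname(clades)
  )
}
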