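#' Fold-change concordance scatter
#'
#' Scatter of the two fold-change vectors computed against each shared
#' reference diet, with the 1:1 diagonal; points in the off-diagonal
#' quadrants trend in different directions.
#'
#' @param object a `concordance_test` from [run_concordance()].
#' @param reference optional single reference diet to show (default all,
#'   facetted).
#' @param ... ignored.
#' @return a ggplot object.
#' @method autoplot concordance_test
#' @export
autoplot.concordance_test <- function(object, reference = NULL, ...) {
  lfc <- object$lfc
  if (!is.null(reference)) {
    lfc <- dplyr::filter(lfc, .data$reference == !!reference)
  }
  wide <- lfc |>
    dplyr::group_by(.data$reference) |>
    dplyr::mutate(which = match(.data$diet, unique(.data$diet))) |>
    dplyr::ungroup() |>
    dplyr::select("gene", "reference", "which", "lfc") |>
    tidyr::pivot_wider(names_from = "which", values_from = "lfc",
                       names_prefix = "lfc")
  ggplot2::ggplot(wide, ggplot2::aes(x = .data$lfc1, y = .data$lfc2)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::facet_wrap(~ reference, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "log2 fold change (first diet vs reference)",
                  y = "log2 fold change (second diet vs reference)") +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential-expression contrast
#'
#' Shrunken log2 fold changes for one tissue/pair against
#' -log10 adjusted p of the chosen LRT contrast.
#'
#' @param de a `de_fit` from [run_de()].
#' @param contrast contrast whose adjusted p-values are shown.
#' @param tissue,pair which fold-change panel to use (defaults: first
#'   available).
#' @param alpha significance threshold drawn as a horizontal line.
#' @return a ggplot object.
#' @export
plot_volcano <- function(de, contrast = "treatment", tissue = NULL,
                         pair = NULL, alpha = de$alpha) {
  stopifnot(inherits(de, "de_fit"))
  fc <- de$fold_changes
  tissue <- tissue %||% fc$tissue[1]
  fc <- dplyr::filter(fc, .data$tissue == !!tissue)
  pair <- pair %||% fc$pair[1]
  fc <- dplyr::filter(fc, .data$pair == !!pair)
  dat <- dplyr::inner_join(
    fc, dplyr::filter(de$results, .data$contrast == !!contrast),
    by = "gene")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$lfc,
                                    y = -log10(.data$p_adj),
                                    colour = log10(.data$base_mean + 1))) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::geom_vline(xintercept = c(-1, 1), linetype = "dotted") +
    ggplot2::labs(x = paste0("log2 fold change (", pair, ", ", tissue, ")"),
                  y = expression(-log[10] ~ adjusted ~ p),
                  colour = "log10 base mean",
                  title = paste("Contrast:", contrast)) +
    ggplot2::theme_minimal()
}

#' @rdname plot_volcano
#' @param object,... autoplot interface to [plot_volcano()].
#' @method autoplot de_fit
#' @export
autoplot.de_fit <- function(object, ...) plot_volcano(object, ...)

#' Eigengene profiles across diets and tissues
#'
#' One panel per module: eigengene value per sample against diet,
#' coloured by tissue, with per-cell means marked.
#'
#' @param modules a `coexpr_modules` object (or module x sample matrix).
#' @param meta sample table with `diet` and `tissue`.
#' @return a ggplot object.
#' @export
plot_eigengenes <- function(modules, meta) {
  eg <- if (inherits(modules, "coexpr_modules")) modules$eigengenes else
    as.matrix(modules)
  dat <- tibble::as_tibble(eg, rownames = "module") |>
    tidyr::pivot_longer(-"module", names_to = "sample_id",
                        values_to = "eigengene") |>
    dplyr::left_join(tibble::as_tibble(meta), by = "sample_id")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$diet, y = .data$eigengene,
                                    colour = .data$tissue)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.4),
                        alpha = 0.7, size = 1) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 2, size = 2.5,
                          position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::facet_wrap(~ module) +
    ggplot2::theme_minimal()
}

#' Scale-free fit across candidate soft-thresholding powers
#'
#' @param st a `soft_threshold` from [pick_soft_threshold()].
#' @return a ggplot object.
#' @export
plot_soft_threshold <- function(st) {
  stopifnot(inherits(st, "soft_threshold"))
  ggplot2::ggplot(st$fits, ggplot2::aes(x = .data$power, y = .data$fit)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = st$target, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = st$power, linetype = "dotted") +
    ggplot2::labs(x = "soft-thresholding power",
                  y = "scale-free fit index") +
    ggplot2::theme_minimal()
}
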