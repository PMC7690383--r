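#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Volcano plot of a differential-methylation result
#'
#' @param object A `dm_result` tibble from [dm_test()].
#' @param ... Unused.
#' @return A ggplot: `delta_beta` against `-log10(q)`, DM calls highlighted,
#'   threshold guides at the configured `db_min` and `q_max`.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.dm_result <- function(object, ...) {
  thr <- attr(object, "thresholds")
  contrast <- attr(object, "contrast")
  df <- dplyr::filter(object, !is.na(.data$q))
  ggplot2::ggplot(df, ggplot2::aes(.data$delta_beta, -log10(.data$q),
                                   colour = .data$is_dm)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_vline(xintercept = c(-thr[["db_min"]], thr[["db_min"]]),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = -log10(thr[["q_max"]]),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                                 name = "DM") +
    ggplot2::labs(
      x = expression(Delta * beta),
      y = expression(-log[10] ~ q),
      title = paste(contrast, collapse = " vs ")
    ) +
    ggplot2::theme_minimal()
}

#' Score plot for an evaluated classifier
#'
#' @param object An `eval_result` carrying a per-sample fold table (e.g. from
#'   [dlda_loocv()]).
#' @param ... Unused.
#' @return A ggplot of per-sample scores by true class, misclassified samples
#'   flagged.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.eval_result <- function(object, ...) {
  folds <- attr(object, "folds")
  if (is.null(folds)) stop("no per-sample scores attached to this result",
                           call. = FALSE)
  df <- dplyr::mutate(dplyr::filter(folds, !is.na(.data$predicted)),
                      correct = .data$predicted == .data$truth)
  ggplot2::ggplot(df, ggplot2::aes(.data$truth, .data$score,
                                   colour = .data$correct)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, size = 1.8) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "grey30", `FALSE` = "firebrick"),
                                 name = "correct") +
    ggplot2::labs(x = "true class", y = "classifier score") +
    ggplot2::theme_minimal()
}

#' Array-versus-pyrosequencing concordance plot
#'
#' @param array_bm,pyro_bm Array- and pyro-scale [beta_matrix()] objects
#'   sharing probes and samples (typically the marker rows).
#' @return A ggplot, one facet per probe, with the Pearson r annotated.
#' @export
plot_concordance <- function(array_bm, pyro_bm) {
  probes <- intersect(rownames(array_bm), rownames(pyro_bm))
  samples <- intersect(colnames(array_bm), colnames(pyro_bm))
  df <- purrr::map_dfr(probes, function(p) {
    tibble::tibble(probe_id = p,
                   array = unclass(array_bm)[p, samples] * 100,
                   pyro = unclass(pyro_bm)[p, samples])
  }) |> dplyr::filter(!is.na(.data$array), !is.na(.data$pyro))
  ann <- df |>
    dplyr::group_by(.data$probe_id) |>
    dplyr::summarise(r = stats::cor(.data$array, .data$pyro), .groups = "drop") |>
    dplyr::mutate(label = sprintf("r = %.3f", .data$r))
  ggplot2::ggplot(df, ggplot2::aes(.data$array, .data$pyro)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(size = 1, alpha = 0.7) +
    ggplot2::geom_text(data = ann, ggplot2::aes(label = .data$label),
                       x = -Inf, y = Inf, hjust = -0.2, vjust = 1.5,
                       inherit.aes = FALSE, size = 3) +
    ggplot2::facet_wrap(~probe_id) +
    ggplot2::labs(x = "array methylation (%)", y = "pyrosequencing methylation (%)") +
    ggplot2::theme_minimal()
}

#' Genomic-context distribution plot
#'
#' @param ctx A tibble from [context_summary()].
#' @return A stacked-proportion ggplot of island context by direction.
#' @export
plot_context <- function(ctx) {
  ggplot2::ggplot(ctx, ggplot2::aes(.data$direction, .data$prop,
                                    fill = .data$island_class)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = NULL, y = "proportion of DM probes", fill = "context") +
    ggplot2::theme_minimal()
}
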