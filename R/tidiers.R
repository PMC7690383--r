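#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a DLDA model
#'
#' @param x A `dlda_model`.
#' @param ... Unused.
#' @return One row per marker: `probe_id`, `weight`.
#' @export
#' @exportS3Method generics::tidy
tidy.dlda_model <- function(x, ...) {
  tibble::tibble(probe_id = x$probe_ids, weight = x$weights)
}

#' @rdname tidy.dlda_model
#' @return `glance()`: one row with `n_markers`, `threshold`, `scale`,
#'   `orientation`, `positive_class`.
#' @export
#' @exportS3Method generics::glance
glance.dlda_model <- function(x, ...) {
  tibble::tibble(n_markers = length(x$probe_ids), threshold = x$threshold,
                 scale = x$scale, orientation = x$orientation,
                 positive_class = x$classes[1])
}

#' Tidy an evaluation result
#'
#' @param x An `eval_result`.
#' @param ... Unused.
#' @return `tidy()`: the per-sample fold table when available (LOOCV), else
#'   the confusion counts in long form.
#' @export
#' @exportS3Method generics::tidy
tidy.eval_result <- function(x, ...) {
  folds <- attr(x, "folds")
  if (!is.null(folds)) return(folds)
  tibble::enframe(as.list(x$confusion), name = "cell", value = "n") |>
    tidyr::unnest("n")
}

#' @rdname tidy.eval_result
#' @return `glance()`: one row with the confusion counts and metrics
#'   (`sensitivity`, `specificity`, `accuracy` as proportions; `auc`).
#' @export
#' @exportS3Method generics::glance
glance.eval_result <- function(x, ...) {
  tibble::tibble(n = x$n, tp = x$confusion[["tp"]], fp = x$confusion[["fp"]],
                 tn = x$confusion[["tn"]], fn = x$confusion[["fn"]],
                 no_call = x$confusion[["no_call"]],
                 sensitivity = x$sensitivity, specificity = x$specificity,
                 accuracy = x$accuracy, auc = x$auc)
}
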