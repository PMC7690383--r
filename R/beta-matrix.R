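#' Probes-by-samples methylation matrix
#'
#' A `beta_matrix` wraps a numeric probes-by-samples matrix of methylation
#' levels together with a measurement scale: `"array"` for intensity-derived
#' beta values in the open interval (0, 1), or `"pyro"` for
#' bisulfite-pyrosequencing percent methylation in \[0, 100\]. Missing entries
#' (`NA`) are permitted on either scale and stand for failed measurements
#' (e.g. low-quality pyrosequencing reactions); they are never coerced to 0.
#'
#' @param values Numeric matrix, probes in rows, samples in columns, with
#'   non-empty unique `rownames` (probe ids) and `colnames` (sample ids).
#' @param scale Either `"array"` or `"pyro"`.
#'
#' @return An object of class `beta_matrix`: the validated matrix with a
#'   `scale` attribute.
#' @export
#' @examples
#' m <- matrix(c(0.1, 0.9, 0.4, 0.6), 2, 2,
#'             dimnames = list(c("cg01", "cg02"), c("s1", "s2")))
#' bm <- beta_matrix(m, "array")
#' beta_scale(bm)
beta_matrix <- function(values, scale = c("array", "pyro")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry probe rownames and sample colnames", call. = FALSE)
  }
  dup_p <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_p) > 0) {
    stop("duplicated probe id(s): ", paste(utils::head(dup_p, 5), collapse = ", "),
         call. = FALSE)
  }
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s) > 0) {
    stop("duplicated sample id(s): ", paste(utils::head(dup_s, 5), collapse = ", "),
         call. = FALSE)
  }
  check_beta_range(values, scale)
  structure(values, scale = scale, class = c("beta_matrix", "matrix", "array"))
}

# Range check that names the first offending probe/sample.
check_beta_range <- function(values, scale) {
  lims <- if (scale == "array") c(0, 1) else c(0, 100)
  open <- scale == "array"
  bad <- which(
    !is.na(values) &
      (if (open) values <= lims[1] | values >= lims[2]
       else values < lims[1] | values > lims[2])
  )
  if (length(bad) > 0) {
    i <- arrayInd(bad[1], dim(values))
    stop(sprintf(
      "value %g out of range for scale '%s' at probe '%s', sample '%s'",
      values[bad[1]], scale, rownames(values)[i[1]], colnames(values)[i[2]]
    ), call. = FALSE)
  }
  invisible(values)
}

#' @rdname beta_matrix
#' @param x,bm A `beta_matrix`.
#' @export
beta_scale <- function(x) attr(x, "scale")

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("<beta_matrix> %d probes x %d samples, scale = %s, %d missing\n",
              nrow(x), ncol(x), beta_scale(x), sum(is.na(x))))
  utils::str(unclass(x)[seq_len(min(3L, nrow(x))), seq_len(min(4L, ncol(x))), drop = FALSE])
  invisible(x)
}

#' @rdname beta_matrix
#' @param ... Unused.
#' @export
#' @exportS3Method tibble::as_tibble
as_tibble.beta_matrix <- function(x, ...) {
  tibble::as_tibble(unclass(x), rownames = "probe_id")
}

#' Tidy a beta matrix to long format
#'
#' @param bm A [beta_matrix()].
#' @return A tibble with columns `probe_id`, `sample_id`, `beta`.
#' @export
beta_long <- function(bm) {
  as_tibble.beta_matrix(bm) |>
    tidyr::pivot_longer(-"probe_id", names_to = "sample_id", values_to = "beta")
}

# Subset that keeps class/scale. Drops to plain numeric when a single
# probe/sample is extracted with drop = TRUE (matrix semantics preserved).
#' @export
`[.beta_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- unclass(x)[i, j, ..., drop = drop]
  if (is.matrix(out)) {
    structure(out, scale = beta_scale(x), class = class(x))
  } else {
    out
  }
}
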