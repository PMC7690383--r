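#' Spearman rank correlation with exact small-sample p
#'
#' Average-rank tie handling. The p-value is exact (permutation null of the
#' rank statistic) for n <= 10 with no ties, and uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` otherwise.
#'
#' @param x,y Numeric vectors; pairs with missing values are dropped.
#' @return Tibble with `rho`, `p`, `n`. `rho` is `NA` (with `p = NA`) when
#'   either vector is constant.
#' @export
spearman_corr <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) stop("need at least 4 paired non-missing values", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(tibble::tibble(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- stats::cor(x, y, method = "spearman")
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (n <= 10 && !ties) {
    p <- stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
  }
  tibble::tibble(rho = rho, p = p, n = n)
}

#' Two-sided Mann-Whitney test
#'
#' Reports the U statistic for the first group and a two-sided p-value: exact
#' (full enumeration of the U null) when `n1 * n2 <= 10000` and the data are
#' tie-free, otherwise the normal approximation with tie correction and
#' continuity correction.
#'
#' @param x,y Numeric vectors for the two groups.
#' @return Tibble with `u`, `p`, `method` (`"exact"`/`"approximate"`).
#' @export
mannwhitney <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && length(x) * length(y) <= 10000
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = !exact))
  tibble::tibble(u = unname(wt$statistic), p = wt$p.value,
                 method = if (exact) "exact" else "approximate")
}

#' Overlap CpG probes with regulatory intervals
#'
#' Maps each probe's 1-based manifest position onto the 0-based half-open BED
#' intervals (`pos0 = pos - 1`; overlap iff `start <= pos0 < end`) and
#' reports, for every probe, its single nearest interval with a signed
#' distance: 0 inside the interval, negative when the probe lies upstream of
#' the interval start, positive when downstream of its end (plus-strand
#' convention). All additional overlapping intervals are listed too.
#'
#' @param manifest Probe annotation tibble with `probe_id`, `chrom`, `pos`.
#' @param intervals Interval tibble from [read_intervals()].
#' @return Tibble with `probe_id`, `chrom`, `pos`, `region`, `distance`,
#'   `nearest` (logical; exactly one `TRUE` row per probe). Probes on
#'   chromosomes absent from `intervals` appear once with `region = NA`.
#' @export
overlap_probes <- function(manifest, intervals) {
  if (nrow(intervals) == 0 || nrow(manifest) == 0) {
    return(tibble::tibble(probe_id = manifest$probe_id, chrom = manifest$chrom,
                          pos = manifest$pos, region = NA_character_,
                          distance = NA_real_, nearest = TRUE))
  }
  # probes as 1-width points in 1-based GRanges space; BED -> 1-based start+1
  pr <- GenomicRanges::GRanges(manifest$chrom,
                               IRanges::IRanges(manifest$pos, width = 1))
  rg <- GenomicRanges::GRanges(intervals$chrom,
                               IRanges::IRanges(intervals$start + 1, intervals$end))
  signed_dist <- function(pi, ri) {
    pos0 <- manifest$pos[pi] - 1
    st <- intervals$start[ri]; en <- intervals$end[ri]
    dplyr::case_when(pos0 >= st & pos0 < en ~ 0,
                     pos0 < st ~ pos0 - st,
                     TRUE ~ pos0 - (en - 1))
  }
  # disjoint chromosome sets between probes and regions are expected (a probe
  # with no region on its chromosome is reported unmatched), so silence the
  # seqlevel-mismatch warnings
  ov <- suppressWarnings(GenomicRanges::findOverlaps(pr, rg))
  ov_tbl <- tibble::tibble(
    pi = S4Vectors::queryHits(ov), ri = S4Vectors::subjectHits(ov))
  near <- suppressWarnings(GenomicRanges::nearest(pr, rg, select = "arbitrary"))
  near_tbl <- tibble::tibble(pi = seq_len(nrow(manifest)), ri = near) |>
    dplyr::filter(!is.na(.data$ri))
  # nearest(): prefer a true overlap when one exists
  near_tbl <- near_tbl |>
    dplyr::left_join(dplyr::summarise(ov_tbl, ri_ov = .data$ri[1],
                                      .by = "pi"), by = "pi") |>
    dplyr::mutate(ri = dplyr::coalesce(.data$ri_ov, .data$ri)) |>
    dplyr::select("pi", "ri")
  combined <- dplyr::bind_rows(
    dplyr::mutate(near_tbl, nearest = TRUE),
    dplyr::mutate(dplyr::anti_join(ov_tbl, near_tbl, by = c("pi", "ri")),
                  nearest = FALSE)
  )
  no_match <- setdiff(seq_len(nrow(manifest)), combined$pi)
  out <- combined |>
    dplyr::mutate(
      probe_id = manifest$probe_id[.data$pi],
      chrom = manifest$chrom[.data$pi],
      pos = manifest$pos[.data$pi],
      region = intervals$name[.data$ri],
      distance = signed_dist(.data$pi, .data$ri)
    )
  if (length(no_match) > 0) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      pi = no_match, ri = NA_integer_, nearest = TRUE,
      probe_id = manifest$probe_id[no_match],
      chrom = manifest$chrom[no_match], pos = manifest$pos[no_match],
      region = NA_character_, distance = NA_real_))
  }
  out |>
    dplyr::arrange(.data$pi, dplyr::desc(.data$nearest), abs(.data$distance)) |>
    dplyr::select("probe_id", "chrom", "pos", "region", "distance", "nearest")
}

#' Correlate marker methylation with linked gene expression
#'
#' For each marker-gene link, computes the Spearman correlation between the
#' marker's beta values and the gene's expression on the samples present in
#' both matrices, plus a Mann-Whitney comparison of the gene's expression
#' between the positive and negative response groups.
#'
#' @param bm A [beta_matrix()] containing the marker probes.
#' @param expr Genes-by-samples numeric matrix (log-scale expression).
#' @param links Tibble with columns `marker` (probe id) and `gene`.
#' @param samples Sample sheet tibble (for the group comparison).
#' @param classes Length-2 character: groups compared for expression.
#' @return Tibble, one row per usable link: `marker`, `gene`, `n`, `rho`,
#'   `p_rho`, `mean_expr_pos`, `mean_expr_neg`, `p_group`. Links with fewer
#'   than 4 shared samples are skipped with a warning.
#' @export
correlate_markers <- function(bm, expr, links, samples,
                              classes = c("pCR", "pIR")) {
  purrr::pmap_dfr(links[, c("marker", "gene")], function(marker, gene) {
    if (!marker %in% rownames(bm) || !gene %in% rownames(expr)) {
      warning("link ", marker, " -> ", gene,
              " skipped: id absent from inputs", call. = FALSE)
      return(NULL)
    }
    shared <- intersect(colnames(bm), colnames(expr))
    b <- unclass(bm)[marker, shared]
    e <- expr[gene, shared]
    keep <- !is.na(b) & !is.na(e)
    if (sum(keep) < 4) {
      warning("link ", marker, " -> ", gene,
              " skipped: fewer than 4 shared samples", call. = FALSE)
      return(NULL)
    }
    sc <- spearman_corr(b[keep], e[keep])
    grp <- samples$group[match(shared, samples$sample_id)]
    e_pos <- e[grp == classes[1] & !is.na(e)]
    e_neg <- e[grp == classes[2] & !is.na(e)]
    mw <- if (length(e_pos) > 0 && length(e_neg) > 0) {
      mannwhitney(e_pos, e_neg)
    } else tibble::tibble(u = NA_real_, p = NA_real_)
    tibble::tibble(marker = marker, gene = gene, n = sc$n, rho = sc$rho,
                   p_rho = sc$p,
                   mean_expr_pos = mean(e_pos), mean_expr_neg = mean(e_neg),
                   p_group = mw$p)
  })
}
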