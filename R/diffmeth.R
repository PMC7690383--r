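#' Empirical-Bayes variance prior for moderated testing
#'
#' Fits the scaled inverse-chi-squared prior of the moderated t framework by
#' method of moments on the log sample variances: if per-probe variances
#' follow `s0_sq * d0 / chisq(d0)` priors with residual degrees of freedom
#' `df_g`, then `log(s2)` has a known digamma/trigamma mean and variance,
#' which are inverted here. When the observed dispersion of `log(s2)` does not
#' exceed what sampling alone explains, the prior degrees of freedom are
#' infinite and every probe shares the common variance.
#'
#' @param s2 Vector of per-probe sample variances (pooled within groups).
#' @param df_g Residual degrees of freedom each variance was estimated with.
#' @return A list of class `mod_t_params` with `d0` (prior df, possibly
#'   `Inf`) and `s0_sq` (prior variance).
#' @export
fit_variance_prior <- function(s2, df_g) {
  s2 <- s2[!is.na(s2)]
  if (length(s2) == 0 || all(s2 == 0)) {
    stop("cannot fit a variance prior: all variances are zero or missing",
         call. = FALSE)
  }
  if (length(s2) < 10) {
    warning("variance prior fitted on ", length(s2),
            " probes; estimate is low-confidence", call. = FALSE)
  }
  pos <- s2[s2 > 0]
  z <- log(pos)
  e <- z - digamma(df_g / 2) + log(df_g / 2)
  ev <- mean(e)
  excess <- stats::var(e) - trigamma(df_g / 2)
  if (!is.finite(excess) || excess <= 0) {
    # no excess dispersion beyond sampling: common variance across probes
    d0 <- Inf
    s0_sq <- mean(pos)
  } else {
    d0 <- 2 * trigamma_inverse(excess)
    s0_sq <- exp(ev + digamma(d0 / 2) - log(d0 / 2))
  }
  structure(list(d0 = d0, s0_sq = s0_sq), class = "mod_t_params")
}

# Newton inversion of trigamma on (0, Inf); monotone decreasing.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Moderated two-group test on beta values
#'
#' Tests each probe for a mean difference between two sample groups with
#' empirical-Bayes variance moderation: the pooled within-group variance of
#' each probe is shrunk towards the prior as
#' `s2_tilde = (d0 * s0_sq + df_g * s2) / (d0 + df_g)` and the t statistic
#' `delta_beta / (s_tilde * sqrt(1/n1 + 1/n2))` is referred to a t
#' distribution on `d0 + df_g` degrees of freedom. The effect `delta_beta` is
#' `mean(group1) - mean(group2)`, so `direction = "hyper"` means higher
#' methylation in `group1`. Benjamini-Hochberg adjustment is applied within
#' the contrast, over testable probes only.
#'
#' Probes with fewer than two non-missing samples in either group are
#' untestable: they are returned with missing statistics and excluded from the
#' FDR denominator.
#'
#' @param bm A [beta_matrix()] (any scale; the test is scale-agnostic).
#' @param samples Sample sheet tibble with `sample_id` and `group`.
#' @param contrast Length-2 character: groups to compare as (group1, group2),
#'   e.g. `c("pCR", "NT")`.
#' @param params Optional `mod_t_params`; fitted from the data when `NULL`.
#'   `d0 = 0` gives the ordinary pooled two-sample t test.
#' @param q_max,db_min DM-call thresholds: q below `q_max` and `|delta_beta|`
#'   strictly above `db_min` (both inequalities strict).
#' @param use_mvalues Run the test on M-values `log2(beta / (1 - beta))`
#'   instead of betas. The reported `delta_beta` stays on the beta scale so
#'   the effect filter keeps its meaning.
#' @return A `dm_result` tibble with one row per probe: `probe_id`,
#'   `delta_beta`, `t_mod`, `df_total`, `p`, `q`, `direction`, `is_dm`, plus
#'   attributes `contrast`, `params`, `thresholds`.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_probes = 500, seed = 3))
#' dm <- dm_test(cohort$beta, cohort$samples, c("pIR", "NT"))
#' dplyr::count(dm, is_dm, direction)
dm_test <- function(bm, samples, contrast, params = NULL,
                    q_max = 0.05, db_min = 0.15, use_mvalues = FALSE) {
  stopifnot(length(contrast) == 2)
  g1 <- samples$sample_id[samples$group == contrast[1]]
  g2 <- samples$sample_id[samples$group == contrast[2]]
  g1 <- intersect(g1, colnames(bm))
  g2 <- intersect(g2, colnames(bm))
  if (length(g1) < 2 || length(g2) < 2) {
    stop("each contrast group needs at least two samples", call. = FALSE)
  }
  x1 <- unclass(bm)[, g1, drop = FALSE]
  x2 <- unclass(bm)[, g2, drop = FALSE]

  db <- unname(rowMeans(x1, na.rm = TRUE) - rowMeans(x2, na.rm = TRUE))
  if (use_mvalues) {
    x1 <- log2(x1 / (1 - x1))
    x2 <- log2(x2 / (1 - x2))
  }
  n1 <- rowSums(!is.na(x1))
  n2 <- rowSums(!is.na(x2))
  testable <- n1 >= 2 & n2 >= 2
  v1 <- apply(x1, 1, stats::var, na.rm = TRUE)
  v2 <- apply(x2, 1, stats::var, na.rm = TRUE)
  df_g <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df_g

  if (is.null(params)) {
    params <- fit_variance_prior(s2[testable], stats::median(df_g[testable]))
  }
  stopifnot(inherits(params, "mod_t_params"))
  d0 <- params$d0
  s2_tilde <- if (is.infinite(d0)) rep(params$s0_sq, length(s2))
              else (d0 * params$s0_sq + df_g * s2) / (d0 + df_g)
  # reference-distribution df capped at the pooled total, as in limma's eBayes
  df_total <- pmin(d0 + df_g, sum(df_g[testable]))

  eff <- if (use_mvalues) rowMeans(x1, na.rm = TRUE) - rowMeans(x2, na.rm = TRUE) else db
  se <- sqrt(s2_tilde * (1 / n1 + 1 / n2))
  t_mod <- eff / se
  p <- 2 * stats::pt(-abs(t_mod), df_total)
  t_mod[!testable] <- NA_real_
  p[!testable] <- NA_real_

  n_untestable <- sum(!testable)
  if (n_untestable > 0) {
    rlang::inform(sprintf(
      "%d probe(s) untestable (fewer than 2 usable samples in a group); excluded from FDR",
      n_untestable), class = "methresp_dm")
  }
  q <- rep(NA_real_, length(p))
  q[testable] <- bh_fdr(p[testable])

  res <- tibble::tibble(
    probe_id = rownames(bm),
    delta_beta = unname(db),
    t_mod = unname(t_mod),
    df_total = unname(df_total),
    p = unname(p),
    q = unname(q),
    direction = dplyr::case_when(db > 0 ~ "hyper", db < 0 ~ "hypo",
                                 TRUE ~ NA_character_),
    is_dm = !is.na(q) & q < q_max & abs(db) > db_min
  )
  attr(res, "contrast") <- contrast
  attr(res, "params") <- params
  attr(res, "thresholds") <- c(q_max = q_max, db_min = db_min)
  class(res) <- c("dm_result", class(res))
  res
}

#' Benjamini-Hochberg adjusted p-values
#'
#' @param p Vector of p-values in \[0, 1\] (`NA` allowed and propagated).
#' @return Step-up adjusted q-values, capped at 1.
#' @export
bh_fdr <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    k <- which(ok & (p < 0 | p > 1))[1]
    stop("p-value out of [0, 1] at position ", k, ": ", p[k], call. = FALSE)
  }
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Call differentially methylated probes
#'
#' Applies the joint significance and effect-size rule — q strictly below
#' `q_max` and `|delta_beta|` strictly above `db_min` — and tallies calls by
#' direction.
#'
#' @param dm A `dm_result` tibble from [dm_test()].
#' @param q_max,db_min Thresholds (strict inequalities).
#' @return The filtered tibble of DM probes, with a `counts` attribute
#'   (named: hyper, hypo, total).
#' @export
call_dm <- function(dm, q_max = 0.05, db_min = 0.15) {
  out <- dplyr::filter(dm, !is.na(.data$q), .data$q < q_max,
                       abs(.data$delta_beta) > db_min)
  counts <- c(hyper = sum(out$direction == "hyper"),
              hypo = sum(out$direction == "hypo"),
              total = nrow(out))
  attr(out, "counts") <- counts
  out
}

#' Partition two DM probe sets into exclusive and shared compartments
#'
#' @param dm_a,dm_b Character vectors of probe ids (or `dm_result` tibbles,
#'   from which DM probe ids are taken).
#' @return A tibble with one row per probe and columns `probe_id`,
#'   `compartment` (`only_a`, `only_b`, `shared`); a `counts` attribute gives
#'   the three cardinalities.
#' @export
#' @examples
#' vp <- venn_partition(c("cg1", "cg2"), c("cg2", "cg3"))
#' attr(vp, "counts")
venn_partition <- function(dm_a, dm_b) {
  as_ids <- function(x) {
    if (is.data.frame(x)) unique(x$probe_id[x$is_dm %||% TRUE]) else unique(as.character(x))
  }
  a <- as_ids(dm_a)
  b <- as_ids(dm_b)
  shared <- intersect(a, b)
  only_a <- setdiff(a, b)
  only_b <- setdiff(b, a)
  out <- tibble::tibble(
    probe_id = c(only_a, only_b, shared),
    compartment = rep(c("only_a", "only_b", "shared"),
                      c(length(only_a), length(only_b), length(shared)))
  )
  attr(out, "counts") <- c(only_a = length(only_a), only_b = length(only_b),
                           shared = length(shared))
  out
}

#' Genomic-context distribution of a DM set
#'
#' Cross-tabulates DM probes by gene-region class, CpG-island context and
#' methylation direction, with proportions within each direction (so e.g. the
#' fraction of hypermethylated probes falling in islands can be read off
#' directly).
#'
#' @param probe_ids Character vector of DM probe ids.
#' @param manifest Probe annotation tibble ([read_manifest()] format).
#' @param direction Character vector parallel to `probe_ids` ("hyper"/"hypo").
#' @return A tibble with counts and within-direction proportions for each
#'   `direction x region_class x island_class` cell, plus marginal proportion
#'   columns `prop_region` and `prop_island`.
#' @export
context_summary <- function(probe_ids, manifest, direction) {
  stopifnot(length(probe_ids) == length(direction))
  if (length(probe_ids) == 0) {
    return(tibble::tibble(direction = character(), region_class = character(),
                          island_class = character(), n = integer(),
                          prop = numeric(), prop_region = numeric(),
                          prop_island = numeric()))
  }
  idx <- match(probe_ids, manifest$probe_id)
  if (anyNA(idx)) {
    stop("unannotated probe(s): ",
         paste(utils::head(probe_ids[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(
    direction = direction,
    region_class = manifest$region_class[idx],
    island_class = manifest$island_class[idx]
  ) |>
    dplyr::count(.data$direction, .data$region_class, .data$island_class) |>
    dplyr::group_by(.data$direction) |>
    dplyr::mutate(prop = .data$n / sum(.data$n)) |>
    dplyr::group_by(.data$direction, .data$region_class) |>
    dplyr::mutate(prop_region = sum(.data$n)) |>
    dplyr::group_by(.data$direction, .data$island_class) |>
    dplyr::mutate(prop_island = sum(.data$n)) |>
    dplyr::group_by(.data$direction) |>
    dplyr::mutate(prop_region = .data$prop_region / sum(.data$n),
                  prop_island = .data$prop_island / sum(.data$n)) |>
    dplyr::ungroup()
}

#' Most-variable probes by standard deviation
#'
#' @param bm A [beta_matrix()].
#' @param sd_min Keep probes whose across-sample SD (denominator n-1) is
#'   strictly greater than this.
#' @return Character vector of probe ids.
#' @export
select_variable_probes <- function(bm, sd_min = 0.2) {
  sds <- apply(unclass(bm), 1, stats::sd, na.rm = TRUE)
  rownames(bm)[!is.na(sds) & sds > sd_min]
}

#' Correlation-based hierarchical clustering of samples
#'
#' Agglomerative clustering of samples on the distance `1 - Pearson
#' correlation` between their methylation profiles, average linkage, cut into
#' `k` clusters. Deterministic for a given column order (ties resolve by
#' `stats::hclust`'s ordering, which follows the input order).
#'
#' @param bm A [beta_matrix()], typically restricted to
#'   [select_variable_probes()].
#' @param k Number of clusters.
#' @return A tibble with `sample_id` and `cluster` (integer); the `hclust`
#'   object is attached as attribute `tree`.
#' @export
cluster_samples <- function(bm, k = 3) {
  if (k > ncol(bm)) stop("k exceeds the number of samples", call. = FALSE)
  d <- stats::as.dist(1 - stats::cor(unclass(bm), use = "pairwise.complete.obs"))
  tree <- stats::hclust(d, method = "average")
  labels <- stats::cutree(tree, k = k)
  out <- tibble::tibble(sample_id = colnames(bm), cluster = unname(labels))
  attr(out, "tree") <- tree
  out
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Standard two-sided convention: the p-value sums the hypergeometric
#' probabilities, at fixed margins, of every table whose point probability
#' does not exceed that of the observed table (up to a small relative
#' tolerance for floating-point ties).
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return The two-sided p-value.
#' @export
#' @examples
#' fisher_exact_2x2(matrix(c(3, 8, 15, 6), 2)) # cluster enrichment example
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("need a 2x2 table", call. = FALSE)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  stats::fisher.test(tab)$p.value
}

#' Fisher enrichment of a group across sample clusters
#'
#' Convenience wrapper: tests whether membership of a target group (e.g. pCR)
#' is enriched in one cluster versus the rest.
#'
#' @param clusters Tibble from [cluster_samples()].
#' @param samples Sample sheet tibble.
#' @param group Target group label.
#' @param cluster Cluster id tested against all others.
#' @return A tibble with the 2x2 counts and the two-sided Fisher p.
#' @export
cluster_enrichment <- function(clusters, samples, group = "pCR", cluster = 3) {
  joined <- dplyr::inner_join(clusters, samples, by = "sample_id")
  in_cl <- joined$cluster == cluster
  in_gr <- joined$group == group
  tab <- matrix(c(sum(!in_cl & in_gr), sum(in_cl & in_gr),
                  sum(!in_cl & !in_gr), sum(in_cl & !in_gr)), 2)
  tibble::tibble(
    cluster = cluster, group = group,
    group_in_cluster = tab[2, 1], other_in_cluster = tab[2, 2],
    group_elsewhere = tab[1, 1], other_elsewhere = tab[1, 2],
    p = fisher_exact_2x2(tab)
  )
}
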