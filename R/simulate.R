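#' Configuration for the synthetic cohort generator
#'
#' Builds the parameter set for [simulate_cohort()] and friends. Defaults
#' emulate a three-group rectal-cancer methylation study: 5 normal tissues
#' (NT), 11 complete responders (pCR) and 21 incomplete responders (pIR)
#' profiled on an array scale, with pIR-dominant hypomethylation, pCR
#' island-biased hypermethylation, and three designated marker CpGs
#' hypomethylated in pIR whose per-probe discrimination (Mann-Whitney AUC,
#' pCR vs pIR) is calibrated to roughly 0.70-0.75.
#'
#' @param n_NT,n_pCR,n_pIR Group sizes.
#' @param n_probes Total probe count (markers included).
#' @param dm_fraction_pCR,dm_fraction_pIR Fractions of probes differentially
#'   methylated versus NT in each tumour group.
#' @param dm_shared_frac Fraction of the pCR DM set that is also DM in pIR
#'   (shared Venn compartment).
#' @param hyper_prop_pCR,hyper_prop_pIR Proportion of each group's exclusive
#'   DM probes that are hypermethylated (the rest are hypomethylated).
#' @param island_hyper_prop_pCR,island_hyper_prop_pIR Proportion of each
#'   group's hypermethylated exclusive DM probes that fall in CpG islands.
#' @param delta_beta_effect Injected |group mean - NT mean| for DM probes.
#' @param background_sd Within-group SD of non-marker probes (beta scale).
#' @param marker_ids Ids of the three marker CpGs, in order A, B, C.
#' @param marker_auc_targets Per-marker target AUC (pCR vs pIR) used to set
#'   the pCR-pIR mean gap via the Gaussian closed form
#'   `AUC = pnorm(gap / (sd * sqrt(2)))`.
#' @param marker_sd Within-group SD of the marker probes.
#' @param marker_means Optional 3x3 numeric matrix (rows = markers A, B, C;
#'   columns `NT`, `pCR`, `pIR`) overriding the AUC-derived means.
#' @param pyro_noise_sd Gaussian noise SD, in percentage points, added by the
#'   pyrosequencing replica.
#' @param ffpe_offset_markerA Additive offset (percentage points) applied to
#'   marker A in FFPE samples on the pyro scale; emulates the higher apparent
#'   methylation of formalin-fixed material at that CpG.
#' @param pyro_missing_frac Fraction of replica entries set missing to emulate
#'   failed pyrosequencing reactions.
#' @param ffpe_frac Fraction of tumour samples labelled FFPE in the sample
#'   sheet (NT samples are always FF).
#' @param expr_links Data frame with columns `gene`, `marker` (an id from
#'   `marker_ids`) and `rho` (target Spearman correlation, signed). Defaults
#'   link marker A positively (+0.52) and marker C negatively (-0.42) to one
#'   gene each.
#' @param n_expr Number of tumour samples with expression data (sampled from
#'   the pCR/pIR columns).
#' @param n_genes Total genes in the expression matrix (unlinked genes are
#'   noise).
#' @param seed Integer seed; fixing the full configuration makes every
#'   generator output reproducible bit-for-bit.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 7)
#' cohort <- simulate_cohort(cfg)
#' dim(cohort$beta)
sim_config <- function(n_NT = 5, n_pCR = 11, n_pIR = 21,
                       n_probes = 20000,
                       dm_fraction_pCR = 0.034, dm_fraction_pIR = 0.104,
                       dm_shared_frac = 0.858,
                       hyper_prop_pCR = 0.44, hyper_prop_pIR = 0.18,
                       island_hyper_prop_pCR = 0.66, island_hyper_prop_pIR = 0.36,
                       delta_beta_effect = 0.30,
                       background_sd = 0.05,
                       marker_ids = c("cg01072658", "cg03085846", "cg13770628"),
                       marker_auc_targets = c(0.706, 0.754, 0.697),
                       marker_sd = 0.15,
                       marker_means = NULL,
                       pyro_noise_sd = 3.5,
                       ffpe_offset_markerA = 5,
                       pyro_missing_frac = 0.05,
                       ffpe_frac = 0.35,
                       expr_links = NULL,
                       n_expr = 27,
                       n_genes = 50,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (is.null(cfg$marker_means)) {
    gap <- marker_sd * sqrt(2) * stats::qnorm(marker_auc_targets)
    pcr <- c(0.55, 0.58, 0.52)
    cfg$marker_means <- cbind(NT = pcr, pCR = pcr, pIR = pcr - gap)
    rownames(cfg$marker_means) <- marker_ids
  }
  if (is.null(cfg$expr_links)) {
    cfg$expr_links <- tibble::tibble(
      gene = c("OBSL1", "INSIG1"),
      marker = marker_ids[c(1, 3)],
      rho = c(0.52, -0.42)
    )
  }
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  counts <- c(cfg$n_NT, cfg$n_pCR, cfg$n_pIR, cfg$n_probes)
  if (any(counts <= 0)) stop("sample and probe counts must be positive", call. = FALSE)
  props <- c(cfg$dm_fraction_pCR, cfg$dm_fraction_pIR, cfg$dm_shared_frac,
             cfg$hyper_prop_pCR, cfg$hyper_prop_pIR,
             cfg$island_hyper_prop_pCR, cfg$island_hyper_prop_pIR,
             cfg$pyro_missing_frac, cfg$ffpe_frac)
  if (any(props < 0 | props > 1)) stop("proportions must lie in [0, 1]", call. = FALSE)
  mm <- cfg$marker_means
  if (!is.matrix(mm) || nrow(mm) != length(cfg$marker_ids) ||
      !all(c("NT", "pCR", "pIR") %in% colnames(mm))) {
    stop("marker_means must be a markers x {NT,pCR,pIR} matrix", call. = FALSE)
  }
  if (any(mm <= 0 | mm >= 1)) stop("marker means must lie in (0, 1)", call. = FALSE)
  if (any(mm[, "pIR"] >= mm[, "pCR"])) {
    stop("marker means must satisfy pIR < pCR (markers hypomethylated in pIR)",
         call. = FALSE)
  }
  if (!all(cfg$expr_links$marker %in% cfg$marker_ids)) {
    bad <- setdiff(cfg$expr_links$marker, cfg$marker_ids)
    stop("expression link to unknown marker: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cfg
}

# Stage-level substreams derived from the one configured seed, so a stage can
# be rerun independently and still reproduce.
stage_seed <- function(seed, stage) {
  offsets <- c(cohort = 0L, pyro = 104729L, expr = 224737L)
  (as.integer(seed) %% 20000003L) * 101L + offsets[[stage]]
}

# Beta draw with moment-matched shape parameters; sd is capped just below the
# feasibility bound sqrt(m (1 - m)).
rbeta_moment <- function(n, mean, sd) {
  sd <- pmin(sd, 0.9 * sqrt(mean * (1 - mean)))
  nu <- mean * (1 - mean) / sd^2 - 1
  stats::rbeta(n, mean * nu, (1 - mean) * nu)
}

#' Simulate a three-group methylation cohort
#'
#' Draws a probes-by-samples beta matrix with annotated genomic context, a
#' sample sheet, and a truth table of every injected effect. Background probes
#' come from island-context-conditioned unimodal beta distributions (islands
#' mostly unmethylated, open sea mostly methylated), giving the bimodal
#' genome-wide mixture typical of methylation arrays. Differential methylation
#' versus NT is injected by shifting group means by `delta_beta_effect`, with
#' hypermethylation probability and island placement following the configured
#' direction and context biases. The three marker CpGs get the configured
#' group means (NT ~ pCR > pIR) with SD `marker_sd`. All values are clamped to
#' \[0.001, 0.999\] so logit transforms stay finite.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `beta` (a [beta_matrix()]), `manifest`
#'   (probe annotation tibble), `samples` (sample sheet tibble) and `truth`
#'   (tibble of injected effects: one row per probe whose group means differ).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  validate_sim_config(cfg)
  set.seed(stage_seed(cfg$seed, "cohort"))

  n_probes <- cfg$n_probes
  marker_ids <- cfg$marker_ids
  probe_ids <- sprintf("cg%08d", seq_len(n_probes))
  probe_ids[seq_along(marker_ids)] <- marker_ids
  probe_ids <- sample(probe_ids)  # markers at random rows

  island_class <- sample(island_classes, n_probes, replace = TRUE,
                         prob = c(0.31, 0.23, 0.10, 0.36))
  region_class <- sample(region_classes, n_probes, replace = TRUE,
                         prob = c(0.37, 0.33, 0.30))
  manifest <- tibble::tibble(
    probe_id = probe_ids,
    chrom = sample(paste0("chr", 1:22), n_probes, replace = TRUE),
    pos = sample.int(1e8L, n_probes, replace = TRUE),
    region_class = region_class,
    island_class = island_class,
    flags = ""
  )

  # context-conditioned background means
  base_mu <- c(island = 0.15, shore = 0.35, shelf = 0.55, open_sea = 0.75)
  base_sp <- c(island = 0.08, shore = 0.12, shelf = 0.12, open_sea = 0.08)
  mu0 <- stats::rnorm(n_probes, base_mu[island_class], base_sp[island_class])
  mu0 <- pmin(pmax(mu0, 0.05), 0.95)

  is_marker <- probe_ids %in% marker_ids
  eligible <- which(!is_marker)

  d <- cfg$delta_beta_effect
  n_dm_pCR <- round(cfg$dm_fraction_pCR * n_probes)
  n_shared <- round(cfg$dm_shared_frac * n_dm_pCR)
  n_only_pCR <- n_dm_pCR - n_shared
  n_only_pIR <- round(cfg$dm_fraction_pIR * n_probes) - n_shared
  stopifnot(n_only_pIR >= 0, n_only_pCR + n_shared + n_only_pIR <= length(eligible))

  # Draw a DM compartment: directions first, then probe identities with the
  # island bias applied to the hypermethylated draws.
  draw_set <- function(n, hyper_prop, island_hyper_prop, pool) {
    if (n == 0) return(list(idx = integer(0), hyper = logical(0), pool = pool))
    hyper <- stats::runif(n) < hyper_prop
    isl_pool <- pool[island_class[pool] == "island"]
    oth_pool <- pool[island_class[pool] != "island"]
    idx <- integer(n)
    for (k in seq_len(n)) {
      from_island <- if (hyper[k]) stats::runif(1) < island_hyper_prop
                     else stats::runif(1) < length(isl_pool) / (length(isl_pool) + length(oth_pool))
      if (from_island && length(isl_pool) > 0) {
        j <- sample.int(length(isl_pool), 1); idx[k] <- isl_pool[j]; isl_pool <- isl_pool[-j]
      } else {
        j <- sample.int(length(oth_pool), 1); idx[k] <- oth_pool[j]; oth_pool <- oth_pool[-j]
      }
    }
    list(idx = idx, hyper = hyper, pool = c(isl_pool, oth_pool))
  }

  s1 <- draw_set(n_only_pCR, cfg$hyper_prop_pCR, cfg$island_hyper_prop_pCR, eligible)
  s2 <- draw_set(n_only_pIR, cfg$hyper_prop_pIR, cfg$island_hyper_prop_pIR, s1$pool)
  s3 <- draw_set(n_shared, mean(c(cfg$hyper_prop_pCR, cfg$hyper_prop_pIR)),
                 mean(c(cfg$island_hyper_prop_pCR, cfg$island_hyper_prop_pIR)), s2$pool)

  # per-group probe means; keep the injected shift feasible by pulling the NT
  # base into a range where mean +/- delta stays inside (0.03, 0.97)
  mu_NT <- mu0
  mu_pCR <- mu0
  mu_pIR <- mu0
  inject <- function(idx, hyper, groups) {
    for (k in seq_along(idx)) {
      i <- idx[k]
      if (hyper[k]) mu_NT[i] <<- min(mu_NT[i], 0.97 - d)
      else mu_NT[i] <<- max(mu_NT[i], 0.03 + d)
      shifted <- mu_NT[i] + if (hyper[k]) d else -d
      if ("pCR" %in% groups) mu_pCR[i] <<- shifted else mu_pCR[i] <<- mu_NT[i]
      if ("pIR" %in% groups) mu_pIR[i] <<- shifted else mu_pIR[i] <<- mu_NT[i]
    }
  }
  inject(s1$idx, s1$hyper, "pCR")
  inject(s2$idx, s2$hyper, "pIR")
  inject(s3$idx, s3$hyper, c("pCR", "pIR"))

  mrow <- match(marker_ids, probe_ids)
  mu_NT[mrow] <- cfg$marker_means[, "NT"]
  mu_pCR[mrow] <- cfg$marker_means[, "pCR"]
  mu_pIR[mrow] <- cfg$marker_means[, "pIR"]

  sd_probe <- rep(cfg$background_sd, n_probes)
  sd_probe[mrow] <- cfg$marker_sd

  draw_group <- function(mu, n) {
    matrix(rbeta_moment(n_probes * n, rep(mu, n), rep(sd_probe, n)),
           nrow = n_probes, ncol = n)
  }
  vals <- cbind(draw_group(mu_NT, cfg$n_NT),
                draw_group(mu_pCR, cfg$n_pCR),
                draw_group(mu_pIR, cfg$n_pIR))
  vals <- pmin(pmax(vals, 0.001), 0.999)
  sample_ids <- c(sprintf("NT%02d", seq_len(cfg$n_NT)),
                  sprintf("pCR%02d", seq_len(cfg$n_pCR)),
                  sprintf("pIR%02d", seq_len(cfg$n_pIR)))
  dimnames(vals) <- list(probe_ids, sample_ids)

  group <- rep(c("NT", "pCR", "pIR"), c(cfg$n_NT, cfg$n_pCR, cfg$n_pIR))
  n_tum <- cfg$n_pCR + cfg$n_pIR
  pres_tum <- sample(c("FFPE", "FF"), n_tum, replace = TRUE,
                     prob = c(cfg$ffpe_frac, 1 - cfg$ffpe_frac))
  samples <- tibble::tibble(
    sample_id = sample_ids,
    group = group,
    preservation = c(rep("FF", cfg$n_NT), pres_tum),
    batch = "b1",
    cohort = "discovery"
  )

  dm_idx <- c(s1$idx, s2$idx, s3$idx, mrow)
  truth <- tibble::tibble(
    probe_id = probe_ids[dm_idx],
    kind = rep(c("dm", "dm", "dm", "marker"),
               c(length(s1$idx), length(s2$idx), length(s3$idx), length(mrow))),
    dm_group = rep(c("pCR", "pIR", "both", "marker"),
                   c(length(s1$idx), length(s2$idx), length(s3$idx), length(mrow))),
    direction = c(ifelse(c(s1$hyper, s2$hyper, s3$hyper), "hyper", "hypo"),
                  rep("hypo_pIR", length(mrow))),
    mean_NT = mu_NT[dm_idx],
    mean_pCR = mu_pCR[dm_idx],
    mean_pIR = mu_pIR[dm_idx],
    island_class = island_class[dm_idx]
  )

  list(beta = beta_matrix(vals, "array"),
       manifest = manifest,
       samples = samples,
       truth = truth)
}

#' Simulate a bisulfite-pyrosequencing replica
#'
#' Re-expresses an array-scale beta matrix on the 0-100 percent scale of
#' bisulfite pyrosequencing: `100 * beta` plus Gaussian measurement noise,
#' plus a fixed offset on marker A for FFPE samples, clamped to \[0, 100\].
#' A configurable fraction of entries is set missing to emulate reactions that
#' fail quality control.
#'
#' @param bm An array-scale [beta_matrix()] (typically restricted to the
#'   marker probes).
#' @param samples Sample sheet tibble with `sample_id` and `preservation`.
#' @param cfg A [sim_config()]; uses `pyro_noise_sd`, `ffpe_offset_markerA`,
#'   `pyro_missing_frac`, `marker_ids` and the seed.
#' @return A pyro-scale [beta_matrix()] with the same dimensions as `bm`.
#' @export
simulate_pyro_replica <- function(bm, samples, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (beta_scale(bm) != "array") {
    stop("pyro replica needs an array-scale input matrix", call. = FALSE)
  }
  set.seed(stage_seed(cfg$seed, "pyro"))
  vals <- unclass(bm) * 100
  vals <- vals + matrix(stats::rnorm(length(vals), 0, cfg$pyro_noise_sd),
                        nrow(vals), ncol(vals))
  a_row <- match(cfg$marker_ids[1], rownames(vals))
  if (!is.na(a_row)) {
    pres <- samples$preservation[match(colnames(vals), samples$sample_id)]
    vals[a_row, which(pres == "FFPE")] <-
      vals[a_row, which(pres == "FFPE")] + cfg$ffpe_offset_markerA
  }
  vals <- pmin(pmax(vals, 0), 100)
  if (cfg$pyro_missing_frac > 0) {
    drop <- which(stats::runif(length(vals)) < cfg$pyro_missing_frac)
    vals[drop] <- NA_real_
  }
  beta_matrix(vals, "pyro")
}

#' Simulate expression linked to marker methylation
#'
#' For each configured gene, generates log-scale expression whose Spearman
#' correlation with its linked marker's beta values targets the configured
#' `rho`: the marker betas are mapped to normal scores and mixed with
#' independent Gaussian noise at the Pearson correlation
#' `2 * sin(pi * rho / 6)` that a bivariate normal needs to realise Spearman
#' `rho`. Remaining genes are uncorrelated noise. Expression is generated for
#' a random subset of `n_expr` tumour samples, emulating partial overlap
#' between methylation and expression cohorts.
#'
#' @param bm Array-scale [beta_matrix()] containing the marker probes.
#' @param samples Sample sheet tibble.
#' @param cfg A [sim_config()].
#' @return A list with `expr` (genes-by-samples numeric matrix, log scale)
#'   and `links` (the realised link table).
#' @export
simulate_expression <- function(bm, samples, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  links <- tibble::as_tibble(cfg$expr_links)
  missing_markers <- setdiff(links$marker, rownames(bm))
  if (length(missing_markers) > 0) {
    stop("marker probe(s) absent from beta matrix: ",
         paste(missing_markers, collapse = ", "), call. = FALSE)
  }
  set.seed(stage_seed(cfg$seed, "expr"))
  tumour <- samples$sample_id[samples$group %in% c("pCR", "pIR")]
  n_expr <- min(cfg$n_expr, length(tumour))
  expr_samples <- sort(sample(tumour, n_expr))

  genes <- unique(c(links$gene, sprintf("GENE%03d", seq_len(cfg$n_genes))))
  genes <- genes[seq_len(max(cfg$n_genes, nrow(links)))]
  expr <- matrix(stats::rnorm(length(genes) * n_expr, 8, 1),
                 nrow = length(genes), ncol = n_expr,
                 dimnames = list(genes, expr_samples))
  for (k in seq_len(nrow(links))) {
    beta <- unclass(bm)[links$marker[k], expr_samples]
    z <- stats::qnorm((rank(beta) - 0.5) / length(beta))
    rho_p <- 2 * sin(pi * links$rho[k] / 6)
    y <- rho_p * z + sqrt(max(0, 1 - rho_p^2)) * stats::rnorm(length(z))
    expr[links$gene[k], ] <- 8 + y
  }
  list(expr = expr, links = links)
}
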