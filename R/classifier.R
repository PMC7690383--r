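#' Rank-based AUC of one marker
#'
#' Mann-Whitney AUC: the probability that a random sample from the positive
#' class carries a higher value than a random sample from the negative class,
#' ties counted one half (`AUC = U / (n1 * n2)`).
#'
#' @param values Numeric vector of marker levels (missing values dropped in
#'   pairs with their labels).
#' @param labels Logical or two-level vector; `positive` names the class whose
#'   higher values push AUC above 0.5.
#' @param positive Positive class label.
#' @param directed If `FALSE`, returns `max(AUC, 1 - AUC)` — the
#'   orientation-free ranking version used for feature screening.
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' probe_auc(c(0.1, 0.2, 0.15, 0.3), c("a", "a", "b", "b"), positive = "b")
probe_auc <- function(values, labels, positive, directed = TRUE) {
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]
  labels <- labels[keep]
  pos <- values[labels == positive]
  neg <- values[labels != positive]
  if (length(pos) == 0 || length(neg) == 0) {
    stop("both classes must be non-empty for AUC", call. = FALSE)
  }
  r <- rank(c(pos, neg))
  u <- sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2
  auc <- u / (length(pos) * length(neg))
  if (directed) auc else max(auc, 1 - auc)
}

#' AUC-ranked feature selection with stepwise redundancy elimination
#'
#' Two-stage marker screening: (1) rank candidate probes by orientation-free
#' AUC for separating the two classes and keep the `top_k` best; (2) remove
#' redundant probes by forward-backward stepwise linear regression of a 0/1
#' class indicator on the kept probes, with F-test entry at `p <= p_enter`
#' and removal at `p >= p_remove`.
#'
#' @param bm A [beta_matrix()].
#' @param samples Sample sheet tibble.
#' @param candidates Character vector of candidate probe ids (e.g. the
#'   exclusive DM probes between the two classes).
#' @param classes Length-2 character: (positive, negative) group labels.
#' @param top_k Probes kept after the AUC ranking.
#' @param p_enter,p_remove Stepwise entry/removal p-value thresholds.
#' @return Tibble of retained markers in entry order with their screening
#'   AUCs; zero rows (with a warning) when nothing passes entry.
#' @export
select_features <- function(bm, samples, candidates, classes = c("pCR", "pIR"),
                            top_k = 10, p_enter = 0.05, p_remove = 0.10) {
  ids <- samples$sample_id[samples$group %in% classes]
  ids <- intersect(colnames(bm), ids)
  lab <- samples$group[match(ids, samples$sample_id)]
  candidates <- intersect(candidates, rownames(bm))
  x <- unclass(bm)[candidates, ids, drop = FALSE]

  aucs <- apply(x, 1, probe_auc, labels = lab, positive = classes[1],
                directed = FALSE)
  ranked <- candidates[order(-aucs, candidates)]
  kept <- utils::head(ranked, top_k)

  y <- as.numeric(lab == classes[1])
  df <- as.data.frame(t(x[kept, , drop = FALSE]))
  retained <- stepwise_lm(y, df, p_enter = p_enter, p_remove = p_remove)
  if (length(retained) == 0) {
    warning("no probe passed the stepwise entry threshold; empty marker list",
            call. = FALSE)
  }
  tibble::tibble(probe_id = retained,
                 auc = aucs[match(retained, candidates)])
}

# Forward-backward stepwise OLS on named columns of `df` against numeric y.
# Entry: smallest-p candidate with p <= p_enter; after each entry, backward
# removals of any term with p >= p_remove (partial F == t test for one term).
stepwise_lm <- function(y, df, p_enter = 0.05, p_remove = 0.10) {
  current <- character(0)
  pool <- names(df)
  fit_p <- function(vars) {
    # per-term partial F p-values from drop-one comparisons
    fit <- stats::lm(stats::reformulate(sprintf("`%s`", vars), "y"),
                     data = cbind(y = y, df))
    dr <- stats::drop1(fit, test = "F")
    stats::setNames(dr[["Pr(>F)"]][-1], vars)
  }
  add_p <- function(var) {
    vars <- c(current, var)
    p <- fit_p(vars)
    p[[var]]
  }
  repeat {
    cand <- setdiff(pool, current)
    if (length(cand) == 0) break
    pa <- vapply(cand, add_p, numeric(1))
    pa[is.na(pa)] <- 1  # perfectly collinear additions explain nothing
    best <- which.min(pa)
    if (pa[best] > p_enter) break
    current <- c(current, cand[best])
    # backward pass
    repeat {
      if (length(current) == 0) break
      pd <- fit_p(current)
      pd[is.na(pd)] <- 1
      worst <- which.max(pd)
      if (pd[worst] < p_remove) break
      current <- current[-worst]
    }
  }
  current
}

#' Train a diagonal linear discriminant (DLDA) classifier
#'
#' Gaussian classifier with a shared diagonal covariance and equal priors,
#' which reduces to the linear score `S(x) = sum_j w_j x_j` with
#' `w_j = (mu_pos,j - mu_neg,j) / s2_pool,j` and decision threshold
#' `tau = sum_j w_j (mu_pos,j + mu_neg,j) / 2`. The orientation flag records
#' which side of `tau` is called positive, fixed at training time from the
#' class means (with these weights the positive class always scores high, so
#' training yields `"pos_high"`; the flag exists because imported published
#' models may state either convention).
#'
#' @param bm A [beta_matrix()] restricted (or restrictable) to the markers.
#' @param samples Sample sheet tibble.
#' @param markers Ordered marker probe ids.
#' @param classes Length-2 character: (positive, negative) group labels; the
#'   positive class is the one sensitivity refers to (pCR in this pipeline).
#' @param priors `"equal"` (default; midpoint threshold) or `"proportional"`
#'   (adds `log(n_pos / n_neg)` to the threshold side, shifting `tau`).
#' @return An object of class `dlda_model`: list with `probe_ids`, `weights`,
#'   `threshold`, `scale`, `orientation` (`"pos_high"`/`"pos_low"`),
#'   `classes`.
#' @export
dlda_train <- function(bm, samples, markers, classes = c("pCR", "pIR"),
                       priors = c("equal", "proportional")) {
  priors <- match.arg(priors)
  missing_m <- setdiff(markers, rownames(bm))
  if (length(missing_m) > 0) {
    stop("marker(s) absent from beta matrix: ",
         paste(missing_m, collapse = ", "), call. = FALSE)
  }
  pos_ids <- intersect(colnames(bm), samples$sample_id[samples$group == classes[1]])
  neg_ids <- intersect(colnames(bm), samples$sample_id[samples$group == classes[2]])
  if (length(pos_ids) < 2 || length(neg_ids) < 2) {
    stop("each class needs at least two samples", call. = FALSE)
  }
  xp <- unclass(bm)[markers, pos_ids, drop = FALSE]
  xn <- unclass(bm)[markers, neg_ids, drop = FALSE]
  mu_p <- rowMeans(xp, na.rm = TRUE)
  mu_n <- rowMeans(xn, na.rm = TRUE)
  n_p <- rowSums(!is.na(xp))
  n_n <- rowSums(!is.na(xn))
  vp <- apply(xp, 1, stats::var, na.rm = TRUE)
  vn <- apply(xn, 1, stats::var, na.rm = TRUE)
  s2 <- ((n_p - 1) * vp + (n_n - 1) * vn) / (n_p + n_n - 2)
  if (any(!is.finite(s2) | s2 <= 0)) {
    bad <- markers[which(!is.finite(s2) | s2 <= 0)[1]]
    stop("zero pooled variance for marker '", bad, "'", call. = FALSE)
  }
  w <- (mu_p - mu_n) / s2
  tau <- sum(w * (mu_p + mu_n) / 2)
  if (priors == "proportional") {
    tau <- tau - log(length(pos_ids) / length(neg_ids))
  }
  if (all(w == 0)) {
    warning("equal class means: degenerate model with all-zero weights",
            call. = FALSE)
  }
  structure(list(probe_ids = markers, weights = unname(w), threshold = tau,
                 scale = beta_scale(bm), orientation = "pos_high",
                 classes = classes),
            class = "dlda_model")
}

#' @export
print.dlda_model <- function(x, ...) {
  cat("<dlda_model>", x$classes[1], "vs", x$classes[2],
      sprintf("(scale %s, %s)\n", x$scale, x$orientation))
  cat("  Score =", paste(sprintf("%s x %.4g", x$probe_ids, x$weights),
                         collapse = " + "), "\n")
  cat(sprintf("  threshold = %.4g\n", x$threshold))
  invisible(x)
}

#' Score samples with a DLDA model
#'
#' Computes the linear score `S(x) = sum_j w_j x_j` per sample and the
#' predicted label. A sample missing any marker gets a no-call (`NA`
#' prediction) rather than an imputed score. Ties at exactly `tau` go to the
#' positive side under `"pos_high"` (score `>= tau`) and under `"pos_low"`
#' (score `<= tau`).
#'
#' @param model A `dlda_model`.
#' @param bm A [beta_matrix()] on the model's scale containing the markers, or
#'   a plain markers-by-samples numeric matrix (taken to be on the model's
#'   scale without range validation — useful for scoring arbitrary points).
#' @return Tibble with `sample_id`, `score`, `predicted`.
#' @export
dlda_score <- function(model, bm) {
  if (inherits(bm, "beta_matrix") && beta_scale(bm) != model$scale) {
    stop(sprintf("input is on scale '%s' but the model expects '%s'",
                 beta_scale(bm), model$scale), call. = FALSE)
  }
  missing_m <- setdiff(model$probe_ids, rownames(bm))
  if (length(missing_m) > 0) {
    stop("marker(s) absent from beta matrix: ",
         paste(missing_m, collapse = ", "), call. = FALSE)
  }
  x <- unclass(bm)[model$probe_ids, , drop = FALSE]
  score <- colSums(x * model$weights)
  pos_side <- if (model$orientation == "pos_high") score >= model$threshold
              else score <= model$threshold
  predicted <- ifelse(pos_side, model$classes[1], model$classes[2])
  predicted[is.na(score)] <- NA_character_
  tibble::tibble(sample_id = colnames(bm), score = unname(score),
                 predicted = unname(predicted))
}

#' Evaluate predictions against true labels
#'
#' Confusion counts and derived metrics for a two-class problem. No-call
#' samples (missing predictions) are excluded from the confusion table and
#' counted separately. Sensitivity refers to the positive class
#' (`classes[1]`), specificity to the negative. AUC is the rank-based AUC of
#' the scores for the positive class, orientation-corrected for `"pos_low"`
#' models.
#'
#' @param predicted,truth Character vectors of class labels.
#' @param scores Numeric score per sample (for AUC; optional).
#' @param classes Length-2 character: (positive, negative).
#' @param orientation `"pos_high"` if larger scores indicate the positive
#'   class.
#' @return An object of class `eval_result`: list with `confusion` (tp, fp,
#'   tn, fn, no_call), `sensitivity`, `specificity`, `accuracy`, `auc`
#'   (proportions in \[0,1\]; `NA` when undefined).
#' @export
evaluate_predictions <- function(predicted, truth, scores = NULL,
                                 classes = c("pCR", "pIR"),
                                 orientation = "pos_high") {
  stopifnot(length(predicted) == length(truth))
  no_call <- is.na(predicted)
  pr <- predicted[!no_call]
  tr <- truth[!no_call]
  sc <- if (!is.null(scores)) scores[!no_call] else NULL
  tp <- sum(pr == classes[1] & tr == classes[1])
  fn <- sum(pr == classes[2] & tr == classes[1])
  tn <- sum(pr == classes[2] & tr == classes[2])
  fp <- sum(pr == classes[1] & tr == classes[2])
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- if (length(pr) > 0) (tp + tn) / length(pr) else NA_real_
  auc <- NA_real_
  if (!is.null(sc) && tp + fn > 0 && tn + fp > 0) {
    auc <- probe_auc(sc, tr, positive = classes[1])
    if (orientation == "pos_low") auc <- 1 - auc
  }
  structure(list(
    confusion = c(tp = tp, fp = fp, tn = tn, fn = fn, no_call = sum(no_call)),
    sensitivity = sens, specificity = spec, accuracy = acc, auc = auc,
    classes = classes, n = length(predicted)
  ), class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> n = %d (%d no-call)\n", x$n, x$confusion["no_call"]))
  cat(sprintf("  sensitivity %.1f%%  specificity %.1f%%  accuracy %.1f%%  AUC %.3f\n",
              100 * x$sensitivity, 100 * x$specificity, 100 * x$accuracy, x$auc))
  invisible(x)
}

#' Leave-one-out cross-validation of the DLDA classifier
#'
#' Holds out each sample in turn, retrains on the rest and predicts the
#' held-out sample. `mode = "classifier_only"` refits the DLDA weights on a
#' fixed marker panel per fold; `mode = "nested"` also reruns the whole
#' feature selection ([select_features()]) inside every fold, so the held-out
#' sample never influences marker choice. Folds that would leave a class with
#' fewer than two training samples are skipped with a warning.
#'
#' @param bm A [beta_matrix()].
#' @param samples Sample sheet tibble; only rows whose group is in `classes`
#'   are used.
#' @param markers Marker panel (`classifier_only`) or candidate pool
#'   (`nested`).
#' @param classes Length-2 character: (positive, negative).
#' @param mode `"classifier_only"` or `"nested"`.
#' @param top_k Passed to [select_features()] in nested mode.
#' @return An `eval_result` with the per-sample fold table attached as
#'   attribute `folds` (tibble: sample_id, truth, score, predicted).
#' @export
dlda_loocv <- function(bm, samples, markers, classes = c("pCR", "pIR"),
                       mode = c("classifier_only", "nested"), top_k = 10) {
  mode <- match.arg(mode)
  sheet <- samples[samples$group %in% classes, , drop = FALSE]
  ids <- intersect(colnames(bm), sheet$sample_id)
  truth <- sheet$group[match(ids, sheet$sample_id)]
  if (length(ids) < 3 || min(table(truth)) < 2) {
    stop("LOOCV needs n >= 3 with at least two samples per class", call. = FALSE)
  }
  folds <- purrr::map(seq_along(ids), function(i) {
    train_ids <- ids[-i]
    train_truth <- truth[-i]
    if (min(table(factor(train_truth, levels = classes))) < 2) {
      warning("fold ", ids[i], " skipped: a class would have < 2 training samples",
              call. = FALSE)
      return(tibble::tibble(sample_id = ids[i], truth = truth[i],
                            score = NA_real_, predicted = NA_character_))
    }
    train_bm <- bm[, train_ids]
    train_sheet <- sheet[sheet$sample_id %in% train_ids, , drop = FALSE]
    panel <- if (mode == "nested") {
      sf <- suppressWarnings(
        select_features(train_bm, train_sheet, markers, classes, top_k = top_k))
      sf$probe_id
    } else markers
    if (length(panel) == 0) {
      return(tibble::tibble(sample_id = ids[i], truth = truth[i],
                            score = NA_real_, predicted = NA_character_))
    }
    model <- dlda_train(train_bm, train_sheet, panel, classes)
    pred <- dlda_score(model, bm[, ids[i], drop = FALSE])
    tibble::tibble(sample_id = ids[i], truth = truth[i],
                   score = pred$score, predicted = pred$predicted)
  })
  fold_tbl <- dplyr::bind_rows(folds)
  res <- evaluate_predictions(fold_tbl$predicted, fold_tbl$truth,
                              fold_tbl$score, classes)
  attr(res, "folds") <- fold_tbl
  res
}

#' Recalibrate a model threshold on a new measurement scale
#'
#' Keeps the linear weights and moves only the decision threshold, as needed
#' when a classifier trained on array beta values is applied to percent-scale
#' pyrosequencing data. Candidate thresholds are the midpoints between
#' adjacent distinct sorted scores (plus one candidate below the minimum and
#' one above the maximum); the candidate maximizing overall accuracy wins,
#' ties broken towards higher sensitivity, then towards the lower threshold.
#' Samples missing any marker are dropped (no-call) before the scan.
#'
#' @param model A `dlda_model`.
#' @param bm A [beta_matrix()] on the new scale.
#' @param samples Sample sheet tibble with true groups.
#' @param classes Length-2 character: (positive, negative); defaults to the
#'   model's.
#' @return The model with updated `threshold` and `scale`; the scanned
#'   candidate table is attached as attribute `scan`.
#' @export
recalibrate_threshold <- function(model, bm, samples, classes = model$classes) {
  scored_model <- model
  scored_model$scale <- beta_scale(bm)  # scoring is scale-agnostic arithmetic
  scored <- dlda_score(scored_model, bm)
  keep <- !is.na(scored$score)
  truth <- samples$group[match(scored$sample_id, samples$sample_id)]
  keep <- keep & truth %in% classes
  s <- scored$score[keep]
  tr <- truth[keep]
  if (length(unique(s)) < 2) {
    stop("cannot recalibrate: all usable scores are identical", call. = FALSE)
  }
  u <- sort(unique(s))
  cand <- c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  metrics <- purrr::map_dfr(cand, function(tau) {
    pos_side <- if (model$orientation == "pos_high") s >= tau else s <= tau
    pred <- ifelse(pos_side, classes[1], classes[2])
    tp <- sum(pred == classes[1] & tr == classes[1])
    tn <- sum(pred == classes[2] & tr == classes[2])
    tibble::tibble(tau = tau,
                   accuracy = (tp + tn) / length(s),
                   sensitivity = tp / sum(tr == classes[1]))
  })
  best <- metrics |>
    dplyr::arrange(dplyr::desc(.data$accuracy), dplyr::desc(.data$sensitivity),
                   .data$tau) |>
    dplyr::slice(1)
  out <- model
  out$threshold <- best$tau
  out$scale <- beta_scale(bm)
  attr(out, "scan") <- metrics
  out
}

#' Read and write DLDA models as plain text
#'
#' Models serialize to a small JSON file holding the marker ids, weights,
#' threshold, scale, orientation and class labels, so a published score of
#' the form `S = w_A x_A + w_B x_B + w_C x_C` with a stated cutoff can be
#' shipped and imported with either orientation convention.
#'
#' @param model A `dlda_model`.
#' @param path File path.
#' @return `read_dlda_model()` returns a `dlda_model`.
#' @export
write_dlda_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_dlda_model
#' @export
read_dlda_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("probe_ids", "weights", "threshold", "scale", "orientation", "classes")
  miss <- setdiff(need, names(m))
  if (length(miss) > 0) stop("model file missing field(s): ",
                             paste(miss, collapse = ", "), call. = FALSE)
  if (length(m$probe_ids) != length(m$weights) || length(m$probe_ids) < 1) {
    stop("model must have one weight per marker and at least one marker",
         call. = FALSE)
  }
  if (!m$orientation %in% c("pos_high", "pos_low")) {
    stop("orientation must be 'pos_high' or 'pos_low'", call. = FALSE)
  }
  structure(m[need], class = "dlda_model")
}

#' Candidate probe pool for classifier construction
#'
#' Builds the marker candidate pool from three contrasts: probes DM versus
#' the reference group exclusively in one of the two response classes
#' (FDR-based call), intersected with probes that also differ between the
#' response classes at raw `p < p_max` with `|delta_beta| > db_min` (no FDR
#' on the between-class contrast, which only screens candidates).
#'
#' @param bm A [beta_matrix()].
#' @param samples Sample sheet tibble.
#' @param classes Length-2 character: response classes (positive, negative).
#' @param ref Reference group label.
#' @param q_max,db_min DM-call thresholds for the versus-reference contrasts.
#' @param p_max Raw-p threshold for the between-class screen.
#' @return Character vector of candidate probe ids; the Venn compartment
#'   counts of the two versus-reference DM sets are attached as attribute
#'   `venn_counts`.
#' @export
candidate_probes <- function(bm, samples, classes = c("pCR", "pIR"),
                             ref = "NT", q_max = 0.05, db_min = 0.15,
                             p_max = 0.05) {
  dm_pos <- dm_test(bm, samples, c(classes[1], ref), q_max = q_max, db_min = db_min)
  dm_neg <- dm_test(bm, samples, c(classes[2], ref), q_max = q_max, db_min = db_min)
  vp <- venn_partition(call_dm(dm_pos, q_max, db_min)$probe_id,
                       call_dm(dm_neg, q_max, db_min)$probe_id)
  exclusive <- vp$probe_id[vp$compartment != "shared"]
  dm_between <- dm_test(bm, samples, classes, q_max = q_max, db_min = db_min)
  between <- dm_between$probe_id[!is.na(dm_between$p) &
                                   dm_between$p < p_max &
                                   abs(dm_between$delta_beta) > db_min]
  out <- intersect(exclusive, between)
  attr(out, "venn_counts") <- attr(vp, "counts")
  out
}
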