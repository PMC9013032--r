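#' Train/test split specification
#'
#' @param seed integer seed controlling the random partition.
#' @param train_fraction fraction of encounters assigned to training
#'   (default 3:1, i.e. 0.75).
#' @param stratified if `TRUE`, split within the binarized discharge-SOI
#'   strata so both classes keep the exact ratio.
#' @return A `split_spec` list.
#' @export
split_spec <- function(seed, train_fraction = 0.75, stratified = FALSE) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  structure(list(seed = as.integer(seed), train_fraction = train_fraction,
                 stratified = isTRUE(stratified)),
            class = "split_spec")
}

#' Randomly split encounters into training and testing sets
#'
#' Partitions the encounter set exhaustively and disjointly at the
#' configured ratio (sizes differ from the exact target by at most one
#' per stratum due to rounding). Reproducible: the same seed always gives
#' the same partition.
#'
#' @param encset an [encounter_set()].
#' @param spec a [split_spec()].
#' @return List with elements `train` and `test`, both `encounter_set`s.
#' @export
split_train_test <- function(encset, spec) {
  n <- nrow(encset$encounters)
  if (n < 4) stop_fatal("need at least 4 encounters to split 3:1")
  ids <- encset$encounters$encounter_id
  train_ids <- with_seed(spec$seed, {
    if (spec$stratified) {
      cls <- binarize_outcome(encset$encounters$discharge_soi)
      unlist(lapply(split(ids, cls), function(g) {
        sample(g, round(spec$train_fraction * length(g)))
      }), use.names = FALSE)
    } else {
      sample(ids, round(spec$train_fraction * n))
    }
  })
  list(train = subset_encounters(encset, train_ids),
       test = subset_encounters(encset, setdiff(ids, train_ids)))
}

# Shared threshold sweep: scores sorted descending, tied scores grouped
# at a single threshold; returns cumulative TP/FP at each distinct score.
threshold_sweep <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  last <- cumsum(rle(s)$lengths)       # index of each tie-group's end
  tp <- cumsum(y)[last]
  fp <- last - tp
  list(threshold = s[last], tp = tp, fp = fp,
       P = sum(labels), N = sum(1 - labels))
}

#' ROC curve and area under it
#'
#' Sweeps every distinct score as a classification threshold (predicted
#' high iff score >= threshold, ties grouped), anchoring the curve at
#' (0,0), and integrates by the trapezoidal rule -- which makes the area
#' identical to the Mann-Whitney concordance probability.
#'
#' @param scores numeric scores (higher = more severe).
#' @param labels binary labels (1 = high severity).
#' @return List of class `roc_curve` with `points` (data.frame
#'   `threshold`, `fpr`, `tpr`; the (0,0) anchor carries threshold `Inf`)
#'   and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (sum(labels) == 0 || sum(labels) == length(labels)) {
    stop_fatal("ROC needs both classes present")
  }
  sw <- threshold_sweep(scores, labels)
  pts <- data.frame(threshold = c(Inf, sw$threshold),
                    fpr = c(0, sw$fp / sw$N),
                    tpr = c(0, sw$tp / sw$P))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc), class = "roc_curve")
}

#' Precision-recall curve and average precision
#'
#' Precision and recall at every distinct score threshold (ties grouped).
#' The area is the average-precision step sum
#' `sum((recall_i - recall_{i-1}) * precision_i)`, not a trapezoid --
#' linear interpolation between PR points is known to overstate the area.
#'
#' @inheritParams roc_curve
#' @return List of class `pr_curve` with `points` (data.frame `threshold`,
#'   `recall`, `precision`) and `auc`.
#' @export
pr_curve <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (sum(labels) == 0) stop_fatal("PR analysis needs at least one positive")
  sw <- threshold_sweep(scores, labels)
  recall <- sw$tp / sw$P
  precision <- sw$tp / (sw$tp + sw$fp)
  auc <- sum((recall - c(0, utils::head(recall, -1))) * precision)
  structure(list(points = data.frame(threshold = sw$threshold,
                                     recall = recall,
                                     precision = precision),
                 auc = auc),
            class = "pr_curve")
}

#' Optimal classification cutoff from ROC geometry
#'
#' Returns the score threshold whose ROC point minimizes the Euclidean
#' distance to the upper-left corner (0, 1), i.e. sqrt(FPR^2 +
#' (1-TPR)^2). Only realizable cutoffs (distinct score values) are
#' candidates; ties break toward the larger threshold, the more
#' conservative high-severity call.
#'
#' @param roc a [roc_curve()] result.
#' @return The optimal threshold (a score value).
#' @export
optimal_cutoff <- function(roc) {
  pts <- roc$points[is.finite(roc$points$threshold), , drop = FALSE]
  if (!nrow(pts)) stop_fatal("ROC curve has no realizable cutoffs")
  d2 <- pts$fpr^2 + (1 - pts$tpr)^2
  # thresholds are stored in decreasing order; which.min takes the first
  # (largest threshold) among ties
  pts$threshold[which.min(d2)]
}

#' Classification metrics at a fixed cutoff
#'
#' Predicts high severity iff score >= cutoff and reports accuracy, the
#' false-positive rate FP/(FP+TN) and the false-negative rate
#' FN/(FN+TP).
#'
#' @inheritParams roc_curve
#' @param cutoff finite classification threshold.
#' @return List with `accuracy`, `fpr`, `fnr` and the 2x2 confusion
#'   counts.
#' @export
classification_metrics <- function(scores, labels, cutoff) {
  stopifnot(is.finite(cutoff))
  labels <- as.numeric(labels)
  pred <- as.numeric(scores >= cutoff)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  list(accuracy = (tp + tn) / length(labels),
       fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
       fnr = if (fn + tp > 0) fn / (fn + tp) else NA_real_,
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Compare training and testing cohorts descriptively
#'
#' A Table-1-style report: mean age with a Welch two-sample test, and
#' counts with proportions for sex, race and the admission/discharge SOI
#' levels with chi-square tests of homogeneity. Variables whose values
#' are entirely missing are skipped with a warning.
#'
#' @param train,test `encounter_set`s from [split_train_test()].
#' @return data.frame with columns `variable`, `level`, `train`, `test`,
#'   `train_prop`, `test_prop`, `p_value` (the p-value repeats on each of
#'   a variable's rows).
#' @export
descriptive_comparison <- function(train, test) {
  a <- train$encounters
  b <- test$encounters
  if (!nrow(a) || !nrow(b)) stop_fatal("both sets must be non-empty")
  rows <- list()
  if (all(is.na(a$age)) || all(is.na(b$age))) {
    warning("age unavailable; skipped", call. = FALSE)
  } else {
    p <- stats::t.test(a$age, b$age)$p.value
    rows[[length(rows) + 1]] <- data.frame(
      variable = "age", level = "mean",
      train = mean(a$age, na.rm = TRUE), test = mean(b$age, na.rm = TRUE),
      train_prop = NA_real_, test_prop = NA_real_, p_value = p)
  }
  for (v in c("sex", "race", "admit_soi", "discharge_soi")) {
    va <- a[[v]]
    vb <- b[[v]]
    if (all(is.na(va)) || all(is.na(vb))) {
      warning(v, " unavailable; skipped", call. = FALSE)
      next
    }
    lev <- sort(unique(c(va, vb)))
    ca <- table(factor(va, levels = lev))
    cb <- table(factor(vb, levels = lev))
    p <- tryCatch(
      suppressWarnings(stats::chisq.test(rbind(ca, cb))$p.value),
      error = function(e) NA_real_)
    rows[[length(rows) + 1]] <- data.frame(
      variable = v, level = as.character(lev),
      train = as.numeric(ca), test = as.numeric(cb),
      train_prop = as.numeric(ca) / sum(ca),
      test_prop = as.numeric(cb) / sum(cb),
      p_value = p)
  }
  do.call(rbind, rows)
}

#' Fit and evaluate one model variant end to end
#'
#' Fits the variant on the training set, derives the optimal cutoff from
#' the TRAINING ROC curve only, then measures accuracy and error rates on
#' the held-out test set at that fixed cutoff. The report carries the
#' training-set ROC/PR curves and AUCs together with the test-set
#' classification metrics.
#'
#' @param train,test `encounter_set`s.
#' @param maps a [reference_maps] object.
#' @param variant model variant (see [design_info()]).
#' @param phase `"discharge"` (all diagnoses, outcome = discharge SOI) or
#'   `"admission"` (POA/exempt diagnoses, outcome = admission SOI).
#' @param ridge,maxit,tol passed to [fit_severity_model()].
#' @return An object of class `eval_report`.
#' @export
evaluate_variant <- function(train, test, maps,
                             variant = c("full", "comorbidity",
                                         "body_system"),
                             phase = c("discharge", "admission"),
                             ridge = 0, maxit = 100L, tol = 1e-8) {
  variant <- match.arg(variant)
  phase <- match.arg(phase)
  soi_col <- if (phase == "admission") "admit_soi" else "discharge_soi"
  ftr_tr <- build_features(train, maps, phase)
  y_tr <- binarize_outcome(train$encounters[[soi_col]])
  fit <- fit_severity_model(encode_design(ftr_tr, variant), y_tr,
                            variant = variant, phase = phase,
                            ridge = ridge, maxit = maxit, tol = tol,
                            version_label = maps$version_label)
  p_tr <- predict_probability(fit, ftr_tr)
  roc <- roc_curve(p_tr, y_tr)
  pr <- pr_curve(p_tr, y_tr)
  cutoff <- optimal_cutoff(roc)
  train_metrics <- classification_metrics(p_tr, y_tr, cutoff)
  ftr_te <- build_features(test, maps, phase)
  y_te <- binarize_outcome(test$encounters[[soi_col]])
  p_te <- predict_probability(fit, ftr_te)
  test_metrics <- classification_metrics(p_te, y_te, cutoff)
  structure(
    list(variant = variant, phase = phase,
         n_train = nrow(train$encounters), n_test = nrow(test$encounters),
         n_variables = design_info(variant, maps$registry)$n_variables,
         roc_auc = roc$auc, pr_auc = pr$auc,
         roc_points = roc$points, pr_points = pr$points,
         optimal_cutoff = cutoff,
         train_accuracy = train_metrics$accuracy,
         accuracy = test_metrics$accuracy,
         fpr = test_metrics$fpr, fnr = test_metrics$fnr,
         model = fit, version_label = maps$version_label),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> ", x$variant, " model, ", x$phase, " phase (",
      x$n_variables, " variables)\n",
      "  train (n=", x$n_train, "): ROC AUC ",
      sprintf("%.1f%%", 100 * x$roc_auc), ", PR AUC ",
      sprintf("%.1f%%", 100 * x$pr_auc), ", cutoff ",
      sprintf("%.3f", x$optimal_cutoff), "\n",
      "  test  (n=", x$n_test, "): accuracy ",
      sprintf("%.2f%%", 100 * x$accuracy), ", FPR ",
      sprintf("%.2f%%", 100 * x$fpr), ", FNR ",
      sprintf("%.2f%%", 100 * x$fnr), "\n", sep = "")
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param report an `eval_report`.
#' @param path output path.
#' @param include_points whether to embed the full ROC/PR point lists.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path, include_points = TRUE) {
  doc <- unclass(report)
  doc$model <- unclass(doc$model)
  if (!include_points) {
    doc$roc_points <- NULL
    doc$pr_points <- NULL
  }
  doc$format <- "jscore-eval/1"
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
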