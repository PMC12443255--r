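#' @name evaluation
#' @title Six-metric evaluation protocol
#' @description
#' Confusion-matrix tallies and the six headline metrics used for ACP
#' classifiers — accuracy (ACC), sensitivity (SN), specificity (SP),
#' Matthews correlation coefficient (MCC), F1 and precision — plus ROC
#' construction with trapezoidal AUC and stratified k-fold
#' cross-validation with optional fold-internal resampling.
NULL

#' Confusion counts
#'
#' @param y_true,y_pred equal-length binary (0/1) vectors.
#' @return A `confusion_counts` list with integer `TP`, `FP`, `TN`,
#'   `FN`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  stopifnot(all(y_true %in% c(0L, 1L)), all(y_pred %in% c(0L, 1L)))
  structure(list(
    TP = sum(y_true == 1L & y_pred == 1L),
    FP = sum(y_true == 0L & y_pred == 1L),
    TN = sum(y_true == 0L & y_pred == 0L),
    FN = sum(y_true == 1L & y_pred == 0L)),
    class = "confusion_counts")
}

# ratio with the 0/0 -> 0 convention used throughout the metric suite
safe_ratio <- function(num, den) if (den == 0) 0 else num / den

#' Metric suite from confusion counts
#'
#' Computes ACC, SN (recall), SP, MCC, F1 and precision from the four
#' confusion tallies. Any metric with a zero denominator returns 0,
#' the convention that keeps MCC and F1 defined for degenerate
#' predictors.
#'
#' @param counts a `confusion_counts` (or list with TP/FP/TN/FN).
#' @return Named numeric vector `ACC`, `SN`, `SP`, `MCC`, `F1`,
#'   `Precision`.
#' @export
metric_suite <- function(counts) {
  tp <- as.numeric(counts$TP); fp <- as.numeric(counts$FP)
  tn <- as.numeric(counts$TN); fn <- as.numeric(counts$FN)
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  acc <- safe_ratio(tp + tn, tp + fp + tn + fn)
  sn <- safe_ratio(tp, tp + fn)
  sp <- safe_ratio(tn, tn + fp)
  mcc_den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den
  precision <- safe_ratio(tp, tp + fp)
  f1 <- safe_ratio(2 * precision * sn, precision + sn)
  c(ACC = acc, SN = sn, SP = sp, MCC = mcc, F1 = f1, Precision = precision)
}

#' ROC curve and trapezoidal AUC
#'
#' Builds the ROC over descending unique score thresholds (tied scores
#' grouped into one step) and integrates the area by the trapezoidal
#' rule over adjacent (FPR, TPR) points.
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param y_true binary truth with at least one positive and one
#'   negative.
#' @return List with `curve` (data frame `threshold`, `FPR`, `TPR`,
#'   including the (0,0) anchor) and `auc`.
#' @export
roc_auc <- function(scores, y_true) {
  y_true <- as.integer(y_true)
  stopifnot(length(scores) == length(y_true), all(y_true %in% c(0L, 1L)))
  n_pos <- sum(y_true == 1L); n_neg <- sum(y_true == 0L)
  if (n_pos == 0L || n_neg == 0L) stop("need both classes in y_true")
  thr <- sort(unique(scores), decreasing = TRUE)
  ord <- order(-scores)
  s <- scores[ord]; y <- y_true[ord]
  cum_tp <- cumsum(y == 1L); cum_fp <- cumsum(y == 0L)
  # index of the last sample at or above each threshold
  last <- findInterval(-thr, -s)
  tpr <- c(0, cum_tp[last] / n_pos)
  fpr <- c(0, cum_fp[last] / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(curve = data.frame(threshold = c(Inf, thr), FPR = fpr, TPR = tpr),
       auc = auc)
}

# stratified fold assignment: within each class, shuffle then deal
# round-robin into `folds` groups
stratified_folds <- function(y, folds, seed) {
  assignment <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      if (length(idx) < folds) stop("class ", cls, " has fewer members (",
                                    length(idx), ") than folds (", folds, ")")
      assignment[sample(idx)] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assignment
}

#' Stratified k-fold cross-validation
#'
#' Evaluates the soft-voting ensemble (or any configuration of its
#' members) under stratified, seeded k-fold cross-validation, with
#' three resampling modes. `"safe"` applies ANBS inside each training
#' fold only, so no synthetic sample ever leaks into a test fold.
#' `"paper"` balances the full dataset once and then folds it — the
#' protocol used when a single pre-balanced dataset feeds every model —
#' which is reported for comparability but mixes synthetic points into
#' test folds. `"none"` trains on the folds as they come.
#'
#' @param data a [labeled_matrix]; each class needs at least `folds`
#'   members.
#' @param folds number of folds (default 10).
#' @param resample_mode `"safe"` (default), `"paper"` or `"none"`.
#' @param config an [ensemble_config()] for the per-fold models.
#' @param sampler an [anbs_config()] used when resampling.
#' @param seed master seed; per-fold seeds are derived from it.
#' @return List with `per_fold` (data frame of per-fold ACC, SN, SP,
#'   MCC, F1, Precision, AUC) and `mean` (named vector of means).
#' @export
cross_validate <- function(data, folds = 10L,
                           resample_mode = c("safe", "paper", "none"),
                           config = ensemble_config(),
                           sampler = anbs_config(), seed = 1L) {
  resample_mode <- match.arg(resample_mode)
  stopifnot(inherits(data, "labeled_matrix"))

  if (resample_mode == "paper") {
    sampler$seed <- as.integer(derive_seed(seed, 9999L))
    data <- anbs(data, sampler)
  }
  fold_of <- stratified_folds(data$y, folds, seed)

  per_fold <- lapply(seq_len(folds), function(f) {
    tr <- fold_of != f; te <- fold_of == f
    train <- labeled_matrix(data$X[tr, , drop = FALSE], data$y[tr])
    if (resample_mode == "safe") {
      fold_sampler <- sampler
      fold_sampler$seed <- as.integer(derive_seed(seed, f))
      train <- suppressWarnings(anbs(train, fold_sampler))
    }
    cfg <- config
    cfg$seed <- as.integer(derive_seed(seed, 1000L + f))
    model <- train_ensemble(train, cfg)
    pred <- predict(model, data$X[te, , drop = FALSE])
    m <- metric_suite(confusion(data$y[te], pred$labels))
    auc <- if (length(unique(data$y[te])) == 2L) {
      roc_auc(pred$prob, data$y[te])$auc
    } else NA_real_
    c(fold = f, m, AUC = auc)
  })
  per_fold <- as.data.frame(do.call(rbind, per_fold))
  means <- colMeans(per_fold[, -1, drop = FALSE], na.rm = TRUE)
  list(per_fold = per_fold, mean = means)
}

#' Write a cross-validation report as delimited text
#'
#' @param cv result of [cross_validate()].
#' @param path output path; per-fold rows plus a `mean` summary row.
#' @return `path` invisibly.
#' @export
write_cv_report <- function(cv, path) {
  tab <- cv$per_fold
  tab$fold <- as.character(tab$fold)
  tab[nrow(tab) + 1L, ] <- c("mean", as.list(unname(cv$mean)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
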