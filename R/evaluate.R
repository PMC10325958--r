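#' Regression performance metrics
#'
#' RMSE, MAE and the coefficient of determination
#' `R2 = 1 - SS_res / SS_tot`. With a constant truth vector R2 is
#' undefined and returned as `NA` with a warning.
#'
#' @param y_true,y_pred numeric vectors of equal length (>= 2).
#' @return named numeric: `rmse`, `mae`, `r_squared`.
#' @export
regressionMetrics <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2)
  err <- y_true - y_pred
  rmse <- sqrt(mean(err^2))
  mae <- mean(abs(err))
  if (sd(y_true) == 0) {
    warning("constant y_true: R^2 undefined")
    r2 <- NA_real_
  } else {
    r2 <- 1 - sum(err^2) / sum((y_true - mean(y_true))^2)
  }
  c(rmse = rmse, mae = mae, r_squared = r2)
}

#' Area under the ROC curve (rank formulation)
#'
#' Mann-Whitney form: the probability that a random positive scores above a
#' random negative, with ties counted one half. Computed from midranks, so
#' it is invariant under any strictly monotone transform of the scores.
#'
#' @param y_true 0/1 labels (both classes present).
#' @param scores numeric scores, higher = more positive.
#' @return AUC in `[0, 1]`.
#' @export
rocAuc <- function(y_true, scores) {
  y_true <- as.integer(y_true)
  n1 <- sum(y_true == 1)
  n0 <- sum(y_true == 0)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: only one class present")
  r <- rank(scores)   # midranks handle ties at 1/2
  (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification performance metrics
#'
#' AUC (rank formulation), plus threshold metrics at `threshold` on the
#' positive-class probability: accuracy, sensitivity (true positive rate),
#' specificity (true negative rate), balanced accuracy
#' `(sensitivity + specificity) / 2`, and the 2x2 confusion matrix.
#'
#' @param y_true 0/1 labels (both classes present).
#' @param p_pred positive-class probabilities or scores.
#' @param threshold classification threshold (default 0.5; predicted
#'   positive when `p_pred >= threshold`).
#' @return list with `metrics` (named numeric: `auc`, `balanced_accuracy`,
#'   `accuracy`, `sensitivity`, `specificity`) and `confusion` (2x2 matrix,
#'   predicted x truth).
#' @export
classificationMetrics <- function(y_true, p_pred, threshold = 0.5) {
  stopifnot(length(y_true) == length(p_pred))
  y_true <- as.integer(y_true)
  auc <- rocAuc(y_true, p_pred)
  y_hat <- as.integer(p_pred >= threshold)
  tp <- sum(y_hat == 1 & y_true == 1)
  tn <- sum(y_hat == 0 & y_true == 0)
  fp <- sum(y_hat == 1 & y_true == 0)
  fn <- sum(y_hat == 0 & y_true == 1)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  confusion <- matrix(c(tn, fp, fn, tp), 2, 2,
                      dimnames = list(predicted = c("0", "1"),
                                      truth = c("0", "1")))
  list(metrics = c(auc = auc,
                   balanced_accuracy = (sens + spec) / 2,
                   accuracy = (tp + tn) / length(y_true),
                   sensitivity = sens, specificity = spec),
       confusion = confusion)
}

#' Bootstrap percentile confidence interval for the ROC AUC
#'
#' Resamples the (label, score) pairs with replacement, stratified by class
#' so every replicate contains both classes, recomputes the AUC per
#' replicate, and reports the 2.5/97.5 percentiles of the replicate
#' distribution (default 10,000 replicates).
#'
#' @param y_true 0/1 labels (both classes present).
#' @param p_pred scores.
#' @param nBoot bootstrap replicates (default 10000).
#' @param seed integer.
#' @param level confidence level (default 0.95).
#' @return list: `ci` (numeric(2)), `replicates` (numeric(nBoot)).
#' @export
bootstrapAucCi <- function(y_true, p_pred, nBoot = 10000, seed,
                           level = 0.95) {
  y_true <- as.integer(y_true)
  i1 <- which(y_true == 1)
  i0 <- which(y_true == 0)
  if (!length(i1) || !length(i0)) stop("both classes required")
  set.seed(as.integer(seed) %% .Machine$integer.max)
  reps <- vapply(seq_len(nBoot), function(b) {
    s1 <- sample(i1, length(i1), replace = TRUE)
    s0 <- sample(i0, length(i0), replace = TRUE)
    idx <- c(s1, s0)
    rocAuc(y_true[idx], p_pred[idx])
  }, numeric(1))
  a <- (1 - level) / 2
  list(ci = unname(quantile(reps, c(a, 1 - a))), replicates = reps)
}

#' Per-subgroup classification error table
#'
#' Counts test samples and misclassifications per exposure group; the
#' misclassified column sums to the confusion-matrix off-diagonal total.
#'
#' @param y_true 0/1 labels.
#' @param y_pred_class 0/1 predicted labels.
#' @param group_labels group label per sample.
#' @return data.frame with columns `group`, `n`, `n_misclassified`.
#' @export
subgroupErrorTable <- function(y_true, y_pred_class, group_labels) {
  stopifnot(length(y_true) == length(y_pred_class),
            length(y_true) == length(group_labels))
  err <- as.integer(y_true) != as.integer(y_pred_class)
  groups <- sort(unique(as.character(group_labels)))
  data.frame(
    group = groups,
    n = vapply(groups, function(g) sum(group_labels == g), integer(1)),
    n_misclassified = vapply(groups, function(g)
      sum(err[group_labels == g]), integer(1)),
    row.names = NULL)
}

#' Full evaluation report for a fitted endpoint
#'
#' Convenience wrapper building an [EvalReport-class]: regression metrics,
#' or classification metrics with a bootstrap AUC CI and a per-subgroup
#' error table.
#'
#' @param y_true truth (numeric, or 0/1 for classification).
#' @param y_pred predictions (numeric, or positive-class probabilities).
#' @param task `"regression"` or `"classification"`.
#' @param group_labels optional exposure-group label per sample
#'   (classification subgroup table).
#' @param nBoot bootstrap replicates for the AUC CI.
#' @param seed integer for the bootstrap.
#' @param threshold classification threshold.
#' @return An [EvalReport-class].
#' @export
evaluatePredictions <- function(y_true, y_pred,
                                task = c("regression", "classification"),
                                group_labels = NULL, nBoot = 10000,
                                seed = 1, threshold = 0.5) {
  task <- match.arg(task)
  if (task == "regression") {
    return(methods::new("EvalReport", task = task,
                        metrics = regressionMetrics(y_true, y_pred),
                        aucCi = numeric(0), nBootstrap = 0L,
                        confusion = matrix(integer(0), 0, 0),
                        subgroupErrors = data.frame()))
  }
  cm <- classificationMetrics(y_true, y_pred, threshold)
  ci <- bootstrapAucCi(y_true, y_pred, nBoot = nBoot, seed = seed)
  sub <- if (is.null(group_labels)) data.frame() else
    subgroupErrorTable(y_true, as.integer(y_pred >= threshold),
                       group_labels)
  methods::new("EvalReport", task = task, metrics = cm$metrics,
               aucCi = ci$ci, nBootstrap = as.integer(nBoot),
               confusion = cm$confusion, subgroupErrors = sub)
}
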