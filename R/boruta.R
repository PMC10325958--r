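#' Minimum hit count for shadow-test confirmation
#'
#' For a feature observed over `nIter` iterations, the smallest number of
#' "hits" (iterations in which its importance beat the shadow percentile)
#' for which the two-sided binomial test against success probability 0.5,
#' Bonferroni-corrected over `nFeatures` simultaneous tests, is significant
#' in the upper tail at level `alpha`: the smallest `k` with
#' `2 * P(Bin(nIter, 0.5) >= k) <= alpha / nFeatures`.
#'
#' @param nIter number of iterations.
#' @param nFeatures number of features tested simultaneously.
#' @param alpha family-wise significance level (default 0.05).
#' @return integer hit count, or `NA` if no count in `0..nIter` is
#'   significant.
#' @export
minHitsToConfirm <- function(nIter, nFeatures, alpha = 0.05) {
  k <- 0:nIter
  p_upper <- 1 - pbinom(k - 1, nIter, 0.5)
  ok <- which(2 * p_upper <= alpha / nFeatures)
  if (!length(ok)) return(NA_integer_)
  k[ok[1]]
}

.binomTwoSided <- function(k, n) {
  min(1, 2 * min(pbinom(k, n, 0.5), 1 - pbinom(k - 1, n, 0.5)))
}

#' Shadow-feature (Boruta-style) all-relevant selection
#'
#' Iteratively tests every predictor against randomised copies of itself.
#' Each iteration (i) permutes each live feature's column to create a fresh
#' "shadow" feature, (ii) fits a random forest on the real and shadow
#' features together, (iii) scores a feature a "hit" when its impurity
#' importance exceeds the 50th percentile of that iteration's shadow
#' importances, and (iv) applies a two-sided binomial test of the hit count
#' against chance (p = 0.5), Bonferroni-corrected over the features still
#' undecided, at level `alpha`: significant in the upper tail confirms a
#' feature, in the lower tail rejects it. Rejected features leave the model
#' immediately; confirmed features stay in the forest as competition.
#' Features undecided after `maxIter` iterations are `tentative` (and are
#' treated as not retained downstream).
#'
#' @param x samples x features numeric matrix (at least 2 features).
#' @param y target: numeric for `task = "regression"`, binary/factor for
#'   `task = "classification"`; must not be constant.
#' @param task `"regression"` or `"classification"`.
#' @param maxIter maximum iterations (default 100).
#' @param seed integer; the whole procedure is reproducible.
#' @param numTrees random-forest size per iteration (default 500).
#' @param thresholdPercentile shadow-importance percentile a feature must
#'   beat (default 50; 100 gives the classic shadow-max variant, which is
#'   markedly more conservative for weak features).
#' @param alpha significance level before Bonferroni correction
#'   (default 0.05).
#' @param importance forest importance measure, `"impurity"` (default) or
#'   `"permutation"`.
#' @return A [BorutaResult-class].
#' @export
borutaSelect <- function(x, y, task = c("regression", "classification"),
                         maxIter = 100, seed, numTrees = 500,
                         thresholdPercentile = 50, alpha = 0.05,
                         importance = c("impurity", "permutation")) {
  task <- match.arg(task)
  importance <- match.arg(importance)
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need at least 2 features")
  if (length(unique(y)) < 2) stop("target is constant")
  if (task == "regression") {
    if (is.factor(y) || is.character(y))
      stop("task/target mismatch: regression needs a numeric target")
    y <- as.numeric(y)
  } else {
    if (is.numeric(y) && length(unique(y)) > 10)
      stop("task/target mismatch: classification target has too many levels")
    y <- factor(y)
  }
  feats <- colnames(x)
  if (is.null(feats)) feats <- colnames(x) <- paste0("V", seq_len(ncol(x)))

  set.seed(as.integer(seed) %% .Machine$integer.max)
  undecided <- feats
  decisions <- setNames(rep("tentative", length(feats)), feats)
  hits <- setNames(rep(0L, length(feats)), feats)
  iters_live <- setNames(rep(0L, length(feats)), feats)
  hist_cols <- c(feats, paste0("shadow_", feats))
  history <- matrix(NA_real_, nrow = 0, ncol = length(hist_cols),
                    dimnames = list(NULL, hist_cols))
  it <- 0L
  while (length(undecided) && it < maxIter) {
    it <- it + 1L
    live <- feats[decisions[feats] != "rejected"]
    shadows <- apply(x[, live, drop = FALSE], 2, sample)
    colnames(shadows) <- paste0("shadow_", live)
    xx <- cbind(x[, live, drop = FALSE], shadows)
    fit <- ranger::ranger(x = as.data.frame(xx), y = y,
                          num.trees = numTrees, importance = importance,
                          seed = sample.int(.Machine$integer.max, 1),
                          num.threads = 1)
    imp <- fit$variable.importance
    thr <- quantile(imp[colnames(shadows)], thresholdPercentile / 100,
                    names = FALSE)
    row <- setNames(rep(NA_real_, length(hist_cols)), hist_cols)
    row[names(imp)] <- imp
    history <- rbind(history, row)

    scored <- intersect(live, undecided)
    hit <- imp[scored] > thr
    hits[scored] <- hits[scored] + as.integer(hit)
    iters_live[scored] <- iters_live[scored] + 1L

    cutoff <- alpha / length(live)   # Bonferroni over live features
    for (f in scored) {
      p <- .binomTwoSided(hits[f], iters_live[f])
      if (p <= cutoff) {
        decisions[f] <- if (hits[f] / iters_live[f] > 0.5) "confirmed"
                        else "rejected"
      }
    }
    undecided <- feats[decisions == "tentative"]
  }
  rownames(history) <- NULL
  methods::new("BorutaResult", decisions = decisions, hitCounts = hits,
               nIterations = it, iterationsLive = iters_live,
               importanceHistory = history,
               thresholdPercentile = thresholdPercentile, alpha = alpha)
}
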