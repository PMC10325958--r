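# Level0 learner registry. Each learner is fit(x, y) -> model plus
# predict(model, x) -> numeric vector (point prediction, or probability of
# the positive class for classification). Learners needing standardised
# inputs (kNN) scale with training-fold statistics only; e1071::svm scales
# internally from its own training data; tree models are unscaled.

.fitScaled <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0] <- 1
  list(center = ctr, scale = scl)
}
.applyScale <- function(x, s) scale(x, center = s$center, scale = s$scale)

.level0Regression <- function() {
  list(
    lin_reg = list(
      fit = function(x, y) lm(y ~ ., data = data.frame(x, y = y)),
      predict = function(m, x) unname(predict(m, data.frame(x)))),
    elastic_net = list(
      fit = function(x, y) glmnet::cv.glmnet(x, y, alpha = 0.5, nfolds = 5),
      predict = function(m, x)
        as.vector(predict(m, x, s = "lambda.min"))),
    random_forest = list(
      fit = function(x, y)
        ranger::ranger(x = as.data.frame(x), y = y, num.trees = 500,
                       seed = sample.int(.Machine$integer.max, 1),
                       num.threads = 1),
      predict = function(m, x)
        predict(m, data = as.data.frame(x), num.threads = 1)$predictions),
    xgboost = list(
      fit = function(x, y)
        xgboost::xgboost(x, y, nrounds = 150, learning_rate = 0.1,
                         max_depth = 3, nthreads = 1, verbosity = 0),
      predict = function(m, x) as.vector(predict(m, x))),
    svr = list(
      fit = function(x, y) e1071::svm(x, y, type = "eps-regression",
                                      kernel = "radial"),
      predict = function(m, x) unname(predict(m, x))))
}

.level0Classification <- function() {
  list(
    logistic = list(
      fit = function(x, y)
        suppressWarnings(glm(y ~ ., data = data.frame(x, y = y),
                             family = binomial())),
      predict = function(m, x)
        unname(suppressWarnings(predict(m, data.frame(x),
                                        type = "response")))),
    random_forest = list(
      fit = function(x, y)
        ranger::ranger(x = as.data.frame(x), y = y, num.trees = 500,
                       probability = TRUE,
                       seed = sample.int(.Machine$integer.max, 1),
                       num.threads = 1),
      predict = function(m, x)
        predict(m, data = as.data.frame(x), num.threads = 1)$
          predictions[, "1"]),
    xgboost = list(
      fit = function(x, y)
        xgboost::xgboost(x, y, nrounds = 150, learning_rate = 0.1,
                         max_depth = 3, nthreads = 1, verbosity = 0),
      predict = function(m, x)
        as.vector(predict(m, x, type = "response"))),
    knn = list(
      fit = function(x, y) {
        s <- .fitScaled(x)
        list(model = caret::knn3(.applyScale(x, s), y,
                                 k = min(5, nrow(x) - 1)), scaling = s)
      },
      predict = function(m, x)
        predict(m$model, .applyScale(x, m$scaling), type = "prob")[, "1"]),
    naive_bayes = list(
      fit = function(x, y) e1071::naiveBayes(as.data.frame(x), y),
      predict = function(m, x)
        predict(m, as.data.frame(x), type = "raw")[, "1"]))
}

.stratifiedFolds <- function(y, k, task) {
  n <- length(y)
  fold <- integer(n)
  if (task == "classification") {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  } else {
    fold <- sample(rep_len(seq_len(k), n))
  }
  fold
}

#' Fit a stacked ensemble
#'
#' Level0 learners (regression: linear regression, elastic net, random
#' forest, gradient-boosted trees, support-vector regression;
#' classification: logistic regression, random forest, gradient-boosted
#' trees, k-nearest neighbours, naive Bayes) are applied to the training
#' data with repeated k-fold cross-validation (default fivefold, 10
#' repeats; classification folds stratified by class). Each sample's
#' held-out predictions, averaged over repeats, form the out-of-fold (OOF)
#' meta-feature matrix on which the level1 meta-model — a random forest for
#' regression, gradient-boosted trees for classification — is trained.
#' Every level0 learner is then refitted on the full training set for
#' deployment. A learner that errors on any fold is dropped from the
#' ensemble with a warning, never silently imputed.
#'
#' @param x training samples x predictors numeric matrix (column names
#'   required).
#' @param y training target: numeric (regression) or binary coded 0/1
#'   (classification).
#' @param task `"regression"` or `"classification"`.
#' @param seed integer controlling folds and every stochastic learner.
#' @param kFolds,nRepeats cross-validation scheme (defaults 5 and 10).
#' @param level0 optional character subset of the level0 menu.
#' @return A [StackingModel-class].
#' @export
fitStack <- function(x, y, task = c("regression", "classification"), seed,
                     kFolds = 5, nRepeats = 10, level0 = NULL) {
  task <- match.arg(task)
  x <- as.matrix(x)
  if (is.null(colnames(x))) stop("x needs column names")
  n <- nrow(x)
  if (n < 2 * kFolds) stop("need at least 2*kFolds training samples")
  if (task == "classification") {
    y <- factor(y, levels = sort(unique(as.character(y))))
    if (nlevels(y) != 2) stop("classification target must be binary")
    levels(y) <- c("0", "1")
  } else {
    y <- as.numeric(y)
  }

  menu <- if (task == "regression") .level0Regression()
          else .level0Classification()
  if (!is.null(level0)) {
    bad <- setdiff(level0, names(menu))
    if (length(bad)) stop("unknown level0 learners: ",
                          paste(bad, collapse = ", "))
    menu <- menu[level0]
  }

  set.seed(as.integer(seed) %% .Machine$integer.max)
  oof_sum <- matrix(0, n, length(menu),
                    dimnames = list(rownames(x), names(menu)))
  failed <- setNames(rep(FALSE, length(menu)), names(menu))
  fold_ids <- vector("list", nRepeats)
  for (r in seq_len(nRepeats)) {
    fold <- .stratifiedFolds(if (task == "classification") y else
                               as.numeric(y), kFolds, task)
    fold_ids[[r]] <- fold
    for (k in seq_len(kFolds)) {
      tr <- fold != k
      for (nm in names(menu)) {
        if (failed[nm]) next
        pred <- tryCatch({
          m <- menu[[nm]]$fit(x[tr, , drop = FALSE],
                              if (task == "classification") y[tr]
                              else y[tr])
          menu[[nm]]$predict(m, x[!tr, , drop = FALSE])
        }, error = function(e) e)
        if (inherits(pred, "error") || any(!is.finite(pred))) {
          warning("level0 learner '", nm, "' failed and is excluded: ",
                  if (inherits(pred, "error")) conditionMessage(pred)
                  else "non-finite predictions")
          failed[nm] <- TRUE
        } else {
          oof_sum[!tr, nm] <- oof_sum[!tr, nm] + pred
        }
      }
    }
  }
  keep <- names(menu)[!failed]
  if (!length(keep)) stop("all level0 learners failed")
  oof <- oof_sum[, keep, drop = FALSE] / nRepeats

  if (task == "regression") {
    level1 <- ranger::ranger(x = as.data.frame(oof), y = y,
                             num.trees = 500,
                             seed = sample.int(.Machine$integer.max, 1),
                             num.threads = 1)
    level1_name <- "random_forest"
  } else {
    level1 <- xgboost::xgboost(oof, y, nrounds = 100, learning_rate = 0.1,
                               max_depth = 2, nthreads = 1, verbosity = 0)
    level1_name <- "gradient_boosted_trees"
  }
  full <- lapply(keep, function(nm)
    menu[[nm]]$fit(x, y))
  names(full) <- keep

  methods::new("StackingModel", task = task, level0Names = keep,
               level0Full = full, level1 = level1,
               level1Name = level1_name, oofMatrix = oof,
               foldIds = fold_ids,
               cvScheme = list(kFolds = kFolds, nRepeats = nRepeats,
                               seed = seed),
               featureNames = colnames(x))
}

#' Predict from a stacked ensemble
#'
#' Runs test samples through the full-train level0 models and maps their
#' outputs through the level1 meta-model.
#'
#' @param model a [StackingModel-class] from [fitStack()].
#' @param x test samples x predictors matrix; columns must match the
#'   training predictors exactly.
#' @return For regression, a numeric vector. For classification, a matrix
#'   of class probabilities with columns `"0"` and `"1"` (rows sum to 1);
#'   the positive-class probability is column `"1"`.
#' @export
predictStack <- function(model, x) {
  x <- as.matrix(x)
  miss <- setdiff(model@featureNames, colnames(x))
  extra <- setdiff(colnames(x), model@featureNames)
  if (length(miss) || length(extra))
    stop("feature mismatch; missing: [", paste(miss, collapse = ", "),
         "] extra: [", paste(extra, collapse = ", "), "]")
  x <- x[, model@featureNames, drop = FALSE]
  if (nrow(x) == 0) {
    return(if (model@task == "regression") numeric(0)
           else matrix(numeric(0), 0, 2, dimnames = list(NULL, c("0", "1"))))
  }
  menu <- if (model@task == "regression") .level0Regression()
          else .level0Classification()
  meta <- vapply(model@level0Names, function(nm)
    menu[[nm]]$predict(model@level0Full[[nm]], x), numeric(nrow(x)))
  meta <- matrix(meta, nrow = nrow(x),
                 dimnames = list(rownames(x), model@level0Names))
  if (model@task == "regression") {
    predict(model@level1, data = as.data.frame(meta),
            num.threads = 1)$predictions
  } else {
    p1 <- as.vector(predict(model@level1, meta, type = "response"))
    p1 <- pmin(pmax(p1, 0), 1)
    cbind("0" = 1 - p1, "1" = p1)
  }
}
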