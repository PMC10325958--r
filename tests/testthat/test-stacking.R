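linearData <- function(n, seed, sd = 0.1) {
  set.seed(seed)
  x <- cbind(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  list(x = x, y = 2 * x[, "x1"] - x[, "x2"] + rnorm(n, 0, sd))
}

test_that("a perfect level0 model propagates through the meta-model", {
  d <- linearData(120, seed = 1, sd = 1e-9)
  m <- fitStack(d$x, d$y, "regression", seed = 5, nRepeats = 2,
                level0 = "lin_reg")
  dt <- linearData(120, seed = 2, sd = 1e-9)
  pred <- predictStack(m, dt$x)
  r2 <- regressionMetrics(dt$y, pred)[["r_squared"]]
  expect_gte(r2, 0.99)
})

test_that("a planted linear signal is recovered by the full ensemble", {
  d <- linearData(150, seed = 3)
  m <- fitStack(d$x, d$y, "regression", seed = 7, nRepeats = 2)
  dt <- linearData(150, seed = 4)
  pred <- predictStack(m, dt$x)
  expect_gt(regressionMetrics(dt$y, pred)[["r_squared"]], 0.9)
})

test_that("out-of-fold bookkeeping never mixes folds and fitting is pure", {
  d <- linearData(60, seed = 9)
  m <- fitStack(d$x, d$y, "regression", seed = 21, nRepeats = 3,
                level0 = c("lin_reg", "random_forest"))
  # every repeat assigns each sample to exactly one of k folds
  for (fold in m@foldIds) {
    expect_length(fold, 60)
    expect_true(all(fold %in% seq_len(m@cvScheme$kFolds)))
  }
  expect_equal(dim(m@oofMatrix), c(60, 2))
  # leakage check: fitting depends only on (x, y, seed); anything done to
  # test data (including corrupted labels) leaves the model state identical
  dt <- linearData(30, seed = 10)
  dt$y <- sample(dt$y)  # corrupt test labels before predicting
  p1 <- predictStack(m, dt$x)
  m2 <- fitStack(d$x, d$y, "regression", seed = 21, nRepeats = 3,
                 level0 = c("lin_reg", "random_forest"))
  expect_identical(m2@oofMatrix, m@oofMatrix)
  expect_identical(m2@foldIds, m@foldIds)
  expect_identical(predictStack(m2, dt$x), p1)
  # oof predictions differ from full-train resubstitution predictions
  resub <- predictStack(m, d$x)
  expect_false(isTRUE(all.equal(unname(m@oofMatrix[, "lin_reg"]), resub)))
})

test_that("stacking keeps pace with the best level0 model on dose data", {
  # dose-regression cohorts (the ensemble's design target); each level0
  # model's own test RMSE comes from its full-train fit inside the ensemble
  menu <- mixdose:::.level0Regression()
  ratios <- vapply(1:5, function(seed) {
    panel <- mixdose:::.engineerPanel(generateCohort(seed = 100 + seed))
    exp_df <- exposureDesign(panel)
    rownames(exp_df) <- colnames(panel)
    split <- splitTrainTest(exp_df, seed = seed)
    y <- setNames(makeTargets(exp_df, 1.3)$photon_equivalent_dose,
                  rownames(exp_df))
    # screen first, as in the pipeline, so lm is not rank-deficient
    scr <- screenFeatures(buildPredictorMatrix(panel)[split$train, ],
                          y[split$train])
    x <- buildPredictorMatrix(panel)[, retainedFeatures(scr)]
    m <- fitStack(x[split$train, ], y[split$train], "regression",
                  seed = seed, nRepeats = 2)
    stack_rmse <- regressionMetrics(
      y[split$test], predictStack(m, x[split$test, ]))[["rmse"]]
    singles <- vapply(m@level0Names, function(nm)
      regressionMetrics(y[split$test],
                        menu[[nm]]$predict(m@level0Full[[nm]],
                                           x[split$test, ]))[["rmse"]],
      numeric(1))
    stack_rmse / min(singles)
  }, numeric(1))
  expect_lte(mean(ratios), 1.05)
})

test_that("classification stacks return coherent probabilities", {
  set.seed(31)
  n <- 80
  x <- cbind(a = rnorm(n), b = rnorm(n))
  y <- as.integer(x[, "a"] + rnorm(n, 0, 0.5) > 0)
  m <- fitStack(x, y, "classification", seed = 13, nRepeats = 2,
                level0 = c("logistic", "random_forest", "naive_bayes"))
  xt <- cbind(a = rnorm(20), b = rnorm(20))
  p <- predictStack(m, xt)
  expect_equal(dim(p), c(20, 2))
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(unname(rowSums(p)), rep(1, 20))
  # duplicated test row: identical predictions
  p2 <- predictStack(m, xt[c(1, 1, 5), ])
  expect_equal(p2[1, ], p2[2, ])
  # empty test set: empty predictions
  p0 <- predictStack(m, xt[0, , drop = FALSE])
  expect_equal(nrow(p0), 0)
  m_reg <- fitStack(cbind(a = rnorm(30), b = rnorm(30)), rnorm(30),
                    "regression", seed = 1, nRepeats = 2,
                    level0 = "lin_reg")
  expect_length(predictStack(m_reg, xt[0, , drop = FALSE]), 0)
})

test_that("feature mismatches and invalid targets are rejected", {
  d <- linearData(40, seed = 2)
  m <- fitStack(d$x, d$y, "regression", seed = 3, nRepeats = 2,
                level0 = "lin_reg")
  bad <- d$x[, c("x1", "x2")]
  expect_error(predictStack(m, bad), "x3")
  colnames(bad) <- c("x1", "zz")
  expect_error(predictStack(m, cbind(d$x, zz = 1)), "zz")
  expect_error(fitStack(d$x, rep(0:2, length.out = 40), "classification",
                        seed = 1), "binary")
  expect_error(fitStack(d$x[1:6, ], d$y[1:6], "regression", seed = 1),
               "2\\*kFolds")
})
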