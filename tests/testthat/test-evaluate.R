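test_that("regression metrics match closed forms", {
  y <- c(0.3, 1.7, 2.2, 5)
  expect_equal(unname(regressionMetrics(y, y)),
               c(0, 0, 1))
  m <- regressionMetrics(c(0, 2), c(1, 1))
  expect_equal(unname(m), c(1, 1, 0))  # the mean predictor: R^2 = 0
  m2 <- regressionMetrics(c(0, 0, 3), c(0, 0, 0))
  expect_equal(m2[["rmse"]], sqrt(3))
  expect_equal(m2[["mae"]], 1)
  expect_warning(m3 <- regressionMetrics(c(2, 2, 2), c(1, 2, 3)),
                 "undefined")
  expect_true(is.na(m3[["r_squared"]]))
})

test_that("rmse dominates mae on arbitrary inputs", {
  set.seed(14)
  for (i in 1:20) {
    y <- rnorm(sample(5:50, 1))
    p <- y + rnorm(length(y), 0, runif(1, 0.01, 3))
    m <- regressionMetrics(y, p)
    expect_gte(m[["rmse"]], m[["mae"]])
  }
})

test_that("AUC follows the rank formulation with ties at one half", {
  expect_equal(rocAuc(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1)), 0.75)
  expect_equal(rocAuc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(rocAuc(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)  # all ties
  expect_error(rocAuc(c(1, 1), c(0.2, 0.3)), "one class")
  # invariance under strictly monotone transforms of the scores
  set.seed(15)
  y <- rbinom(40, 1, 0.4)
  s <- rnorm(40)
  a <- rocAuc(y, s)
  expect_equal(rocAuc(y, exp(s)), a)
  expect_equal(rocAuc(y, 5 * s - 2), a)
  expect_equal(rocAuc(y, rank(s)), a)
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(16)
  for (i in 1:5) {
    y <- c(0, 1, rbinom(30, 1, 0.5))
    s <- round(rnorm(32), 1)  # rounding forces ties
    expect_equal(rocAuc(y, s),
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                direction = "<"))))
  }
})

test_that("threshold metrics and the confusion matrix are consistent", {
  y <- c(1, 1, 1, 0, 0, 0, 0)
  p <- c(0.9, 0.8, 0.3, 0.4, 0.2, 0.6, 0.1)
  cm <- classificationMetrics(y, p)
  expect_equal(unname(cm$metrics["sensitivity"]), 2 / 3)
  expect_equal(unname(cm$metrics["specificity"]), 3 / 4)
  expect_equal(unname(cm$metrics["balanced_accuracy"]),
               (2 / 3 + 3 / 4) / 2)
  expect_equal(sum(cm$confusion), length(y))
  expect_equal(cm$confusion["1", "1"], 2)
  # a constant classifier has balanced accuracy 1/2 for any class balance
  for (p_pos in c(0.2, 0.5, 0.8)) {
    yy <- c(0, 1, rbinom(30, 1, p_pos))
    cc <- classificationMetrics(yy, rep(0.9, 32))
    expect_equal(unname(cc$metrics["balanced_accuracy"]), 0.5)
  }
  perfect <- classificationMetrics(c(1, 1, 0), c(0.9, 0.8, 0.1))
  expect_equal(unname(perfect$metrics[c("auc", "balanced_accuracy")]),
               c(1, 1))
})

test_that("bootstrap AUC interval behaves on degenerate and fixed seeds", {
  y <- rep(c(1, 0), each = 10)
  p <- c(runif(10, 0.8, 1), runif(10, 0, 0.2))  # perfectly separable
  b <- bootstrapAucCi(y, p, nBoot = 200, seed = 4)
  expect_equal(b$ci, c(1, 1))
  expect_length(b$replicates, 200)
  set.seed(17)
  p2 <- rnorm(20)
  b1 <- bootstrapAucCi(y, p2, nBoot = 300, seed = 8)
  b2 <- bootstrapAucCi(y, p2, nBoot = 300, seed = 8)
  expect_identical(b1$ci, b2$ci)
  expect_true(b1$ci[1] <= rocAuc(y, p2) && rocAuc(y, p2) <= b1$ci[2])
  expect_error(bootstrapAucCi(rep(1, 5), rnorm(5), 10, seed = 1), "class")
})

test_that("subgroup error tables conserve the confusion total", {
  y <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  yhat <- c(1, 0, 1, 1, 0, 0, 1, 0, 0, 0)
  g <- c("a", "a", "b", "b", "a", "a", "b", "b", "c", "c")
  tab <- subgroupErrorTable(y, yhat, g)
  expect_equal(tab$n, c(4L, 4L, 2L))
  expect_equal(sum(tab$n_misclassified), 2L)
  expect_equal(tab$n_misclassified[tab$group == "c"], 0L)
  # crafted 7-error case concentrated in one subgroup (6 of 7)
  y2 <- rep(c(0, 1), c(30, 10))
  yhat2 <- y2
  g2 <- rep(c("photon3Gy", "other"), c(20, 20))
  yhat2[1:6] <- 1   # six false positives in the photon-only subgroup
  yhat2[31] <- 0    # one false negative elsewhere
  tab2 <- subgroupErrorTable(y2, yhat2, g2)
  expect_equal(tab2$n_misclassified[tab2$group == "photon3Gy"], 6L)
  expect_equal(tab2$n_misclassified[tab2$group == "other"], 1L)
  cm <- classificationMetrics(y2, yhat2)$confusion
  expect_equal(sum(tab2$n_misclassified), sum(cm) - sum(diag(cm)))
})

test_that("evaluatePredictions assembles a coherent report object", {
  set.seed(19)
  y <- rbinom(30, 1, 0.5)
  p <- plogis(2 * y - 1 + rnorm(30))
  rep <- evaluatePredictions(y, p, "classification",
                             group_labels = rep(c("g1", "g2"), 15),
                             nBoot = 100, seed = 3)
  expect_s4_class(rep, "EvalReport")
  expect_equal(sum(rep@confusion), 30)
  expect_equal(sum(rep@subgroupErrors$n), 30)
  expect_true(all(diff(c(rep@aucCi[1], evalMetrics(rep)[["auc"]],
                         rep@aucCi[2])) >= -1e-9))
  rr <- evaluatePredictions(rnorm(10), rnorm(10), "regression")
  expect_named(evalMetrics(rr), c("rmse", "mae", "r_squared"))
})
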