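ctVec <- function(down, up) {
  setNames(c(rep_len(down, 3), rep_len(up, 4)),
           c("Lrg1", "Phlda3", "Rhoc", "Ccr7", "Cd19", "Cxcr5", "Ly6d"))
}

test_that("gene net signal is the difference of group geometric means", {
  expect_equal(geneNetSignal(ctVec(20, 10)), 10)
  expect_equal(geneNetSignal(ctVec(13.7, 13.7)), 0)
  expect_equal(geneNetSignal(ctVec(c(8, 2, 4), 1)), 3)  # GM{8,2,4} = 4
  # invariant to gene order within groups
  v <- ctVec(c(8, 2, 4), c(1, 5, 2, 9))
  expect_equal(geneNetSignal(v), geneNetSignal(rev(v)))
  expect_error(geneNetSignal(v[-2]), "Phlda3")
  v[1] <- 0
  expect_error(geneNetSignal(v), "positive")
})

test_that("count transformation yields exact ln columns and the NLR", {
  ex <- makeExposures(dp = c(0, 1, 2), dn = c(0, 0.5, 0.2))
  sig <- rbind(CD45 = c(exp(2), 1, 50), CD3e = c(2, 3, 4),
               Ly_6G = c(exp(1), 1, 10), CD19 = c(5, 6, 7),
               m1 = c(1.1, 2.2, 3.3))
  panel <- makePanel(sig, ex,
                     category = c(rep("blood_count", 4), "metabolite_serum"))
  out <- transformCounts(panel)
  s <- SummarizedExperiment::assay(out, "signal")
  expect_equal(unname(s["ln_Ly_6G_CD45_ratio", 1]), -1)  # ln(e/e^2)
  expect_equal(unname(s["ln_CD45", 2]), 0)               # count 1 -> ln 0
  expect_false(any(c("CD45", "CD3e", "Ly_6G", "CD19") %in% rownames(out)))
  expect_true("m1" %in% rownames(out))
  # scaling a count column shifts its ln column by ln(c)
  sig2 <- sig; sig2["CD3e", ] <- sig["CD3e", ] * 10
  out2 <- transformCounts(makePanel(sig2, ex,
                          category = c(rep("blood_count", 4),
                                       "metabolite_serum")))
  expect_equal(SummarizedExperiment::assay(out2, "signal")["ln_CD3e", ],
               s["ln_CD3e", ] + log(10))
  # non-positive raw counts are an explicit failure at construction
  sig3 <- sig; sig3["CD19", 2] <- 0
  expect_error(makePanel(sig3, ex,
                         category = c(rep("blood_count", 4),
                                      "metabolite_serum")),
               "positive")
})

countDonorPanels <- function(n_recip = 3L, n_donor = 1L, seed = 2) {
  d <- defaultDesign()
  sp <- defaultBiomarkerSpecs()
  is_count <- sp$category == "blood_count"
  dr <- d; dr$groups$n_animals <- rep(n_recip, 6)
  dd <- d; dd$groups$n_animals <- rep(n_donor, 6)
  list(recip = generateCohort(dr, sp[!is_count, ], seed = seed),
       donor = generateCohort(dd, sp[is_count, ], seed = seed + 1))
}

test_that("blood-count matching stays within strata and is reproducible", {
  pp <- countDonorPanels(n_recip = 4L, n_donor = 2L)
  m1 <- matchBloodCounts(pp$recip, pp$donor, seed = 9)
  m2 <- matchBloodCounts(pp$recip, pp$donor, seed = 9)
  expect_identical(SummarizedExperiment::assay(m1, "signal"),
                   SummarizedExperiment::assay(m2, "signal"))
  rec <- exposureDesign(m1)
  don <- exposureDesign(pp$donor)
  rownames(don) <- colnames(pp$donor)
  expect_equal(don[rec$count_donor, "group"], rec$group)
  expect_equal(don[rec$count_donor, "time_days"], rec$time_days)
})

test_that("a lone donor serves every recipient in its stratum", {
  pp <- countDonorPanels(n_recip = 6L, n_donor = 2L)
  # strata have 3 recipients and 1 donor each (2 donors split over 2 times)
  m <- matchBloodCounts(pp$recip, pp$donor, seed = 3)
  rec <- exposureDesign(m)
  per_stratum <- split(rec$count_donor,
                       paste(rec$group, rec$time_days))
  expect_true(all(vapply(per_stratum,
                         function(d) length(unique(d)) == 1L, logical(1))))
})

test_that("exhaustive matching preserves donor group means exactly", {
  # equal donor and recipient counts: matching is a permutation, so the
  # within-stratum mean of any matched count equals the donor mean
  pp <- countDonorPanels(n_recip = 4L, n_donor = 4L)
  m <- matchBloodCounts(pp$recip, pp$donor, seed = 13)
  rec <- exposureDesign(m)
  don <- exposureDesign(pp$donor)
  ms <- SummarizedExperiment::assay(m, "signal")["CD19", ]
  ds <- SummarizedExperiment::assay(pp$donor, "signal")["CD19", ]
  m_means <- tapply(log(ms), paste(rec$group, rec$time_days), mean)
  d_means <- tapply(log(ds), paste(don$group, don$time_days), mean)
  expect_equal(m_means, d_means[names(m_means)])
  # and each donor is used exactly once
  expect_equal(sort(rec$count_donor), sort(colnames(pp$donor)))
})

test_that("matching errors on a stratum with no donors", {
  pp <- countDonorPanels()
  donor_sub <- pp$donor[, exposureDesign(pp$donor)$group != "sham"]
  expect_error(matchBloodCounts(pp$recip, donor_sub, seed = 1), "sham")
})

test_that("the correlation screen honours its inclusive boundary", {
  set.seed(41)
  n <- 60
  dpe <- c(rep(0, 12), runif(n - 12, 2.9, 3.8))
  x <- cbind(at_threshold = vectorWithCorrelation(dpe, 0.30, seed = 1),
             below = vectorWithCorrelation(dpe, 0.29, seed = 2),
             strong = vectorWithCorrelation(dpe, 0.80, seed = 3),
             Sex = rep_len(c(0, 1), n))
  rep <- screenFeatures(x, dpe)
  expect_true(all(c("at_threshold", "strong") %in% retainedFeatures(rep)))
  expect_equal(rep@droppedLowCorrelation$name, "below")
  expect_equal(rep@droppedLowCorrelation$r_with_dpe, 0.29,
               tolerance = 1e-10)
  expect_equal(rep@forcedKept, "Sex")
  # every input feature lands in exactly one bucket
  all_out <- c(retainedFeatures(rep), rep@droppedLowCorrelation$name,
               names(rep@droppedCollinear), rep@forcedKept)
  expect_setequal(all_out, colnames(x))
  expect_equal(anyDuplicated(all_out), 0L)
})

test_that("collinearity pruning removes worst offenders per the rule", {
  set.seed(42)
  n <- 80
  dpe <- runif(n, 0, 4)
  base <- vectorWithCorrelation(dpe, 0.75, seed = 5)
  # four exact duplicates: each starts with 3 strong partners; the rule
  # removes offenders until none has >= 2 partners, i.e. two are dropped
  x <- cbind(dup1 = base, dup2 = base, dup3 = base, dup4 = base,
             other = vectorWithCorrelation(dpe, 0.6, seed = 6))
  rep <- screenFeatures(x, dpe, forced = character(0))
  expect_length(names(rep@droppedCollinear), 2L)
  expect_length(intersect(retainedFeatures(rep),
                          c("dup1", "dup2", "dup3", "dup4")), 2L)
  expect_true("other" %in% retainedFeatures(rep))
  # deterministic tie-break: alphabetically first offenders dropped
  expect_equal(names(rep@droppedCollinear), c("dup1", "dup2"))
})

test_that("screening is idempotent on its own output", {
  set.seed(43)
  n <- 70
  dpe <- runif(n, 0, 4)
  x <- cbind(a = vectorWithCorrelation(dpe, 0.9, seed = 1),
             b = vectorWithCorrelation(dpe, 0.5, seed = 2),
             c = vectorWithCorrelation(dpe, 0.1, seed = 3),
             d = vectorWithCorrelation(dpe, 0.45, seed = 4),
             Sex = rep_len(c(0, 1), n), Time = rep_len(c(1, 7), n))
  r1 <- screenFeatures(x, dpe)
  x2 <- x[, c(retainedFeatures(r1), r1@forcedKept)]
  r2 <- screenFeatures(x2, dpe)
  expect_setequal(retainedFeatures(r2), retainedFeatures(r1))
  expect_length(r2@droppedLowCorrelation$name, 0L)
  expect_length(r2@droppedCollinear, 0L)
  expect_error(screenFeatures(x, rep(3, n)), "constant")
})

test_that("predictor matrix assembly covers engineered features and modes", {
  panel <- mixdose:::.engineerPanel(generateCohort(smallDesign(4L),
                                                   seed = 6))
  x <- buildPredictorMatrix(panel)
  expect_true(all(c("gene_net_sig", "ln_CD19", "ln_Ly_6G_CD45_ratio",
                    "Sex", "Time") %in% colnames(x)))
  expect_false(any(c("Lrg1", "CD19", "CD45") %in% colnames(x)))
  x2 <- buildPredictorMatrix(panel, exclude = "CD19")
  expect_false("ln_CD19" %in% colnames(x2))
  x3 <- buildPredictorMatrix(panel, useGeneNetSignalOnly = FALSE)
  expect_true("Lrg1" %in% colnames(x3))
})
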