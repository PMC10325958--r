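#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with defaults matching
#' the analysis protocol: correlation screen at |r| >= 0.3 with the
#' photon-equivalent dose, collinearity cut at |r| >= 0.7, shadow-feature
#' selection against the 50th shadow percentile at alpha = 0.05 with
#' Bonferroni correction, stacking with fivefold cross-validation repeated
#' 10 times, and 10,000 bootstrap replicates for ROC confidence intervals.
#'
#' @param seed master integer seed; all stage seeds are derived from it.
#' @param input optional path to a cohort CSV (see [readCohortCsv()]); when
#'   `NULL` a synthetic cohort is generated.
#' @param design,specs synthetic-cohort design and biomarker specs.
#' @param mode `"full"` (all dosimetry endpoints plus the CD19 injury
#'   endpoint), `"no-cd19"` (CD19 counts removed from the predictors), or
#'   `"cd19-outcome"` (only the CD19 injury endpoint).
#' @param endpoints optional character subset of
#'   `photon_equivalent_dose`, `neutron_dose`, `neutron_10_percent`,
#'   `neutron_0p5_Gy`, `cd19_outcome`.
#' @param rbeGrid,rMin,rCollinear,borutaMaxIter,borutaTrees,alpha,kFolds,nRepeats,nBoot
#'   stage parameters (see the stage functions).
#' @param outputDir optional directory for JSON/CSV reports.
#' @return A `RunConfig` list.
#' @export
runConfig <- function(seed = 1, input = NULL, design = defaultDesign(),
                      specs = defaultBiomarkerSpecs(),
                      mode = c("full", "no-cd19", "cd19-outcome"),
                      endpoints = NULL, rbeGrid = c(0.05, 10, 0.01),
                      rMin = 0.3, rCollinear = 0.7, borutaMaxIter = 100,
                      borutaTrees = 500, alpha = 0.05, kFolds = 5,
                      nRepeats = 10, nBoot = 10000, outputDir = NULL) {
  mode <- match.arg(mode)
  if (is.null(endpoints)) {
    endpoints <- switch(mode,
      "full" = c("photon_equivalent_dose", "neutron_dose",
                 "neutron_10_percent", "neutron_0p5_Gy", "cd19_outcome"),
      "no-cd19" = c("photon_equivalent_dose", "neutron_dose",
                    "neutron_10_percent", "neutron_0p5_Gy"),
      "cd19-outcome" = "cd19_outcome")
  }
  structure(list(seed = as.integer(seed), input = input, design = design,
                 specs = specs, mode = mode, endpoints = endpoints,
                 rbeGrid = rbeGrid, rMin = rMin, rCollinear = rCollinear,
                 borutaMaxIter = borutaMaxIter, borutaTrees = borutaTrees,
                 alpha = alpha, kFolds = kFolds, nRepeats = nRepeats,
                 nBoot = nBoot, outputDir = outputDir),
            class = "RunConfig")
}

.endpointTask <- function(ep) {
  switch(ep,
         photon_equivalent_dose = "regression",
         neutron_dose = "regression",
         cd19_outcome = "regression",
         neutron_10_percent = "classification",
         neutron_0p5_Gy = "classification",
         stop("unknown endpoint: ", ep))
}

#' Stratified random half split into training and testing sets
#'
#' Splits samples into halves of sizes `ceiling(n/2)` (training) and
#' `floor(n/2)` (testing), stratified by exposure group x sampling time so
#' no stratum is lost from either half. With 89 samples the split is 45/44.
#'
#' @param exposures data.frame with `group` and `time_days` columns; row
#'   names (or a `sample_id` column) identify samples.
#' @param seed integer.
#' @return list with character vectors `train` and `test`.
#' @export
splitTrainTest <- function(exposures, seed) {
  ids <- if (!is.null(exposures$sample_id)) as.character(exposures$sample_id)
         else rownames(exposures)
  n <- length(ids)
  stopifnot(n >= 2)
  strata <- paste(exposures$group, exposures$time_days, sep = "|")
  set.seed(as.integer(seed) %% .Machine$integer.max)
  train <- character(0)
  leftovers <- character(0)
  for (s in sort(unique(strata))) {
    sid <- ids[strata == s]
    sid <- if (length(sid) > 1) sample(sid) else sid
    ntr <- length(sid) %/% 2
    train <- c(train, sid[seq_len(ntr)])
    if (length(sid) %% 2 == 1) leftovers <- c(leftovers, sid[ntr + 1])
  }
  need <- ceiling(n / 2) - length(train)
  if (need > 0 && length(leftovers)) {
    pick <- if (length(leftovers) > 1)
      sample(leftovers, min(need, length(leftovers))) else leftovers[seq_len(min(need, 1))]
    train <- c(train, pick)
  }
  list(train = sort(train), test = sort(setdiff(ids, train)))
}

.engineerPanel <- function(panel) {
  if (all(c(.GENES_CT_DOWN, .GENES_CT_UP) %in% rownames(panel)))
    panel <- addGeneNetSignal(panel)
  transformCounts(panel)
}

.simulateStudyPanel <- function(config) {
  # Emulates the study's data collection: transcripts/metabolites and blood
  # counts come from different animals, joined by random matching within
  # exposure-group x time strata.
  specs <- config$specs
  is_count <- specs$category == "blood_count"
  omics <- generateCohort(config$design, specs[!is_count, , drop = FALSE],
                          seed = config$seed + 1L)
  if (!any(is_count)) return(omics)
  donors <- generateCohort(config$design, specs[is_count, , drop = FALSE],
                           seed = config$seed + 2L)
  matchBloodCounts(omics, donors, seed = config$seed + 3L)
}

#' Run the full biodosimetry analysis pipeline
#'
#' Executes, in order: cohort acquisition (synthetic generation with
#' blood-count matching, or CSV ingestion) - stratified train/test half
#' split - RBE estimation on training data only - photon-equivalent dose
#' targets for all samples - feature engineering (gene net signal, ln
#' counts, neutrophil/lymphocyte ratio) - correlation/collinearity screen
#' (training data) - shadow-feature selection per endpoint (training data)
#' - stacked-ensemble fitting (training data) - prediction and evaluation
#' on the held-out test set. Nothing fitted ever sees a test sample.
#'
#' If the shadow-feature step confirms no predictor for an endpoint, the
#' screened predictor set is used instead with a warning. Classification
#' endpoints with a single class in the training half are skipped with a
#' warning.
#'
#' @param config a [runConfig()] list.
#' @param verbose log per-stage timing messages.
#' @return (invisibly) list with elements `panel`, `split`, `rbeFit`,
#'   `targets`, `screen`, `boruta` (per endpoint), `models` (per endpoint),
#'   `reports` (per endpoint, [EvalReport-class]), `manifest`.
#' @export
runPipeline <- function(config = runConfig(), verbose = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  say <- function(...) if (verbose)
    message(sprintf("[%7.1fs] ", proc.time()[["elapsed"]] - t0), ...)

  panel <- if (is.null(config$input)) .simulateStudyPanel(config)
           else readCohortCsv(config$input)
  say("cohort: ", ncol(panel), " samples x ", nrow(panel), " biomarkers")
  panel <- .engineerPanel(panel)
  exposures <- exposureDesign(panel)
  rownames(exposures) <- colnames(panel)

  split <- splitTrainTest(exposures, seed = config$seed + 4L)
  tr <- split$train
  te <- split$test
  say("split: ", length(tr), " train / ", length(te), " test")

  rbe_fit <- estimateRbe(panel[, tr], rbeGrid = config$rbeGrid)
  say("RBE_opt = ", format(rbeOpt(rbe_fit), digits = 4))
  targets <- makeTargets(exposures, rbeOpt(rbe_fit))

  exclude <- if (config$mode == "no-cd19") "CD19" else character(0)
  x_all <- buildPredictorMatrix(panel, exclude = exclude)
  screen <- screenFeatures(x_all[tr, , drop = FALSE],
                           targets[tr, "photon_equivalent_dose"],
                           rMin = config$rMin,
                           rCollinear = config$rCollinear)
  say("screen: ", length(retainedFeatures(screen)), " retained")

  boruta <- list(); models <- list(); reports <- list()
  seed_i <- config$seed + 10L
  for (ep in config$endpoints) {
    task <- .endpointTask(ep)
    if (ep == "cd19_outcome") {
      if (!"ln_CD19" %in% rownames(panel)) {
        warning("no CD19 counts; skipping cd19_outcome")
        next
      }
      y <- SummarizedExperiment::assay(panel, "signal")["ln_CD19", ]
      cand <- setdiff(c(retainedFeatures(screen), screen@forcedKept),
                      c("ln_CD45", "ln_CD3e", "ln_Ly_6G", "ln_CD19",
                        "ln_Ly_6G_CD45_ratio"))
    } else {
      y <- setNames(targets[[ep]], rownames(targets))
      cand <- c(retainedFeatures(screen), screen@forcedKept)
    }
    if (task == "classification" && length(unique(y[tr])) < 2) {
      warning("single class in training data; skipping ", ep)
      next
    }
    x_ep <- x_all[, cand, drop = FALSE]
    b <- borutaSelect(x_ep[tr, , drop = FALSE], y[tr], task = task,
                      maxIter = config$borutaMaxIter, seed = seed_i,
                      numTrees = config$borutaTrees, alpha = config$alpha)
    boruta[[ep]] <- b
    sel <- confirmedFeatures(b)
    if (!length(sel)) {
      warning("no feature confirmed for ", ep,
              "; using the screened predictor set")
      sel <- cand
    }
    say(ep, ": ", length(sel), " predictors after selection")
    m <- fitStack(x_ep[tr, sel, drop = FALSE], y[tr], task = task,
                  seed = seed_i + 1L, kFolds = config$kFolds,
                  nRepeats = config$nRepeats)
    models[[ep]] <- m
    pred <- predictStack(m, x_ep[te, sel, drop = FALSE])
    if (task == "classification") {
      reports[[ep]] <- evaluatePredictions(
        y[te], pred[, "1"], task = "classification",
        group_labels = exposures[te, "group"], nBoot = config$nBoot,
        seed = seed_i + 2L)
    } else {
      reports[[ep]] <- evaluatePredictions(y[te], pred, task = "regression")
    }
    say(ep, " evaluated")
    seed_i <- seed_i + 10L
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("mixdose")),
    seed = config$seed, mode = config$mode,
    endpoints = names(reports),
    n_train = length(tr), n_test = length(te),
    train_ids = tr, test_ids = te,
    rbe_opt = rbeOpt(rbe_fit),
    predictors = lapply(models, function(m) m@featureNames),
    thresholds = list(r_min = config$rMin, r_collinear = config$rCollinear,
                      shadow_percentile = 50, alpha = config$alpha,
                      k_folds = config$kFolds, n_repeats = config$nRepeats,
                      n_bootstrap = config$nBoot))
  out <- list(panel = panel, split = split, rbeFit = rbe_fit,
              targets = targets, screen = screen, boruta = boruta,
              models = models, reports = reports, manifest = manifest)
  if (!is.null(config$outputDir)) .writeReports(out, config$outputDir)
  invisible(out)
}

.reportToList <- function(r) {
  out <- list(task = r@task, metrics = as.list(r@metrics))
  if (r@task == "classification") {
    out$auc_ci_95 <- r@aucCi
    out$n_bootstrap <- r@nBootstrap
    out$confusion <- r@confusion
    if (nrow(r@subgroupErrors)) out$subgroup_errors <- r@subgroupErrors
  }
  out
}

.writeReports <- function(out, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wj <- function(x, f) jsonlite::write_json(
    x, file.path(dir, f), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  wj(list(rbe_opt = rbeOpt(out$rbeFit),
          features_used = out$rbeFit@featuresUsed,
          n_samples = out$rbeFit@nSamples), "rbe_fit.json")
  utils::write.csv(objectiveGrid(out$rbeFit),
                   file.path(dir, "rbe_objective_grid.csv"),
                   row.names = FALSE)
  wj(list(retained = out$screen@retained,
          forced_kept = out$screen@forcedKept,
          dropped_low_correlation = out$screen@droppedLowCorrelation,
          dropped_collinear = out$screen@droppedCollinear), "screen.json")
  wj(lapply(out$boruta, function(b) as.list(borutaDecisions(b))),
     "boruta_decisions.json")
  wj(lapply(out$reports, .reportToList), "eval_reports.json")
  wj(out$manifest, "manifest.json")
  invisible(dir)
}
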