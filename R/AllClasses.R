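#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats cor sd quantile rnorm runif predict var setNames
#'   pbinom binomial glm lm coef
#' @importFrom utils head modifyList
NULL

.BIOMARKER_CATEGORIES <- c("gene", "metabolite_serum", "metabolite_urine",
                           "blood_count", "demographic", "derived")

#' BiomarkerPanel: samples-by-biomarker container for biodosimetry
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding one assay
#' `"signal"` (features in rows, samples in columns), per-feature metadata in
#' `rowData` (`category`, one of gene / metabolite_serum / metabolite_urine /
#' blood_count / demographic / derived, and `scale`, `"identity"` or `"ln"`),
#' and the per-animal exposure design in `colData` (`photon_dose_Gy`,
#' `neutron_dose_Gy`, `time_days`, `sex` coded Female = 0 / Male = 1, and the
#' exposure `group` label).
#'
#' Gene features carry qRT-PCR cycle-threshold (C_T) semantics: a lower C_T
#' means more transcript, so genes upregulated by radiation have C_T values
#' that decrease with dose. Blood-count features on the `"identity"` scale
#' are raw cell counts and must be strictly positive (they are ln-transformed
#' downstream, see [transformCounts()]).
#'
#' @export
setClass("BiomarkerPanel", contains = "SummarizedExperiment")

setValidity("BiomarkerPanel", function(object) {
  msg <- character()
  if (!"signal" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'signal' is required")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("category", "scale") %in% colnames(rd))) {
    msg <- c(msg, "rowData must have 'category' and 'scale' columns")
  } else {
    bad <- setdiff(unique(rd$category), .BIOMARKER_CATEGORIES)
    if (length(bad))
      msg <- c(msg, paste0("unknown categories: ", paste(bad, collapse = ", ")))
    raw_counts <- rd$category == "blood_count" & rd$scale == "identity"
    if (any(raw_counts)) {
      v <- SummarizedExperiment::assay(object, "signal")[raw_counts, , drop = FALSE]
      if (any(!is.finite(v)) || any(v <= 0))
        msg <- c(msg, "raw blood-count signals must be strictly positive")
    }
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicated feature names")
  cd <- SummarizedExperiment::colData(object)
  need <- c("photon_dose_Gy", "neutron_dose_Gy", "time_days", "sex", "group")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("colData missing: ", paste(miss, collapse = ", ")))
  else if (any(cd$photon_dose_Gy < 0) || any(cd$neutron_dose_Gy < 0))
    msg <- c(msg, "doses must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a BiomarkerPanel
#'
#' @param signal numeric matrix, features x samples.
#' @param exposures data.frame (or DataFrame) of per-sample design variables
#'   with columns `photon_dose_Gy`, `neutron_dose_Gy`, `time_days`, `sex`,
#'   `group`; one row per column of `signal`.
#' @param category character vector, one category per feature.
#' @param scale character vector, `"identity"` or `"ln"` per feature
#'   (recycled); marks whether a signal is stored on its measurement scale or
#'   already ln-transformed.
#' @return A [BiomarkerPanel-class] object.
#' @export
BiomarkerPanel <- function(signal, exposures, category,
                           scale = "identity") {
  signal <- as.matrix(signal)
  scale <- rep_len(scale, nrow(signal))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(signal = signal),
    rowData = S4Vectors::DataFrame(category = as.character(category),
                                   scale = as.character(scale),
                                   row.names = rownames(signal)),
    colData = S4Vectors::DataFrame(exposures))
  methods::new("BiomarkerPanel", se)
}

#' @describeIn BiomarkerPanel per-feature category vector, named by feature.
#' @param x,object a `BiomarkerPanel`.
#' @export
featureCategories <- function(x) {
  setNames(SummarizedExperiment::rowData(x)$category, rownames(x))
}

#' @describeIn BiomarkerPanel the exposure design as a data.frame.
#' @export
exposureDesign <- function(x) {
  as.data.frame(SummarizedExperiment::colData(x))
}

setMethod("show", "BiomarkerPanel", function(object) {
  cat("BiomarkerPanel:", ncol(object), "samples x", nrow(object),
      "biomarkers\n")
  tab <- table(SummarizedExperiment::rowData(object)$category)
  cat("  categories:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat("  groups:",
      paste(unique(SummarizedExperiment::colData(object)$group),
            collapse = ", "), "\n")
})

#' RbeFit: fitted biomarker-weighted neutron RBE
#'
#' Result of [estimateRbe()]. `rbeOpt` maximises, over a grid of candidate
#' RBE values, the sum over biomarkers of squared Pearson correlations
#' between each biomarker signal and the photon-equivalent dose
#' D_PE(RBE) = D_P + RBE x D_N.
#'
#' @slot rbeOpt numeric(1), the grid argmax (dimensionless).
#' @slot objectiveGrid data.frame with columns `rbe` and `objective`.
#' @slot featuresUsed character, biomarkers entering the objective.
#' @slot nSamples integer, samples used for the correlations.
#' @export
setClass("RbeFit", representation(rbeOpt = "numeric",
                                  objectiveGrid = "data.frame",
                                  featuresUsed = "character",
                                  nSamples = "integer"))

setValidity("RbeFit", function(object) {
  og <- object@objectiveGrid
  if (!all(c("rbe", "objective") %in% names(og)))
    return("objectiveGrid needs 'rbe' and 'objective' columns")
  best <- og$objective[which.min(abs(og$rbe - object@rbeOpt))]
  if (isTRUE(any(og$objective > best + 1e-8, na.rm = TRUE)))
    return("objective at rbeOpt must be the grid maximum")
  if (isTRUE(any(og$objective < -1e-8, na.rm = TRUE)) ||
      isTRUE(any(og$objective > length(object@featuresUsed) + 1e-8,
                 na.rm = TRUE)))
    return("objective must lie in [0, number of features]")
  TRUE
})

#' @describeIn RbeFit the fitted optimal RBE.
#' @param x,object an `RbeFit`.
#' @export
rbeOpt <- function(x) x@rbeOpt

#' @describeIn RbeFit the objective curve over the RBE grid.
#' @export
objectiveGrid <- function(x) x@objectiveGrid

setMethod("show", "RbeFit", function(object) {
  cat("RbeFit: RBE_opt =", format(object@rbeOpt, digits = 4),
      "over", length(object@featuresUsed), "biomarkers,",
      object@nSamples, "samples\n")
  cat("  objective at optimum:",
      format(max(object@objectiveGrid$objective), digits = 4), "\n")
})

#' ScreenReport: correlation / collinearity feature screen outcome
#'
#' Result of [screenFeatures()]. Partitions the candidate predictors into
#' `retained`, `droppedLowCorrelation` (|r| with D_PE below the threshold),
#' `droppedCollinear` (too many strong correlations with other survivors)
#' and `forcedKept` (Sex, Time: exempt from both filters).
#'
#' @slot retained character.
#' @slot droppedLowCorrelation data.frame (`name`, `r_with_dpe`).
#' @slot droppedCollinear list of character vectors of partners, named by
#'   dropped feature.
#' @slot forcedKept character.
#' @slot rMin,rCollinear numeric thresholds used.
#' @export
setClass("ScreenReport", representation(retained = "character",
                                        droppedLowCorrelation = "data.frame",
                                        droppedCollinear = "list",
                                        forcedKept = "character",
                                        rMin = "numeric",
                                        rCollinear = "numeric"))

setMethod("show", "ScreenReport", function(object) {
  cat("ScreenReport:", length(object@retained), "retained,",
      nrow(object@droppedLowCorrelation), "below |r| =", object@rMin,
      "with D_PE,", length(object@droppedCollinear), "collinear,",
      length(object@forcedKept), "forced kept\n")
})

#' @describeIn ScreenReport retained predictor names (excluding forced).
#' @param x,object a `ScreenReport`.
#' @export
retainedFeatures <- function(x) x@retained

#' BorutaResult: shadow-feature selection outcome
#'
#' Result of [borutaSelect()]. Each feature is `confirmed` (importance beat
#' the 50th percentile of shadow importances significantly more often than
#' chance), `rejected` (significantly less often), or `tentative`.
#'
#' @slot decisions named character, one of confirmed / rejected / tentative.
#' @slot hitCounts named integer, iterations in which the feature beat the
#'   shadow percentile (counted while it was still live).
#' @slot nIterations integer, iterations run.
#' @slot iterationsLive named integer, iterations each feature stayed live.
#' @slot importanceHistory matrix, iterations x (features + shadows);
#'   NA once a feature left the model.
#' @slot thresholdPercentile numeric, shadow percentile (50).
#' @slot alpha numeric, family-wise level before Bonferroni correction.
#' @export
setClass("BorutaResult", representation(decisions = "character",
                                        hitCounts = "integer",
                                        nIterations = "integer",
                                        iterationsLive = "integer",
                                        importanceHistory = "matrix",
                                        thresholdPercentile = "numeric",
                                        alpha = "numeric"))

setValidity("BorutaResult", function(object) {
  if (!all(object@decisions %in% c("confirmed", "rejected", "tentative")))
    return("invalid decision labels")
  if (any(object@hitCounts > object@iterationsLive[names(object@hitCounts)]))
    return("hitCounts cannot exceed iterations a feature was live")
  TRUE
})

#' @describeIn BorutaResult names of confirmed features.
#' @param x,object a `BorutaResult`.
#' @export
confirmedFeatures <- function(x) names(x@decisions)[x@decisions == "confirmed"]

#' @describeIn BorutaResult the full decision vector.
#' @export
borutaDecisions <- function(x) x@decisions

setMethod("show", "BorutaResult", function(object) {
  d <- object@decisions
  cat("BorutaResult after", object@nIterations, "iterations:",
      sum(d == "confirmed"), "confirmed,", sum(d == "rejected"),
      "rejected,", sum(d == "tentative"), "tentative\n")
  if (any(d == "confirmed"))
    cat("  confirmed:", paste(names(d)[d == "confirmed"], collapse = ", "),
        "\n")
})

#' StackingModel: level0/level1 stacked ensemble
#'
#' Result of [fitStack()]. Level0 models are fitted with repeated k-fold
#' cross-validation; each sample's out-of-fold (OOF) predictions, averaged
#' over repeats, form the meta-feature matrix on which the level1 model is
#' trained. Level0 models are then refitted on the full training set for
#' deployment; [predictStack()] runs test samples through the full-train
#' level0 models and maps their outputs through level1.
#'
#' @slot task `"regression"` or `"classification"`.
#' @slot level0Names character, fitted level0 learners.
#' @slot level0Full list of full-train level0 fits.
#' @slot level1 the meta-model fit.
#' @slot level1Name character.
#' @slot oofMatrix samples x level0 numeric matrix of averaged OOF
#'   predictions.
#' @slot foldIds list (per repeat) of integer fold assignments, for leakage
#'   audits.
#' @slot cvScheme list(kFolds, nRepeats, seed).
#' @slot featureNames character, training predictor columns.
#' @export
setClass("StackingModel", representation(task = "character",
                                         level0Names = "character",
                                         level0Full = "list",
                                         level1 = "ANY",
                                         level1Name = "character",
                                         oofMatrix = "matrix",
                                         foldIds = "list",
                                         cvScheme = "list",
                                         featureNames = "character"))

setMethod("show", "StackingModel", function(object) {
  cat("StackingModel (", object@task, "): level0 = ",
      paste(object@level0Names, collapse = ", "),
      "; level1 = ", object@level1Name, "\n", sep = "")
  cat("  CV:", object@cvScheme$kFolds, "folds x",
      object@cvScheme$nRepeats, "repeats;",
      nrow(object@oofMatrix), "training samples\n")
})

#' EvalReport: regression or classification performance report
#'
#' @slot task `"regression"` or `"classification"`.
#' @slot metrics named numeric (RMSE/MAE/R2, or AUC, balanced accuracy,
#'   accuracy, sensitivity, specificity).
#' @slot aucCi numeric(2), 95 percent bootstrap percentile CI (classification).
#' @slot nBootstrap integer.
#' @slot confusion 2x2 integer matrix (classification).
#' @slot subgroupErrors data.frame (`group`, `n`, `n_misclassified`).
#' @export
setClass("EvalReport", representation(task = "character",
                                      metrics = "numeric",
                                      aucCi = "numeric",
                                      nBootstrap = "integer",
                                      confusion = "matrix",
                                      subgroupErrors = "data.frame"))

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport (", object@task, "):\n", sep = "")
  m <- object@metrics
  for (nm in names(m))
    cat("  ", format(nm, width = 18), format(m[[nm]], digits = 4), "\n")
  if (object@task == "classification" && length(object@aucCi) == 2)
    cat("   AUC 95% CI: (", format(object@aucCi[1], digits = 4), ", ",
        format(object@aucCi[2], digits = 4), ") from ",
        object@nBootstrap, " bootstraps\n", sep = "")
})

#' @describeIn EvalReport named metric vector.
#' @param x,object an `EvalReport`.
#' @export
evalMetrics <- function(x) x@metrics
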