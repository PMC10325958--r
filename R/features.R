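.GENES_CT_DOWN <- c("Lrg1", "Phlda3", "Rhoc")          # upregulated genes
.GENES_CT_UP <- c("Ccr7", "Cd19", "Cxcr5", "Ly6d")     # downregulated genes

.geomMean <- function(x) exp(mean(log(x)))

#' Gene net signal from qRT-PCR C_T values
#'
#' The seven-gene summary score: the geometric mean of the C_T values of
#' the genes whose C_T decreases with dose (Lrg1, Phlda3, Rhoc — the
#' radiation-upregulated group) minus the geometric mean of the genes whose
#' C_T increases with dose (Ccr7, Cd19, Cxcr5, Ly6d). Computed on the C_T
#' scale directly; invariant to gene order within each group.
#'
#' @param ct named numeric vector of C_T values containing all seven genes,
#'   or a genes x samples matrix with gene rownames.
#' @return numeric net signal, one value per sample.
#' @examples
#' geneNetSignal(c(Lrg1 = 8, Phlda3 = 2, Rhoc = 4,
#'                 Ccr7 = 1, Cd19 = 1, Cxcr5 = 1, Ly6d = 1))  # 3
#' @export
geneNetSignal <- function(ct) {
  if (is.matrix(ct)) {
    return(apply(ct, 2, function(col)
      geneNetSignal(setNames(col, rownames(ct)))))
  }
  genes <- c(.GENES_CT_DOWN, .GENES_CT_UP)
  miss <- setdiff(genes, names(ct))
  if (length(miss))
    stop("missing genes: ", paste(miss, collapse = ", "))
  ct <- ct[genes]
  if (any(!is.finite(ct)) || any(ct <= 0))
    stop("C_T values must be positive (geometric mean undefined)")
  .geomMean(ct[.GENES_CT_DOWN]) - .geomMean(ct[.GENES_CT_UP])
}

#' Append the gene net signal to a panel
#'
#' Adds a `gene_net_sig` feature (category `derived`) computed per sample
#' from the seven gene rows with [geneNetSignal()].
#'
#' @param panel a [BiomarkerPanel-class] containing the seven gene rows.
#' @return the panel with one extra row.
#' @export
addGeneNetSignal <- function(panel) {
  genes <- c(.GENES_CT_DOWN, .GENES_CT_UP)
  miss <- setdiff(genes, rownames(panel))
  if (length(miss))
    stop("missing genes: ", paste(miss, collapse = ", "))
  ct <- SummarizedExperiment::assay(panel, "signal")[genes, , drop = FALSE]
  .appendFeature(panel, "gene_net_sig", geneNetSignal(ct),
                 category = "derived", scale = "identity")
}

.appendFeature <- function(panel, name, values, category, scale) {
  if (name %in% rownames(panel))
    stop("feature already present: ", name)
  sig <- rbind(SummarizedExperiment::assay(panel, "signal"),
               matrix(values, nrow = 1, dimnames = list(name, NULL)))
  rd <- SummarizedExperiment::rowData(panel)
  BiomarkerPanel(sig, exposureDesign(panel),
                 category = c(rd$category, category),
                 scale = c(rd$scale, scale))
}

#' ln-transform blood cell counts and add the neutrophil/lymphocyte ratio
#'
#' Replaces each raw blood-count feature (CD45, CD3e, Ly_6G, CD19, or any
#' `blood_count` row on the identity scale) with its natural-log transform
#' `ln_<name>`, and — when both Ly_6G and CD45 are present — adds the
#' ln-transformed neutrophil/lymphocyte ratio `ln_Ly_6G_CD45_ratio`
#' (category `derived`). Raw count columns leave the predictor set.
#'
#' @param panel a [BiomarkerPanel-class].
#' @return the transformed panel.
#' @export
transformCounts <- function(panel) {
  rd <- SummarizedExperiment::rowData(panel)
  raw <- which(rd$category == "blood_count" & rd$scale == "identity")
  if (!length(raw)) return(panel)
  sig <- SummarizedExperiment::assay(panel, "signal")
  counts <- sig[raw, , drop = FALSE]
  bad <- which(counts <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("non-positive count for sample ",
         paste(unique(colnames(counts)[bad[, 2]]), collapse = ", "))
  ln <- log(counts)
  rownames(ln) <- paste0("ln_", rownames(counts))
  out_sig <- rbind(sig[-raw, , drop = FALSE], ln)
  category <- c(rd$category[-raw], rep("blood_count", nrow(ln)))
  scale <- c(rd$scale[-raw], rep("ln", nrow(ln)))
  if (all(c("Ly_6G", "CD45") %in% rownames(counts))) {
    ratio <- log(counts["Ly_6G", ] / counts["CD45", ])
    out_sig <- rbind(out_sig,
                     matrix(ratio, nrow = 1,
                            dimnames = list("ln_Ly_6G_CD45_ratio", NULL)))
    category <- c(category, "derived")
    scale <- c(scale, "ln")
  }
  BiomarkerPanel(out_sig, exposureDesign(panel), category, scale)
}

#' Attach blood counts by random matching of individuals
#'
#' Blood cell counts measured on separate animals are joined to the omics
#' samples by randomly matching individuals within the same
#' (exposure group, sampling time) stratum: donors are drawn without
#' replacement until a stratum's donor pool is exhausted, then the pool is
#' reshuffled (so reuse only starts once every donor has been used).
#' Matching never crosses strata. Fully reproducible under `seed`.
#'
#' @param panel recipient [BiomarkerPanel-class] (omics samples).
#' @param countPanel donor [BiomarkerPanel-class] carrying `blood_count`
#'   features measured on its own animals.
#' @param seed integer.
#' @return `panel` with the donor blood-count rows appended and a
#'   `count_donor` column added to its exposure design.
#' @export
matchBloodCounts <- function(panel, countPanel, seed) {
  rd <- SummarizedExperiment::rowData(countPanel)
  crows <- which(rd$category == "blood_count")
  if (!length(crows)) stop("countPanel has no blood_count features")
  rec <- exposureDesign(panel)
  don <- exposureDesign(countPanel)
  rec_str <- paste(rec$group, rec$time_days, sep = "|")
  don_str <- paste(don$group, don$time_days, sep = "|")
  miss <- setdiff(unique(rec_str), unique(don_str))
  if (length(miss))
    stop("no count donors for strata: ", paste(miss, collapse = ", "))

  set.seed(as.integer(seed) %% .Machine$integer.max)
  donor_of <- character(nrow(rec))
  for (s in sort(unique(rec_str))) {
    r_idx <- which(rec_str == s)
    pool <- colnames(countPanel)[don_str == s]
    seq_don <- character(0)
    while (length(seq_don) < length(r_idx))
      seq_don <- c(seq_don, if (length(pool) > 1) sample(pool) else pool)
    donor_of[r_idx] <- seq_don[seq_along(r_idx)]
  }
  counts <- SummarizedExperiment::assay(countPanel, "signal")[
    crows, donor_of, drop = FALSE]
  colnames(counts) <- colnames(panel)
  sig <- rbind(SummarizedExperiment::assay(panel, "signal"), counts)
  prd <- SummarizedExperiment::rowData(panel)
  rec$count_donor <- donor_of
  BiomarkerPanel(sig, rec,
                 category = c(prd$category, rd$category[crows]),
                 scale = c(prd$scale, rd$scale[crows]))
}

#' Assemble the samples x predictors matrix for modelling
#'
#' Collects the modelling predictors: metabolites, (ln) blood counts and
#' derived features (gene net signal, ln neutrophil/lymphocyte ratio), plus
#' the demographic columns `Sex` (Female = 0, Male = 1) and `Time` (days).
#' Per-gene C_T columns are excluded by default — the seven genes are
#' summarised by `gene_net_sig` — but can be kept.
#'
#' @param panel a [BiomarkerPanel-class] after feature engineering.
#' @param useGeneNetSignalOnly logical; if FALSE, raw per-gene C_T columns
#'   are also included.
#' @param exclude character, feature names to drop (e.g. `"CD19"` for the
#'   no-CD19 ablation; matches ln-transformed names too).
#' @return numeric matrix, samples x predictors.
#' @export
buildPredictorMatrix <- function(panel, useGeneNetSignalOnly = TRUE,
                                 exclude = character()) {
  rd <- SummarizedExperiment::rowData(panel)
  cats <- c("metabolite_serum", "metabolite_urine", "blood_count", "derived",
            if (!useGeneNetSignalOnly) "gene")
  keep <- rd$category %in% cats
  x <- t(SummarizedExperiment::assay(panel, "signal")[keep, , drop = FALSE])
  if (length(exclude)) {
    drop <- colnames(x) %in% c(exclude, paste0("ln_", exclude))
    x <- x[, !drop, drop = FALSE]
  }
  exp_df <- exposureDesign(panel)
  cbind(x, Sex = exp_df$sex, Time = exp_df$time_days)
}

#' Correlation and collinearity screen of candidate predictors
#'
#' Two-step filter computed on training data only. Step 1 drops predictors
#' whose Pearson correlation with the photon-equivalent dose satisfies
#' `|r| < rMin` (inclusive retention at the threshold). Step 2 reduces
#' multicollinearity among the survivors: any predictor with `|r| >=
#' rCollinear` against at least `severalMin` other surviving predictors
#' qualifies for removal; the worst offender (most such partners, ties
#' broken toward the weaker |r| with dose, then alphabetically) is removed
#' and the counts recomputed until none qualifies. Predictors named in
#' `forced` (by default Sex and Time) are exempt from both steps and
#' reported as `forcedKept`.
#'
#' @param x samples x predictors numeric matrix
#'   (see [buildPredictorMatrix()]).
#' @param dpe numeric, photon-equivalent dose per sample; must not be
#'   constant.
#' @param rMin minimum absolute correlation with `dpe` (default 0.3).
#' @param rCollinear collinearity threshold (default 0.7).
#' @param severalMin how many strong partners constitute "several"
#'   (default 2).
#' @param forced predictor names exempt from filtering.
#' @return A [ScreenReport-class].
#' @export
screenFeatures <- function(x, dpe, rMin = 0.3, rCollinear = 0.7,
                           severalMin = 2, forced = c("Sex", "Time")) {
  stopifnot(is.matrix(x), nrow(x) == length(dpe))
  if (sd(dpe) == 0) stop("dpe is constant; cannot screen")
  feats <- colnames(x)
  forced <- intersect(forced, feats)
  cand <- setdiff(feats, forced)

  r_dpe <- setNames(rep(NA_real_, length(feats)), feats)
  for (f in feats) {
    v <- x[, f]
    r_dpe[f] <- if (sd(v) == 0) 0 else cor(v, dpe)
  }
  eps <- 1e-9   # guard FP wobble at the inclusive thresholds
  low <- cand[abs(r_dpe[cand]) < rMin - eps]
  surv <- setdiff(cand, low)

  dropped_coll <- list()
  repeat {
    live <- c(surv, forced)
    if (length(surv) == 0 || length(live) < 2) break
    cm <- abs(cor(x[, live, drop = FALSE]))
    diag(cm) <- 0
    n_part <- vapply(surv, function(f)
      sum(cm[f, ] >= rCollinear - eps), integer(1))
    qual <- surv[n_part >= severalMin]
    if (!length(qual)) break
    ord <- order(-n_part[qual], abs(r_dpe[qual]), qual)
    worst <- qual[ord[1]]
    dropped_coll[[worst]] <- live[cm[worst, live] >= rCollinear - eps]
    surv <- setdiff(surv, worst)
  }
  methods::new("ScreenReport",
               retained = surv,
               droppedLowCorrelation = data.frame(
                 name = low, r_with_dpe = unname(r_dpe[low]),
                 stringsAsFactors = FALSE),
               droppedCollinear = dropped_coll,
               forcedKept = forced,
               rMin = rMin, rCollinear = rCollinear)
}
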