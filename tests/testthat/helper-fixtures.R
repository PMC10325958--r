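# Shared fixture builders. Everything is generated in code; no data files.

# A minimal exposure table with arbitrary, non-collinear photon/neutron doses.
makeExposures <- function(dp, dn, time = 1L, sex = 0L,
                          group = paste0("g", seq_along(dp))) {
  data.frame(sample_id = sprintf("S%02d", seq_along(dp)),
             group = group, photon_dose_Gy = dp, neutron_dose_Gy = dn,
             time_days = time, sex = sex, stringsAsFactors = FALSE)
}

# A panel built directly from a feature matrix (features x samples).
makePanel <- function(signal, exposures, category, scale = "identity") {
  colnames(signal) <- exposures$sample_id
  BiomarkerPanel(signal, exposures, category = category, scale = scale)
}

# Biomarker specs where every biomarker shares one true RBE, with all
# non-dose variation (noise, time and sex effects) suppressed to noiseScale.
sharedRbeSpecs <- function(rbe, noiseScale = 1) {
  sp <- defaultBiomarkerSpecs()
  sp$true_rbe <- rbe
  sp$noise_sd <- sp$noise_sd * noiseScale
  sp$time_effect <- sp$time_effect * noiseScale
  sp$sex_effect <- sp$sex_effect * noiseScale
  sp
}

# A compact design (one animal count per group) for fast cohort tests.
smallDesign <- function(n_per_group = 5L) {
  d <- defaultDesign()
  d$groups$n_animals <- rep(n_per_group, nrow(d$groups))
  d
}

# Construct a vector with an exact sample Pearson correlation r to `ref`,
# by Gram-Schmidt: combine standardized ref with an orthogonal residual.
vectorWithCorrelation <- function(ref, r, seed = 1) {
  set.seed(seed)
  z <- rnorm(length(ref))
  z <- residuals(lm(z ~ ref))
  z <- z / sd(z)
  refs <- (ref - mean(ref)) / sd(ref)
  r * refs + sqrt(1 - r^2) * z
}

# Independent brute-force oracle for the RBE objective: plain loops, no
# shared code with estimateRbe().
bruteForceRbe <- function(dp, dn, signal, lo = 0.05, hi = 10, step = 0.001) {
  grid <- seq(lo, hi, by = step)
  best <- NA_real_; best_obj <- -Inf
  for (r in grid) {
    dpe <- dp + r * dn
    if (sd(dpe) == 0) next
    obj <- 0
    for (i in seq_len(nrow(signal)))
      obj <- obj + cor(dpe, signal[i, ])^2
    if (obj > best_obj + 1e-12) { best_obj <- obj; best <- r }
  }
  list(rbe = best, objective = best_obj)
}
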