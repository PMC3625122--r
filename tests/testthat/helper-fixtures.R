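# Shared fixtures built in code.

# A pattern set with known structure: orthonormal templates (via QR) plus
# optional condition-specific noise; one row per (run, condition, stimulus).
make_patterns <- function(n_runs = 4, n_vox = 12,
                          conditions = c("AV_congruent", "AV_incongruent",
                                         "V", "A"),
                          gains = c(AV_congruent = 1, AV_incongruent = 1,
                                    V = 1, A = 0),
                          noise_sd = c(AV_congruent = 0, AV_incongruent = 0,
                                       V = 0, A = 0),
                          intercept = 0, seed = 1, orthogonal = TRUE) {
  set.seed(seed)
  tm <- matrix(rnorm(4 * n_vox), 4, n_vox)
  if (orthogonal && n_vox >= 5) {
    # orthogonal to each other and to the constant vector, so Pearson
    # correlations between templates are exactly zero
    q <- qr.Q(qr(cbind(1, t(tm))))
    tm <- t(q[, 2:5, drop = FALSE])
  }
  tm <- tm / sqrt(rowSums(tm^2))
  rows <- expand.grid(stimulus = 0:3, condition = conditions,
                      run = 0:(n_runs - 1), stringsAsFactors = FALSE)
  g <- gains[rows$condition]
  sig <- noise_sd[rows$condition]
  gn <- ifelse(g > 0, g, 1)
  eta <- matrix(rnorm(nrow(rows) * n_vox), nrow(rows), n_vox) * sig
  v <- tm[rows$stimulus + 1L, , drop = FALSE] * g + eta * gn + intercept
  pattern_set(v, rows$stimulus, rows$run, rows$condition, "testROI")
}

# Simulate one subject at the pattern level and return the tidy metrics.
simulate_subject_metrics <- function(noise_sd, n_runs = 18, n_vox = 150,
                                     seed = 1,
                                     conditions = names(noise_sd),
                                     gains = c(AV_congruent = 1,
                                               AV_incongruent = 1,
                                               V = 1, A = 0),
                                     analyses = list(roi_decoding = FALSE,
                                                     reliability = TRUE,
                                                     similarity = TRUE,
                                                     univariate = TRUE)) {
  spec <- design_spec(n_runs = n_runs)
  seeds <- avmvpa:::derive_seeds(seed, 3)
  des <- generate_design(spec, seeds[1])
  tr <- ground_truth(gains = gains, noise_sd = noise_sd,
                     n_voxels = n_vox, seed = seeds[2])
  ps <- generate_trial_patterns(tr, des, "ROI", seeds[3])
  analyze_subject_rois(list(V2 = ps), analyses = analyses,
                       conditions = conditions)
}
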