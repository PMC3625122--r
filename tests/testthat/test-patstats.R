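test_that("Fisher z matches closed-form values and is odd", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5493, tolerance = 1e-4)
  expect_equal(fisher_z(0.5), atanh(0.5))
  r <- c(-0.9, -0.2, 0.3, 0.7)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_error(fisher_z(1.5), "not a correlation")
  expect_true(is.finite(fisher_z(1)))
})

test_that("split-half reliability reproduces a hand-computed example", {
  # stimulus 0: odd-run mean (1,2,3), even-run mean (1,2,4)
  v <- rbind(c(1, 2, 3), c(1, 2, 4),
             c(5, 1, 2), c(5, 1, 2),
             c(2, 7, 1), c(2, 7, 1),
             c(0, 3, 9), c(0, 3, 9))
  ps <- pattern_set(v, rep(0:3, each = 2), rep(0:1, times = 4),
                    rep("V", 8))
  rel <- pattern_reliability(ps)
  zs <- attr(rel, "per_stimulus")$V
  # pencil oracle: r = 3 / sqrt(2 * 42/9) = 0.9820, z = atanh(r) = 2.350
  expect_equal(zs[1], 2.350, tolerance = 1e-3)
  expect_equal(zs[1], atanh(3 / sqrt(2 * 42 / 9)), tolerance = 1e-12)
})

test_that("noiseless patterns give clipped-large reliability above any noisy case", {
  clean <- make_patterns(n_runs = 4)
  noisy <- make_patterns(n_runs = 4,
                         noise_sd = c(AV_congruent = 1, AV_incongruent = 1,
                                      V = 1, A = 1))
  rc <- pattern_reliability(clean, "V")
  rn <- pattern_reliability(noisy, "V")
  expect_gt(rc$value, 10)           # atanh near 1 under the clip bound
  expect_gt(rc$value, rn$value)
})

test_that("higher pattern noise lowers reliability_z across simulated subjects", {
  noise <- c(AV_congruent = 0.6, AV_incongruent = 1.2, V = 0.6, A = 0.6)
  d <- t(vapply(1:30, function(s) {
    st <- simulate_subject_metrics(noise, n_runs = 8, n_vox = 60, seed = s)
    rel <- st[st$metric == "reliability_z", ]
    c(rel$value[rel$condition == "AV_incongruent"],
      rel$value[rel$condition == "V"])
  }, numeric(2)))
  tt <- t.test(d[, 1], d[, 2], paired = TRUE)
  expect_lt(tt$p.value, 0.05)
  expect_lt(mean(d[, 1] - d[, 2]), 0)
})

test_that("similarity is zero for orthogonal templates and scale invariant", {
  ps <- make_patterns(n_runs = 4, n_vox = 16, orthogonal = TRUE)
  sim <- pattern_similarity(ps, "V")
  expect_lt(abs(sim$value), 1e-10)
  scaled <- ps; scaled$vectors <- ps$vectors * 10
  noisy <- make_patterns(n_runs = 4, n_vox = 16,
                         noise_sd = c(AV_congruent = .5, AV_incongruent = .5,
                                      V = .5, A = .5), seed = 5)
  sc <- noisy; sc$vectors <- noisy$vectors * 10
  expect_equal(pattern_similarity(noisy, "V")$value,
               pattern_similarity(sc, "V")$value, tolerance = 1e-12)
})

test_that("mean correction makes inter-stimulus correlations negative", {
  vals <- vapply(1:20, function(s) {
    ps <- make_patterns(n_runs = 4, n_vox = 40, orthogonal = FALSE,
                        noise_sd = c(AV_congruent = .3, AV_incongruent = .3,
                                     V = .3, A = .3), seed = s)
    pattern_similarity(mean_correct(ps), "V")$value
  }, numeric(1))
  expect_lt(mean(vals), -0.1)
  expect_lt(t.test(vals)$p.value, 0.01)
})

test_that("the 16x16 matrix has unit diagonal when noiseless, is symmetric, and A types share no signal", {
  clean <- make_patterns(n_runs = 4, n_vox = 40,
                         gains = c(AV_congruent = 1, AV_incongruent = 1,
                                   V = 1, A = 1))
  M <- full_correlation_matrix(clean)
  expect_equal(dim(M), c(16L, 16L))
  expect_equal(unname(diag(M)), rep(1, 16), tolerance = 1e-12)
  expect_lt(max(abs(M - t(M))), 1e-12)
  # stimulus-major ordering
  expect_equal(rownames(M)[1:4], paste0("s0_", unique(clean$condition)))
  # zero-gain condition: correlations with visual types average to zero
  offs <- replicate(15, {
    s <- sample.int(1e6, 1)
    ps <- make_patterns(n_runs = 6, n_vox = 60,
                        noise_sd = c(AV_congruent = .4, AV_incongruent = .4,
                                     V = .4, A = .4), seed = s)
    M <- full_correlation_matrix(mean_correct(ps))
    a_rows <- grepl("_A$", rownames(M))
    vis <- grepl("_V$", colnames(M))
    mean(M[a_rows, vis])
  })
  expect_lt(abs(mean(offs)), 0.05)
  bad <- make_patterns(n_runs = 2)
  bad <- subset_patterns(bad, !(bad$stimulus == 0 & bad$condition == "V"))
  expect_error(full_correlation_matrix(bad), "missing trial type")
})

test_that("ROI mean amplitude is linear in gain and zero for zero patterns", {
  ps <- make_patterns(n_runs = 3, intercept = 0)
  amp1 <- roi_mean_amplitude(ps)
  ps2 <- ps; ps2$vectors <- ps$vectors * 2
  amp2 <- roi_mean_amplitude(ps2)
  expect_equal(amp2$mean_beta, 2 * amp1$mean_beta, tolerance = 1e-12)
  zero <- ps; zero$vectors[] <- 0
  expect_true(all(roi_mean_amplitude(zero)$mean_beta == 0))
})

test_that("equal gains give no amplitude difference across conditions (null ANOVA)", {
  noise <- c(AV_congruent = 0.7, AV_incongruent = 1.1, V = 0.7, A = 0.7)
  m <- t(vapply(1:15, function(s) {
    st <- simulate_subject_metrics(noise, n_runs = 8, n_vox = 60,
                                   seed = 100 + s)
    amp <- st[st$metric == "mean_beta", ]
    vapply(c("AV_congruent", "AV_incongruent", "V"), function(cc)
      amp$value[amp$condition == cc], numeric(1))
  }, numeric(3)))
  r <- rm_anova_gg(m)
  expect_gt(r$p_gg, 0.05)
})
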