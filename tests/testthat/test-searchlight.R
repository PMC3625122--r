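test_that("sphere offsets match brute-force lattice enumeration", {
  expect_equal(nrow(sphere_offsets(0)), 1L)
  expect_equal(nrow(sphere_offsets(1)), 7L)
  # independent brute force over the bounding lattice
  brute <- function(r) {
    n <- 0L
    for (dx in -r:r) for (dy in -r:r) for (dz in -r:r)
      if (dx^2 + dy^2 + dz^2 <= r^2) n <- n + 1L
    n
  }
  expect_equal(nrow(sphere_offsets(4)), brute(4L))
  expect_equal(nrow(sphere_offsets(4)), 257L)
  expect_equal(nrow(sphere_offsets(2)), brute(2L))
})

test_that("sphere offsets are closed under the 48 signed axis permutations", {
  offs <- sphere_offsets(3)
  key <- function(m) sort(paste(m[, 1], m[, 2], m[, 3]))
  base <- key(offs)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  for (p in perms) for (sx in c(-1, 1)) for (sy in c(-1, 1))
    for (sz in c(-1, 1)) {
      tr <- sweep(offs[, p, drop = FALSE], 2, c(sx, sy, sz), `*`)
      expect_identical(key(tr), base)
    }
  expect_true(any(rowSums(abs(offs)) == 0))  # contains the origin
})

make_sl_fixture <- function(noise_v = 0.5, seed = 3) {
  geom <- brain_geometry(dim = c(10, 12, 5), roi_sizes = c(V1 = 18L))
  spec <- design_spec(n_runs = 4)
  des <- generate_design(spec, seed)
  tr <- ground_truth(geom, noise_sd = c(AV_congruent = 0.7,
                                        AV_incongruent = 1.1,
                                        V = noise_v, A = 0.7),
                     seed = seed + 1)
  bold <- generate_bold_runs(tr, des, geom, noise_sd_ts = 0.3,
                             seed = seed + 2)
  maps <- fit_runwise_glm(bold, mask = geom$grey_mask)
  list(geom = geom, maps = maps)
}

test_that("searchlight accuracy concentrates at the signal and is 0.25 in pure noise", {
  fx <- make_sl_fixture(noise_v = 0.3)
  sl <- searchlight_accuracy_maps(fx$maps, fx$geom$grey_mask, "V",
                                  radius = 2)
  acc <- sl$V
  roi <- fx$geom$roi_masks$V1
  grey <- fx$geom$grey_mask
  # distance of every grey voxel to the ROI
  ric <- which(roi, arr.ind = TRUE)
  gic <- which(grey, arr.ind = TRUE)
  dmin <- apply(gic, 1, function(v)
    sqrt(min(colSums((t(ric) - v)^2))))
  near <- acc[grey][dmin == 0]
  far <- acc[grey][dmin > 2]
  expect_gt(mean(near, na.rm = TRUE), 0.5)
  expect_lt(abs(mean(far, na.rm = TRUE) - 0.25), 0.05)
  expect_true(all(acc[grey] >= 0 & acc[grey] <= 1, na.rm = TRUE))
  expect_true(all(is.na(acc[!grey])))
})

test_that("a searchlight sphere covering exactly an ROI reproduces the ROI accuracy", {
  fx <- make_sl_fixture(noise_v = 0.7, seed = 11)
  geom <- fx$geom
  # craft a mask equal to one radius-1 sphere inside the grey matter
  ctr <- c(5, 6, 3)
  offs <- sphere_offsets(1)
  sph <- array(FALSE, geom$dim)
  sph[sweep(offs, 2, ctr, `+`)] <- TRUE
  stopifnot(all(sph | !sph), all(geom$grey_mask[sph]))
  conds <- "V"
  ps <- extract_patterns(fx$maps, sph, conds, what = "t")
  roi_acc <- jackknife_accuracy(mean_correct(ps), "V")$accuracy
  sl <- searchlight_accuracy_maps(
    fx$maps, sph, conds, radius = 1)
  expect_equal(sl$V[ctr[1], ctr[2], ctr[3]], roi_acc)
})

test_that("accuracy contrasts subtract voxelwise and are antisymmetric", {
  a <- array(runif(60), c(5, 4, 3)); b <- array(runif(60), c(5, 4, 3))
  expect_true(all(accuracy_contrast(a, a) == 0))
  expect_equal(accuracy_contrast(a, b), -accuracy_contrast(b, a))
  expect_error(accuracy_contrast(a, array(0, c(2, 2, 2))), "mismatch")
})

test_that("cluster labelling groups 6-connected voxels correctly", {
  dims <- c(6, 6, 3)
  coords <- rbind(c(1, 1, 1), c(2, 1, 1), c(2, 2, 1),  # one cluster
                  c(5, 5, 2), c(5, 5, 3),              # second cluster
                  c(1, 6, 3))                          # singleton
  lab <- avmvpa:::label_components(coords, dims, 6)
  expect_equal(length(unique(lab)), 3L)
  expect_equal(lab[1], lab[2])
  expect_equal(lab[2], lab[3])
  expect_equal(lab[4], lab[5])
  expect_false(lab[1] == lab[4] || lab[1] == lab[6] || lab[4] == lab[6])
  # diagonal voxels merge under 18- but not 6-connectivity
  diag2 <- rbind(c(1, 1, 1), c(2, 2, 1))
  expect_equal(length(unique(avmvpa:::label_components(diag2, dims, 6))), 2L)
  expect_equal(length(unique(avmvpa:::label_components(diag2, dims, 18))), 1L)
})

test_that("an injected coherent blob is detected as exactly one significant cluster", {
  dims <- c(16, 16, 8)
  mask <- array(TRUE, dims)
  blob <- array(FALSE, dims); blob[6:9, 6:9, 3:5] <- TRUE
  set.seed(21)
  subj <- lapply(1:12, function(i) {
    m <- array(rnorm(prod(dims), 0, 1), dims)
    m[blob] <- m[blob] + 2.5
    m
  })
  ct <- cluster_inference(subj, mask, n_permutations = 300, seed = 5)
  sig <- ct[ct$p_fwe <= 0.05, ]
  expect_equal(nrow(sig), 1L)
  # the significant cluster covers the blob core
  expect_gte(sig$size_voxels, sum(blob) * 0.5)
  expect_true(blob[sig$peak_x + 1L, sig$peak_y + 1L, sig$peak_z + 1L])
})

test_that("cluster inference is invariant to subject order", {
  dims <- c(10, 10, 4); mask <- array(TRUE, dims)
  set.seed(31)
  subj <- lapply(1:8, function(i) array(rnorm(prod(dims)), dims) +
                   0.8 * as.numeric(seq_len(prod(dims)) %% 7 == 0))
  t1 <- cluster_inference(subj, mask, cluster_forming_p = 0.01,
                          n_permutations = 150, seed = 9)
  t2 <- cluster_inference(rev(subj), mask, cluster_forming_p = 0.01,
                          n_permutations = 150, seed = 9)
  expect_equal(as.data.frame(t1)[c("size_voxels", "peak_t")],
               as.data.frame(t2)[c("size_voxels", "peak_t")])
})

test_that("few permutations trigger a resolution warning", {
  dims <- c(4, 4, 2); mask <- array(TRUE, dims)
  subj <- lapply(1:4, function(i) array(rnorm(32), dims))
  expect_warning(cluster_inference(subj, mask, n_permutations = 50),
                 "100 permutations")
})
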