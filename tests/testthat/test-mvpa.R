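test_that("pattern extraction has the documented shape and ordering", {
  # build per-run trial maps by hand: 18 runs, mask of 10 voxels
  dims <- c(5, 2, 1)
  mask <- array(TRUE, dims)
  conds <- c("V")
  maps <- lapply(1:18, function(r) {
    lab <- paste0("s", 0:3, "_V")
    structure(list(tstat = matrix(rnorm(4 * 10), 4, 10,
                                  dimnames = list(lab, NULL)),
                   beta = matrix(0, 4, 10, dimnames = list(lab, NULL)),
                   labels = lab, mask = mask, dim = c(dims, 4)),
              class = "trial_maps")
  })
  ps <- extract_patterns(maps, mask, conds)
  expect_equal(dim(ps$vectors), c(72L, 10L))
  expect_equal(ps$run, rep(0:17, each = 4))
  expect_equal(ps$stimulus, rep(0:3, 18))
  # single-voxel mask returns that voxel's t values
  m1 <- array(FALSE, dims); m1[3] <- TRUE
  ps1 <- extract_patterns(maps, m1, conds)
  expect_equal(as.numeric(ps1$vectors),
               as.numeric(vapply(maps, function(m) m$tstat[, 3], numeric(4))))
  expect_error(extract_patterns(maps, array(FALSE, dims), conds), "empty")
})

test_that("mean correction centres each cell and preserves distances", {
  ps <- make_patterns(n_runs = 3, noise_sd = c(AV_congruent = 0.5,
                                               AV_incongruent = 0.5,
                                               V = 0.5, A = 0.5),
                      intercept = 2, seed = 2)
  mc <- mean_correct(ps)
  for (r in 0:2) for (cc in unique(ps$condition)) {
    i <- ps$run == r & ps$condition == cc
    expect_lt(max(abs(colSums(mc$vectors[i, ]))), 1e-12)
    expect_equal(as.numeric(dist(mc$vectors[i, ])),
                 as.numeric(dist(ps$vectors[i, ])), tolerance = 1e-12)
  }
  # identical rows centre to zero
  ident <- pattern_set(matrix(5, 4, 6), 0:3, rep(0L, 4), rep("V", 4))
  expect_true(all(mean_correct(ident)$vectors == 0))
  # incomplete cell errors
  bad <- subset_patterns(ps, -1)
  expect_error(mean_correct(bad), "incomplete")
})

test_that("the four-way classifier uses six machines and separates clean clusters", {
  set.seed(3)
  centers <- matrix(rnorm(4 * 8, sd = 4), 4, 8)
  mk <- function(n_per) {
    rows <- do.call(rbind, lapply(1:4, function(k)
      centers[rep(k, n_per), ] + matrix(rnorm(n_per * 8, sd = 0.2),
                                        n_per, 8)))
    pattern_set(rows, rep(0:3, each = n_per),
                rep(seq_len(n_per), times = 4) - 1L,
                rep("V", 4 * n_per), check = FALSE)
  }
  pred <- ovo_classify(mk(20), mk(5))
  expect_equal(attr(pred, "n_classifiers"), 6L)
  expect_equal(ovo_n_classifiers(4), 6)
  expect_equal(mean(pred == mk(5)$stimulus), 1.0)
})

test_that("pure-noise train/test converges to chance accuracy 0.25", {
  set.seed(4)
  accs <- replicate(60, {
    tr <- pattern_set(matrix(rnorm(24 * 10), 24, 10), rep(0:3, 6),
                      rep(0:5, each = 4), rep("V", 24), check = FALSE)
    te <- pattern_set(matrix(rnorm(8 * 10), 8, 10), rep(0:3, 2),
                      rep(6:7, each = 4), rep("V", 8), check = FALSE)
    mean(ovo_classify(tr, te) == te$stimulus)
  })
  se <- sqrt(0.25 * 0.75 / (60 * 8))
  expect_lt(abs(mean(accs) - 0.25), 4 * se)
})

test_that("vote ties resolve by summed decision values, verified by enumeration", {
  # training: three tight clusters for classes 0,1,2 at simplex corners and
  # a diffuse class 3; test point equidistant from 0,1,2 engineers a
  # three-way vote tie among them
  base <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(10, 10, 10))
  train <- do.call(rbind, lapply(1:4, function(k)
    base[rep(k, 6), ] + matrix(rnorm(18, sd = 1e-3), 6, 3)))
  trp <- pattern_set(train, rep(0:3, each = 6), rep(0:5, times = 4),
                     rep("V", 24), check = FALSE)
  test_pt <- matrix(c(1/3, 1/3, 1/3), 1, 3)
  tep <- pattern_set(test_pt, 0L, 99L, "V", check = FALSE)
  pred <- ovo_classify(trp, tep)
  votes <- attr(pred, "votes"); dsum <- attr(pred, "decision")
  # reconstruct the decision from the reported vote/decision tables
  cand <- which(votes[1, ] == max(votes[1, ]))
  if (length(cand) > 1L) cand <- cand[dsum[1, cand] == max(dsum[1, cand])]
  expect_equal(as.integer(pred[1]), as.integer(colnames(votes)[min(cand)]))
  # independent oracle: enumerate the six pairwise machines directly
  votes2 <- setNames(numeric(4), 0:3); d2 <- setNames(numeric(4), 0:3)
  for (p in combn(0:3, 2, simplify = FALSE)) {
    sel <- trp$stimulus %in% p
    fit <- e1071::svm(trp$vectors[sel, ],
                      factor(trp$stimulus[sel], levels = p),
                      kernel = "linear", cost = 1, scale = FALSE)
    pr <- predict(fit, test_pt, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    first <- strsplit(colnames(dv)[1], "/")[[1]][1]
    d <- if (identical(first, as.character(p[1]))) dv[1] else -dv[1]
    win <- if (d > 0) p[1] else p[2]
    votes2[as.character(win)] <- votes2[as.character(win)] + 1
    d2[as.character(p[1])] <- d2[as.character(p[1])] + d
    d2[as.character(p[2])] <- d2[as.character(p[2])] - d
  }
  expect_equal(unname(votes[1, ]), unname(votes2))
  cand2 <- which(votes2 == max(votes2))
  if (length(cand2) > 1L) cand2 <- cand2[d2[cand2] == max(d2[cand2])]
  expect_equal(as.integer(pred[1]), as.integer(names(votes2)[min(cand2)]))
})

test_that("degenerate training data returns a label without crashing", {
  v <- matrix(1, 8, 3)
  trp <- pattern_set(v, rep(0:3, 2), rep(0:1, each = 4), rep("V", 8),
                     check = FALSE)
  tep <- pattern_set(matrix(1, 2, 3), c(0L, 1L), c(9L, 9L), c("V", "V"),
                     check = FALSE)
  expect_no_error(pred <- ovo_classify(trp, tep))
  expect_true(all(pred %in% 0:3))
})

test_that("leave-one-run-out uses one fold per run and is perfect on noiseless templates", {
  ps <- make_patterns(n_runs = 18, noise_sd = c(AV_congruent = 0,
                                                AV_incongruent = 0,
                                                V = 0, A = 0))
  jk <- jackknife_accuracy(ps, "V")
  expect_equal(jk$n_folds, 18L)
  expect_equal(length(jk$fold_accuracy), 18L)
  expect_equal(jk$accuracy, 1.0)
  one_run <- subset_patterns(ps, ps$run == 0)
  expect_error(jackknife_accuracy(one_run, "V"), ">= 2 runs")
})

test_that("label permutation yields chance-level jackknife accuracy", {
  ps <- make_patterns(n_runs = 4, n_vox = 8,
                      noise_sd = c(AV_congruent = 0.8, AV_incongruent = 0.8,
                                   V = 0.8, A = 0.8), seed = 6)
  sub <- subset_patterns(ps, ps$condition == "V")
  set.seed(7)
  accs <- replicate(400, {
    shuf <- sub
    for (r in 0:3) {
      i <- which(shuf$run == r)
      shuf$stimulus[i] <- sample(shuf$stimulus[i])
    }
    jackknife_accuracy(shuf, "V")$accuracy
  })
  se <- sqrt(0.25 * 0.75 / (400 * 16))
  expect_lt(abs(mean(accs) - 0.25), 4 * se)
})

test_that("two SVM implementations agree on decoding accuracy", {
  skip_if_not_installed("kernlab")
  # pooled over datasets so that the comparison resolves below 0.01 (a
  # single fold only has 4 test decisions)
  acc_pair <- vapply(1:6, function(sd) {
    ps <- make_patterns(n_runs = 12, n_vox = 30,
                        noise_sd = c(AV_congruent = 0.8,
                                     AV_incongruent = 0.8,
                                     V = 0.8, A = 0.8), seed = sd + 20)
    mc <- mean_correct(ps)
    sub <- subset_patterns(mc, mc$condition == "V")
    runs <- sort(unique(sub$run))
    rowMeans(vapply(runs, function(r) {
      tr <- subset_patterns(sub, sub$run != r)
      te <- subset_patterns(sub, sub$run == r)
      a1 <- mean(ovo_classify(tr, te) == te$stimulus)
      fit <- kernlab::ksvm(tr$vectors, factor(tr$stimulus),
                           kernel = "vanilladot", C = 1, scaled = FALSE,
                           kpar = list())
      a2 <- mean(as.integer(as.character(
        kernlab::predict(fit, te$vectors))) == te$stimulus)
      c(a1, a2)
    }, numeric(2)))
  }, numeric(2))
  expect_lte(abs(mean(acc_pair[1, ]) - mean(acc_pair[2, ])), 0.01 + 1e-9)
})
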