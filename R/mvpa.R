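#' Extract ROI patterns from trial maps
#'
#' Masks per-run trial t-maps (or betas) with an ROI and vectorises them
#' into a [pattern_set()]. Row order is deterministic: run-major, then
#' condition in design order, then stimulus. Voxel order is the mask's scan
#' order (x fastest, the array's linear order).
#'
#' @param maps A list of `trial_maps` (one per run, as from
#'   [fit_runwise_glm()]).
#' @param roi_mask Logical array; must be contained in the mask the GLM
#'   was fitted over.
#' @param conditions Condition labels in design order.
#' @param what `"t"` for t-patterns (decoding/correlations) or `"beta"`.
#' @param roi ROI name for the result.
#' @return A [pattern_set()].
#' @export
extract_patterns <- function(maps, roi_mask, conditions, what = c("t", "beta"),
                             roi = "ROI") {
  what <- match.arg(what)
  if (sum(roi_mask) == 0L) stop("empty ROI mask")
  glm_mask <- maps[[1]]$mask
  if (is.null(glm_mask)) stop("trial maps carry no mask")
  if (any(roi_mask & !glm_mask)) stop("ROI mask extends outside GLM mask")
  cols <- which(which(glm_mask) %in% which(roi_mask))
  vecs <- list(); stim <- integer(0); run <- integer(0); cond <- character(0)
  for (ri in seq_along(maps)) {
    mp <- maps[[ri]]
    M <- if (what == "t") mp$tstat else mp$beta
    lab <- mp$labels
    for (cc in conditions) {
      for (s in 0:3) {
        j <- match(paste0("s", s, "_", cc), lab)
        if (is.na(j)) next
        vecs[[length(vecs) + 1L]] <- M[j, cols]
        stim <- c(stim, s); run <- c(run, ri - 1L); cond <- c(cond, cc)
      }
    }
  }
  pattern_set(do.call(rbind, vecs), stim, run, cond, roi)
}

#' Mean-correct patterns across stimuli within condition
#'
#' Subtracts, within every (run, condition) cell, the voxelwise mean of the
#' four stimulus patterns from each of them, so the cell's patterns sum to
#' zero per voxel. This removes any intercept common to the stimuli without
#' changing the geometry of the pattern distribution (pairwise distances
#' are preserved), and it is what makes inter-stimulus correlations of the
#' corrected patterns negative in expectation. With `by_run = FALSE` the
#' mean is instead pooled across all runs of a condition.
#'
#' @param ps A [pattern_set()]; each (run, condition) cell must contain all
#'   four stimuli (each condition cell, when pooled).
#' @param by_run Correct per (run, condition) cell (default) or per
#'   condition pooled across runs.
#' @return A mean-corrected [pattern_set()].
#' @export
mean_correct <- function(ps, by_run = TRUE) {
  v <- ps$vectors
  grp <- if (by_run) paste(ps$run, ps$condition) else ps$condition
  n_stim <- length(unique(ps$stimulus))
  for (g in unique(grp)) {
    i <- which(grp == g)
    if (by_run && length(i) != n_stim)
      stop("incomplete (run, condition) cell: ", g)
    v[i, ] <- sweep(v[i, , drop = FALSE], 2, colMeans(v[i, , drop = FALSE]))
  }
  out <- ps
  out$vectors <- v
  out
}

# Orient a binary SVM decision value so that positive favours `pos_label`.
# e1071 names the decision-value column "<a>/<b>" with positive favouring a.
oriented_decision <- function(dv, pos_label) {
  nm <- colnames(dv)[1]
  first <- strsplit(nm, "/", fixed = TRUE)[[1]][1]
  if (identical(first, as.character(pos_label))) dv[, 1] else -dv[, 1]
}

#' Four-way one-against-one SVM classification
#'
#' The four-way classifier is six binary linear support vector machines
#' (cost `C`, no kernel, no feature scaling), one per unordered stimulus
#' pair. Each test pattern receives one vote per machine; the prediction is
#' the label with most votes. Ties are broken by the largest sum of signed
#' decision values among the tied labels, then by the lowest stimulus
#' index. Degenerate training data never crashes: a pair whose machine
#' cannot be fit contributes a zero decision value and votes for its
#' lower-indexed label.
#'
#' @param train,test [pattern_set()]s with equal voxel counts; `train`
#'   must contain all stimulus labels.
#' @param cost SVM cost parameter C.
#' @return Integer vector of predicted stimulus labels for the test rows,
#'   with attributes `votes` and `decision` (test rows x labels).
#' @export
ovo_classify <- function(train, test, cost = 1) {
  labs <- sort(unique(train$stimulus))
  if (length(labs) < 2L) stop("training data must contain >= 2 classes")
  if (ncol(train$vectors) != ncol(test$vectors))
    stop("train/test voxel counts differ")
  nt <- nrow(test$vectors)
  votes <- matrix(0, nt, length(labs), dimnames = list(NULL, labs))
  dsum <- matrix(0, nt, length(labs), dimnames = list(NULL, labs))
  pairs <- utils::combn(labs, 2)
  for (p in seq_len(ncol(pairs))) {
    a <- pairs[1, p]; b <- pairs[2, p]
    sel <- train$stimulus %in% c(a, b)
    x <- train$vectors[sel, , drop = FALSE]
    y <- factor(train$stimulus[sel], levels = c(a, b))
    d <- tryCatch({
      fit <- e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE)
      pr <- stats::predict(fit, test$vectors, decision.values = TRUE)
      oriented_decision(attr(pr, "decision.values"), a)
    }, error = function(e) rep(0, nt))
    va <- d > 0 | (d == 0 & a < b)   # zero decision -> lower index
    votes[, as.character(a)] <- votes[, as.character(a)] + va
    votes[, as.character(b)] <- votes[, as.character(b)] + !va
    dsum[, as.character(a)] <- dsum[, as.character(a)] + d
    dsum[, as.character(b)] <- dsum[, as.character(b)] - d
  }
  pred <- integer(nt)
  for (i in seq_len(nt)) {
    cand <- which(votes[i, ] == max(votes[i, ]))
    if (length(cand) > 1L) {
      cand <- cand[dsum[i, cand] == max(dsum[i, cand])]
    }
    pred[i] <- labs[min(cand)]
  }
  structure(pred, votes = votes, decision = dsum,
            n_classifiers = ncol(pairs))
}

#' Number of pairwise machines in a k-way one-against-one classifier
#' @param k Number of classes.
#' @return `choose(k, 2)`.
#' @export
ovo_n_classifiers <- function(k) choose(k, 2)

#' Leave-one-run-out jackknife decoding accuracy
#'
#' Condition-specific four-way decoding: in each fold, the condition's
#' patterns from all runs but one train the one-against-one classifier and
#' the held-out run's four patterns are tested. Accuracy is the unweighted
#' mean over folds of the fraction correct; chance is 1/4.
#'
#' @param ps A (typically mean-corrected) [pattern_set()].
#' @param condition Condition label to decode within.
#' @param cost SVM cost parameter.
#' @return List: `accuracy`, `fold_accuracy`, `n_folds`.
#' @export
jackknife_accuracy <- function(ps, condition, cost = 1) {
  sel <- ps$condition == condition
  if (!any(sel)) stop("condition not present: ", condition)
  sub <- subset_patterns(ps, sel)
  runs <- sort(unique(sub$run))
  if (length(runs) < 2L) stop("need >= 2 runs for leave-one-run-out")
  fold_acc <- vapply(runs, function(r) {
    tr <- subset_patterns(sub, sub$run != r)
    te <- subset_patterns(sub, sub$run == r)
    pred <- ovo_classify(tr, te, cost = cost)
    mean(pred == te$stimulus)
  }, numeric(1))
  list(accuracy = mean(fold_acc), fold_accuracy = fold_acc,
       n_folds = length(runs))
}

#' Condition-wise decoding accuracies for one pattern set
#'
#' @param ps A [pattern_set()] (mean-correct it first).
#' @param conditions Conditions to decode (default: all present).
#' @param cost SVM cost parameter.
#' @return Data frame with columns `roi`, `condition`, `accuracy`,
#'   `n_folds`.
#' @export
decode_conditions <- function(ps, conditions = unique(ps$condition),
                              cost = 1) {
  rows <- lapply(conditions, function(cc) {
    jk <- jackknife_accuracy(ps, cc, cost = cost)
    data.frame(roi = ps$roi, condition = cc, accuracy = jk$accuracy,
               n_folds = jk$n_folds, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
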