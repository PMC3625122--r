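#' Fisher z-transform of a correlation
#'
#' `atanh` with the argument clipped to +/-(1 - 1e-12) so that perfectly
#' correlated (e.g. noiseless) patterns give a large finite value rather
#' than infinity.
#'
#' @param r Correlation(s) in \[-1, 1\].
#' @return Fisher z value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-15, na.rm = TRUE))
    stop("|r| > 1 is not a correlation")
  atanh(pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12))
}

# odd/even split on 1-based acquisition order: run index 0 is run #1, odd
run_parity_odd <- function(run) (run + 1L) %% 2L == 1L

# mean pattern over a subset of rows; NULL if empty
mean_pattern <- function(ps, sel) {
  if (!any(sel)) return(NULL)
  colMeans(ps$vectors[sel, , drop = FALSE])
}

#' Split-half pattern reliability
#'
#' For each condition and stimulus, the stimulus's patterns are averaged
#' separately over odd and even runs (1-based acquisition order) and the
#' Pearson correlation between the two mean patterns is Fisher
#' z-transformed. The condition's reliability is the mean z over stimuli.
#' Reliability indexes trial-to-trial pattern stability: more pattern noise
#' attenuates the split-half correlation.
#'
#' @param ps A [pattern_set()] (typically mean-corrected).
#' @param conditions Conditions to evaluate (default all present).
#' @return Data frame `roi`, `condition`, `metric = "reliability_z"`,
#'   `value`, with per-stimulus z values in attribute `per_stimulus`.
#'   Stimuli whose mean pattern has zero variance are skipped with a
#'   warning and recorded as `NA` in `per_stimulus`.
#' @export
pattern_reliability <- function(ps, conditions = unique(ps$condition)) {
  odd <- run_parity_odd(ps$run)
  if (!any(odd) || all(odd)) stop("need at least one odd and one even run")
  detail <- list()
  rows <- lapply(conditions, function(cc) {
    zs <- vapply(sort(unique(ps$stimulus)), function(s) {
      sel <- ps$condition == cc & ps$stimulus == s
      mo <- mean_pattern(ps, sel & odd)
      me <- mean_pattern(ps, sel & !odd)
      if (is.null(mo) || is.null(me)) return(NA_real_)
      if (stats::sd(mo) == 0 || stats::sd(me) == 0) {
        warning("zero-variance mean pattern for stimulus ", s,
                " in condition ", cc, "; skipped")
        return(NA_real_)
      }
      fisher_z(stats::cor(mo, me))
    }, numeric(1))
    detail[[cc]] <<- zs
    data.frame(roi = ps$roi, condition = cc, metric = "reliability_z",
               value = mean(zs, na.rm = TRUE), stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), per_stimulus = detail)
}

#' Inter-stimulus pattern similarity
#'
#' For each condition, each stimulus's patterns are averaged over all runs
#' and the six pairwise Pearson correlations between the four mean patterns
#' are Fisher z-transformed; the condition value is their mean. After mean
#' correction the four corrected patterns sum to zero, so these
#' correlations are negative in expectation (about -1/3 for orthogonal
#' templates) regardless of the noise level — similarity tracks the
#' separation structure of the class centroids, not trial noise.
#'
#' @param ps A [pattern_set()].
#' @param conditions Conditions to evaluate.
#' @return Data frame `roi`, `condition`, `metric = "similarity_z"`,
#'   `value`, with the pairwise z values in attribute `per_pair`.
#' @export
pattern_similarity <- function(ps, conditions = unique(ps$condition)) {
  stims <- sort(unique(ps$stimulus))
  if (length(stims) < 2L) stop("need >= 2 stimuli")
  detail <- list()
  rows <- lapply(conditions, function(cc) {
    means <- lapply(stims, function(s)
      mean_pattern(ps, ps$condition == cc & ps$stimulus == s))
    if (any(vapply(means, is.null, logical(1))))
      stop("missing stimulus in condition ", cc)
    prs <- utils::combn(seq_along(stims), 2)
    zs <- apply(prs, 2, function(ij) {
      a <- means[[ij[1]]]; b <- means[[ij[2]]]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) {
        warning("zero-variance mean pattern in condition ", cc, "; skipped")
        return(NA_real_)
      }
      fisher_z(stats::cor(a, b))
    })
    detail[[cc]] <<- zs
    data.frame(roi = ps$roi, condition = cc, metric = "similarity_z",
               value = mean(zs, na.rm = TRUE), stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), per_pair = detail)
}

#' Full 16 x 16 trial-type correlation matrix
#'
#' Correlations between the mean patterns of all 16 (stimulus, condition)
#' trial types. Off-diagonal cells correlate the two types' all-run mean
#' patterns (a symmetric block); diagonal cells are the odd/even split-half
#' correlation within the type. Row/column order is stimulus-major:
#' stimulus 0 in all conditions (design order), then stimulus 1, etc.
#'
#' @param ps A [pattern_set()] containing all 16 trial types.
#' @param conditions Condition order within each stimulus block.
#' @return 16 x 16 matrix with `dimnames` `s<stimulus>_<condition>`.
#' @export
full_correlation_matrix <- function(ps, conditions = unique(ps$condition)) {
  stims <- sort(unique(ps$stimulus))
  types <- expand.grid(condition = conditions, stimulus = stims,
                       stringsAsFactors = FALSE)[, c("stimulus", "condition")]
  nm <- paste0("s", types$stimulus, "_", types$condition)
  k <- nrow(types)
  odd <- run_parity_odd(ps$run)
  all_means <- lapply(seq_len(k), function(i) {
    sel <- ps$stimulus == types$stimulus[i] & ps$condition == types$condition[i]
    if (!any(sel)) stop("missing trial type: ", nm[i])
    mean_pattern(ps, sel)
  })
  M <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) {
    sel <- ps$stimulus == types$stimulus[i] & ps$condition == types$condition[i]
    M[i, i] <- stats::cor(mean_pattern(ps, sel & odd),
                          mean_pattern(ps, sel & !odd))
    if (i < k) for (j in (i + 1L):k) {
      r <- stats::cor(all_means[[i]], all_means[[j]])
      M[i, j] <- r; M[j, i] <- r
    }
  }
  M
}

#' ROI-mean response amplitude per condition
#'
#' Averages the (not mean-corrected) trial betas of the ROI's voxels across
#' stimuli and runs, yielding one scalar amplitude per condition — the
#' univariate signal the multivariate measures are dissociated from.
#'
#' @param maps List of `trial_maps` (per run) or a [pattern_set()] of beta
#'   patterns.
#' @param roi_mask Logical array (required for `trial_maps` input).
#' @param conditions Condition labels.
#' @return Data frame `condition`, `mean_beta`.
#' @export
roi_mean_amplitude <- function(maps, roi_mask = NULL,
                               conditions = NULL) {
  if (inherits(maps, "pattern_set")) {
    ps <- maps
    conditions <- conditions %||% unique(ps$condition)
  } else {
    if (is.null(roi_mask) || sum(roi_mask) == 0L) stop("empty ROI mask")
    if (is.null(conditions)) stop("conditions required for trial_maps input")
    ps <- extract_patterns(maps, roi_mask, conditions, what = "beta")
  }
  rows <- lapply(conditions, function(cc) {
    sel <- ps$condition == cc
    data.frame(condition = cc,
               mean_beta = mean(ps$vectors[sel, , drop = FALSE]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a correlation matrix as a plain-text grid
#' @param M Matrix from [full_correlation_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_correlation_matrix <- function(M, path) {
  utils::write.table(format(M, digits = 6), path, sep = "\t", quote = FALSE)
  invisible(path)
}
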