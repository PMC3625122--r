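#' Construct a pattern set
#'
#' A pattern set holds per-trial voxel vectors with their stimulus, run and
#' condition labels for one ROI. Within every (run, condition) cell there is
#' exactly one row per stimulus.
#'
#' @param vectors Numeric matrix, trials x voxels.
#' @param stimulus Integer stimulus label (0-based) per row.
#' @param run Integer run index (0-based) per row.
#' @param condition Character condition label per row.
#' @param roi ROI name.
#' @param check Validate the one-row-per-(run, condition, stimulus)
#'   invariant.
#' @return Object of class `pattern_set`.
#' @export
pattern_set <- function(vectors, stimulus, run, condition, roi = "ROI",
                        check = TRUE) {
  vectors <- as.matrix(vectors)
  n <- nrow(vectors)
  stopifnot(length(stimulus) == n, length(run) == n, length(condition) == n)
  ps <- structure(list(vectors = vectors,
                       stimulus = as.integer(stimulus),
                       run = as.integer(run),
                       condition = as.character(condition),
                       roi = roi),
                  class = "pattern_set")
  if (check) {
    tab <- table(ps$run, ps$condition, ps$stimulus)
    if (any(tab > 1L))
      stop("duplicate (run, condition, stimulus) rows in pattern set")
  }
  ps
}

#' @export
print.pattern_set <- function(x, ...) {
  cat(sprintf("Pattern set [%s]: %d trials x %d voxels, %d runs, conditions: %s\n",
              x$roi, nrow(x$vectors), ncol(x$vectors),
              length(unique(x$run)),
              paste(unique(x$condition), collapse = ", ")))
  invisible(x)
}

#' Subset a pattern set by row index or condition
#' @param ps A `pattern_set`.
#' @param i Row indices or logical vector.
#' @return A `pattern_set`.
#' @export
subset_patterns <- function(ps, i) {
  pattern_set(ps$vectors[i, , drop = FALSE], ps$stimulus[i], ps$run[i],
              ps$condition[i], ps$roi, check = FALSE)
}

#' Generate per-trial activation patterns
#'
#' Realises the generative model of [ground_truth()] for every stimulus
#' trial of a design: `g(c) * (template_s + eta) + intercept` with `eta`
#' i.i.d. N(0, sigma_c^2) per voxel and trial. When `g(c) = 0` (the
#' auditory-only condition) the pattern is intercept plus noise only, so it
#' carries no stimulus information. Blank trials produce no pattern.
#'
#' @param truth A [ground_truth()].
#' @param design An [generate_design()] result.
#' @param roi ROI name (must exist in `truth$templates`).
#' @param seed Integer seed.
#' @return A [pattern_set()] with one row per stimulus trial, in design
#'   (run-major, onset) order.
#' @export
generate_trial_patterns <- function(truth, design, roi = names(truth$templates)[1],
                                    seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  tm <- truth$templates[[roi]]
  if (is.null(tm)) stop("unknown ROI: ", roi)
  icpt <- truth$intercepts[[roi]]
  ev <- design[!is.na(design$stimulus), , drop = FALSE]
  nv <- ncol(tm)
  n <- nrow(ev)
  g <- truth$gains[ev$condition]
  sig <- truth$noise_sd[ev$condition]
  vec <- with_seed(seed, {
    eta <- matrix(stats::rnorm(n * nv), n, nv) * sig
    # noise enters inside the gain for stimulus-driven conditions; at unit
    # gain when g = 0 so no-visual patterns are baseline + pattern noise
    gn <- ifelse(g > 0, g, 1)
    sigvec <- tm[ev$stimulus + 1L, , drop = FALSE] * g
    sigvec + eta * gn + matrix(icpt, n, nv, byrow = TRUE)
  })
  pattern_set(vec, ev$stimulus, ev$run, ev$condition, roi, check = FALSE)
}
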