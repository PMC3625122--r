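#' Canonical double-gamma haemodynamic response function
#'
#' The canonical HRF as the difference of two gamma densities,
#' `h(t) = dgamma(t; 6, 1) - dgamma(t; 16, 1) / 6`, sampled on \[0, 32\] s
#' at `dt` and scaled to unit peak. Peak latency is about 5 s and the
#' undershoot integral leaves the kernel with positive total area.
#'
#' @param dt Sampling interval in seconds.
#' @return Numeric vector of kernel samples at `seq(0, 32, by = dt)`.
#' @export
canonical_hrf <- function(dt) {
  if (dt <= 0) stop("dt must be positive")
  t <- seq(0, 32, by = dt)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

# HRF-convolved boxcar regressors sampled at volume acquisition times.
# Boxcars are built on an oversampled grid (dt = tr/oversample), convolved
# with the canonical HRF at that resolution, then read out at t = k * tr.
convolved_regressor <- function(onsets, durations, n_volumes, tr,
                                oversample = 16L) {
  dt <- tr / oversample
  n_fine <- n_volumes * oversample
  u <- numeric(n_fine)
  tfine <- (seq_len(n_fine) - 1L) * dt
  for (i in seq_along(onsets)) {
    on <- onsets[i]; off <- on + durations[i]
    u[tfine >= on & tfine < off] <- 1
  }
  h <- canonical_hrf(dt)
  conv <- stats::convolve(u, rev(h), type = "open")[seq_len(n_fine)] * dt
  conv[(seq_len(n_volumes) - 1L) * oversample + 1L]
}

#' Build a run-wise trial design matrix
#'
#' One HRF-convolved boxcar column per trial type present in the run (a
#' trial type is a (stimulus, condition) pair; with the full design that is
#' 16 columns), one column for the blank trials, one for the response
#' intervals (the 2 s post-stimulus windows in which the fixation-task
#' response is given), any nuisance columns, and a constant — at least 19
#' columns for a full run. Convolution is computed at 16x oversampling and
#' sampled at volume acquisition times.
#'
#' @param events Design rows for a single run (dummies already excluded
#'   from the timebase; onsets relative to the first analysed volume).
#' @param n_volumes Number of analysed volumes.
#' @param tr Repetition time (s).
#' @param nuisance Optional numeric matrix of nuisance regressors
#'   (n_volumes rows), e.g. motion parameters.
#' @param isi Response-interval duration appended to each trial (s).
#' @param oversample Temporal oversampling factor for convolution.
#' @return List of class `design_matrix`: `X` (n_volumes x p), `labels`,
#'   and `trial_cols` (named indices of the trial-type columns, labelled
#'   `s<stimulus>_<condition>`).
#' @export
build_design_matrix <- function(events, n_volumes, tr, nuisance = NULL,
                                isi = 2, oversample = 16L) {
  if (length(unique(events$run)) > 1L)
    stop("events must belong to a single run")
  stim_ev <- events[!is.na(events$stimulus), , drop = FALSE]
  blank_ev <- events[is.na(events$stimulus), , drop = FALSE]

  cols <- list(); labels <- character(0)
  if (nrow(stim_ev) > 0L) {
    type <- paste0("s", stim_ev$stimulus, "_", stim_ev$condition)
    for (tt in unique(type)) {
      sel <- type == tt
      cols[[length(cols) + 1L]] <- convolved_regressor(
        stim_ev$onset[sel], stim_ev$duration[sel], n_volumes, tr, oversample)
      labels <- c(labels, tt)
    }
  }
  if (nrow(blank_ev) > 0L) {
    cols[[length(cols) + 1L]] <- convolved_regressor(
      blank_ev$onset, blank_ev$duration, n_volumes, tr, oversample)
    labels <- c(labels, "blank")
  }
  if (nrow(events) > 0L) {
    cols[[length(cols) + 1L]] <- convolved_regressor(
      events$onset + events$duration, rep(isi, nrow(events)), n_volumes, tr,
      oversample)
    labels <- c(labels, "response")
  }
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    stopifnot(nrow(nuisance) == n_volumes)
    for (j in seq_len(ncol(nuisance))) {
      cols[[length(cols) + 1L]] <- nuisance[, j]
      labels <- c(labels, colnames(nuisance)[j] %||% paste0("nuisance", j))
    }
  }
  cols[[length(cols) + 1L]] <- rep(1, n_volumes)
  labels <- c(labels, "constant")

  X <- do.call(cbind, cols)
  colnames(X) <- labels
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- labels[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  trial_cols <- which(labels %in% labels[grepl("^s[0-9]+_", labels)])
  names(trial_cols) <- labels[trial_cols]
  structure(list(X = X, labels = labels, trial_cols = trial_cols,
                 tr = tr, oversample = oversample),
            class = "design_matrix")
}

#' Fit the run-wise general linear model
#'
#' Ordinary least squares per in-mask voxel: `beta = (X'X)^-1 X'y`,
#' residual variance `RSS / df` with `df = n - rank(X)`, and a t-statistic
#' per trial-type column (contrast picking out that column). Trial-type
#' t-patterns feed the decoding and correlation analyses; uncorrected betas
#' feed the univariate amplitude analysis.
#'
#' @param data A 4D array (x, y, z, volumes) or a volumes x voxels matrix.
#' @param dm A [build_design_matrix()] result.
#' @param mask Logical array selecting analysed voxels (required for 4D
#'   input; ignored for matrix input).
#' @param dummies Optional logical vector flagging dummy volumes to drop
#'   before fitting.
#' @return Object of class `trial_maps`: matrices `beta` and `tstat`
#'   (trial types x voxels), `sigma2`, `df`, `labels`, plus `mask`/`dim`
#'   when 4D input was given.
#' @export
fit_glm <- function(data, dm, mask = NULL, dummies = NULL) {
  stopifnot(inherits(dm, "design_matrix"))
  dim4 <- NULL
  if (is.array(data) && length(dim(data)) == 4L) {
    dim4 <- dim(data)
    if (is.null(mask)) stop("mask required for 4D input")
    Y <- t(apply(data, 4, function(v) v[mask]))
    # apply() collapses a single-voxel mask; keep volumes x voxels
    if (sum(mask) == 1L) Y <- matrix(Y, ncol = 1L)
  } else {
    Y <- as.matrix(data)
  }
  if (!is.null(dummies)) {
    stopifnot(length(dummies) == nrow(Y))
    Y <- Y[!dummies, , drop = FALSE]
  }
  X <- dm$X
  if (nrow(Y) != nrow(X))
    stop("data has ", nrow(Y), " volumes but design matrix has ", nrow(X))
  n <- nrow(X); p <- qr(X)$rank
  df <- n - p
  if (df <= 0) stop("non-positive residual degrees of freedom")
  XtX_inv <- chol2inv(chol(crossprod(X)))
  B <- XtX_inv %*% crossprod(X, Y)              # p x V
  res <- Y - X %*% B
  sigma2 <- colSums(res^2) / df
  d <- diag(XtX_inv)
  se <- sqrt(outer(d, sigma2))                  # p x V
  Tmat <- B / se
  Tmat[se == 0] <- 0
  tc <- dm$trial_cols
  structure(list(beta = B[tc, , drop = FALSE],
                 tstat = Tmat[tc, , drop = FALSE],
                 beta_all = B, labels = names(tc),
                 sigma2 = sigma2, df = df,
                 mask = mask, dim = dim4),
            class = "trial_maps")
}

#' Separable 3D Gaussian smoothing
#'
#' Utility for smoothing synthetic volumes (default off everywhere in the
#' pipeline). FWHM is given in the same units as `voxel_size`.
#'
#' @param vol 3D numeric array.
#' @param fwhm Full width at half maximum.
#' @param voxel_size Voxel edge length in the same units as `fwhm`.
#' @return Smoothed array of the same shape.
#' @export
smooth_gaussian <- function(vol, fwhm, voxel_size = 1) {
  if (fwhm <= 0) return(vol)
  sd <- fwhm / (2 * sqrt(2 * log(2))) / voxel_size
  r <- max(1L, ceiling(3 * sd))
  k <- stats::dnorm(-r:r, sd = sd); k <- k / sum(k)
  sm1 <- function(x) {
    n <- length(x)
    xp <- c(rep(x[1], r), x, rep(x[n], r))
    as.numeric(stats::filter(xp, k, sides = 2))[(r + 1):(r + n)]
  }
  for (d in 1:3) {
    margins <- setdiff(1:3, d)
    vol <- aperm(apply(vol, margins, sm1), order(c(d, margins)))
  }
  vol
}
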