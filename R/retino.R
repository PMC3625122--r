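#' Generate phase-encoded retinotopic mapping time series
#'
#' The wedge completes 12 cycles of 20 steps over the run and the ring 20
#' cycles of 12 steps (240 timepoints by default), so a responsive voxel's
#' series is `baseline + amplitude * cos(2*pi*f*t/N - phase) + noise` with
#' f = 12 (wedge) or 20 (ring) cycles per run and a voxel-specific
#' ground-truth phase. Non-responsive grey-matter voxels are baseline plus
#' noise. `snr` parameterises amplitude as `snr * noise_sd` (time-domain
#' amplitude-to-noise ratio); with `noise_sd = 0`, `amplitude` is used
#' directly.
#'
#' @param geometry A [brain_geometry()]; the union of ROI masks is the
#'   responsive set.
#' @param stim `"wedge"` or `"ring"`.
#' @param n_timepoints Volumes in the run; must be a multiple of the cycle
#'   count and hold the stimulus frequency below Nyquist.
#' @param amplitude Response amplitude (used when `noise_sd` is 0 or `snr`
#'   is `NULL`).
#' @param noise_sd White-noise SD.
#' @param snr Optional amplitude/noise ratio overriding `amplitude`.
#' @param baseline Mean signal level.
#' @param truth Optional [ground_truth()] carrying per-voxel phases; drawn
#'   uniformly at random if absent.
#' @param seed Integer seed.
#' @return List of class `retino_series`: 4D `data`, 3D `phase` volume
#'   (ground truth, `NA` off the responsive set), logical `responsive`
#'   mask, and `stim_freq` (cycles per run).
#' @export
generate_retino_series <- function(geometry, stim = c("wedge", "ring"),
                                   n_timepoints = 240L, amplitude = 1,
                                   noise_sd = 0.2, snr = NULL,
                                   baseline = 100, truth = NULL, seed = 1L) {
  stim <- match.arg(stim)
  f <- if (stim == "wedge") 12L else 20L
  if (n_timepoints %% f != 0L)
    stop("n_timepoints must be divisible by the cycle count (", f, ")")
  if (f >= n_timepoints / 2)
    stop("stimulus frequency at or above the Nyquist bin")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (!is.null(snr) && noise_sd > 0) amplitude <- snr * noise_sd
  responsive <- Reduce(`|`, geometry$roi_masks)
  nr <- sum(responsive)
  grey_lin <- which(geometry$grey_mask)
  resp_lin <- which(responsive)
  phases <- if (!is.null(truth) && !is.null(truth$retino_phases)) {
    truth$retino_phases[[stim]][match(resp_lin, grey_lin)]
  } else {
    with_seed(seed + 1L, stats::runif(nr, 0, 2 * pi))
  }
  tt <- seq_len(n_timepoints) - 1L
  carrier <- outer(tt, phases, function(t, ph) cos(2 * pi * f * t /
                                                     n_timepoints - ph))
  data <- with_seed(seed, {
    vol <- array(stats::rnorm(prod(geometry$dim) * n_timepoints,
                              0, noise_sd) + baseline,
                 c(geometry$dim, n_timepoints))
    idx <- outer(resp_lin, (tt) * prod(geometry$dim), `+`)
    vol[idx] <- vol[idx] + amplitude * t(carrier)
    vol
  })
  phase_vol <- array(NA_real_, geometry$dim)
  phase_vol[resp_lin] <- phases
  structure(list(data = data, phase = phase_vol, responsive = responsive,
                 stim_freq = f, stim = stim, amplitude = amplitude,
                 noise_sd = noise_sd),
            class = "retino_series")
}

#' Spectral analysis of a phase-encoded time series
#'
#' Normalises the series to percent signal change (divide by its mean,
#' subtract 1), optionally removes a linear trend, and takes the discrete
#' Fourier transform. The phase lag at the stimulus frequency is
#' `-Arg(X_f)` mapped to \[0, 2pi) (so a response `cos(wt - phi)` recovers
#' `phi`), and the spectral SNR is the power at the stimulus bin divided by
#' the mean power over bins 3..Nyquist excluding the stimulus bin +/- 1 and
#' its second harmonic.
#'
#' @param ts Numeric time series (one voxel).
#' @param stim_freq Stimulus frequency in cycles per run.
#' @param normalize Convert to percent signal change first.
#' @param detrend Remove a linear trend first.
#' @return List: `power` (bins 0..N-1), `phase` (at `stim_freq`), `snr`.
#'   A zero-variance series returns `snr = 0` and `phase = NA`.
#' @export
spectral_analysis <- function(ts, stim_freq, normalize = TRUE,
                              detrend = TRUE) {
  n <- length(ts)
  if (n < 2L * stim_freq) stop("series too short for the stimulus frequency")
  if (stats::sd(ts) == 0)
    return(list(power = rep(0, n), phase = NA_real_, snr = 0))
  x <- ts
  if (normalize) {
    mu <- mean(x)
    if (mu == 0) stop("cannot convert to percent signal change: zero mean")
    x <- x / mu - 1
  }
  if (detrend) x <- stats::lm.fit(cbind(1, seq_len(n)), x)$residuals
  X <- stats::fft(x)
  power <- Mod(X)^2
  Xf <- X[stim_freq + 1L]
  phase <- (-Arg(Xf)) %% (2 * pi)
  nyq <- floor(n / 2)
  keep <- setdiff(3:nyq, c(stim_freq - 1L, stim_freq, stim_freq + 1L,
                           2L * stim_freq))
  noise_power <- mean(power[keep + 1L])
  snr <- if (noise_power > 0) power[stim_freq + 1L] / noise_power else Inf
  list(power = power, phase = phase, snr = snr)
}

#' Voxelwise retinotopic mapping analysis
#'
#' Applies [spectral_analysis()] to every in-mask voxel of a 4D mapping
#' run and assembles phase, SNR and power-peak volumes.
#'
#' @param data 4D array.
#' @param mask Logical array of voxels to analyse.
#' @param stim_freq Stimulus frequency in cycles per run.
#' @param ... Passed to [spectral_analysis()].
#' @return List: `phase` (3D, \[0, 2pi)), `snr` (3D), `peak_bin` (3D; the
#'   maximal non-DC power bin in cycles per run).
#' @export
retino_map <- function(data, mask, stim_freq, ...) {
  dims <- dim(data)[1:3]
  vox <- which(mask)
  Y <- t(apply(data, 4, function(v) v[vox]))
  if (length(vox) == 1L) Y <- matrix(Y, ncol = 1L)
  phase <- array(NA_real_, dims); snr <- array(NA_real_, dims)
  peak <- array(NA_real_, dims)
  nyq <- floor(nrow(Y) / 2)
  for (i in seq_along(vox)) {
    sa <- spectral_analysis(Y[, i], stim_freq, ...)
    phase[vox[i]] <- sa$phase
    snr[vox[i]] <- sa$snr
    peak[vox[i]] <- which.max(sa$power[2:(nyq + 1L)])
  }
  list(phase = phase, snr = snr, peak_bin = peak)
}

#' Threshold spectral SNR into a responsive-voxel mask
#'
#' @param snr 3D SNR array (or vector).
#' @param threshold SNR threshold (> 0; voxels with `snr >= threshold`).
#' @return Logical mask; `NA` SNR is non-responsive. Raising the threshold
#'   never adds voxels.
#' @export
select_responsive <- function(snr, threshold) {
  if (threshold < 0) stop("threshold must be non-negative")
  m <- !is.na(snr) & snr >= threshold
  m
}

#' Convert a response phase to visual-field coordinates
#'
#' Wedge phases map to polar angle (clockwise from the upper vertical
#' meridian, phase 0 = upper meridian); ring phases map linearly to
#' eccentricity on \[0, 8\] degrees (the stimulated extent).
#'
#' @param phase Phase(s) in \[0, 2pi).
#' @param stimulus `"wedge"` or `"ring"`.
#' @param max_eccentricity Stimulated eccentricity extent (degrees).
#' @param delay Constant hemodynamic phase offset subtracted before
#'   mapping (radians; default 0).
#' @return Polar angle (radians) or eccentricity (degrees).
#' @export
phase_to_coordinates <- function(phase, stimulus = c("wedge", "ring"),
                                 max_eccentricity = 8, delay = 0) {
  stimulus <- match.arg(stimulus)
  ph <- (phase - delay) %% (2 * pi)
  if (stimulus == "wedge") ph
  else max_eccentricity * ph / (2 * pi)
}

# circular RMSE between two phase vectors
circular_rmse <- function(a, b) {
  d <- Arg(exp(1i * (a - b)))
  sqrt(mean(d^2))
}
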