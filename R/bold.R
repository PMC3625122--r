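#' Generate synthetic BOLD runs
#'
#' Realises each run as a 4D volume time series: every stimulus trial
#' contributes, in the voxels of its ROI, a 3 s boxcar convolved with the
#' canonical HRF and scaled by that voxel's trial amplitude from the
#' pattern generative model (the same model as
#' [generate_trial_patterns()]; the realised per-trial patterns are
#' returned so downstream recovery can be checked exactly). Trials
#' superpose linearly. Blank trials generate no signal. White Gaussian
#' noise of SD `noise_sd_ts` is added to every voxel, a constant `baseline`
#' everywhere, and the dummy volumes are prepended/appended and flagged.
#'
#' @param truth A [ground_truth()] built on `geometry`.
#' @param design An [generate_design()] result.
#' @param geometry A [brain_geometry()].
#' @param noise_sd_ts Time-series white-noise SD (must be >= 0).
#' @param seed Integer seed.
#' @param baseline Constant added to every voxel time course.
#' @param out_dir If non-`NULL`, write each run as
#'   `run-<r>_bold.nii.gz` plus an `events.tsv` there.
#' @return List of class `bold_runs`: `runs` (list with 4D `data` and
#'   logical `dummies` per run), `patterns` (named list of
#'   [pattern_set()]s, one per ROI), `design`, `geometry`.
#' @export
generate_bold_runs <- function(truth, design, geometry, noise_sd_ts = 1,
                               seed = 1L, baseline = 100, out_dir = NULL) {
  if (noise_sd_ts < 0) stop("noise_sd_ts must be non-negative")
  spec <- attr(design, "spec")
  stopifnot(!is.null(spec))
  nvol <- spec$volumes_per_run
  n_an <- nvol - spec$n_dummy_start - spec$n_dummy_end
  seeds <- derive_seeds(seed, length(geometry$roi_masks) + 1L)
  patterns <- list()
  for (i in seq_along(geometry$roi_masks)) {
    nm <- names(geometry$roi_masks)[i]
    patterns[[nm]] <- generate_trial_patterns(truth, design, nm, seeds[i])
  }
  runs <- with_seed(seeds[length(seeds)], {
    lapply(sort(unique(design$run)), function(r) {
      ev <- design[design$run == r, , drop = FALSE]
      stim <- ev[!is.na(ev$stimulus), , drop = FALSE]
      # per-trial HRF-convolved regressors on the analysed timebase
      R <- vapply(seq_len(nrow(stim)), function(i)
        convolved_regressor(stim$onset[i], stim$duration[i], n_an, spec$tr),
        numeric(n_an))
      vol <- array(stats::rnorm(prod(geometry$dim) * nvol, 0, noise_sd_ts) +
                     baseline,
                   c(geometry$dim, nvol))
      an_idx <- (spec$n_dummy_start + 1L):(nvol - spec$n_dummy_end)
      for (nm in names(geometry$roi_masks)) {
        ps <- patterns[[nm]]
        rows <- which(ps$run == r)
        # align pattern rows to this run's stimulus events
        key_ev <- paste(stim$stimulus, stim$condition)
        key_ps <- paste(ps$stimulus[rows], ps$condition[rows])
        amp <- ps$vectors[rows[match(key_ev, key_ps)], , drop = FALSE]
        sig <- R %*% amp                       # n_an x n_roivox
        vmask <- which(geometry$roi_masks[[nm]])
        idx <- outer(vmask, (an_idx - 1L) * prod(geometry$dim), `+`)
        vol[idx] <- vol[idx] + t(sig)
      }
      dum <- rep(FALSE, nvol)
      dum[seq_len(spec$n_dummy_start)] <- TRUE
      dum[(nvol - spec$n_dummy_end + 1L):nvol] <- TRUE
      list(data = vol, dummies = dum, run = r)
    })
  })
  out <- structure(list(runs = runs, patterns = patterns, design = design,
                        geometry = geometry, noise_sd_ts = noise_sd_ts,
                        baseline = baseline, seed = as.integer(seed)),
                   class = "bold_runs")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (rr in runs)
      write_volume(rr$data, file.path(out_dir,
                                      sprintf("run-%02d_bold.nii.gz", rr$run)),
                   geometry$affine)
    write_events_tsv(design, file.path(out_dir, "events.tsv"))
  }
  out
}

#' Write a volume as NIfTI
#'
#' @param data 3D or 4D numeric array.
#' @param path Output `.nii.gz` path.
#' @param affine 4x4 voxel-to-world matrix.
#' @return `path`, invisibly.
#' @export
write_volume <- function(data, path, affine = diag(4)) {
  img <- RNifti::asNifti(data)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume as a plain array
#'
#' @param path NIfTI file path.
#' @return Numeric array with an `affine` attribute.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  out <- as.array(img)
  attr(out, "affine") <- RNifti::xform(img)
  out
}

#' Fit run-wise GLMs to generated BOLD runs
#'
#' Convenience wrapper: builds each run's design matrix, drops dummy
#' volumes and fits [fit_glm()] over a mask.
#'
#' @param bold A [generate_bold_runs()] result.
#' @param mask Logical array (defaults to the union of ROI masks).
#' @param nuisance Optional per-run list of nuisance matrices.
#' @return List of `trial_maps`, one per run.
#' @export
fit_runwise_glm <- function(bold, mask = NULL, nuisance = NULL) {
  spec <- attr(bold$design, "spec")
  n_an <- spec$volumes_per_run - spec$n_dummy_start - spec$n_dummy_end
  if (is.null(mask)) {
    mask <- Reduce(`|`, bold$geometry$roi_masks)
  }
  lapply(bold$runs, function(rr) {
    ev <- bold$design[bold$design$run == rr$run, , drop = FALSE]
    dm <- build_design_matrix(ev, n_an, spec$tr,
                              nuisance = nuisance[[as.character(rr$run)]],
                              isi = spec$isi)
    fit_glm(rr$data, dm, mask = mask, dummies = rr$dummies)
  })
}
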