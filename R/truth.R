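#' Ground truth for the pattern generative model
#'
#' The simulator's generative model: each stimulus has a fixed voxel-pattern
#' template per ROI (unit-norm rows, identical across conditions); a trial
#' pattern in condition c is `g(c) * (template + eta) + intercept`, with
#' `eta` i.i.d. Gaussian pattern noise of condition-specific SD `sigma_c`.
#' The gain g is equal across the three visual conditions by default and 0
#' for the auditory-only condition, whose patterns are intercept plus noise
#' only. Mean amplitude is therefore constant across visual conditions while
#' trial-to-trial pattern scatter (hence decodability and split-half
#' reliability) tracks `sigma_c` — the amplitude/reliability dissociation is
#' built into the model.
#'
#' Default noise SDs make the incongruent condition noisier (1.1) than the
#' congruent and visual-only conditions (0.7): with unit-norm templates the
#' pairwise template separation is about sqrt(2), so these SDs put four-way
#' decoding well off ceiling and off floor.
#'
#' @param geometry A [brain_geometry()] (templates are drawn per ROI), or
#'   `NULL` with `n_voxels` to build a single unnamed ROI.
#' @param conditions Condition labels.
#' @param gains Named per-condition signal gain g.
#' @param noise_sd Named per-condition pattern-noise SD sigma.
#' @param intercept_mean,intercept_sd Per-voxel additive offset distribution
#'   (common across conditions and stimuli).
#' @param n_stimuli Number of stimulus templates.
#' @param n_voxels Voxel count when `geometry` is `NULL`.
#' @param seed Integer seed.
#' @return Object of class `ground_truth`: per-ROI `templates` (n_stimuli x
#'   n_voxels, unit-norm rows), `intercepts`, the dials, and per-voxel
#'   ground-truth retinotopic phases (`wedge_phase`, `ring_phase` in
#'   \[0, 2pi), over grey-matter voxels of the geometry).
#' @export
ground_truth <- function(geometry = NULL,
                         conditions = c("AV_congruent", "AV_incongruent",
                                        "V", "A"),
                         gains = c(AV_congruent = 1, AV_incongruent = 1,
                                   V = 1, A = 0),
                         noise_sd = c(AV_congruent = 0.7,
                                      AV_incongruent = 1.1,
                                      V = 0.7, A = 0.7),
                         intercept_mean = 0.5, intercept_sd = 0.1,
                         n_stimuli = 4L, n_voxels = 150L, seed = 1L) {
  if (any(noise_sd < 0)) stop("noise_sd must be non-negative")
  if (any(gains < 0)) stop("gains must be non-negative")
  stopifnot(all(conditions %in% names(gains)),
            all(conditions %in% names(noise_sd)))
  sizes <- if (is.null(geometry)) c(ROI = as.integer(n_voxels))
           else roi_voxel_counts(geometry)
  out <- with_seed(seed, {
    templates <- lapply(sizes, function(nv) {
      tm <- matrix(stats::rnorm(n_stimuli * nv), n_stimuli, nv)
      tm / sqrt(rowSums(tm^2))
    })
    intercepts <- lapply(sizes, function(nv)
      stats::rnorm(nv, intercept_mean, intercept_sd))
    ph <- NULL
    if (!is.null(geometry)) {
      ng <- sum(geometry$grey_mask)
      ph <- list(wedge = stats::runif(ng, 0, 2 * pi),
                 ring = stats::runif(ng, 0, 2 * pi))
    }
    list(templates = templates, intercepts = intercepts, phases = ph)
  })
  structure(list(
    templates = out$templates,
    intercepts = out$intercepts,
    gains = gains[conditions],
    noise_sd = noise_sd[conditions],
    conditions = conditions,
    n_stimuli = as.integer(n_stimuli),
    retino_phases = out$phases,
    seed = as.integer(seed)
  ), class = "ground_truth")
}

#' Serialise ground truth to JSON
#'
#' @param truth A `ground_truth`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(truth, path) {
  jsonlite::write_json(
    list(gains = as.list(truth$gains), noise_sd = as.list(truth$noise_sd),
         conditions = truth$conditions, n_stimuli = truth$n_stimuli,
         seed = truth$seed,
         templates = lapply(truth$templates, unclass),
         intercepts = truth$intercepts),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
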