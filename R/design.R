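#' Experimental design specification
#'
#' Describes the event-related run structure of the audiovisual experiment:
#' four stimuli crossed with four conditions (AV congruent, AV incongruent,
#' visual-only, auditory-only) gives 16 stimulus trials per run, plus four
#' blank baseline trials, presented in randomised order. Each trial is a 3 s
#' clip followed by a 2 s inter-stimulus interval; volumes are acquired at a
#' TR of 2.72 s, 42 per run (including 3 leading and 2 trailing dummy
#' volumes), so a run spans 114.24 s.
#'
#' @param n_runs Number of runs per subject (17--24 allowed; default 18).
#' @param n_stimuli Number of distinct stimuli (fixed at 4).
#' @param conditions Ordered condition labels.
#' @param n_blanks_per_run Blank baseline trials per run.
#' @param stim_duration Stimulus duration in seconds.
#' @param isi Inter-stimulus interval in seconds.
#' @param tr Repetition time in seconds.
#' @param volumes_per_run Volumes acquired per run, dummies included.
#' @param n_dummy_start,n_dummy_end Dummy volumes at run start/end.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(n_runs = 18L,
                        n_stimuli = 4L,
                        conditions = c("AV_congruent", "AV_incongruent",
                                       "V", "A"),
                        n_blanks_per_run = 4L,
                        stim_duration = 3,
                        isi = 2,
                        tr = 2.72,
                        volumes_per_run = 42L,
                        n_dummy_start = 3L,
                        n_dummy_end = 2L) {
  if (n_runs < 1L) stop("need at least one run")
  if (n_stimuli != length(unique(conditions)) && n_stimuli < 1L)
    stop("invalid stimulus count")
  spec <- structure(list(
    n_runs = as.integer(n_runs),
    n_stimuli = as.integer(n_stimuli),
    conditions = as.character(conditions),
    n_blanks_per_run = as.integer(n_blanks_per_run),
    stim_duration = stim_duration,
    isi = isi,
    tr = tr,
    volumes_per_run = as.integer(volumes_per_run),
    n_dummy_start = as.integer(n_dummy_start),
    n_dummy_end = as.integer(n_dummy_end)
  ), class = "design_spec")
  spec$n_trials_per_run <- spec$n_stimuli * length(spec$conditions) +
    spec$n_blanks_per_run
  spec$run_duration <- spec$volumes_per_run * spec$tr
  # duration available after dummy removal, in which all trials must fit
  spec$analyzed_duration <-
    (spec$volumes_per_run - spec$n_dummy_start - spec$n_dummy_end) * spec$tr
  trial_len <- spec$stim_duration + spec$isi
  if (spec$n_trials_per_run * trial_len > spec$analyzed_duration)
    stop(sprintf(
      "run too short: %d trials x %.2f s = %.2f s exceed the %.2f s of analysed volumes",
      spec$n_trials_per_run, trial_len, spec$n_trials_per_run * trial_len,
      spec$analyzed_duration))
  spec
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf(
    "Design: %d runs, %d stimuli x %d conditions + %d blanks per run\n",
    x$n_runs, x$n_stimuli, length(x$conditions), x$n_blanks_per_run))
  cat(sprintf("  TR %.2f s, %d volumes/run (run duration %.2f s)\n",
              x$tr, x$volumes_per_run, x$run_duration))
  invisible(x)
}

#' Generate a randomised experiment design
#'
#' Lays out, for every run, exactly one trial for each (stimulus, condition)
#' pair plus the blank trials, in a seeded uniform random order on a fixed
#' 5 s grid (3 s stimulus + 2 s ISI) starting at the first analysed volume.
#' Onsets are seconds from run start after dummy removal.
#'
#' @param spec A [design_spec()].
#' @param seed Integer seed; identical seeds give identical designs.
#' @return A data frame of class `experiment_design` with columns
#'   `run` (0-based), `onset` (s), `duration` (s), `stimulus` (0--3, `NA`
#'   for blanks), `condition` (condition label or `"blank"`), and
#'   `n_color_changes` (1--3, the incidental fixation task load).
#' @export
generate_design <- function(spec = design_spec(), seed = 1L) {
  stopifnot(inherits(spec, "design_spec"))
  k <- length(spec$conditions)
  base <- data.frame(
    stimulus = c(rep(seq_len(spec$n_stimuli) - 1L, times = k),
                 rep(NA_integer_, spec$n_blanks_per_run)),
    condition = c(rep(spec$conditions, each = spec$n_stimuli),
                  rep("blank", spec$n_blanks_per_run)),
    stringsAsFactors = FALSE
  )
  n_t <- nrow(base)
  trial_len <- spec$stim_duration + spec$isi
  runs <- with_seed(seed, lapply(seq_len(spec$n_runs) - 1L, function(r) {
    ord <- sample.int(n_t)
    ev <- base[ord, , drop = FALSE]
    ev$run <- r
    ev$onset <- (seq_len(n_t) - 1L) * trial_len
    ev$duration <- spec$stim_duration
    ev$n_color_changes <- sample(1:3, n_t, replace = TRUE)
    ev
  }))
  design <- do.call(rbind, runs)
  rownames(design) <- NULL
  design <- design[, c("run", "onset", "duration", "stimulus", "condition",
                       "n_color_changes")]
  structure(design,
            class = c("experiment_design", "data.frame"),
            spec = spec, seed = as.integer(seed))
}

#' Write design events as BIDS-style TSV
#'
#' @param design An `experiment_design`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(design, path) {
  write_tsv(as.data.frame(design), path)
}
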