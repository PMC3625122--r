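#' Default pipeline configuration
#'
#' The configuration bundles the design spec, the ground-truth dials, the
#' geometry, analysis toggles and named seeds. Defaults encode the study
#' conditions: 15 subjects, 18 runs each, gains equal across visual
#' conditions and zero for auditory-only, pattern noise higher in the AV
#' incongruent condition, 150-voxel ROIs.
#'
#' @param n_subjects Number of simulated subjects.
#' @param ... Overrides for top-level config fields.
#' @return A list of class `avmvpa_config`.
#' @export
default_config <- function(n_subjects = 15L, ...) {
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    design = list(n_runs = 18L),
    truth = list(
      gains = c(AV_congruent = 1, AV_incongruent = 1, V = 1, A = 0),
      noise_sd = c(AV_congruent = 0.7, AV_incongruent = 1.1,
                   V = 0.7, A = 0.7),
      intercept_mean = 0.5, intercept_sd = 0.1),
    geometry = list(dim = c(40L, 40L, 20L),
                    roi_sizes = c(V1 = 150L, V2 = 150L, V3 = 150L)),
    analyses = list(roi_decoding = TRUE, reliability = TRUE,
                    similarity = TRUE, univariate = TRUE,
                    searchlight = FALSE, retinotopy = FALSE),
    use_glm = FALSE,          # pattern-level fast path by default
    noise_sd_ts = 1,
    searchlight_radius = 4,
    searchlight_conditions = c("AV_congruent", "AV_incongruent", "V"),
    retino = list(n_timepoints = 240L, snr = 5, noise_sd = 0.2,
                  snr_threshold = 3),
    seeds = list(design = 11L, truth = 12L, noise = 13L,
                 permutation = 14L),
    out_dir = NULL)
  ov <- list(...)
  for (nm in names(ov)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(ov[[nm]]) &&
                     !is.null(names(ov[[nm]])))
      utils::modifyList(cfg[[nm]], ov[[nm]]) else ov[[nm]]
  }
  structure(cfg, class = "avmvpa_config")
}

#' Read / write a pipeline configuration as JSON
#' @param path JSON file path.
#' @return For `read_config`, an `avmvpa_config`.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_config()
  for (nm in names(raw)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(raw[[nm]]))
      utils::modifyList(cfg[[nm]], raw[[nm]]) else raw[[nm]]
  }
  # restore the named numeric dials parsed as lists
  for (f in c("gains", "noise_sd"))
    if (is.list(cfg$truth[[f]])) cfg$truth[[f]] <- unlist(cfg$truth[[f]])
  if (is.list(cfg$geometry$roi_sizes))
    cfg$geometry$roi_sizes <- unlist(cfg$geometry$roi_sizes)
  cfg
}

#' @rdname read_config
#' @param cfg An `avmvpa_config`.
#' @export
write_config <- function(cfg, path) {
  # named atomic vectors must become JSON objects, not bare arrays,
  # or their names are lost on the round trip
  named_to_list <- function(x) {
    if (is.list(x)) lapply(x, named_to_list)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  jsonlite::write_json(named_to_list(unclass(cfg)), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  write_config(cfg, tf)
  unname(tools::md5sum(tf))
}

#' Simulate one subject's ROI pattern data
#'
#' Pattern-level fast path: draws a design and subject-specific ground
#' truth and realises the per-trial ROI patterns directly (the same
#' generative model the BOLD route recovers via the GLM).
#'
#' @param cfg An [default_config()].
#' @param subject Subject index (1-based), used only for bookkeeping.
#' @param seeds Integer vector of three seeds (design, truth, noise).
#' @return List: `design`, `truth`, `patterns` (named list of
#'   [pattern_set()] per ROI).
#' @export
simulate_subject <- function(cfg, subject, seeds) {
  spec <- do.call(design_spec, cfg$design)
  des <- generate_design(spec, seeds[1])
  tr_args <- cfg$truth
  rois <- cfg$geometry$roi_sizes
  # independent templates and noise streams per ROI
  truth_seeds <- derive_seeds(seeds[2], length(rois))
  ps_seeds <- derive_seeds(seeds[3], length(rois))
  truths <- list(); pats <- list()
  for (i in seq_along(rois)) {
    nm <- names(rois)[i]
    tri <- do.call(ground_truth,
                   c(tr_args, list(n_voxels = unname(rois[i]),
                                   seed = truth_seeds[i])))
    truths[[nm]] <- tri
    pats[[nm]] <- generate_trial_patterns(tri, des, "ROI", ps_seeds[i])
    pats[[nm]]$roi <- nm
  }
  list(design = des, truth = truths, patterns = pats, subject = subject)
}

#' Subject-level ROI analyses
#'
#' Mean-corrects each ROI's patterns, then computes condition-specific
#' decoding accuracy, split-half reliability, inter-stimulus similarity
#' and the uncorrected mean amplitude.
#'
#' @param patterns Named list of [pattern_set()]s (one per ROI).
#' @param analyses Named logical toggles (`roi_decoding`, `reliability`,
#'   `similarity`, `univariate`).
#' @param conditions Condition order for outputs.
#' @return Tidy data frame: `roi`, `condition`, `metric`, `value`.
#' @export
analyze_subject_rois <- function(patterns,
                                 analyses = list(roi_decoding = TRUE,
                                                 reliability = TRUE,
                                                 similarity = TRUE,
                                                 univariate = TRUE),
                                 conditions = NULL) {
  out <- list()
  for (nm in names(patterns)) {
    ps <- patterns[[nm]]
    conds <- conditions %||% unique(ps$condition)
    mc <- mean_correct(ps)
    if (isTRUE(analyses$roi_decoding)) {
      acc <- decode_conditions(mc, conds)
      out[[length(out) + 1L]] <- data.frame(
        roi = nm, condition = acc$condition, metric = "accuracy",
        value = acc$accuracy, stringsAsFactors = FALSE)
    }
    if (isTRUE(analyses$reliability)) {
      rel <- pattern_reliability(mc, conds)
      out[[length(out) + 1L]] <- data.frame(
        roi = nm, condition = rel$condition, metric = "reliability_z",
        value = rel$value, stringsAsFactors = FALSE)
    }
    if (isTRUE(analyses$similarity)) {
      sim <- pattern_similarity(mc, conds)
      out[[length(out) + 1L]] <- data.frame(
        roi = nm, condition = sim$condition, metric = "similarity_z",
        value = sim$value, stringsAsFactors = FALSE)
    }
    if (isTRUE(analyses$univariate)) {
      amp <- roi_mean_amplitude(ps, conditions = conds)
      out[[length(out) + 1L]] <- data.frame(
        roi = nm, condition = amp$condition, metric = "mean_beta",
        value = amp$mean_beta, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Run the end-to-end pipeline
#'
#' Simulates `cfg$n_subjects` subjects and runs the enabled analyses,
#' producing a tidy per-subject result table and group statistics per ROI
#' and metric. With `use_glm = TRUE` each subject's BOLD runs are
#' synthesised and analysed through the run-wise GLM (t-patterns for the
#' multivariate measures, betas for amplitude); otherwise the pattern-level
#' fast path is used. Requesting the searchlight auto-enables the GLM
#' route (logged). Identical configs give identical outputs.
#'
#' @param cfg An [default_config()].
#' @param quiet Suppress stage log messages.
#' @return List of class `avmvpa_results`: `subject_table` (tidy rows:
#'   subject, roi, condition, metric, value), `group` (per roi x metric
#'   [group_metric_stats()]), `config_hash`, `config`. Tables are written
#'   under `cfg$out_dir` when set.
#' @export
run_pipeline <- function(cfg = default_config(), quiet = FALSE) {
  log_msg <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  if (isTRUE(cfg$analyses$searchlight) && !isTRUE(cfg$use_glm)) {
    cfg$use_glm <- TRUE
    log_msg("searchlight requested: enabling the GLM route")
  }
  seeds <- derive_seeds(cfg$seeds$design %||% 1L, cfg$n_subjects * 3L)
  seeds <- matrix(seeds, ncol = 3L)
  conds <- names(cfg$truth$gains)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  rows <- list()
  sl_maps <- list()
  retino_rows <- list()
  any_analysis <- any(unlist(cfg$analyses[c("roi_decoding", "reliability",
                                            "similarity", "univariate")]))
  for (s in seq_len(cfg$n_subjects)) {
    log_msg("subject %d/%d", s, cfg$n_subjects)
    if (isTRUE(cfg$use_glm)) {
      sub <- stage("synth", {
        spec <- do.call(design_spec, cfg$design)
        des <- generate_design(spec, seeds[s, 1])
        geom <- do.call(brain_geometry, cfg$geometry)
        tr_args <- cfg$truth; tr_args$seed <- seeds[s, 2]
        truth <- do.call(ground_truth, c(tr_args, list(geometry = geom)))
        bold <- generate_bold_runs(truth, des, geom, cfg$noise_sd_ts,
                                   seed = seeds[s, 3],
                                   out_dir = if (!is.null(cfg$out_dir))
                                     file.path(cfg$out_dir,
                                               sprintf("sub-%02d", s)))
        list(des = des, geom = geom, bold = bold)
      })
      if (any_analysis || isTRUE(cfg$analyses$searchlight)) {
        glm_mask <- if (isTRUE(cfg$analyses$searchlight))
          sub$geom$grey_mask else NULL
        maps <- stage("glm", fit_runwise_glm(sub$bold, mask = glm_mask))
        pats <- stage("extract", {
          ex <- lapply(names(sub$geom$roi_masks), function(nm)
            extract_patterns(maps, sub$geom$roi_masks[[nm]], conds,
                             what = "t", roi = nm))
          names(ex) <- names(sub$geom$roi_masks)
          ex
        })
        if (isTRUE(cfg$analyses$searchlight)) {
          sl <- stage("searchlight", searchlight_accuracy_maps(
            maps, sub$geom$grey_mask,
            intersect(cfg$searchlight_conditions, conds),
            radius = cfg$searchlight_radius))
          sl_maps[[s]] <- sl
        }
        if (any_analysis) {
          res <- stage("roi_analyses",
                       analyze_subject_rois(pats, cfg$analyses, conds))
          if (isTRUE(cfg$analyses$univariate)) {
            # replace t-based amplitude with the uncorrected betas
            res <- res[res$metric != "mean_beta", , drop = FALSE]
            for (nm in names(sub$geom$roi_masks)) {
              amp <- roi_mean_amplitude(maps, sub$geom$roi_masks[[nm]],
                                        conds)
              res <- rbind(res, data.frame(
                roi = nm, condition = amp$condition, metric = "mean_beta",
                value = amp$mean_beta, stringsAsFactors = FALSE))
            }
          }
          res$subject <- s
          rows[[length(rows) + 1L]] <- res
        }
      }
    } else if (any_analysis) {
      sub <- stage("synth", simulate_subject(cfg, s, seeds[s, ]))
      res <- stage("roi_analyses",
                   analyze_subject_rois(sub$patterns, cfg$analyses, conds))
      res$subject <- s
      rows[[length(rows) + 1L]] <- res
    } else {
      sub <- stage("synth", simulate_subject(cfg, s, seeds[s, ]))
      if (!is.null(cfg$out_dir)) {
        dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
        write_events_tsv(sub$design, file.path(
          cfg$out_dir, sprintf("sub-%02d_events.tsv", s)))
      }
    }
    if (isTRUE(cfg$analyses$retinotopy)) {
      retino_rows[[s]] <- stage("retinotopy", {
        geom <- do.call(brain_geometry, cfg$geometry)
        out <- lapply(c("wedge", "ring"), function(stim) {
          rs <- generate_retino_series(
            geom, stim, cfg$retino$n_timepoints, snr = cfg$retino$snr,
            noise_sd = cfg$retino$noise_sd, seed = seeds[s, 3] + 1L)
          mp <- retino_map(rs$data, rs$responsive, rs$stim_freq)
          err <- Arg(exp(1i * (mp$phase[rs$responsive] -
                                 rs$phase[rs$responsive])))
          data.frame(subject = s, stimulus = stim,
                     circular_rmse = sqrt(mean(err^2)),
                     mean_snr = mean(mp$snr[rs$responsive]),
                     stringsAsFactors = FALSE)
        })
        do.call(rbind, out)
      })
    }
  }
  subject_table <- if (length(rows)) do.call(rbind, rows) else NULL
  group <- NULL
  if (!is.null(subject_table) &&
      length(unique(subject_table$subject)) >= 2L) {
    visual <- setdiff(conds, "A")
    group <- list()
    for (nm in unique(subject_table$roi)) {
      for (met in unique(subject_table$metric)) {
        d <- subject_table[subject_table$roi == nm &
                             subject_table$metric == met, ]
        tab <- stats::reshape(d[, c("subject", "condition", "value")],
                              idvar = "subject", timevar = "condition",
                              direction = "wide")
        m <- as.matrix(tab[, -1, drop = FALSE])
        colnames(m) <- sub("^value\\.", "", colnames(m))
        mu0 <- if (met == "accuracy") 0.25 else NULL
        group[[paste(nm, met, sep = ".")]] <-
          group_metric_stats(m, mu0 = mu0,
                             omnibus_conditions = intersect(colnames(m),
                                                            visual))
      }
    }
  }
  searchlight <- NULL
  if (length(sl_maps)) {
    searchlight <- list(subject_maps = sl_maps)
    conds_sl <- names(sl_maps[[1]])
    if (length(sl_maps) >= 2L && length(conds_sl) >= 2L) {
      prs <- utils::combn(conds_sl, 2)
      searchlight$clusters <- lapply(seq_len(ncol(prs)), function(i) {
        a <- prs[1, i]; b <- prs[2, i]
        cmaps <- lapply(sl_maps, function(m)
          accuracy_contrast(m[[a]], m[[b]]))
        cluster_inference(cmaps,
                          n_permutations = 500L,
                          seed = cfg$seeds$permutation %||% 1L)
      })
      names(searchlight$clusters) <- paste(prs[1, ], prs[2, ], sep = "-")
    }
  }
  out <- structure(list(subject_table = subject_table, group = group,
                        searchlight = searchlight,
                        retino = if (length(retino_rows))
                          do.call(rbind, retino_rows) else NULL,
                        config = cfg, config_hash = config_hash(cfg),
                        seeds = cfg$seeds),
                   class = "avmvpa_results")
  if (!is.null(cfg$out_dir) && !is.null(subject_table)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    st <- subject_table
    st$config_hash <- out$config_hash
    write_tsv(st, file.path(cfg$out_dir, "subject_results.tsv"))
  }
  log_msg("pipeline finished in %.1f s",
          as.numeric(difftime(Sys.time(), t0, units = "secs")))
  out
}
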