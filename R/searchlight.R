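#' Integer sphere offsets for a searchlight
#'
#' All integer voxel offsets (dx, dy, dz) with Euclidean norm at most
#' `radius`. Radius 4 gives 257 offsets. The set contains the origin and is
#' closed under sign flips and axis permutations.
#'
#' @param radius Sphere radius in voxels (>= 0).
#' @return Integer matrix, offsets x 3.
#' @export
sphere_offsets <- function(radius) {
  if (radius < 0) stop("radius must be >= 0")
  r <- floor(radius)
  g <- as.matrix(expand.grid(dx = -r:r, dy = -r:r, dz = -r:r))
  g[rowSums(g^2) <= radius^2, , drop = FALSE]
}

#' Whole-volume searchlight accuracy maps
#'
#' Centres a sphere on every grey-matter voxel, reads out the in-mask
#' sphere voxels' trial patterns, mean-corrects them within (run,
#' condition) and runs the condition-specific leave-one-run-out
#' one-against-one decoding; the fold-mean accuracy is written to the seed
#' voxel. Spheres truncated by the mask edge use the voxels available;
#' seeds with fewer than two in-mask voxels are left undefined (`NA`).
#'
#' @param maps List of per-run `trial_maps` fitted over `grey_mask`.
#' @param grey_mask Logical array of analysed voxels.
#' @param conditions Conditions to map.
#' @param radius Sphere radius in voxels.
#' @param cost SVM cost parameter.
#' @return Named list (one per condition) of 3D accuracy arrays, `NA`
#'   outside the mask.
#' @export
searchlight_accuracy_maps <- function(maps, grey_mask, conditions,
                                      radius = 4, cost = 1) {
  dims <- dim(grey_mask)
  ps <- extract_patterns(maps, grey_mask, conditions, what = "t",
                         roi = "searchlight")
  vox <- which(grey_mask)                     # linear indices, x fastest
  col_of <- integer(prod(dims)); col_of[vox] <- seq_along(vox)
  coords <- which(grey_mask, arr.ind = TRUE)
  offs <- sphere_offsets(radius)
  out <- lapply(conditions, function(cc) array(NA_real_, dims))
  names(out) <- conditions
  for (i in seq_along(vox)) {
    nb <- sweep(offs, 2, coords[i, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
          nb[, 2] >= 1 & nb[, 2] <= dims[2] &
          nb[, 3] >= 1 & nb[, 3] <= dims[3]
    lin <- (nb[ok, 3] - 1L) * dims[1] * dims[2] +
           (nb[ok, 2] - 1L) * dims[1] + nb[ok, 1]
    cols <- col_of[lin]
    cols <- cols[cols > 0L]
    if (length(cols) < 2L) next
    loc <- ps
    loc$vectors <- ps$vectors[, cols, drop = FALSE]
    loc <- mean_correct(loc)
    for (cc in conditions)
      out[[cc]][vox[i]] <- jackknife_accuracy(loc, cc, cost = cost)$accuracy
  }
  out
}

#' Voxelwise accuracy contrast
#'
#' @param maps_a,maps_b 3D arrays on the same grid.
#' @return `maps_a - maps_b` (NA where either is undefined).
#' @export
accuracy_contrast <- function(maps_a, maps_b) {
  if (!identical(dim(maps_a), dim(maps_b))) stop("grid mismatch")
  maps_a - maps_b
}

# connectivity offsets for cluster labelling
connectivity_offsets <- function(connectivity = 6) {
  if (connectivity == 6) {
    matrix(c(1, 0, 0, -1, 0, 0, 0, 1, 0, 0, -1, 0, 0, 0, 1, 0, 0, -1),
           ncol = 3, byrow = TRUE)
  } else if (connectivity == 18) {
    g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    g[rowSums(abs(g)) %in% 1:2, , drop = FALSE]
  } else stop("connectivity must be 6 or 18")
}

# Label connected components among suprathreshold voxels given their
# array coordinates. Min-label propagation over the neighbour graph.
label_components <- function(coords, dims, connectivity = 6) {
  n <- nrow(coords)
  if (n == 0L) return(integer(0))
  lin <- (coords[, 3] - 1) * dims[1] * dims[2] +
         (coords[, 2] - 1) * dims[1] + coords[, 1]
  offs <- connectivity_offsets(connectivity)
  lab <- seq_len(n)
  # precompute neighbour pairs once
  pairs <- NULL
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(coords, 2, offs[k, ], `+`)
    inb <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
           nb[, 2] >= 1 & nb[, 2] <= dims[2] &
           nb[, 3] >= 1 & nb[, 3] <= dims[3]
    nl <- rep(NA_real_, n)
    nl[inb] <- (nb[inb, 3] - 1) * dims[1] * dims[2] +
               (nb[inb, 2] - 1) * dims[1] + nb[inb, 1]
    m <- match(nl, lin)
    hit <- which(!is.na(m))
    if (length(hit))
      pairs <- rbind(pairs, cbind(hit, m[hit]))
  }
  if (!is.null(pairs)) {
    repeat {
      new <- pmin(lab[pairs[, 1]], lab[pairs[, 2]])
      changed <- FALSE
      for (side in 1:2) {
        upd <- new < lab[pairs[, side]]
        if (any(upd)) {
          changed <- TRUE
          # aggregate min per voxel to avoid order dependence
          agg <- tapply(new[upd], pairs[upd, side], min)
          idx <- as.integer(names(agg))
          lab[idx] <- pmin(lab[idx], as.integer(agg))
        }
      }
      if (!changed) break
    }
  }
  match(lab, sort(unique(lab)))
}

#' Group cluster inference by sign-flip permutation
#'
#' One-sample t-test across subjects' contrast maps, thresholded at the
#' one-sided cluster-forming level, connected-component clustering, and
#' family-wise-error corrected cluster p-values from the permutation
#' distribution of the maximum cluster size under random sign flips of
#' whole subject maps. The permutation p is `(b + 1) / (m + 1)` where `b`
#' counts flips whose maximum cluster size reaches the observed size.
#'
#' @param subject_maps List of 3D arrays (one per subject) or an
#'   n_subjects x n_voxels matrix with `mask`.
#' @param mask Logical array of analysed voxels (required for matrix
#'   input; default: voxels finite in all subjects).
#' @param cluster_forming_p One-sided cluster-forming threshold on the
#'   t-map (default 0.001).
#' @param n_permutations Number of random sign flips.
#' @param seed Integer seed for the flips.
#' @param connectivity Cluster connectivity, 6 (faces, default) or 18
#'   (faces + edges).
#' @return Data frame of class `cluster_table`: `cluster`, `size_voxels`,
#'   `peak_x`, `peak_y`, `peak_z` (0-based), `peak_t`, `p_fwe`; attributes
#'   `tmap`, `threshold`, `max_null` (the permutation max-size
#'   distribution).
#' @export
cluster_inference <- function(subject_maps, mask = NULL,
                              cluster_forming_p = 0.001,
                              n_permutations = 1000L, seed = 1L,
                              connectivity = 6) {
  if (n_permutations < 100L)
    warning("fewer than 100 permutations gives a coarse FWE p resolution")
  if (is.list(subject_maps)) {
    dims <- dim(subject_maps[[1]])
    if (is.null(mask))
      mask <- Reduce(`&`, lapply(subject_maps, function(m) is.finite(m)))
    X <- t(vapply(subject_maps, function(m) m[mask],
                  numeric(sum(mask))))
  } else {
    X <- as.matrix(subject_maps)
    if (is.null(mask)) stop("mask required for matrix input")
    dims <- dim(mask)
  }
  n <- nrow(X); V <- ncol(X)
  if (n < 2L) stop("need >= 2 subjects")
  df <- n - 1L
  thr <- stats::qt(1 - cluster_forming_p, df)
  coords_all <- which(mask, arr.ind = TRUE)

  ssq <- colSums(X^2)
  tstat_from_mean <- function(m) {
    v <- (ssq - n * m^2) / df
    v[v < .Machine$double.eps] <- .Machine$double.eps
    m / sqrt(v / n)
  }
  m_obs <- colMeans(X)
  t_obs <- tstat_from_mean(m_obs)

  max_cluster <- function(tv) {
    sup <- which(tv > thr)
    if (!length(sup)) return(list(max = 0L, lab = integer(0), sup = sup))
    lab <- label_components(coords_all[sup, , drop = FALSE], dims,
                            connectivity)
    list(max = max(tabulate(lab)), lab = lab, sup = sup)
  }
  obs <- max_cluster(t_obs)

  signs <- with_seed(seed,
    matrix(sample(c(-1, 1), n_permutations * n, replace = TRUE),
           n_permutations, n))
  Mperm <- (signs %*% X) / n
  max_null <- vapply(seq_len(n_permutations), function(p)
    max_cluster(tstat_from_mean(Mperm[p, ]))$max, integer(1))

  if (length(obs$sup)) {
    sizes <- tabulate(obs$lab)
    tab <- do.call(rbind, lapply(seq_along(sizes), function(cl) {
      vi <- obs$sup[obs$lab == cl]
      pk <- vi[which.max(t_obs[vi])]
      data.frame(cluster = cl, size_voxels = sizes[cl],
                 peak_x = coords_all[pk, 1] - 1L,
                 peak_y = coords_all[pk, 2] - 1L,
                 peak_z = coords_all[pk, 3] - 1L,
                 peak_t = t_obs[pk],
                 p_fwe = (sum(max_null >= sizes[cl]) + 1) /
                   (n_permutations + 1))
    }))
    tab <- tab[order(-tab$size_voxels), , drop = FALSE]
    tab$cluster <- seq_len(nrow(tab))
    rownames(tab) <- NULL
  } else {
    tab <- data.frame(cluster = integer(0), size_voxels = integer(0),
                      peak_x = integer(0), peak_y = integer(0),
                      peak_z = integer(0), peak_t = numeric(0),
                      p_fwe = numeric(0))
  }
  tmap <- array(NA_real_, dims); tmap[mask] <- t_obs
  structure(tab, class = c("cluster_table", "data.frame"),
            tmap = tmap, threshold = thr, max_null = max_null, df = df)
}
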