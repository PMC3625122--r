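#' Synthetic brain geometry
#'
#' A voxel grid with a grey-matter mask and three disjoint rectangular
#' region-of-interest slabs standing in for retinotopically delineated V1,
#' V2 and V3. Every ROI voxel is a grey-matter voxel and the ROIs are
#' pairwise disjoint. The affine maps voxel indices to world millimetres at
#' the stated isotropic voxel size.
#'
#' @param dim Grid shape (x, y, z voxel counts).
#' @param roi_sizes Named integer vector of ROI voxel counts; each ROI is a
#'   contiguous slab placed inside the grey mask.
#' @param voxel_size Isotropic voxel size in mm.
#' @return An object of class `brain_geometry` with elements `dim`,
#'   `affine`, `grey_mask` (logical array), `roi_masks` (named list of
#'   logical arrays).
#' @export
brain_geometry <- function(dim = c(40L, 40L, 20L),
                           roi_sizes = c(V1 = 150L, V2 = 150L, V3 = 150L),
                           voxel_size = 3) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3L, all(dim >= 4L))
  grey <- array(FALSE, dim)
  margin <- pmax(1L, dim %/% 8L)
  grey[(margin[1] + 1L):(dim[1] - margin[1]),
       (margin[2] + 1L):(dim[2] - margin[2]),
       (margin[3] + 1L):(dim[3] - margin[3])] <- TRUE

  # stack ROI slabs along y inside the grey mask, filling x fastest within
  # a slab so sizes need not be multiples of the slab cross-section
  gi <- which(grey, arr.ind = TRUE)
  x0 <- min(gi[, 1]); y0 <- min(gi[, 2]); z0 <- min(gi[, 3])
  nx <- min(10L, max(gi[, 1]) - x0 + 1L)
  nz <- min(3L, max(gi[, 3]) - z0 + 1L)
  roi_masks <- list()
  ycur <- y0
  for (nm in names(roi_sizes)) {
    n <- as.integer(roi_sizes[[nm]])
    ny <- ceiling(n / (nx * nz))
    if (ycur + ny - 1L > max(gi[, 2]))
      stop("grid too small for requested ROI sizes")
    m <- array(FALSE, dim)
    slab <- as.matrix(expand.grid(x = x0:(x0 + nx - 1L),
                                  y = ycur:(ycur + ny - 1L),
                                  z = z0:(z0 + nz - 1L)))
    slab <- slab[order(slab[, "y"], slab[, "z"], slab[, "x"]), , drop = FALSE]
    m[slab[seq_len(n), , drop = FALSE]] <- TRUE
    roi_masks[[nm]] <- m
    ycur <- ycur + ny + 1L  # one-voxel gap keeps ROIs disjoint
  }
  affine <- diag(c(rep(voxel_size, 3), 1))
  structure(list(dim = dim, affine = affine, grey_mask = grey,
                 roi_masks = roi_masks, voxel_size = voxel_size),
            class = "brain_geometry")
}

#' @export
print.brain_geometry <- function(x, ...) {
  cat(sprintf("Geometry %dx%dx%d, %d grey voxels, ROIs: %s\n",
              x$dim[1], x$dim[2], x$dim[3], sum(x$grey_mask),
              paste(sprintf("%s=%d", names(x$roi_masks),
                            vapply(x$roi_masks, sum, 0L)), collapse = ", ")))
  invisible(x)
}

#' Number of voxels in each ROI
#' @param geometry A `brain_geometry`.
#' @return Named integer vector.
#' @export
roi_voxel_counts <- function(geometry) {
  vapply(geometry$roi_masks, sum, integer(1))
}
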