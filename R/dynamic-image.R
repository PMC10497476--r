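#' Dynamic PET image
#'
#' A 4D array of decay-corrected activity concentration (kBq/mL) with its
#' frame schedule and voxel geometry. Geometry follows the NIfTI convention:
#' voxel indices are 0-based, the affine maps voxel-center indices to world
#' millimetres. The default affine is diagonal in the voxel spacing with the
#' first voxel center at the origin.
#'
#' @param data 4D numeric array (x, y, z, frame).
#' @param schedule A `frame_schedule`; frame count must match `dim(data)[4]`.
#' @param spacing Voxel spacing in mm, length 3 (default 4 x 4 x 2.886).
#' @param affine Optional 4x4 voxel-index-to-world-mm matrix.
#' @return A `dynamic_image`.
#' @export
dynamic_image <- function(data, schedule, spacing = c(4, 4, 2.886),
                          affine = NULL) {
  if (length(dim(data)) != 4L)
    stop("data must be a 4D array (x, y, z, frame)")
  validate_schedule(schedule)
  if (dim(data)[4] != n_frames(schedule))
    stop("4th dimension (", dim(data)[4], ") != frame count (",
         n_frames(schedule), ")")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 positive values (mm)")
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
  } else {
    affine <- as.matrix(affine)
    if (!all(dim(affine) == c(4, 4))) stop("affine must be 4x4")
  }
  structure(list(data = data, schedule = schedule, spacing = spacing,
                 affine = affine),
            class = "dynamic_image")
}

#' @export
print.dynamic_image <- function(x, ...) {
  d <- dim(x$data)
  cat("Dynamic PET image: ", d[1], " x ", d[2], " x ", d[3], " voxels, ",
      d[4], " frames (0-", schedule_end(x$schedule), " s)\n", sep = "")
  cat("  spacing ", paste(signif(x$spacing, 4), collapse = " x "), " mm",
      if (!is.null(x$schedule$name)) paste0(", protocol ", x$schedule$name),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.dynamic_image <- function(x) dim(x$data)

# world-mm coordinates of all voxel centers for one axis-aligned grid;
# returns an nvox x 3 matrix ordered like the flattened array
voxel_centers <- function(image) {
  d <- dim(image$data)[1:3]
  idx <- as.matrix(expand.grid(x = seq_len(d[1]) - 1,
                               y = seq_len(d[2]) - 1,
                               z = seq_len(d[3]) - 1))
  world <- cbind(idx, 1) %*% t(image$affine)
  world[, 1:3, drop = FALSE]
}

# flatten 4D to nvox x nframes
as_voxel_matrix <- function(image) {
  d <- dim(image$data)
  matrix(image$data, nrow = prod(d[1:3]), ncol = d[4])
}
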