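#' Aorta centerline
#'
#' An ordered polyline of world-mm points along the descending aorta (or the
#' phantom's blood cylinder). Supplied as input — segmentation is out of
#' scope here.
#'
#' @param points data.frame or matrix with columns x_mm, y_mm, z_mm (>= 2
#'   rows, consecutive points distinct).
#' @return A `centerline` data.frame.
#' @export
centerline <- function(points) {
  pts <- as.data.frame(points)
  need <- c("x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(pts))) {
    if (ncol(pts) >= 3) names(pts)[1:3] <- need
    else stop("centerline needs columns x_mm, y_mm, z_mm")
  }
  pts <- pts[, need]
  if (nrow(pts) < 2) stop("centerline needs at least 2 points")
  dup <- rowSums(abs(diff(as.matrix(pts)))) == 0
  if (any(dup)) stop("consecutive centerline points must be distinct")
  structure(pts, class = c("centerline", "data.frame"))
}

#' Cylindrical blood-pool ROI
#'
#' Builds the binary mask of a cylinder of given transversal (in-plane x-y)
#' radius around a vessel centerline, the standard image-derived-input-
#' function ROI in the descending aorta. A voxel is included iff its center
#' lies within the centerline's z range and its in-plane distance to the
#' centerline point nearest in z is at most `radius_mm`. Inclusion is by
#' voxel center (no partial-volume weighting).
#'
#' @param cl A [centerline()] (world mm).
#' @param radius_mm Transversal radius in mm (default 4).
#' @param geometry A [dynamic_image()] supplying grid shape, spacing and
#'   affine.
#' @return Logical 3D array mask; errors if empty.
#' @export
cylinder_mask <- function(cl, radius_mm = 4, geometry) {
  cl <- centerline(cl)
  if (radius_mm <= 0) stop("radius_mm must be > 0")
  d <- dim(geometry$data)[1:3]
  centers <- voxel_centers(geometry)
  zr <- range(cl$z_mm)
  inz <- centers[, 3] >= zr[1] - 1e-9 & centers[, 3] <= zr[2] + 1e-9
  mask <- logical(nrow(centers))
  if (any(inz)) {
    sub <- centers[inz, , drop = FALSE]
    nearest <- vapply(sub[, 3], function(z) which.min(abs(cl$z_mm - z)),
                      integer(1))
    dx <- sub[, 1] - cl$x_mm[nearest]
    dy <- sub[, 2] - cl$y_mm[nearest]
    mask[inz] <- dx^2 + dy^2 <= radius_mm^2
  }
  if (!any(mask))
    stop("cylinder mask is empty (radius ", radius_mm,
         " mm, centerline z ", signif(zr[1], 4), "-", signif(zr[2], 4),
         " mm); check that the centerline lies inside the field of view")
  array(mask, dim = d)
}

#' Extract a time-activity curve from a mask
#'
#' Per-frame unweighted mean over the masked voxels.
#'
#' @param data A [dynamic_image()].
#' @param mask Logical/0-1 3D array on the same grid.
#' @param label Role tag of the returned [tac()].
#' @return A [tac()] on `data`'s schedule.
#' @export
extract_tac <- function(data, mask, label = "tissue") {
  if (!all(dim(mask) == dim(data$data)[1:3]))
    stop("mask shape does not match image grid")
  sel <- as.vector(mask) > 0
  if (!any(sel)) stop("mask is empty")
  vals <- colMeans(as_voxel_matrix(data)[sel, , drop = FALSE])
  suppressWarnings(tac(data$schedule, vals, label = label))
}

#' Extract the image-derived input function
#'
#' Convenience wrapper: [cylinder_mask()] then [extract_tac()], returned as
#' an [input_function()].
#'
#' @inheritParams cylinder_mask
#' @param data A [dynamic_image()].
#' @param plasma_to_blood_ratio See [input_function()].
#' @return An `input_function`.
#' @export
extract_idif <- function(data, cl, radius_mm = 4, plasma_to_blood_ratio = 1.0) {
  mask <- cylinder_mask(cl, radius_mm, data)
  blood <- extract_tac(data, mask, label = "blood")
  input_function(data$schedule, blood$values, plasma_to_blood_ratio)
}

#' Area under a time-activity curve
#'
#' Trapezoid over the (mid-time, value) samples. When `t0 = 0` and the first
#' mid-time is positive a (0, 0) sample is prepended (activity starts at
#' zero at injection). When `t1` lies beyond the last mid-time the last
#' value is held constant out to `t1`, so AUCs over a common window (e.g.
#' 0-60 min) are comparable across framing protocols whose last mid-times
#' differ.
#'
#' @param x A [tac()].
#' @param t0,t1 Integration window in minutes, `t0 < t1`.
#' @return AUC in kBq.min/mL.
#' @export
tac_auc <- function(x, t0 = 0, t1 = schedule_end(x$schedule) / 60) {
  mids <- frame_midtimes(x$schedule)
  if (t0 >= t1) stop("t0 must be < t1")
  if (t0 < 0 || t1 > schedule_end(x$schedule) / 60 + 1e-9)
    stop("integration window outside [0, scan end]")
  tt <- mids; yy <- x$values
  if (t0 == 0 && tt[1] > 0) { tt <- c(0, tt); yy <- c(0, yy) }
  if (t1 > max(tt)) { yy <- c(yy, yy[length(yy)]); tt <- c(tt, t1) }
  inside <- tt > t0 & tt < t1
  tq <- c(t0, tt[inside], t1)
  yq <- stats::approx(tt, yy, xout = tq, rule = 2)$y
  if (length(tq) < 2) stop("fewer than 2 samples in the integration window")
  utils::tail(cumtrapz(tq, yq), 1)
}

#' Resample an input function onto another schedule
#'
#' Linear interpolation at the target frame mid-times from the (0, 0)-
#' prepended source samples. Used to share one reference input function
#' across framing protocols. Target mid-times beyond the last source
#' mid-time hold the last value, with a warning.
#'
#' @param source An [input_function()] (or [tac()]).
#' @param target Target `frame_schedule`.
#' @return An `input_function` on `target`.
#' @export
resample_if <- function(source, target) {
  validate_schedule(target)
  src_t <- frame_midtimes(source$schedule)
  src_y <- source$values
  if (src_t[1] > 0) { src_t <- c(0, src_t); src_y <- c(0, src_y) }
  tgt_t <- frame_midtimes(target)
  if (max(tgt_t) > max(src_t) + 1e-9)
    warning("target mid-times beyond last source sample; holding last value")
  vals <- stats::approx(src_t, src_y, xout = tgt_t, rule = 2)$y
  ratio <- if (!is.null(source$plasma_to_blood_ratio))
    source$plasma_to_blood_ratio else 1.0
  input_function(target, vals, ratio)
}
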