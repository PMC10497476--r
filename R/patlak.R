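#' Patlak transform of a tissue curve
#'
#' Maps a tissue TAC and a plasma input to the Patlak coordinates
#' \deqn{x(t) = \frac{\int_0^t C_p(\tau) d\tau}{C_p(t)}, \qquad
#'   y(t) = \frac{C_T(t)}{C_p(t)}}
#' for frames with mid-time at or after `t_star`. For an irreversible tracer
#' past its equilibration time the points fall on a line with slope Ki (the
#' net influx rate) and intercept equal to the combined blood plus
#' reversible distribution volume. The plasma integral runs from 0 and is
#' computed by trapezoid on frame mid-times with a (0, 0) sample prepended;
#' all frames from time zero contribute to the integral even though only
#' post-`t_star` frames enter the regression.
#'
#' @param ct Tissue [tac()].
#' @param cp [input_function()] (resampled onto `ct`'s schedule if needed).
#' @param t_star Linearity start time in minutes (frames with mid-time
#'   `>= t_star` are used).
#' @return data.frame with columns `t` (min), `x` (min), `y` (unitless),
#'   `dt` (frame duration, s). Frames with nonpositive plasma activity are
#'   dropped with a warning; fewer than 2 usable frames is an error.
#' @export
patlak_transform <- function(ct, cp, t_star = 10) {
  if (!schedules_identical(ct$schedule, cp$schedule))
    cp <- resample_if(cp, ct$schedule)
  mids <- frame_midtimes(ct$schedule)
  if (t_star < 0 || t_star > max(mids))
    stop("t_star outside the scan (last mid-time ",
         signif(max(mids), 4), " min)")
  cpv <- plasma_values(cp)
  tt <- mids; yy <- cpv
  if (tt[1] > 0) { tt <- c(0, tt); yy <- c(0, yy) }
  cumcp <- cumtrapz(tt, yy)
  if (tt[1] == 0 && mids[1] > 0) cumcp <- cumcp[-1]
  use <- mids >= t_star
  pos <- cpv > 0
  if (any(use & !pos)) {
    warning("dropped ", sum(use & !pos),
            " frame(s) with nonpositive plasma activity")
    use <- use & pos
  }
  if (sum(use) < 2)
    stop("fewer than 2 usable frames at or after t* = ", t_star, " min")
  data.frame(t = mids[use],
             x = cumcp[use] / cpv[use],
             y = ct$values[use] / cpv[use],
             dt = ct$schedule$durations[use])
}

#' Fit the Patlak graphical model
#'
#' The central estimator: ordinary least squares on the Patlak-transformed
#' points. The slope is Ki (mL/min/cm^3), the intercept the combined blood
#' and reversible-compartment distribution volume (mL/cm^3).
#'
#' @param ct Tissue [tac()], or a data.frame of pre-transformed points with
#'   columns `x` and `y` (then `cp` is omitted).
#' @param cp [input_function()].
#' @param t_star Start of the linear segment, minutes (default 10).
#' @param weights `"none"` (default, unweighted OLS) or `"duration"`
#'   (frame-duration weights).
#' @return A `patlak` object with components `Ki`, `intercept`, `sse`,
#'   `points`, `t_star`, `n_frames_used`, `se` (slope/intercept standard
#'   errors when > 2 points). Methods: `print`, `summary`, `coef`,
#'   `predict`, `fitted`, `residuals`, `plot`.
#' @examples
#' sched <- preset_protocol("P-29f")
#' bolus <- function(t) feng_input(t)
#' cp <- input_function(sched, frame_average(bolus, sched))
#' p <- kinetic_params(K1 = 0.094, k2 = 0.3, k3 = 0.1, Vb = 0.05)
#' fine <- seq(0, 3600, by = 0.5) / 60
#' ct <- tac(sched, frame_average(
#'   list(t = fine, y = tissue_curve_2ti(p, bolus, fine)), sched))
#' fit <- patlak(ct, cp, t_star = 10)
#' coef(fit)   # Ki close to 0.094 * 0.1 / 0.4 = 0.0235
#' @export
patlak <- function(ct, cp = NULL, t_star = 10, weights = c("none", "duration")) {
  weights <- match.arg(weights)
  if (is.data.frame(ct)) {
    pts <- ct
    if (!all(c("x", "y") %in% names(pts)))
      stop("point data.frame needs columns x and y")
    if (is.null(pts$dt)) pts$dt <- 1
    if (is.null(pts$t)) pts$t <- pts$x
  } else {
    if (is.null(cp)) stop("cp is required when ct is a TAC")
    pts <- patlak_transform(ct, cp, t_star)
  }
  if (nrow(pts) < 2) stop("need at least 2 points")
  w <- if (weights == "duration") pts$dt else rep(1, nrow(pts))
  fit <- wols(pts$x, pts$y, w)
  structure(list(Ki = fit$slope, intercept = fit$intercept, sse = fit$sse,
                 se = fit$se, points = pts, t_star = t_star,
                 n_frames_used = nrow(pts), weights = weights),
            class = "patlak")
}

# weighted OLS via the closed-form normal equations (the package's own
# regression; lm() is reserved for independent cross-checks)
wols <- function(x, y, w) {
  if (max(x) - min(x) <= 0)
    stop("degenerate fit: all x values equal")
  sw <- sum(w)
  xbar <- sum(w * x) / sw
  ybar <- sum(w * y) / sw
  sxx <- sum(w * (x - xbar)^2)
  slope <- sum(w * (x - xbar) * (y - ybar)) / sxx
  intercept <- ybar - slope * xbar
  res <- y - intercept - slope * x
  sse <- sum(res^2)
  n <- length(x)
  se <- if (n > 2) {
    s2 <- sum(w * res^2) / (n - 2)
    c(slope = sqrt(s2 / sxx), intercept = sqrt(s2 * (1 / sw + xbar^2 / sxx)))
  } else c(slope = NA_real_, intercept = NA_real_)
  list(slope = slope, intercept = intercept, sse = sse, se = se)
}

#' @export
coef.patlak <- function(object, ...) {
  c(Ki = object$Ki, intercept = object$intercept)
}

#' @export
print.patlak <- function(x, ...) {
  cat("Patlak fit (t* = ", x$t_star, " min, ", x$n_frames_used,
      " frames", if (x$weights != "none") ", duration-weighted", ")\n",
      sep = "")
  cat(sprintf("  Ki        = %.6g mL/min/cm^3  (%.4g uL/min/cm^3)\n",
              x$Ki, x$Ki * 1000))
  cat(sprintf("  intercept = %.6g mL/cm^3\n", x$intercept))
  cat(sprintf("  SSE       = %.4g\n", x$sse))
  invisible(x)
}

#' @export
summary.patlak <- function(object, ...) {
  cf <- cbind(estimate = coef(object),
              std.error = object$se[c("slope", "intercept")])
  rownames(cf) <- c("Ki", "intercept")
  out <- list(coefficients = cf, sse = object$sse, t_star = object$t_star,
              n = object$n_frames_used,
              r.squared = stats::cor(object$points$x, object$points$y)^2)
  class(out) <- "summary.patlak"
  out
}

#' @export
print.summary.patlak <- function(x, ...) {
  cat("Patlak graphical analysis (t* =", x$t_star, "min,", x$n, "frames)\n")
  print(signif(x$coefficients, 6))
  cat(sprintf("SSE %.4g, plot R^2 %.6f\n", x$sse, x$r.squared))
  invisible(x)
}

#' @export
fitted.patlak <- function(object, ...) {
  object$intercept + object$Ki * object$points$x
}

#' @export
residuals.patlak <- function(object, ...) {
  object$points$y - fitted(object)
}

#' @export
predict.patlak <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$points$x
       else if (is.data.frame(newdata)) newdata$x else as.numeric(newdata)
  object$intercept + object$Ki * x
}

#' @export
plot.patlak <- function(x, ...,
                        xlab = "Normalized time, int(Cp)/Cp (min)",
                        ylab = "C_T / C_p") {
  graphics::plot(x$points$x, x$points$y, pch = 16, xlab = xlab, ylab = ylab,
                 ...)
  graphics::abline(x$intercept, x$Ki, col = "firebrick")
  graphics::legend("topleft", bty = "n", legend = sprintf(
    "Ki = %.4g uL/min/cm^3\nintercept = %.3g", x$Ki * 1000, x$intercept))
  invisible(x)
}

#' Voxelwise Patlak parametric imaging
#'
#' Vectorized per-voxel Patlak fit. Because the Patlak abscissa depends only
#' on the input function, the regression design is shared across voxels and
#' the per-voxel slope/intercept are obtained in closed form from the
#' centered normal equations applied to the whole voxel-by-frame matrix at
#' once.
#'
#' @param data A [dynamic_image()].
#' @param cp [input_function()] on the same schedule (resampled otherwise).
#' @param t_star Minutes, as in [patlak()].
#' @param mask Optional logical 3D array; voxels outside are set to `fill`.
#' @param fill Value for non-fitted voxels (default 0; use `NA` for NaN-style
#'   maps).
#' @param weights As in [patlak()].
#' @return A `patlak_map`: list with 3D arrays `Ki`, `intercept`, `sse`,
#'   plus `t_star`, `n_frames_used`, `spacing`, `affine`.
#' @export
patlak_voxelwise <- function(data, cp, t_star = 10, mask = NULL, fill = 0,
                             weights = c("none", "duration")) {
  weights <- match.arg(weights)
  d3 <- dim(data$data)[1:3]
  ref <- extract_tac(data, array(TRUE, d3))   # schedule carrier
  pts <- patlak_transform(ref, cp, t_star)    # shared design
  used <- frame_midtimes(data$schedule) %in% pts$t
  cpv <- plasma_values(if (schedules_identical(cp$schedule, data$schedule))
    cp else resample_if(cp, data$schedule))[used]

  Y <- as_voxel_matrix(data)[, used, drop = FALSE] /
    matrix(cpv, nrow = prod(d3), ncol = sum(used), byrow = TRUE)
  x <- pts$x
  w <- if (weights == "duration") pts$dt else rep(1, length(x))
  sw <- sum(w); xbar <- sum(w * x) / sw
  xc <- x - xbar
  sxx <- sum(w * xc^2)
  ybar <- as.numeric(Y %*% w) / sw
  slope <- as.numeric(Y %*% (w * xc)) / sxx
  intercept <- ybar - slope * xbar
  resid <- Y - outer(slope, x) - intercept
  sse <- rowSums(resid^2)

  if (!is.null(mask)) {
    out <- !(as.vector(mask) > 0)
    slope[out] <- fill; intercept[out] <- fill; sse[out] <- fill
  }
  structure(list(Ki = array(slope, d3), intercept = array(intercept, d3),
                 sse = array(sse, d3), t_star = t_star,
                 n_frames_used = length(x), spacing = data$spacing,
                 affine = data$affine, weights = weights),
            class = "patlak_map")
}

#' @export
print.patlak_map <- function(x, ...) {
  d <- dim(x$Ki)
  cat("Patlak parametric maps: ", paste(d, collapse = " x "),
      " voxels (t* = ", x$t_star, " min, ", x$n_frames_used, " frames)\n",
      sep = "")
  cat(sprintf("  Ki range %.4g to %.4g uL/min/cm^3\n",
              min(x$Ki) * 1000, max(x$Ki) * 1000))
  invisible(x)
}

#' ROI-level Patlak fit
#'
#' Fits the Patlak model to the mean TAC of a labeled region — the ROI-based
#' counterpart of [patlak_voxelwise()]. With a shared regression design the
#' ROI-mean of voxelwise parameters equals the fit of the ROI-mean TAC, so
#' the two routes agree up to floating-point error.
#'
#' @param data A [dynamic_image()].
#' @param cp [input_function()].
#' @param t_star Minutes.
#' @param label_mask Integer 3D label array.
#' @param label Region label to fit.
#' @param ... Passed to [patlak()].
#' @return A `patlak` fit.
#' @export
roi_patlak <- function(data, cp, t_star = 10, label_mask, label, ...) {
  sel <- label_mask == label
  if (!any(sel)) stop("label ", label, " not present in mask")
  ct <- extract_tac(data, sel)
  patlak(ct, cp, t_star = t_star, ...)
}
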