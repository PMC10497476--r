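#' Tri-exponential arterial bolus model
#'
#' Population-style model of a decay-corrected FDG arterial input:
#' \deqn{C_p(t) = (A_1 t - A_2 - A_3) e^{-\lambda_1 t} + A_2 e^{-\lambda_2 t}
#'   + A_3 e^{-\lambda_3 t}}
#' with a sharp peak inside the first minute and a slowly decaying tail.
#' The defaults are the widely used FDG population bolus values; they are
#' synthetic defaults for phantom construction, not measured patient values.
#'
#' @param A1 Slope of the initial bolus ramp (kBq/mL/min).
#' @param A2,A3 Tail amplitudes (kBq/mL).
#' @param lambda1,lambda2,lambda3 Decay rates (1/min); must satisfy
#'   `lambda1 > lambda3 >= lambda2 > 0` so the peak is fast and the tail slow.
#' @return A `feng_model` parameter list.
#' @export
feng_model <- function(A1 = 851.1225, A2 = 21.8798, A3 = 20.8113,
                       lambda1 = 4.133859, lambda2 = 0.01043449,
                       lambda3 = 0.1190996) {
  if (!(lambda1 > lambda3 && lambda3 >= lambda2 && lambda2 > 0))
    stop("rates must satisfy lambda1 > lambda3 >= lambda2 > 0")
  structure(list(A1 = A1, A2 = A2, A3 = A3, lambda1 = lambda1,
                 lambda2 = lambda2, lambda3 = lambda3),
            class = "feng_model")
}

#' Evaluate the bolus model
#'
#' @param t Times in minutes (all `>= 0`).
#' @param model A [feng_model()].
#' @return Plasma concentration Cp(t) in kBq/mL; Cp(0) = 0 exactly.
#' @export
feng_input <- function(t, model = feng_model()) {
  if (any(t < 0)) stop("t must be >= 0")
  with(model,
       (A1 * t - A2 - A3) * exp(-lambda1 * t) +
         A2 * exp(-lambda2 * t) + A3 * exp(-lambda3 * t))
}

#' Region kinetic parameters
#'
#' @param K1 Plasma-to-tissue transport rate (mL/min/cm^3).
#' @param k2 Tissue-to-plasma efflux rate (1/min).
#' @param k3 Trapping (phosphorylation) rate (1/min).
#' @param Vb Fractional blood volume in `[0, 1)`.
#' @return A `kinetic_params` list with the derived macro parameter
#'   `Ki = K1 k3 / (k2 + k3)` (`Ki = K1` when `k2 = k3 = 0`, by the pure
#'   trapping limit; `Ki = 0` when `k3 = 0` with efflux present).
#' @export
kinetic_params <- function(K1, k2, k3, Vb = 0) {
  if (any(c(K1, k2, k3) < 0)) stop("K1, k2, k3 must be >= 0")
  if (Vb < 0 || Vb >= 1) stop("Vb must be in [0, 1)")
  structure(list(K1 = K1, k2 = k2, k3 = k3, Vb = Vb,
                 Ki = ki_macro(K1, k2, k3)),
            class = "kinetic_params")
}

ki_macro <- function(K1, k2, k3) {
  if (k2 + k3 == 0) K1 else if (k3 == 0) 0 else K1 * k3 / (k2 + k3)
}

# asymptotic Patlak intercept of the 2TI model: blood volume plus the
# reversible compartment's distribution volume
intercept_macro <- function(K1, k2, k3, Vb) {
  beta <- k2 + k3
  if (beta > 0) (1 - Vb) * K1 * k2 / beta^2 + Vb else Vb
}

#' Two-tissue irreversible forward model
#'
#' Generates the measured tissue curve of a two-tissue compartment model with
#' irreversible trapping (k4 = 0):
#' \deqn{C_{tissue}(t) = K_i \int_0^t C_p + \frac{K_1 k_2}{k_2+k_3}
#'   e^{-(k_2+k_3)t} \otimes C_p, \quad
#'   C_{meas} = (1-V_b) C_{tissue} + V_b C_p}
#' The convolution with the exponential kernel is computed by an exact
#' recurrence for piecewise-linear Cp, so accuracy is limited only by the
#' sampling of `t_grid`. Its Patlak asymptote has slope `Ki` and intercept
#' `(1-Vb) K1 k2/(k2+k3)^2 + Vb`.
#'
#' @param params A [kinetic_params()].
#' @param cp The input function: either a function of minutes or a list/
#'   data.frame with components `t` (min) and `y` (kBq/mL) sampled at least
#'   as finely as `t_grid`.
#' @param t_grid Monotone time grid in minutes starting at 0.
#' @return Numeric vector `C_meas(t_grid)` in kBq/mL.
#' @export
tissue_curve_2ti <- function(params, cp, t_grid) {
  if (t_grid[1] != 0 || is.unsorted(t_grid, strictly = TRUE))
    stop("t_grid must start at 0 and be strictly increasing")
  cpv <- eval_curve(cp, t_grid)
  K1 <- params$K1; k2 <- params$k2; k3 <- params$k3; Vb <- params$Vb
  beta <- k2 + k3
  cum <- cumtrapz(t_grid, cpv)
  if (beta == 0) {
    ctis <- K1 * cum                       # pure trapping limit
  } else {
    conv <- exp_convolve(t_grid, cpv, beta)
    ctis <- ki_macro(K1, k2, k3) * cum + (K1 * k2 / beta) * conv
  }
  (1 - Vb) * ctis + Vb * cpv
}

# coerce a curve (function or sampled {t, y}) to values on t (minutes)
eval_curve <- function(cp, t) {
  if (is.function(cp)) return(cp(t))
  if (is.list(cp) && !is.null(cp$t) && !is.null(cp$y)) {
    if (min(t) < min(cp$t) - 1e-9 || max(t) > max(cp$t) + 1e-9)
      stop("curve samples do not cover the requested times")
    return(stats::approx(cp$t, cp$y, xout = t, rule = 2)$y)
  }
  stop("cp must be a function of minutes or a list with components t and y")
}

cumtrapz <- function(t, y) {
  n <- length(t)
  c(0, cumsum((t[-1] - t[-n]) * (y[-1] + y[-n]) / 2))
}

# y(t_n) = int_0^{t_n} exp(-beta (t_n - s)) f(s) ds, exact for piecewise-
# linear f on the grid
exp_convolve <- function(t, f, beta) {
  n <- length(t)
  out <- numeric(n)
  for (i in seq_len(n - 1)) {
    h <- t[i + 1] - t[i]
    E <- exp(-beta * h)
    g <- -expm1(-beta * h) / beta                 # int_0^h e^{-beta u} du
    a <- f[i]; b <- (f[i + 1] - f[i]) / h
    # int_0^h e^{-beta (h-u)} (a + b u) du
    step <- a * g + b * (h - g) / beta
    out[i + 1] <- out[i] * E + step
  }
  out
}

#' Average a continuous curve over each frame
#'
#' Frame values in dynamic PET are time-averages of the activity over the
#' frame. This computes `(1/dt_i) * int over frame i` by composite trapezoid
#' on an internal sub-grid of at most `step_s` seconds.
#'
#' @param curve Function of minutes, or list/data.frame with `t` (min), `y`.
#' @param schedule A `frame_schedule`; must be covered by the curve support.
#' @param step_s Maximum sub-grid step in seconds (default 0.05; the sharp
#'   bolus ramp needs a fine step for sub-0.1% accuracy on 1-s frames).
#' @return Numeric vector of per-frame averages.
#' @export
frame_average <- function(curve, schedule, step_s = 0.05) {
  validate_schedule(schedule)
  if (!is.function(curve) && is.list(curve) && !is.null(curve$t)) {
    if (max(curve$t) * 60 < schedule_end(schedule) - 1e-6)
      stop("schedule extends past curve support (",
           schedule_end(schedule), " s > ", max(curve$t) * 60, " s)")
  }
  vapply(seq_len(n_frames(schedule)), function(i) {
    a <- schedule$starts[i]; d <- schedule$durations[i]
    nsub <- max(2L, ceiling(d / step_s) + 1L)
    tt <- seq(a, a + d, length.out = nsub) / 60
    yy <- eval_curve(curve, tt)
    utils::tail(cumtrapz(tt, yy), 1) / (d / 60)
  }, numeric(1))
}

# frame averages of a finely sampled curve via the cumulative trapezoid
# integral evaluated at frame boundaries; exact (same quadrature as
# frame_average) when boundaries lie on the sample grid
frame_average_sampled <- function(t_min, y, schedule) {
  cum <- cumtrapz(t_min, y)
  b <- c(schedule$starts, schedule_end(schedule)) / 60
  cb <- stats::approx(t_min, cum, xout = b)$y
  diff(cb) / (schedule$durations / 60)
}

#' Default phantom region table
#'
#' Per-region two-tissue-irreversible micro-parameters chosen so that the
#' macro uptake rates Ki match representative whole-body FDG magnitudes
#' (lesion 23.5, gray matter 36.5, white matter 11.6, lung 0.9, liver 3.7,
#' spleen 4.5, bone marrow 9.8, kidney 5.5, muscle 1.6 uL/min/cm^3), with
#' `k2 + k3` between 0.3 and 1.0 /min. Label 1 is the blood (aorta analog)
#' region.
#'
#' @return data.frame with columns label, name, K1, k2, k3, Vb, is_blood
#'   and the derived Ki_true (mL/min/cm^3).
#' @export
phantom_regions <- function() {
  path <- system.file("extdata", "phantom_regions.csv", package = "patlakpet")
  reg <- utils::read.csv(path)
  reg$Ki_true <- mapply(ki_macro, reg$K1, reg$k2, reg$k3)
  reg
}

#' Phantom specification
#'
#' Describes a synthetic dynamic-PET phantom: grid geometry, a label map
#' (default: a straight 2-voxel-radius blood cylinder along z — the aorta
#' analog — plus ellipsoidal organs and a spherical lesion), per-region
#' kinetics, and a count-like noise level.
#'
#' Noise is Gaussian with standard deviation
#' `alpha * sqrt(max(C, c_floor) / dt_s)` per voxel and frame — variance
#' proportional to activity and inversely proportional to frame duration, a
#' surrogate for count statistics in decay-corrected reconstructions.
#'
#' @param shape Grid size in voxels (default 32 x 32 x 48).
#' @param spacing Voxel spacing mm (default 4 x 4 x 2.886).
#' @param regions Region table as from [phantom_regions()].
#' @param noise_alpha Noise scale `alpha` (kBq/mL per sqrt(kBq/mL/s));
#'   0 gives a noiseless phantom. Default 1.
#' @param smooth_fwhm Optional 3D Gaussian post-smoothing FWHM in mm per
#'   frame (default 0 = off; 3 mm mimics reconstruction-time smoothing).
#' @param seed Integer seed; fixed seed gives bit-identical phantoms.
#' @param input_model A [feng_model()].
#' @param label_map Optional integer array of `shape` giving region labels;
#'   default geometry is built by [default_label_map()].
#' @param c_floor Activity floor (kBq/mL) guarding zero-activity frames in
#'   the noise model.
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(32, 32, 48), spacing = c(4, 4, 2.886),
                         regions = phantom_regions(), noise_alpha = 1,
                         smooth_fwhm = 0, seed = NULL,
                         input_model = feng_model(), label_map = NULL,
                         c_floor = 0.01) {
  if (sum(regions$is_blood) != 1L)
    stop("exactly one blood region required")
  if (is.null(label_map)) label_map <- default_label_map(shape)
  if (!all(dim(label_map) == shape)) stop("label_map does not match shape")
  labs <- sort(unique(as.vector(label_map)))
  labs <- labs[labs != 0]
  missing <- setdiff(labs, regions$label)
  if (length(missing))
    stop("label(s) without kinetic parameters: ", paste(missing, collapse = ", "))
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 regions = regions, noise_alpha = noise_alpha,
                 smooth_fwhm = smooth_fwhm, seed = seed,
                 input_model = input_model, label_map = label_map,
                 c_floor = c_floor),
            class = "phantom_spec")
}

#' Default phantom label map
#'
#' A 2-voxel-radius blood cylinder along z through the grid center, nine
#' ellipsoidal/spherical tissue regions placed clear of the cylinder.
#'
#' @param shape Grid size in voxels.
#' @return Integer array of region labels (0 = background).
#' @export
default_label_map <- function(shape = c(32, 32, 48)) {
  lab <- array(0L, dim = shape)
  idx <- as.matrix(expand.grid(x = seq_len(shape[1]) - 1,
                               y = seq_len(shape[2]) - 1,
                               z = seq_len(shape[3]) - 1))
  ell <- function(c0, r) {
    u <- sweep(idx, 2, c0) / rep(r, each = nrow(idx))
    rowSums(u^2) <= 1
  }
  sc <- function(v) pmin(pmax(round(v * shape / c(32, 32, 48)), 1), shape - 2)
  lab[ell(sc(c(25, 25, 12)), c(2.5, 2.5, 2.5))] <- 2L  # lesion
  lab[ell(sc(c(8, 8, 40)),   c(4, 4, 5))]       <- 3L  # gray matter
  lab[ell(sc(c(23, 8, 40)),  c(3, 3, 4))]       <- 4L  # white matter
  lab[ell(sc(c(8, 24, 30)),  c(4, 4, 6))]       <- 5L  # lung
  lab[ell(sc(c(25, 8, 24)),  c(4, 4, 6))]       <- 6L  # liver
  lab[ell(sc(c(7, 8, 20)),   c(3, 3, 4))]       <- 7L  # spleen
  lab[ell(sc(c(25, 24, 36)), c(3, 3, 5))]       <- 8L  # bone marrow
  lab[ell(sc(c(8, 24, 10)),  c(3, 3, 4))]       <- 9L  # kidney
  lab[ell(sc(c(25, 25, 4)),  c(3, 3, 3))]       <- 10L # muscle
  # blood cylinder last so it is never overwritten
  cx <- floor(shape[1] / 2); cy <- floor(shape[2] / 2)
  incyl <- (idx[, 1] - cx)^2 + (idx[, 2] - cy)^2 <= 2^2
  lab[incyl] <- 1L
  lab
}

#' Build a synthetic dynamic-PET phantom
#'
#' Evaluates the bolus and each region's two-tissue-irreversible curve on a
#' fine internal grid, frame-averages onto `schedule`, fills the label map,
#' adds count-like noise, and (optionally) smooths each frame with a 3D
#' Gaussian. Everything is generated in decay-corrected space.
#'
#' @param spec A [phantom_spec()].
#' @param schedule Target `frame_schedule`.
#' @return A `pet_phantom` list: `image` (a [dynamic_image()]), `label_map`,
#'   ground-truth `ki_true` and `intercept_true` 3D maps (mL/min/cm^3 and
#'   mL/cm^3), `input_true` (noiseless blood [input_function()] on
#'   `schedule`), `centerline` (blood cylinder axis, world mm), `regions`,
#'   `schedule`, `spec`.
#' @export
build_phantom <- function(spec, schedule) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_schedule(schedule)
  if (!is.null(spec$seed)) set.seed(spec$seed)

  cp_fun <- function(t) feng_input(t, spec$input_model)
  reg <- spec$regions
  frame_vals <- matrix(0, nrow = nrow(reg), ncol = n_frames(schedule))
  fine_t <- seq(0, schedule_end(schedule), by = 0.25) / 60
  cp_fine <- cp_fun(fine_t)
  for (r in seq_len(nrow(reg))) {
    if (reg$is_blood[r] == 1) {
      curve <- list(t = fine_t, y = cp_fine)
    } else {
      p <- kinetic_params(reg$K1[r], reg$k2[r], reg$k3[r], reg$Vb[r])
      curve <- list(t = fine_t,
                    y = tissue_curve_2ti(p, list(t = fine_t, y = cp_fine),
                                         fine_t))
    }
    frame_vals[r, ] <- frame_average_sampled(fine_t, curve$y, schedule)
  }

  lab <- as.vector(spec$label_map)
  nvox <- prod(spec$shape)
  mat <- matrix(0, nrow = nvox, ncol = n_frames(schedule))
  rowidx <- match(lab, reg$label)          # NA for background
  filled <- !is.na(rowidx)
  mat[filled, ] <- frame_vals[rowidx[filled], ]

  if (spec$noise_alpha > 0) {
    dt_s <- rep(schedule$durations, each = nvox)
    sd <- spec$noise_alpha * sqrt(pmax(mat, spec$c_floor) / dt_s)
    mat <- mat + stats::rnorm(length(mat), sd = sd)
  }

  arr <- array(mat, dim = c(spec$shape, n_frames(schedule)))
  if (spec$smooth_fwhm > 0)
    arr <- smooth_gaussian_4d(arr, spec$smooth_fwhm, spec$spacing)

  ki_map <- array(0, dim = spec$shape)
  int_map <- array(0, dim = spec$shape)
  for (r in seq_len(nrow(reg))) {
    sel <- spec$label_map == reg$label[r]
    ki_map[sel] <- reg$Ki_true[r]
    int_map[sel] <- intercept_macro(reg$K1[r], reg$k2[r], reg$k3[r], reg$Vb[r])
  }

  img <- dynamic_image(arr, schedule, spacing = spec$spacing)
  cx <- floor(spec$shape[1] / 2) * spec$spacing[1]
  cy <- floor(spec$shape[2] / 2) * spec$spacing[2]
  centerline <- data.frame(
    x_mm = cx, y_mm = cy,
    z_mm = (seq_len(spec$shape[3]) - 1) * spec$spacing[3])

  blood_row <- which(reg$is_blood == 1)
  structure(list(
    image = img, label_map = spec$label_map,
    ki_true = ki_map, intercept_true = int_map,
    input_true = input_function(schedule, frame_vals[blood_row, ]),
    region_tacs = frame_vals, centerline = centerline,
    regions = reg, schedule = schedule, spec = spec),
    class = "pet_phantom")
}

#' @export
print.pet_phantom <- function(x, ...) {
  cat("Synthetic dynamic-PET phantom\n")
  print(x$image)
  cat("  ", nrow(x$regions), " regions, noise alpha = ",
      x$spec$noise_alpha, "\n", sep = "")
  invisible(x)
}

# separable 3D Gaussian smoothing of each frame; edge-renormalized kernels
smooth_gaussian_4d <- function(arr, fwhm_mm, spacing) {
  d <- dim(arr)
  mats <- lapply(1:3, function(ax) gauss_matrix(d[ax], fwhm_mm / spacing[ax]))
  for (f in seq_len(d[4])) {
    v <- arr[, , , f]
    v <- apply_along(v, 1, mats[[1]])
    v <- apply_along(v, 2, mats[[2]])
    v <- apply_along(v, 3, mats[[3]])
    arr[, , , f] <- v
  }
  arr
}

gauss_matrix <- function(n, fwhm_vox) {
  sigma <- fwhm_vox / (2 * sqrt(2 * log(2)))
  K <- outer(seq_len(n), seq_len(n),
             function(i, j) exp(-(i - j)^2 / (2 * sigma^2)))
  K / rowSums(K)
}

apply_along <- function(v, axis, K) {
  d <- dim(v)
  perm <- c(axis, setdiff(1:3, axis))
  vp <- aperm(v, perm)
  m <- K %*% matrix(vp, nrow = d[axis])
  vp <- array(m, dim = d[perm])
  aperm(vp, order(perm))
}
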