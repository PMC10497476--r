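# Shared fixtures, all generated in code.

# fine sampling (0.25 s) of the default bolus over the 60-min scan
fine_grid <- function(end_s = 3600, step_s = 0.25) seq(0, end_s, by = step_s) / 60

default_bolus <- function() {
  m <- feng_model()
  function(t) feng_input(t, m)
}

# noiseless tissue TAC for given kinetics on a schedule, via the fine grid
make_tissue_tac <- function(params, schedule, bolus = default_bolus()) {
  tt <- fine_grid(schedule_end(schedule))
  cpv <- bolus(tt)
  y <- tissue_curve_2ti(params, list(t = tt, y = cpv), tt)
  tac(schedule, frame_average(list(t = tt, y = y), schedule))
}

make_input_tac <- function(schedule, bolus = default_bolus()) {
  input_function(schedule, frame_average(bolus, schedule))
}

# small two-region phantom (blood column + one tissue blob) for fast tests
tiny_phantom_spec <- function(seed = NULL, noise_alpha = 0,
                              regions = phantom_regions(), ...) {
  shape <- c(8, 8, 6)
  lab <- array(0L, dim = shape)
  lab[1:3, 1:3, ] <- 2L                      # lesion blob
  lab[4:6, 4:6, ] <- 1L                      # blood column around the
                                             # build_phantom centerline
  phantom_spec(shape = shape, regions = regions, label_map = lab,
               seed = seed, noise_alpha = noise_alpha, ...)
}

# independent OLS via lm(): the cross-check oracle for the package's own
# closed-form regression
lm_patlak_oracle <- function(ct, cp, t_star) {
  pts <- patlak_transform(ct, cp, t_star)
  fit <- stats::lm(y ~ x, data = pts)
  c(Ki = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    sse = sum(stats::residuals(fit)^2))
}
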