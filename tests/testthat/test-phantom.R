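test_that("bolus model evaluates its closed form", {
  expect_equal(feng_input(0), 0)                       # (-A2-A3)+A2+A3
  # degenerate linear case evaluated through the same formula
  lin <- list(A1 = 1, A2 = 0, A3 = 0, lambda1 = 0, lambda2 = 1, lambda3 = 1)
  expect_equal(feng_input(c(0, 1, 2.5), lin), c(0, 1, 2.5))
  # frozen value from an independent term-by-term evaluation of the formula
  expect_equal(feng_input(1), 53.0791033382, tolerance = 1e-10)
  expect_error(feng_input(-0.1), ">= 0")
  expect_error(feng_model(lambda1 = 0.05), "lambda1 > lambda3")
  # nonnegative over the scan for default parameters
  expect_true(all(feng_input(seq(0, 60, by = 0.01)) >= 0))
})

test_that("two-tissue irreversible forward model matches limiting cases", {
  tt <- fine_grid(600)
  bol <- default_bolus()
  cpv <- bol(tt)

  # K1 = 0: only the blood volume term survives
  p0 <- kinetic_params(0, 0, 0, Vb = 0.3)
  expect_equal(tissue_curve_2ti(p0, bol, tt), 0.3 * cpv)
  p00 <- kinetic_params(0, 0, 0, Vb = 0)
  expect_equal(tissue_curve_2ti(p00, bol, tt), rep(0, length(tt)))

  # k2 = 0, Vb = 0: pure trapping, C = K1 * cumulative integral of Cp
  p <- kinetic_params(0.1, 0, 0.3, Vb = 0)
  manual <- 0.1 * c(0, cumsum(diff(tt) * (cpv[-1] + cpv[-length(cpv)]) / 2))
  expect_equal(tissue_curve_2ti(p, bol, tt), manual, tolerance = 1e-12)

  # macro parameter conventions
  expect_equal(kinetic_params(0.1, 0, 0, 0)$Ki, 0.1)   # pure-trapping limit
  expect_equal(kinetic_params(0.1, 0.2, 0, 0)$Ki, 0)   # no trapping
  expect_equal(kinetic_params(0.09, 0.3, 0.1, 0)$Ki, 0.0225)
})

test_that("forward model agrees with a stiff ODE oracle within 0.1%", {
  skip_if_not_installed("deSolve")
  K1 <- 0.1; k2 <- 0.1; k3 <- 0.05; Vb <- 0.05
  bol <- default_bolus()
  rhs <- function(t, y, parms) {
    cp <- bol(t)
    list(c(K1 * cp - (k2 + k3) * y[1], k3 * y[1]))
  }
  t_out <- seq(0, 60, by = 0.5)
  ode <- deSolve::ode(c(0, 0), t_out, rhs, NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-10)
  oracle <- (1 - Vb) * (ode[, 2] + ode[, 3]) + Vb * bol(t_out)

  tt <- fine_grid()
  ours <- tissue_curve_2ti(kinetic_params(K1, k2, k3, Vb), bol, tt)
  ours_at <- approx(tt, ours, xout = t_out)$y
  late <- t_out >= 1
  expect_lt(max(abs(ours_at[late] - oracle[late]) / oracle[late]), 1e-3)
})

test_that("frame averaging is the time-mean of the curve over each frame", {
  s <- make_schedule(list(c(4, 30), c(2, 60)))
  expect_equal(frame_average(function(t) rep(7.5, length(t)), s),
               rep(7.5, 6))
  # linear curve: mean equals the midpoint value
  s1 <- make_schedule(list(c(1, 10)))
  expect_equal(frame_average(function(t) t, s1), 5 / 60)
  # first 1-s frame of the bolus vs independent adaptive quadrature (frozen)
  s100 <- preset_protocol("P-100f")
  fa <- frame_average(default_bolus(), s100)
  expect_equal(fa[1], 8.19008561042, tolerance = 1e-3)
  expect_error(frame_average(list(t = c(0, 1), y = c(0, 1)),
                             preset_protocol("P-12f")),
               "support")
})

test_that("default region table carries the reference Ki magnitudes", {
  reg <- phantom_regions()
  want <- c(lesion = 23.5, gray_matter = 36.5, white_matter = 11.6,
            lung = 0.9, liver = 3.7, spleen = 4.5, bone_marrow = 9.8,
            kidney = 5.5, muscle = 1.6)
  got <- 1000 * reg$Ki_true[match(names(want), reg$name)]
  expect_equal(unname(got), unname(want), tolerance = 1e-12)
  beta <- reg$k2 + reg$k3
  expect_true(all(beta[reg$is_blood == 0] >= 0.05 &
                    beta[reg$is_blood == 0] <= 1.5))
  expect_equal(sum(reg$is_blood), 1)
})

test_that("noiseless phantom reproduces region curves and ground truth", {
  sched <- preset_protocol("P-12f")
  ph <- build_phantom(tiny_phantom_spec(noise_alpha = 0), sched)
  # ROI-mean TAC equals the frame-averaged region curve exactly
  lesion_tac <- extract_tac(ph$image, ph$label_map == 2L)
  reg <- ph$regions
  expect_equal(lesion_tac$values,
               ph$region_tacs[which(reg$label == 2), ],
               tolerance = 1e-12)
  blood_tac <- extract_tac(ph$image, ph$label_map == 1L)
  expect_equal(blood_tac$values, ph$input_true$values, tolerance = 1e-12)
  # ground-truth maps carry the macro parameters per region
  expect_equal(unique(ph$ki_true[ph$label_map == 2L]), 0.0235)
  expect_equal(unique(ph$ki_true[ph$label_map == 1L]), 0)
  expect_true(all(ph$ki_true[ph$label_map == 0L] == 0))
})

test_that("phantoms are bit-identical under a fixed seed", {
  sched <- preset_protocol("P-12f")
  a <- build_phantom(tiny_phantom_spec(seed = 7, noise_alpha = 1), sched)
  b <- build_phantom(tiny_phantom_spec(seed = 7, noise_alpha = 1), sched)
  expect_identical(a$image$data, b$image$data)
  c_ <- build_phantom(tiny_phantom_spec(seed = 8, noise_alpha = 1), sched)
  expect_false(identical(a$image$data, c_$image$data))
})

test_that("noise SD follows the sqrt(C / frame duration) law", {
  # uniform single-region phantom, two frame durations differing 16-fold
  shape <- c(10, 10, 10)
  lab <- array(2L, dim = shape)
  sched <- make_schedule(list(c(1, 10), c(1, 160)))
  spec <- phantom_spec(shape = shape, label_map = lab, seed = 99,
                       noise_alpha = 1)
  ph <- build_phantom(spec, sched)
  m <- matrix(ph$image$data, nrow = prod(shape))
  truth <- ph$region_tacs[which(ph$regions$label == 2), ]
  sd_emp <- apply(m - rep(truth, each = prod(shape)), 2, sd)
  sd_theory <- 1 * sqrt(pmax(truth, 0.01) / sched$durations)
  expect_equal(sd_emp, sd_theory, tolerance = 0.1)
  # duration ratio alone explains the SD ratio once activity is factored out
  expect_equal(sd_emp[1] / sd_emp[2] / sqrt(truth[1] / truth[2]),
               sqrt(160 / 10), tolerance = 0.1)
})

test_that("phantom spec validates labels and blood region", {
  reg <- phantom_regions()
  lab <- array(99L, dim = c(4, 4, 4))
  expect_error(phantom_spec(shape = c(4, 4, 4), label_map = lab,
                            regions = reg),
               "without kinetic parameters")
  reg2 <- reg; reg2$is_blood <- 0
  expect_error(phantom_spec(regions = reg2), "blood region")
})

test_that("Gaussian post-smoothing is exact on flat fields and reduces noise", {
  sched <- make_schedule(list(c(2, 1800)))
  shape <- c(10, 10, 10)
  lab <- array(2L, dim = shape)
  # noiseless uniform phantom: smoothing must be the identity
  flat <- build_phantom(phantom_spec(shape = shape, label_map = lab,
                                     noise_alpha = 0, smooth_fwhm = 3),
                        sched)
  flat0 <- build_phantom(phantom_spec(shape = shape, label_map = lab,
                                      noise_alpha = 0), sched)
  expect_equal(flat$image$data, flat0$image$data, tolerance = 1e-12)
  # noisy phantom: a kernel wide relative to the voxel size shrinks
  # voxel-to-voxel variance substantially
  noisy <- build_phantom(phantom_spec(shape = shape, label_map = lab,
                                      seed = 3, noise_alpha = 1,
                                      smooth_fwhm = 8), sched)
  noisy0 <- build_phantom(phantom_spec(shape = shape, label_map = lab,
                                       seed = 3, noise_alpha = 1), sched)
  expect_lt(sd(noisy$image$data[, , , 1]),
            0.8 * sd(noisy0$image$data[, , , 1]))
})
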