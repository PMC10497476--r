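# manual Patlak coordinates: trapezoid plasma integral on (0,0)-prepended
# mid-times, computed independently of patlak_transform
manual_patlak_xy <- function(ct, cp, t_star) {
  mids <- frame_midtimes(ct$schedule)
  tt <- c(0, mids); yy <- c(0, cp$values)
  cum <- numeric(length(tt))
  for (i in 2:length(tt))
    cum[i] <- cum[i - 1] + (tt[i] - tt[i - 1]) * (yy[i] + yy[i - 1]) / 2
  use <- mids >= t_star
  list(x = cum[-1][use] / cp$values[use],
       y = ct$values[use] / cp$values[use])
}

test_that("Patlak transform reproduces a manual recomputation", {
  s <- preset_protocol("P-29f")
  cp <- make_input_tac(s)
  ct <- make_tissue_tac(kinetic_params(0.1, 0.1, 0.05, 0), s)
  pts <- patlak_transform(ct, cp, t_star = 10)
  man <- manual_patlak_xy(ct, cp, 10)
  expect_equal(pts$x, man$x, tolerance = 1e-12)
  expect_equal(pts$y, man$y, tolerance = 1e-12)
  expect_true(all(diff(pts$x) > 0))
  expect_true(all(pts$t >= 10))
})

test_that("tissue built from the Patlak identity lies exactly on the line", {
  s <- preset_protocol("P-48f")
  cp <- make_input_tac(s)
  man <- manual_patlak_xy(tac(s, rep(1, 48)), cp, 0)  # x for every frame
  a <- 0.02; b <- 0.5
  ct <- tac(s, (a * man$x + b) * cp$values)
  fit <- patlak(ct, cp, t_star = 10)
  expect_equal(fit$Ki, a, tolerance = 1e-12)
  expect_equal(fit$intercept, b, tolerance = 1e-12)
  expect_equal(fit$sse, 0, tolerance = 1e-18)
  # tissue proportional to plasma: constant ordinate y = d at every frame
  d <- 4.4
  ptsc <- patlak_transform(tac(s, d * cp$values), cp, 10)
  expect_equal(ptsc$y, rep(d, nrow(ptsc)), tolerance = 1e-12)
})

test_that("transform drops nonpositive-plasma frames and validates inputs", {
  s <- make_schedule(list(c(6, 600)))
  cpv <- c(5, 4, 3, 0, 2, 1)
  cp <- suppressWarnings(input_function(s, cpv))
  ct <- tac(s, rep(1, 6))
  expect_warning(pts <- patlak_transform(ct, cp, t_star = 0),
                 "nonpositive plasma")
  expect_equal(nrow(pts), 5)
  cp2 <- suppressWarnings(input_function(s, c(5, 4, 3, 2, 0, 0)))
  expect_error(suppressWarnings(patlak_transform(ct, cp2, t_star = 35)),
               "fewer than 2")
  expect_error(patlak_transform(ct, cp, t_star = 70), "t_star")
})

test_that("OLS fit matches closed forms and an independent lm oracle", {
  # exact line
  pts <- data.frame(x = 1:10, y = 0.02 * (1:10) + 0.5)
  fit <- patlak(pts)
  expect_equal(coef(fit), c(Ki = 0.02, intercept = 0.5), tolerance = 1e-12)
  expect_equal(fit$sse, 0, tolerance = 1e-20)
  # two points: perfect fit
  fit2 <- patlak(data.frame(x = c(1, 3), y = c(2, 8)))
  expect_equal(unname(coef(fit2)), c(3, -1), tolerance = 1e-12)
  expect_equal(fit2$sse, 0, tolerance = 1e-20)
  # noisy points vs lm
  set.seed(31)
  noisy <- data.frame(x = sort(runif(10, 5, 50)))
  noisy$y <- 0.01 * noisy$x + 0.3 + rnorm(10, sd = 0.02)
  ours <- patlak(noisy)
  ref <- lm(y ~ x, data = noisy)
  expect_equal(ours$Ki, unname(coef(ref)[2]), tolerance = 1e-10)
  expect_equal(ours$intercept, unname(coef(ref)[1]), tolerance = 1e-10)
  expect_equal(ours$sse, sum(residuals(ref)^2), tolerance = 1e-10)
  expect_error(patlak(data.frame(x = c(2, 2, 2), y = 1:3)), "degenerate")
})

test_that("patlak object methods are coherent", {
  s <- preset_protocol("P-29f")
  cp <- make_input_tac(s)
  ct <- make_tissue_tac(kinetic_params(0.094, 0.3, 0.1, 0.05), s)
  fit <- patlak(ct, cp)
  expect_s3_class(fit, "patlak")
  expect_named(coef(fit), c("Ki", "intercept"))
  expect_equal(fitted(fit) + residuals(fit), fit$points$y)
  expect_equal(sum(residuals(fit)^2), fit$sse)
  expect_equal(predict(fit, data.frame(x = 0)), fit$intercept)
  sm <- summary(fit)
  expect_gt(sm$r.squared, 0.999)
  expect_output(print(fit), "Ki")
  expect_silent({
    grDevices::pdf(NULL)
    plot(fit)
    grDevices::dev.off()
  })
})

test_that("voxelwise maps equal a per-voxel independent OLS oracle", {
  sched <- preset_protocol("P-12f")
  ph <- build_phantom(tiny_phantom_spec(seed = 5, noise_alpha = 0.5), sched)
  idif <- extract_idif(ph$image, ph$centerline, radius_mm = 4)
  maps <- patlak_voxelwise(ph$image, idif, t_star = 10)
  pts_ref <- patlak_transform(extract_tac(ph$image,
                                          array(TRUE, dim(ph$label_map))),
                              idif, 10)
  cpv <- idif$values[frame_midtimes(sched) %in% pts_ref$t]
  d <- dim(ph$image$data)
  for (v in sample(prod(d[1:3]), 40)) {
    ijk <- arrayInd(v, d[1:3])
    yv <- ph$image$data[ijk[1], ijk[2], ijk[3],
                        frame_midtimes(sched) %in% pts_ref$t] / cpv
    ref <- lm(yv ~ pts_ref$x)
    expect_equal(maps$Ki[v], unname(coef(ref)[2]), tolerance = 1e-9)
    expect_equal(maps$intercept[v], unname(coef(ref)[1]), tolerance = 1e-9)
    expect_equal(maps$sse[v], sum(residuals(ref)^2), tolerance = 1e-8)
  }
})

test_that("uniform images give uniform maps equal to the ROI fit", {
  sched <- preset_protocol("P-19f")
  cp <- make_input_tac(sched)
  ctv <- make_tissue_tac(kinetic_params(0.094, 0.3, 0.1, 0), sched)$values
  arr <- array(rep(ctv, each = 8), dim = c(2, 2, 2, n_frames(sched)))
  img <- dynamic_image(arr, sched)
  maps <- patlak_voxelwise(img, cp, t_star = 10)
  roi <- patlak(tac(sched, ctv), cp, t_star = 10)
  expect_equal(as.vector(maps$Ki), rep(roi$Ki, 8), tolerance = 1e-12)
  expect_equal(as.vector(maps$intercept), rep(roi$intercept, 8),
               tolerance = 1e-12)
  # masked voxels receive the fill value untouched
  m <- array(c(TRUE, rep(FALSE, 7)), c(2, 2, 2))
  mm <- patlak_voxelwise(img, cp, mask = m, fill = NA_real_)
  expect_true(is.na(mm$Ki[2, 2, 2]))
  expect_equal(mm$Ki[1, 1, 1], roi$Ki, tolerance = 1e-12)
})

test_that("ROI fit equals voxelwise values on uniform regions", {
  sched <- preset_protocol("P-29f")
  ph <- build_phantom(tiny_phantom_spec(noise_alpha = 0), sched)
  idif <- extract_idif(ph$image, ph$centerline)
  maps <- patlak_voxelwise(ph$image, idif, t_star = 10)
  roi <- roi_patlak(ph$image, idif, 10, ph$label_map, 2L)
  expect_equal(roi_mean(maps$Ki, ph$label_map, 2L), roi$Ki,
               tolerance = 1e-10)
  # single-voxel ROI equals that voxel's map value
  one <- array(0L, dim(ph$label_map)); one[7, 7, 3] <- 2L
  roi1 <- roi_patlak(ph$image, idif, 10, one, 2L)
  expect_equal(roi1$Ki, maps$Ki[7, 7, 3], tolerance = 1e-12)
  expect_error(roi_patlak(ph$image, idif, 10, ph$label_map, 42L),
               "not present")
})

test_that("pure-trapping lesion recovers the reference Ki within 0.5%", {
  sched <- preset_protocol("P-100f")
  cp <- make_input_tac(sched)
  ct <- make_tissue_tac(kinetic_params(0.0235, 0, 0.05, 0), sched)
  fit <- patlak(ct, cp, t_star = 10)
  expect_equal(fit$Ki * 1000, 23.5, tolerance = 0.005)
})

test_that("noiseless 2TI regions recover Ki within 5% (Vb = 0, t* = 10)", {
  sched <- preset_protocol("P-100f")
  cp <- make_input_tac(sched)
  reg <- phantom_regions()
  reg <- reg[reg$is_blood == 0, ]
  for (r in seq_len(nrow(reg))) {
    p <- kinetic_params(reg$K1[r], reg$k2[r], reg$k3[r], 0)
    fit <- patlak(make_tissue_tac(p, sched), cp, t_star = 10)
    expect_equal(fit$Ki, p$Ki, tolerance = 0.05)
  }
})

test_that("scaling the tissue data scales Ki and intercept linearly", {
  s <- preset_protocol("P-29f")
  cp <- make_input_tac(s)
  ct <- make_tissue_tac(kinetic_params(0.094, 0.3, 0.1, 0.05), s)
  f1 <- patlak(ct, cp)
  f3 <- patlak(tac(s, 3 * ct$values), cp)
  expect_equal(f3$Ki, 3 * f1$Ki, tolerance = 1e-12)
  expect_equal(f3$intercept, 3 * f1$intercept, tolerance = 1e-12)
})

test_that("all Patlak invariants hold at t* = 30 min", {
  sched <- preset_protocol("P-100f")
  cp <- make_input_tac(sched)
  # pure-trapping recovery stays exact to integration error
  ct <- make_tissue_tac(kinetic_params(0.0235, 0, 0.05, 0), sched)
  expect_equal(patlak(ct, cp, t_star = 30)$Ki * 1000, 23.5,
               tolerance = 0.005)
  # voxelwise path still matches the ROI-level independent oracle
  ph <- build_phantom(tiny_phantom_spec(seed = 6, noise_alpha = 0.5),
                      preset_protocol("P-29f"))
  idif <- extract_idif(ph$image, ph$centerline)
  maps <- patlak_voxelwise(ph$image, idif, t_star = 30)
  lesion <- lm_patlak_oracle(extract_tac(ph$image, ph$label_map == 2L),
                             idif, 30)
  expect_equal(roi_mean(maps$Ki, ph$label_map, 2L),
               unname(lesion["Ki"]), tolerance = 1e-10)
  # scale equivariance unchanged
  s29 <- preset_protocol("P-29f")
  cp29 <- make_input_tac(s29)
  ct29 <- make_tissue_tac(kinetic_params(0.094, 0.3, 0.1, 0.05), s29)
  f1 <- patlak(ct29, cp29, t_star = 30)
  f2 <- patlak(tac(s29, 2 * ct29$values), cp29, t_star = 30)
  expect_equal(f2$Ki, 2 * f1$Ki, tolerance = 1e-12)
})
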