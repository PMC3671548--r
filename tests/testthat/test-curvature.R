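test_that("periodic unwrapping removes box jumps and preserves continuous series", {
  expect_equal(unwrap_periodic(c(99, 100, 1, 2), 100), c(99, 100, 101, 102))
  x <- c(1, 2.5, 4, 5.5)
  expect_identical(unwrap_periodic(x, 100), x)
  expect_error(unwrap_periodic(c(0, 50), 100), "ambiguous")
})

test_that("unwrapped trace residual is periodic after trend removal", {
  syn <- generate_membrane(small_sinusoid_spec(seed = 13))
  lf <- assign_leaflets(syn$frame)
  ml <- trace_midline(syn$frame, lf)
  sp <- midline_spectra(ml, lambda_c = 0)
  # winding: one box traversal in X, none in Z
  expect_equal(unname(sp$winding["X"]), 1)
  expect_equal(unname(sp$winding["Z"]), 0)
  # residual after removing the winding trend closes on itself within s
  N <- nrow(ml$points)
  L <- ml$box[1]
  xu <- unwrap_periodic(ml$points[, 1], L)
  res <- xu - sp$trend_X * ml$s * (seq_len(N) - 1)
  closing <- ml$points[1, 1] - ml$points[N, 1]
  closing <- closing - L * round(closing / L)
  res_next <- (xu[N] + closing) - sp$trend_X * ml$s * N
  expect_lt(abs(res_next - res[1]), ml$s)
})

test_that("spectral filter contracts hold: identity, passband, stopband, idempotence, Parseval", {
  N <- 120
  l <- (0:(N - 1))
  z30 <- 3 * sin(2 * pi * l / 30)
  z5 <- 0.4 * sin(2 * pi * l / 5)
  ml <- mc_midline(cbind(l, 0, 20 + z30 + z5), s = 1, box = c(N, 10, 100))

  # lambda_c = 0: inverse transform returns the input exactly
  s0 <- midline_spectra(ml, lambda_c = 0)
  ser0 <- spectra_to_series(s0)
  expect_equal(ser0$z, 20 + z30 + z5, tolerance = 1e-12)
  expect_equal(ser0$x, l, tolerance = 1e-12)

  # stopband: the 5 nm component is removed, the 30 nm one preserved
  s15 <- midline_spectra(ml, lambda_c = 15)
  ser15 <- spectra_to_series(s15)
  expect_lt(max(abs(ser15$z - (20 + z30))), 1e-8)

  # pure passband signal is untouched
  ml30 <- mc_midline(cbind(l, 0, 20 + z30), s = 1, box = c(N, 10, 100))
  expect_lt(max(abs(spectra_to_series(midline_spectra(ml30, 15))$z -
                      (20 + z30))), 1e-12)

  # idempotence: filtering a filtered midline changes nothing
  ml_f <- mc_midline(cbind(ser15$x, 0, ser15$z), s = 1, box = c(N, 10, 100))
  ser2 <- spectra_to_series(midline_spectra(ml_f, lambda_c = 15))
  expect_equal(ser2$z, ser15$z, tolerance = 1e-12)

  # Parseval: filtering cannot increase spectral energy
  expect_lte(sum(Mod(s15$S_Z)^2), sum(Mod(s0$S_Z)^2))
  expect_error(midline_spectra(mc_midline(cbind(1:5, 0, 1:5), 1,
                                          c(10, 10, 10)), 15), "at least 8")
})

test_that("curvature of a straight line is zero and of a circle is 1/R", {
  l <- 0:99
  ml <- mc_midline(cbind(l, 0, rep(5, 100)), s = 1, box = c(100, 10, 100))
  prof <- curvature_profile(midline_spectra(ml, lambda_c = 0))
  expect_lt(max(abs(prof$kappa)), 1e-10)

  ml_c <- circle_midline(R = 20)
  expect_equal(nrow(ml_c$points), 126)
  prof_c <- curvature_profile(midline_spectra(ml_c, lambda_c = 0))
  expect_equal(abs(prof_c$kappa), rep(1 / 20, 126), tolerance = 0.01)
})

test_that("curvature sign flips under orientation reversal, magnitude does not", {
  ml <- circle_midline(R = 20)
  prof <- curvature_profile(midline_spectra(ml, lambda_c = 0))
  ml_rev <- mc_midline(ml$points[rev(seq_len(nrow(ml$points))), ],
                       s = ml$s, box = ml$box)
  prof_rev <- curvature_profile(midline_spectra(ml_rev, lambda_c = 0))
  expect_equal(sign(mean(prof$kappa)), -sign(mean(prof_rev$kappa)))
  expect_equal(mean(abs(prof$kappa)), mean(abs(prof_rev$kappa)),
               tolerance = 1e-9)
})

test_that("spectral first derivative matches central finite differences on a band-limited midline", {
  N <- 200
  l <- 0:(N - 1)
  z <- 20 + 4 * sin(2 * pi * l / 50) + 1.5 * cos(2 * pi * l / 25)
  ml <- mc_midline(cbind(l, 0, z), s = 1, box = c(N, 10, 100))
  sp <- midline_spectra(ml, lambda_c = 0)
  om <- memcurv:::.spectral_omegas(N, 1)
  zd <- memcurv:::.ifft_re(sp$S_Z * om$d1) + sp$trend_Z
  zd_fd <- (z[c(2:N, 1)] - z[c(N, 1:(N - 1))]) / 2
  # central differences themselves carry O(h^2) error; compare where the
  # signal is band-limited the schemes agree to ~1e-3 relative
  expect_lt(max(abs(zd - zd_fd)) / max(abs(zd)), 2e-2)
  # and against the analytic derivative to high accuracy
  zd_true <- 4 * (2 * pi / 50) * cos(2 * pi * l / 50) -
    1.5 * (2 * pi / 25) * sin(2 * pi * l / 25)
  expect_lt(max(abs(zd - zd_true)) / max(abs(zd_true)), 1e-10)
})

test_that("sinusoid crest curvature from the traced pipeline matches the closed form", {
  spec <- small_sinusoid_spec(seed = 3)   # A = 5, wavelength = 50
  syn <- generate_membrane(spec)
  lf <- assign_leaflets(syn$frame)
  prof <- curvature_profile(midline_spectra(trace_midline(syn$frame, lf), 15))
  crest_true <- 5 * (2 * pi / 50)^2
  expect_equal(max(abs(prof$kappa)), crest_true, tolerance = 0.05)
})

test_that("degenerate parameterization is rejected", {
  # all points identical in X with tiny Z wiggle: speed ~ 0
  ml <- mc_midline(cbind(rep(5, 16), 0, 5 + 1e-9 * sin(1:16)), s = 1,
                   box = c(10, 10, 10))
  expect_error(curvature_profile(midline_spectra(ml, 0)), "vanishing")
})

test_that("mean curvature is the mean magnitude and matches quadrature on a sinusoid", {
  ml_c <- circle_midline(R = 50 / 3)   # R = 16.67 nm
  prof <- curvature_profile(midline_spectra(ml_c, lambda_c = 0))
  expect_equal(mean_curvature(prof), 0.06, tolerance = 0.01)

  # flat midline
  ml_f <- mc_midline(cbind(0:49, 0, rep(3, 50)), s = 1, box = c(50, 10, 50))
  expect_lt(mean_curvature(curvature_profile(midline_spectra(ml_f, 0))), 1e-10)

  # traced sinusoid vs dense quadrature of the analytic |kappa(l)|
  spec <- small_sinusoid_spec(seed = 3)
  syn <- generate_membrane(spec)
  lf <- assign_leaflets(syn$frame)
  prof_s <- curvature_profile(midline_spectra(trace_midline(syn$frame, lf), 15))
  xg <- seq(0, 50, length.out = 20001)[-20001]
  sp <- sqrt(1 + curve_eval(spec$curve, xg)$dz^2)
  mean_k_quad <- sum(abs(curve_kappa(spec$curve, xg)) * sp) / sum(sp)
  expect_equal(mean_curvature(prof_s), mean_k_quad, tolerance = 0.02)
})

test_that("curvature time series is flat for flat frames and grows along an amplitude ramp", {
  spec <- membrane_spec(curve_flat(z0 = 12.5), box = c(50, 10, 25),
                        n_x = 64, n_y = 12, sigma = 0, seed = 2)
  frames <- generate_trajectory(spec, n_frames = 3, frame_dt = 4)$frames
  ts <- curvature_timeseries(frames)
  expect_equal(nrow(ts), 3)
  expect_true(all(ts$mean_abs_kappa < 1e-6))
  expect_equal(ts$time, c(0, 4, 8))

  # single frame
  ts1 <- curvature_timeseries(frames[1])
  expect_equal(nrow(ts1), 1)

  # amplitude ramp: mean |kappa| grows monotonically (5% slack for noise)
  amps <- c(1, 2.5, 4, 5)
  curves <- lapply(amps, function(A) curve_sinusoid(A, 50, z0 = 15))
  spec_r <- small_sinusoid_spec(seed = 31)
  traj <- generate_trajectory(spec_r, curves = curves, frame_dt = 4)
  tsr <- curvature_timeseries(traj$frames)
  expect_equal(nrow(tsr), 4)
  expect_true(all(diff(tsr$mean_abs_kappa) > -0.05 * tsr$mean_abs_kappa[-1]))
  expect_gt(tsr$mean_abs_kappa[4], tsr$mean_abs_kappa[1])
})
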