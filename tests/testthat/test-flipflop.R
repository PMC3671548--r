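test_that("flip-flop detection applies the different-lipids restriction", {
  # constant residence: no events
  states <- rep(list(c("upper", "DOPC")), 11)
  rec <- detect_flipflops(residence_from_states(states))
  expect_equal(nrow(rec$events), 0)
  expect_length(rec$intervals, 0)

  # alternation between (upper, DOPC) and (lower, DOPS): 10 events,
  # all intervals equal to the frame spacing
  alt <- rep(list(c("upper", "DOPC"), c("lower", "DOPS")), length.out = 11)
  rec2 <- detect_flipflops(residence_from_states(alt, frame_dt = 4))
  expect_equal(nrow(rec2$events), 10)
  expect_true(all(rec2$intervals == 4))

  # leaflet changes but lipid type identical on both sides: NOT counted
  mixed <- rep(list(c("upper", "DOPC"), c("lower", "DOPC")), length.out = 11)
  rec3 <- detect_flipflops(residence_from_states(mixed))
  expect_equal(nrow(rec3$events), 0)

  # non-uniform frame times are rejected
  bad <- residence_from_states(alt)
  bad$time[5] <- bad$time[5] + 1
  expect_error(detect_flipflops(bad), "non-uniform")
})

test_that("debouncing removes the frame-rate oscillation artifact but keeps genuine transitions", {
  # molecule oscillates on consecutive frames (artifact), then later makes
  # one isolated genuine transition
  states <- list(c("upper", "DOPC"), c("lower", "DOPS"), c("upper", "DOPC"),
                 c("upper", "DOPC"), c("upper", "DOPC"), c("upper", "DOPC"),
                 c("lower", "DOPS"), c("lower", "DOPS"), c("lower", "DOPS"))
  res <- residence_from_states(states, frame_dt = 4)
  raw <- detect_flipflops(res, debounce = 0)
  expect_equal(nrow(raw$events), 3)
  deb <- detect_flipflops(res, debounce = 4)
  expect_equal(nrow(deb$events), 1)
  expect_equal(deb$events$time, 24)
})

test_that("interval histogram bins pooled intervals and matches Poisson bands for exponential draws", {
  h <- interval_histogram(rep(4, 10), bin_width = 4)
  expect_equal(sum(h$counts > 0), 1)
  h2 <- interval_histogram(c(4, 4, 8), bin_width = 4)
  expect_equal(h2$counts, c(2, 1))
  expect_error(interval_histogram(numeric(0), 4), "no intervals")

  iv <- generate_intervals(1, 100, 1e5, seed = 12)
  h3 <- interval_histogram(iv, bin_width = 10)
  expected <- 1e5 * (exp(-h3$breaks[-length(h3$breaks)] / 100) -
                       exp(-h3$breaks[-1] / 100))
  keep <- expected > 25
  expect_true(all(abs(h3$counts[keep] - expected[keep]) <
                    3 * sqrt(expected[keep]) + 1))
})

test_that("double-exponential fit recovers exact model parameters from noiseless bins", {
  t <- seq(2, 1598, by = 4)
  y <- 1000 * exp(-t / 4) + 100 * exp(-t / 300)
  h <- list(mids = t, counts = y, breaks = c(0, t + 2), bin_width = 4)
  fit <- fit_double_exponential(h)
  expect_equal(fit$A1, 1000, tolerance = 1e-3)
  expect_equal(fit$t1, 4, tolerance = 1e-3)
  expect_equal(fit$A2, 100, tolerance = 1e-3)
  expect_equal(fit$t2, 300, tolerance = 1e-3)
  expect_false(fit$degenerate)
})

test_that("Monte-Carlo mixture recovery within 10 percent and t2 error shrinks with sample size", {
  iv <- generate_intervals(c(0.8, 0.2), c(4, 300), 2e5, seed = 42)
  fit <- fit_double_exponential(interval_histogram(iv, 4), frame_dt = 4)
  expect_equal(fit$t1, 4, tolerance = 0.1)
  expect_equal(fit$t2, 300, tolerance = 0.1)
  expect_true(fit$t1_artifact)   # t1 ~ frame spacing is flagged

  # MLE cross-check mode agrees
  mle <- fit_interval_mle(iv)
  expect_equal(mle$t1, 4, tolerance = 0.1)
  expect_equal(mle$t2, 300, tolerance = 0.1)

  errs <- vapply(c(1e3, 1e4, 1e5), function(n) {
    ivn <- generate_intervals(c(0.8, 0.2), c(4, 300), n, seed = 5)
    abs(fit_double_exponential(interval_histogram(ivn, 4))$t2 / 300 - 1)
  }, numeric(1))
  expect_true(errs[3] < errs[1])
})

test_that("single-exponential data is flagged: model comparison prefers one timescale", {
  iv <- generate_intervals(1, 100, 5e4, seed = 9)
  fit <- fit_double_exponential(interval_histogram(iv, 4))
  expect_true(fit$prefers_single || fit$degenerate)
  expect_error(fit_double_exponential(interval_histogram(rep(4, 10), 4)),
               "occupied bins")
})

test_that("fit is stable under halving the histogram bin width", {
  iv <- generate_intervals(c(0.7, 0.3), c(10, 200), 1e5, seed = 77)
  f4 <- fit_double_exponential(interval_histogram(iv, 4))
  f2 <- fit_double_exponential(interval_histogram(iv, 2))
  tol_t1 <- 3 * sqrt(f4$se["t1"]^2 + f2$se["t1"]^2) + 0.05 * f4$t1
  tol_t2 <- 3 * sqrt(f4$se["t2"]^2 + f2$se["t2"]^2) + 0.05 * f4$t2
  expect_lt(abs(f4$t1 - f2$t1), tol_t1)
  expect_lt(abs(f4$t2 - f2$t2), tol_t2)
})

test_that("planted flip-flop schedules are detected exactly through the full pipeline", {
  spec <- small_sinusoid_spec(seed = 7, n_chol = 40, sigma = 0)
  n_lip <- 2 * spec$n_x * spec$n_y
  sched <- data.frame(molecule_id = n_lip + c(3, 3, 7, 12),
                      frame = c(3, 6, 4, 9))
  traj <- generate_trajectory(spec, n_frames = 10, frame_dt = 4,
                              flip_schedule = sched)
  res <- residence_series(traj$frames)
  rec <- detect_flipflops(res, debounce = 0)
  got <- rec$events[order(rec$events$molecule_id, rec$events$time), ]
  want <- traj$events[traj$events$counted, ]
  want <- want[order(want$molecule_id, want$time), ]
  expect_equal(got$molecule_id, want$molecule_id)
  expect_equal(got$time, want$time)
})
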