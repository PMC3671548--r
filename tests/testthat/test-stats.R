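test_that("curvature sampling at points picks the nearest midline point", {
  ml <- circle_midline(R = 20)
  prof <- curvature_profile(midline_spectra(ml, 0))
  # coincident with midline point i -> kappa_i
  expect_equal(sample_curvature_at_points(prof, ml, ml$points[7, , drop = FALSE]),
               prof$kappa[7])
  # displaced 1 nm along the local (radial) normal keeps the same nearest point
  ctr <- c(ml$box[1] / 2, 0, ml$box[3] / 2)
  u <- ml$points[7, ] - c(ctr[1], 0, ctr[3])
  u <- u / sqrt(sum(u^2))
  q <- ml$points[7, ] + u * 1
  expect_equal(sample_curvature_at_points(prof, ml, matrix(q, 1)),
               prof$kappa[7])
})

test_that("curvature at planted cholesterol positions matches the analytic curve", {
  spec <- small_sinusoid_spec(seed = 14, n_chol = 40)
  syn <- generate_membrane(spec)
  lf <- assign_leaflets(syn$frame)
  ml <- trace_midline(syn$frame, lf)
  prof <- curvature_profile(midline_spectra(ml, 15))
  ci <- which(syn$frame$bead_kind == "chol_head")
  ks <- sample_curvature_at_points(prof, ml, syn$frame$coords[ci, , drop = FALSE])
  kt <- syn$truth$chol$kappa
  # 5% of the curvature scale (nearest-point sampling + spectral filtering)
  expect_lt(sqrt(mean((abs(ks) - abs(kt))^2)), 0.05 * max(abs(kt)))
})

test_that("curvature distributions are density-normalized histograms of |kappa|", {
  d <- curvature_distribution(rep(0.05, 100), bin_width = 0.01)
  expect_equal(sum(d$P * d$bin_width), 1, tolerance = 1e-9)
  expect_equal(sum(d$counts > 0), 1)
  expect_error(curvature_distribution(numeric(0), 0.01), "no samples")
  expect_error(curvature_distribution(c(0.1), -1), "bin_width")

  # uniform samples stay within 3-sigma multinomial bands of the flat density
  set.seed(42)
  x <- runif(1e5, 0, 0.1)
  du <- curvature_distribution(x, bin_width = 0.01, kappa_max = 0.1)
  p0 <- 0.01 / 0.1
  sd3 <- 3 * sqrt(1e5 * p0 * (1 - p0))
  expect_true(all(abs(du$counts - 1e5 * p0) < sd3))
})

test_that("free-energy profiles obey the identity, unit-log-ratio and Joule arithmetic", {
  set.seed(7)
  x <- runif(5000, 0, 0.1)
  Pa <- curvature_distribution(x, 0.01, 0.1)
  fe0 <- free_energy_profile(Pa, Pa, T = 320)
  expect_true(all(fe0$E_kBT[!fe0$masked] == 0))

  # constructed ratio e in one bin -> E = -1 kBT; ratio 2 -> -ln 2
  mk <- function(counts) {
    n <- sum(counts)
    structure(list(breaks = seq(0, 0.03, 0.01), mids = c(0.005, 0.015, 0.025),
                   counts = counts, P = counts / (n * 0.01), n = n,
                   bin_width = 0.01, condition = "constructed"),
              class = "mc_curvdist")
  }
  base <- c(1000, 1000, 1000)
  ratio_e <- round(base * c(exp(1), 1, 1))
  fe <- free_energy_profile(mk(ratio_e), mk(base), T = 320)
  # normalization shifts all bins equally; differences carry the signal
  expect_equal(fe$E_kBT[1] - fe$E_kBT[2], -1, tolerance = 1e-3)

  fe2 <- free_energy_profile(mk(c(2000, 1000, 1000)), mk(base), T = 320)
  dE <- fe2$E_kBT[1] - fe2$E_kBT[2]
  expect_equal(dE, -log(2), tolerance = 1e-6)
  expect_equal(fe2$E_J[1] - fe2$E_J[2], 1.380649e-23 * 320 * dE)
  expect_equal(-log(2) * 1.380649e-23 * 320, -3.063e-21, tolerance = 1e-3)

  expect_error(free_energy_profile(Pa, mk(base)), "binning")
})

test_that("free energy is antisymmetric and masks under-sampled bins", {
  set.seed(11)
  a <- curvature_distribution(rbeta(2e4, 2, 5) * 0.15, 0.0085, 0.15)
  b <- curvature_distribution(runif(2e4, 0, 0.15), 0.0085, 0.15)
  fab <- free_energy_profile(a, b, n_min = 10)
  fba <- free_energy_profile(b, a, n_min = 10)
  expect_equal(fab$E_kBT[!fab$masked], -fba$E_kBT[!fba$masked])
  expect_true(all(is.na(fab$E_kBT[fab$masked])))
  expect_true(all(fab$masked == (a$counts < 10 | b$counts < 10)))
})

test_that("a planted Boltzmann re-weighting energy is recovered from 1e6 draws", {
  set.seed(101)
  n <- 1e6
  kmax <- 0.17
  E_fun <- function(k) 1.5 * sin(2 * pi * k / kmax)
  kb_s <- runif(n, 0, kmax)
  Mx <- exp(1.5)
  cand <- runif(3 * n, 0, kmax)
  acc <- runif(3 * n) < exp(-E_fun(cand)) / Mx
  ka_s <- cand[acc][seq_len(n)]
  Pb <- curvature_distribution(kb_s, 0.0085, kmax)
  Pa <- curvature_distribution(ka_s, 0.0085, kmax)
  fe <- free_energy_profile(Pa, Pb, T = 320, n_min = 500)
  # normalization constant of the re-weighting, by quadrature
  kg <- seq(0, kmax, length.out = 20001)
  lnZ <- log(mean(exp(-E_fun(kg))))
  ok <- !fe$masked
  expect_gt(sum(ok), 10)
  expect_lt(max(abs(fe$E_kBT[ok] - (E_fun(fe$kappa[ok]) + lnZ))), 0.05)
})

test_that("partition ratio uses pooled counts and is invariant under frame duplication", {
  res1 <- data.frame(frame = 1, domain = c(rep("DOPC", 10), rep("DOPS", 10)))
  expect_equal(partition_ratio(res1), 1.0)

  res2 <- data.frame(frame = rep(1:3, each = 165),
                     domain = rep(c(rep("DOPC", 65), rep("DOPS", 100)), 3))
  expect_equal(partition_ratio(res2), 0.65)

  # two frames (10, 20) and (30, 20): pooled = 40/40 = 1.0
  res3 <- data.frame(frame = c(rep(1, 30), rep(2, 50)),
                     domain = c(rep("DOPC", 10), rep("DOPS", 20),
                                rep("DOPC", 30), rep("DOPS", 20)))
  expect_equal(partition_ratio(res3), 1.0)
  expect_equal(partition_ratio(rbind(res3, res3)), partition_ratio(res3))

  expect_error(partition_ratio(data.frame(frame = 1, domain = "DOPC")),
               "undefined|DOPS")
  expect_error(partition_ratio(res1[0, , drop = FALSE]), "empty")
})
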