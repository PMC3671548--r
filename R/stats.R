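#' Boltzmann constant (J/K)
#' @keywords internal
.kB <- 1.380649e-23

#' Curvature at arbitrary points (e.g. cholesterol locations)
#'
#' Each query point receives the curvature of its nearest midline point
#' (full 3D minimum-image distance); exact ties resolve to the lower midline
#' index.
#'
#' @param profile an `mc_curvature` aligned index-wise with `midline`.
#' @param midline the `mc_midline` the profile was computed from.
#' @param points m x 3 matrix of query positions (nm).
#' @return numeric vector of kappa values (nm^-1), one per query point.
#' @export
sample_curvature_at_points <- function(profile, midline, points) {
  points <- matrix(points, ncol = 3)
  if (nrow(points) == 0) return(numeric(0))
  P <- midline$points
  chunk <- 512L
  out <- numeric(nrow(points))
  for (cb in seq_len(ceiling(nrow(points) / chunk))) {
    rows <- (((cb - 1L) * chunk + 1L):min(cb * chunk, nrow(points)))
    D2 <- pbc_dist2_cross(points[rows, , drop = FALSE], P, midline$box,
                          midline$periodic)
    out[rows] <- profile$kappa[apply(D2, 1, which.min)]
  }
  out
}

#' Histogram of curvature magnitudes
#'
#' Density-normalized distribution of `|kappa|` over fixed-width bins
#' starting at zero: `sum(P * bin_width) == 1`.
#'
#' @param samples numeric kappa samples (nm^-1); magnitudes are taken.
#' @param bin_width bin width (nm^-1); default 0.0085.
#' @param kappa_max optional upper edge; defaults to covering `max(|samples|)`.
#'   Pass a common value when two distributions must share binning.
#' @param condition free-text label of the sampling condition.
#' @return object of class `mc_curvdist`: `breaks`, `mids`, `counts`, `P`
#'   (density), `n`, `bin_width`, `condition`.
#' @export
curvature_distribution <- function(samples, bin_width = 0.0085,
                                   kappa_max = NULL,
                                   condition = "all_midline") {
  samples <- samples[is.finite(samples)]
  if (length(samples) == 0) stop("curvature_distribution: no samples")
  if (!is.finite(bin_width) || bin_width <= 0) {
    stop("curvature_distribution: bin_width must be > 0")
  }
  a <- abs(samples)
  if (is.null(kappa_max)) kappa_max <- max(a) * (1 + 1e-12)
  nb <- max(1L, as.integer(ceiling(kappa_max / bin_width)))
  breaks <- (0:nb) * bin_width
  if (max(a) > breaks[nb + 1]) {
    stop("curvature_distribution: kappa_max too small for the samples")
  }
  counts <- graphics::hist(a, breaks = breaks, plot = FALSE)$counts
  structure(list(breaks = breaks, mids = (breaks[-1] + breaks[-(nb + 1)]) / 2,
                 counts = counts, P = counts / (length(a) * bin_width),
                 n = length(a), bin_width = bin_width,
                 condition = condition),
            class = "mc_curvdist")
}

#' Boltzmann-inversion free-energy profile between two curvature distributions
#'
#' \eqn{E(\kappa) = -k_B T \ln(P_a(\kappa) / P_b(\kappa))} per bin. Bins in
#' which either distribution holds fewer than `n_min` samples are masked
#' (`NA`); no values are extrapolated into unsampled regions.
#'
#' @param P_a,P_b `mc_curvdist` objects on identical binning.
#' @param T temperature (K); default 320.
#' @param n_min minimum per-bin sample count for an unmasked energy.
#' @return object of class `mc_energy`: data.frame-like list with `kappa`
#'   (bin centres), `E_kBT`, `E_J`, `masked`, plus `T`.
#' @export
free_energy_profile <- function(P_a, P_b, T = 320, n_min = 10) {
  if (T <= 0) stop("free_energy_profile: T must be > 0")
  if (length(P_a$breaks) != length(P_b$breaks) ||
      !isTRUE(all.equal(P_a$breaks, P_b$breaks))) {
    stop("free_energy_profile: distributions must share identical binning")
  }
  masked <- P_a$counts < n_min | P_b$counts < n_min
  E <- -log(P_a$P / P_b$P)
  E[masked] <- NA_real_
  structure(list(kappa = P_a$mids, E_kBT = E, E_J = .kB * T * E,
                 masked = masked, T = T, n_min = n_min),
            class = "mc_energy")
}

#' Time-averaged cholesterol partition ratio between lipid domains
#'
#' Pooled-count convention: counts of cholesterol residing in each domain
#' type are summed over frames before taking the ratio (robust to frames
#' with zero occupancy).
#'
#' @param residence long residence data.frame (see [residence_series()])
#'   with a `domain` column; may span many frames.
#' @param numerator,denominator domain labels; defaults `"DOPC"` / `"DOPS"`.
#' @return the ratio r = sum counts in `numerator` / sum counts in
#'   `denominator`.
#' @export
partition_ratio <- function(residence, numerator = "DOPC",
                            denominator = "DOPS") {
  if (is.null(residence) || nrow(residence) == 0) {
    stop("partition_ratio: empty residence table")
  }
  n_num <- sum(residence$domain == numerator)
  n_den <- sum(residence$domain == denominator)
  if (n_den == 0) {
    stop(sprintf("partition_ratio: no cholesterol ever resides in %s domains; ratio undefined",
                 denominator))
  }
  n_num / n_den
}
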