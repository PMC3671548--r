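#' Unwrap a periodic coordinate series
#'
#' Removes box jumps from a coordinate sampled along the midline so the
#' series is continuous and FFT-able across the periodic seam. Consecutive
#' minimum-image increments must be unambiguous (strictly less than half the
#' box length in magnitude).
#'
#' @param x numeric series of wrapped coordinates (nm).
#' @param box_length box length (nm) along the axis.
#' @return unwrapped series; `x[1]` is preserved.
#' @export
unwrap_periodic <- function(x, box_length) {
  if (length(x) < 2) return(x)
  d <- diff(x)
  dm <- pbc_disp1(d, box_length)
  if (any(abs(dm) >= box_length / 2 * (1 - 1e-9))) {
    stop("unwrap_periodic: ambiguous jump of at least half the box length")
  }
  c(x[1], x[1] + cumsum(dm))
}

# Decompose an unwrapped closed series into winding (linear trend) +
# periodic residual. `closing` is the minimum-image increment from the last
# stored point back to the first.
.decompose_winding <- function(xu, closing, L, N) {
  total <- xu[N] + closing - xu[1]
  W <- round(total / L)
  slope_idx <- W * L / N                # advance per index step
  residual <- xu - slope_idx * (seq_len(N) - 1)
  list(winding = W, slope_idx = slope_idx, residual = residual)
}

#' Fourier spectra of the midline coordinates with low-pass filtering
#'
#' Represents the midline as two parametric series `X(l_i)`, `Z(l_i)` with
#' `l_i = i s`, unwraps each across the periodic box, separates the linear
#' winding trend (one box traversal per loop for a membrane spanning X), and
#' takes the FFT of the periodic residuals. Spectral components with
#' wavelength `lambda <= lambda_c` are zeroed (hard low-pass; the DC term
#' and the winding trend are always kept), suppressing the short-wavelength
#' noise that would otherwise dominate the derivatives.
#'
#' @param midline an `mc_midline` (closed).
#' @param lambda_c cut-off wavelength (nm); components with
#'   `lambda <= lambda_c` are discarded. `0` disables filtering. Default 15.
#' @return object of class `mc_spectra` holding the filtered complex
#'   spectra `S_X`, `S_Z`, the component wavelengths, the winding trends and
#'   bookkeeping (`N`, `s`, `time`).
#' @export
midline_spectra <- function(midline, lambda_c = 15) {
  P <- midline$points
  N <- nrow(P)
  if (N < 8) stop("midline_spectra: need at least 8 midline points")
  s <- midline$s
  box <- midline$box

  prep <- function(axis) {
    L <- box[axis]
    xu <- unwrap_periodic(P[, axis], L)
    closing <- pbc_disp1(P[1, axis] - P[N, axis], L)
    .decompose_winding(xu, closing, L, N)
  }
  dx <- prep(1)
  dz <- prep(3)

  k <- 0:(N - 1)
  m <- pmin(k, N - k)                    # folded harmonic index
  lambda <- ifelse(m == 0, Inf, N * s / m)
  keep <- m == 0 | lambda > lambda_c

  S_X <- stats::fft(dx$residual)
  S_Z <- stats::fft(dz$residual)
  S_X[!keep] <- 0
  S_Z[!keep] <- 0

  structure(list(S_X = S_X, S_Z = S_Z, lambda = lambda, lambda_c = lambda_c,
                 N = N, s = s,
                 trend_X = dx$slope_idx / s,  # dX/dl contribution
                 trend_Z = dz$slope_idx / s,
                 winding = c(X = dx$winding, Z = dz$winding),
                 time = midline$time),
            class = "mc_spectra")
}

# signed angular frequencies (rad per nm of arc length); Nyquist handled
# conservatively: zero for the first derivative, -omega^2 for the second
.spectral_omegas <- function(N, s) {
  k <- 0:(N - 1)
  ks <- ifelse(k <= N / 2, k, k - N)
  omega <- 2 * pi * ks / (N * s)
  d1 <- 1i * omega
  if (N %% 2 == 0) d1[N / 2 + 1] <- 0
  list(d1 = d1, d2 = -omega^2)
}

.ifft_re <- function(S) Re(stats::fft(S, inverse = TRUE)) / length(S)

#' Reconstruct the filtered midline coordinates from spectra
#'
#' @param spectra an `mc_spectra`.
#' @return list with `l`, `x`, `z` of the low-pass-filtered midline.
#' @export
spectra_to_series <- function(spectra) {
  l <- (seq_len(spectra$N) - 1) * spectra$s
  list(l = l,
       x = .ifft_re(spectra$S_X) + spectra$trend_X * l,
       z = .ifft_re(spectra$S_Z) + spectra$trend_Z * l)
}

#' Signed parametric curvature of the midline by spectral differentiation
#'
#' First and second derivatives of `X(l)` and `Z(l)` are obtained by
#' multiplying the spectra by `i 2 pi / lambda` (once and twice) and
#' inverse-transforming; the winding trend contributes its constant slope to
#' the first derivatives. The signed plane-curve curvature is then
#' \deqn{\kappa(l) = \frac{\dot X \ddot Z - \dot Z \ddot X}
#'                       {(\dot X^2 + \dot Z^2)^{3/2}}.}
#'
#' @param spectra an `mc_spectra` from [midline_spectra()].
#' @return object of class `mc_curvature`: `kappa` (nm^-1), `l` (nm),
#'   filtered `x`, `z`, `time`, `lambda_c`.
#' @export
curvature_profile <- function(spectra) {
  N <- spectra$N
  om <- .spectral_omegas(N, spectra$s)
  xd <- .ifft_re(spectra$S_X * om$d1) + spectra$trend_X
  zd <- .ifft_re(spectra$S_Z * om$d1) + spectra$trend_Z
  xdd <- .ifft_re(spectra$S_X * om$d2)
  zdd <- .ifft_re(spectra$S_Z * om$d2)
  speed2 <- xd^2 + zd^2
  if (any(speed2 < 1e-12)) {
    stop("curvature_profile: vanishing parameterization speed (degenerate midline)")
  }
  kappa <- (xd * zdd - zd * xdd) / speed2^1.5
  ser <- spectra_to_series(spectra)
  structure(list(kappa = kappa, l = ser$l, x = ser$x, z = ser$z,
                 time = spectra$time, lambda_c = spectra$lambda_c),
            class = "mc_curvature")
}

#' Mean absolute midline curvature
#'
#' The mean bilayer curvature is the arithmetic mean of `|kappa|` over the
#' midline points (the signed mean of a closed meander is near zero and
#' carries no shape information).
#'
#' @param profile an `mc_curvature`.
#' @return mean |kappa| (nm^-1).
#' @export
mean_curvature <- function(profile) {
  if (length(profile$kappa) == 0) stop("mean_curvature: empty profile")
  mean(abs(profile$kappa))
}

#' Per-frame mean curvature over a trajectory
#'
#' Assigns leaflets on the first frame, then per frame traces the midline,
#' filters, differentiates and records the mean absolute curvature. Frames
#' whose trace or curvature computation fails are skipped with a warning;
#' more than 10% skipped frames is an error.
#'
#' @param frames list of [mc_frame()] objects.
#' @param s,r_p,r_loc,lambda_c pipeline parameters (nm).
#' @return data.frame with `time` (ns), `mean_abs_kappa` (nm^-1),
#'   `n_points`.
#' @export
curvature_timeseries <- function(frames, s = 1.0, r_p = 2.0, r_loc = 3.0,
                                 lambda_c = 15) {
  if (length(frames) < 1) stop("curvature_timeseries: need at least one frame")
  leaflets <- assign_leaflets(frames[[1]], r_p)
  rows <- lapply(frames, function(fr) {
    tryCatch({
      ml <- trace_midline(fr, leaflets, s = s, r_loc = r_loc)
      prof <- curvature_profile(midline_spectra(ml, lambda_c))
      data.frame(time = fr$time, mean_abs_kappa = mean_curvature(prof),
                 n_points = nrow(ml$points))
    }, error = function(e) {
      warning(sprintf("frame at t = %g ns skipped: %s", fr$time,
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
  })
  n_bad <- sum(vapply(rows, is.null, logical(1)))
  if (n_bad > 0.1 * length(frames)) {
    stop(sprintf("curvature_timeseries: %d of %d frames failed", n_bad,
                 length(frames)))
  }
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}
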