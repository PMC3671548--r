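#' Run the full curvature/cholesterol analysis pipeline on a trajectory
#'
#' Per frame: leaflet assignment (first frame, propagated), midline trace,
#' spectral filtering and curvature. Pooled over frames: the curvature
#' distribution sampled at the midline points, the distributions sampled at
#' cholesterol locations (all, and split by the lipid domain the cholesterol
#' resides in), the Boltzmann free-energy profiles between them, the
#' cholesterol partition ratio, and — given at least two frames — flip-flop
#' detection and the double-exponential interval fit.
#'
#' @param frames list of [mc_frame()] objects.
#' @param s midline spacing (nm).
#' @param r_p leaflet graph cut-off (nm).
#' @param r_loc local-frame lateral radius (nm).
#' @param lambda_c spectral cut-off wavelength (nm).
#' @param bin_width curvature histogram bin width (nm^-1).
#' @param T temperature (K) for free energies.
#' @param debounce flip-flop debounce window (ns).
#' @param interval_bin_width flip-flop interval histogram bin width (ns);
#'   defaults to the frame spacing.
#' @param n_min minimum per-bin count for unmasked free energies.
#' @return a nested list (class `mc_report`) with components
#'   `params`, `curvature` (per-frame mean-curvature table),
#'   `distributions`, `energies`, `partition_ratio`, `flipflop`.
#' @export
membrane_report <- function(frames, s = 1.0, r_p = 2.0, r_loc = 3.0,
                            lambda_c = 15, bin_width = 0.0085, T = 320,
                            debounce = 0, interval_bin_width = NULL,
                            n_min = 10) {
  leaflets <- assign_leaflets(frames[[1]], r_p)

  mid_samples <- list()
  chol_samples <- list()
  curv_rows <- list()
  res_rows <- list()
  for (f in seq_along(frames)) {
    fr <- frames[[f]]
    ml <- trace_midline(fr, leaflets, s = s, r_loc = r_loc)
    prof <- curvature_profile(midline_spectra(ml, lambda_c))
    curv_rows[[f]] <- data.frame(time = fr$time,
                                 mean_abs_kappa = mean_curvature(prof),
                                 n_points = nrow(ml$points))
    mid_samples[[f]] <- prof$kappa
    ci <- chol_idx(fr)
    if (length(ci) > 0) {
      res <- assign_cholesterol_residence(fr, leaflets)
      res_rows[[f]] <- cbind(frame = f, time = fr$time,
                             res[c("molecule_id", "leaflet", "domain")])
      kc <- sample_curvature_at_points(prof, ml, fr$coords[ci, , drop = FALSE])
      chol_samples[[f]] <- data.frame(kappa = kc, domain = res$domain)
    }
  }
  curvature <- do.call(rbind, curv_rows)
  residence <- if (length(res_rows)) do.call(rbind, res_rows) else NULL
  mid_k <- unlist(mid_samples)
  chol_df <- if (length(chol_samples)) do.call(rbind, chol_samples) else NULL

  kmax <- max(abs(mid_k), if (!is.null(chol_df)) abs(chol_df$kappa) else 0) *
    (1 + 1e-9)
  dists <- list(all_midline = curvature_distribution(
    mid_k, bin_width, kmax, condition = "all_midline"))
  energies <- list()
  pr <- NULL
  if (!is.null(chol_df) && nrow(chol_df) > 0) {
    dists$chol_all <- curvature_distribution(chol_df$kappa, bin_width, kmax,
                                             condition = "chol_all")
    energies$chol_vs_midline <- free_energy_profile(dists$chol_all,
                                                    dists$all_midline, T,
                                                    n_min)
    for (dom in c("DOPC", "DOPS")) {
      kk <- chol_df$kappa[chol_df$domain == dom]
      if (length(kk) > 0) {
        dists[[paste0("chol_in_", dom)]] <- curvature_distribution(
          kk, bin_width, kmax, condition = paste0("chol_in_", dom))
      }
    }
    if (!is.null(dists$chol_in_DOPC) && !is.null(dists$chol_in_DOPS)) {
      energies$transfer_DOPC_to_DOPS <- free_energy_profile(
        dists$chol_in_DOPS, dists$chol_in_DOPC, T, n_min)
    }
    pr <- tryCatch(partition_ratio(residence), error = function(e) NULL)
  }

  flip <- NULL
  if (!is.null(residence) && length(frames) >= 2) {
    flip <- tryCatch({
      rec <- detect_flipflops(residence, debounce = debounce)
      bw <- if (is.null(interval_bin_width)) rec$frame_dt else interval_bin_width
      fit <- if (length(rec$intervals) > 0) {
        h <- interval_histogram(rec, bw)
        tryCatch(fit_double_exponential(h, frame_dt = rec$frame_dt),
                 error = function(e) list(error = conditionMessage(e)))
      } else NULL
      list(n_events = nrow(rec$events), n_intervals = length(rec$intervals),
           frame_dt = rec$frame_dt, debounce = debounce, fit = fit)
    }, error = function(e) list(error = conditionMessage(e)))
  }

  structure(list(
    params = list(s = s, r_p = r_p, r_loc = r_loc, lambda_c = lambda_c,
                  bin_width = bin_width, T = T, debounce = debounce,
                  n_frames = length(frames)),
    curvature = curvature,
    distributions = dists,
    energies = energies,
    partition_ratio = pr,
    flipflop = flip,
    residence = residence
  ), class = "mc_report")
}

# JSON-serializable view of a report (drops heavy internals)
.report_json <- function(rep) {
  dist_j <- lapply(rep$distributions, function(d) {
    list(condition = d$condition, bin_width = d$bin_width, n = d$n,
         kappa = d$mids, P = d$P)
  })
  en_j <- lapply(rep$energies, function(e) {
    list(T = e$T, kappa = e$kappa, E_kBT = e$E_kBT, masked = e$masked)
  })
  flip_j <- rep$flipflop
  if (!is.null(flip_j$fit) && inherits(flip_j$fit, "mc_expfit")) {
    ft <- flip_j$fit
    flip_j$fit <- list(A1 = ft$A1, t1 = ft$t1, A2 = ft$A2, t2 = ft$t2,
                       se = as.list(ft$se), aic = ft$aic,
                       prefers_single = ft$prefers_single,
                       degenerate = ft$degenerate,
                       t1_artifact = ft$t1_artifact)
  }
  list(params = rep$params,
       mean_curvature = rep$curvature,
       distributions = dist_j,
       energies = en_j,
       partition_ratio = rep$partition_ratio,
       flipflop = flip_j)
}

#' Write a pipeline report as a JSON + CSV bundle
#'
#' @param rep an `mc_report` from [membrane_report()].
#' @param dir output directory (created if missing).
#' @return the directory path, invisibly.
#' @export
write_report <- function(rep, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(.report_json(rep), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  utils::write.csv(rep$curvature, file.path(dir, "mean_curvature.csv"),
                   row.names = FALSE)
  for (nm in names(rep$distributions)) {
    write_distribution_csv(rep$distributions[[nm]],
                           file.path(dir, paste0("distribution_", nm, ".csv")),
                           rep$params)
  }
  for (nm in names(rep$energies)) {
    write_energy_csv(rep$energies[[nm]],
                     file.path(dir, paste0("energy_", nm, ".csv")),
                     rep$params)
  }
  invisible(dir)
}
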