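#' Analytic midline curves for the synthetic membrane generator
#'
#' Graph-type curves `z = f(x)` periodic over the box X length, plus a
#' closed circle. Each carries closed-form first/second derivatives so the
#' generator can export exact normals and curvature.
#'
#' @param z0 baseline height (nm).
#' @name mc_curve
NULL

#' @rdname mc_curve
#' @export
curve_flat <- function(z0 = 0) {
  structure(list(kind = "flat", z0 = z0), class = "mc_curve")
}

#' @rdname mc_curve
#' @param A amplitude (nm).
#' @param wavelength wavelength (nm); must divide the box X length.
#' @param phase phase offset (radians).
#' @export
curve_sinusoid <- function(A, wavelength, phase = 0, z0 = 0) {
  structure(list(kind = "sinusoid", A = A, wavelength = wavelength,
                 phase = phase, z0 = z0), class = "mc_curve")
}

#' @rdname mc_curve
#' @param terms data.frame with columns `A`, `wavelength`, `phase`: a sum of
#'   sine components.
#' @export
curve_fourier <- function(terms, z0 = 0) {
  stopifnot(all(c("A", "wavelength", "phase") %in% names(terms)))
  structure(list(kind = "fourier", terms = terms, z0 = z0),
            class = "mc_curve")
}

#' @rdname mc_curve
#' @param R circle radius (nm).
#' @param center length-2 centre in the XZ plane (nm).
#' @export
curve_circle <- function(R, center) {
  structure(list(kind = "circle", R = R, center = center),
            class = "mc_curve")
}

# z, z', z'' of a graph curve at x (vectorized); circle handled separately
curve_eval <- function(curve, x) {
  switch(curve$kind,
    flat = list(z = rep(curve$z0, length(x)), dz = rep(0, length(x)),
                d2z = rep(0, length(x))),
    sinusoid = {
      w <- 2 * pi / curve$wavelength
      ph <- w * x + curve$phase
      list(z = curve$z0 + curve$A * sin(ph),
           dz = curve$A * w * cos(ph),
           d2z = -curve$A * w^2 * sin(ph))
    },
    fourier = {
      z <- rep(curve$z0, length(x)); dz <- rep(0, length(x))
      d2z <- rep(0, length(x))
      for (r in seq_len(nrow(curve$terms))) {
        w <- 2 * pi / curve$terms$wavelength[r]
        ph <- w * x + curve$terms$phase[r]
        A <- curve$terms$A[r]
        z <- z + A * sin(ph)
        dz <- dz + A * w * cos(ph)
        d2z <- d2z - A * w^2 * sin(ph)
      }
      list(z = z, dz = dz, d2z = d2z)
    },
    stop("curve_eval: not a graph curve"))
}

#' Closed-form signed curvature of a generator curve
#'
#' For graph curves the parameter is `x`; for circles it is the polar
#' angle and the curvature is the constant `1/R` (counter-clockwise
#' orientation).
#'
#' @param curve an `mc_curve`.
#' @param u parameter values.
#' @return signed curvature (nm^-1).
#' @export
curve_kappa <- function(curve, u) {
  if (curve$kind == "circle") return(rep(1 / curve$R, length(u)))
  e <- curve_eval(curve, u)
  e$d2z / (1 + e$dz^2)^1.5
}

# unit upper/outward normal at parameter u: (-z', 0, 1)/speed for graphs,
# radial for circles
curve_normal <- function(curve, u) {
  if (curve$kind == "circle") {
    return(cbind(cos(u), 0, sin(u)))
  }
  e <- curve_eval(curve, u)
  sp <- sqrt(1 + e$dz^2)
  cbind(-e$dz / sp, 0, 1 / sp)
}

curve_point <- function(curve, u) {
  if (curve$kind == "circle") {
    return(cbind(curve$center[1] + curve$R * cos(u), 0,
                 curve$center[2] + curve$R * sin(u)))
  }
  e <- curve_eval(curve, u)
  cbind(u, 0, e$z)
}

#' Arc length of a generator curve over one box period
#'
#' Dense trapezoidal quadrature of the parameterization speed for graph
#' curves; `2 pi R` for circles.
#'
#' @param curve an `mc_curve`.
#' @param Lx box X length (nm); ignored for circles.
#' @param n quadrature resolution.
#' @export
curve_arclength <- function(curve, Lx, n = 20000) {
  if (curve$kind == "circle") return(2 * pi * curve$R)
  xg <- seq(0, Lx, length.out = n + 1)
  sp <- sqrt(1 + curve_eval(curve, xg)$dz^2)
  sum((sp[-1] + sp[-(n + 1)]) / 2) * (Lx / n)
}

# parameters of n points equally spaced in arc length over the period
.arc_equal_params <- function(curve, Lx, n) {
  if (curve$kind == "circle") return(seq(0, 2 * pi, length.out = n + 1)[1:n])
  ng <- 20000
  xg <- seq(0, Lx, length.out = ng + 1)
  sp <- sqrt(1 + curve_eval(curve, xg)$dz^2)
  cum <- c(0, cumsum((sp[-1] + sp[-(ng + 1)]) / 2) * (Lx / ng))
  total <- cum[ng + 1]
  stats::approx(cum, xg, xout = seq(0, total, length.out = n + 1)[1:n])$y
}

#' Specification of a synthetic curved membrane
#'
#' Describes a bilayer whose midline is a prescribed periodic curve in the
#' XZ plane: marker beads of the two leaflets are offset by `h/2` along the
#' local analytic normal, lipid types are laid out in block domains along
#' the curve with the block pattern inverted between leaflets (two inverted
#' asymmetric patches side by side), optional cholesterol head beads are
#' planted at known (leaflet, domain, parameter) positions, and isotropic
#' Gaussian noise is added to every bead.
#'
#' @param curve an `mc_curve`.
#' @param box length-3 box (nm).
#' @param n_x marker columns along the curve (equally spaced in arc length).
#' @param n_y marker rows along Y.
#' @param h bilayer thickness: leaflet offset is `h/2` along the normal
#'   (nm); default 4.
#' @param n_chol number of cholesterol molecules.
#' @param chol_odds named numeric odds of placing a cholesterol in a domain
#'   of each lipid type, e.g. `c(DOPC = 0.65, DOPS = 1)`.
#' @param n_blocks lipid-type blocks along the curve (default 2).
#' @param blocks_inverted logical; invert the block pattern between leaflets
#'   (default TRUE, the asymmetric construction). FALSE gives mixed regions
#'   where the same lipid type faces itself.
#' @param sigma positional noise s.d. (nm); default 0.1.
#' @param chol_depth how far inside its leaflet the cholesterol head sits,
#'   measured from the marker shell towards the bilayer centre (nm).
#' @param seed RNG seed.
#' @param time frame time (ns).
#' @return object of class `mc_memspec`.
#' @export
membrane_spec <- function(curve, box, n_x, n_y, h = 4, n_chol = 0,
                          chol_odds = c(DOPC = 1, DOPS = 1), n_blocks = 2,
                          blocks_inverted = TRUE, sigma = 0.1,
                          chol_depth = 0.5, seed = 1, time = 0) {
  spec <- structure(list(curve = curve, box = as.numeric(box),
                         n_x = as.integer(n_x), n_y = as.integer(n_y),
                         h = h, n_chol = as.integer(n_chol),
                         chol_odds = chol_odds, n_blocks = as.integer(n_blocks),
                         blocks_inverted = blocks_inverted, sigma = sigma,
                         chol_depth = chol_depth, seed = as.integer(seed),
                         time = time),
                    class = "mc_memspec")
  validate_membrane_spec(spec)
  spec
}

#' @rdname membrane_spec
#' @param spec an `mc_memspec`.
#' @export
validate_membrane_spec <- function(spec) {
  r_p_ref <- 2.0
  if (any(spec$box <= 0)) stop("membrane_spec: box lengths must be > 0")
  if (spec$h <= r_p_ref) {
    stop("membrane_spec: leaflet separation h must exceed the leaflet-graph cutoff (2 nm)")
  }
  if (spec$curve$kind %in% c("sinusoid")) {
    ratio <- spec$box[1] / spec$curve$wavelength
    if (abs(ratio - round(ratio)) > 1e-9) {
      stop("membrane_spec: sinusoid wavelength must divide the box X length")
    }
  }
  arc <- curve_arclength(spec$curve, spec$box[1])
  if (arc / spec$n_x >= r_p_ref) {
    stop("membrane_spec: marker spacing along the curve must stay below 2 nm")
  }
  if (spec$box[2] / spec$n_y >= r_p_ref) {
    stop("membrane_spec: marker spacing along Y must stay below 2 nm")
  }
  invisible(spec)
}

# lipid type of (block, leaflet) under the inverted-block construction
.block_type <- function(block, leaflet, blocks_inverted) {
  base <- ifelse(block %% 2 == 1, "DOPC", "DOPS")
  inv <- rep_len(leaflet != "upper" & blocks_inverted, length(base))
  base[inv] <- ifelse(base[inv] == "DOPC", "DOPS", "DOPC")
  base
}

# deterministic cholesterol placement table for a spec (depends only on the
# spec seed, so trajectories can reuse it frame after frame)
.make_chol_table <- function(spec) {
  if (spec$n_chol == 0) {
    return(data.frame(leaflet = character(0), block = integer(0),
                      u = numeric(0), y = numeric(0)))
  }
  rs <- .seeded_rng(spec$seed + 77000L)
  leaflet <- ifelse(rs$unif(spec$n_chol) < 0.5, "upper", "lower")
  odds <- spec$chol_odds / sum(spec$chol_odds)
  type <- names(odds)[1 + (rs$unif(spec$n_chol) >= odds[1])]
  # parameter range of each block, with a margin so the nearest lipid marker
  # is unambiguously of the block's own type
  if (spec$curve$kind == "circle") {
    period <- 2 * pi
    margin <- 1.5 / spec$curve$R
  } else {
    period <- spec$box[1]
    margin <- 1.5
  }
  bw <- period / spec$n_blocks
  block <- integer(spec$n_chol)
  u <- numeric(spec$n_chol)
  for (i in seq_len(spec$n_chol)) {
    cand <- which(.block_type(seq_len(spec$n_blocks), leaflet[i],
                              spec$blocks_inverted) == type[i])
    if (length(cand) == 0) cand <- seq_len(spec$n_blocks)
    b <- cand[1 + floor(rs$unif(1) * length(cand))]
    block[i] <- b
    u[i] <- (b - 1) * bw + margin + rs$unif(1) * (bw - 2 * margin)
  }
  data.frame(leaflet = leaflet, block = block, u = u,
             y = rs$unif(spec$n_chol) * spec$box[2])
}

# small deterministic uniform/normal stream independent of .Random.seed
.seeded_rng <- function(seed) {
  env <- new.env()
  env$state <- as.double(seed %% 2147483647L)
  nxt <- function(n) {
    out <- numeric(n)
    st <- env$state
    for (i in seq_len(n)) {
      st <- (st * 48271) %% 2147483647
      out[i] <- st / 2147483647
    }
    env$state <- st
    out
  }
  list(unif = nxt)
}

#' Generate a synthetic membrane frame with analytic ground truth
#'
#' @param spec an [membrane_spec()].
#' @param chol_table optional externally maintained cholesterol placement
#'   table (columns `leaflet`, `block`, `u`, `y`), used by
#'   [generate_trajectory()] to keep molecule identity across frames.
#' @return list of class `mc_synth` with `frame` (an [mc_frame()]) and
#'   `truth`: per-molecule `leaflet`/`domain` labels, the analytic midline
#'   table (`l`, `x`, `z`, `kappa`), total `arc_length`, cholesterol
#'   residence and true curvature at each cholesterol parameter.
#' @export
generate_membrane <- function(spec, chol_table = NULL) {
  validate_membrane_spec(spec)
  u <- .arc_equal_params(spec$curve, spec$box[1], spec$n_x)
  base <- curve_point(spec$curve, u)
  nrm <- curve_normal(spec$curve, u)
  yy <- (seq_len(spec$n_y) - 0.5) * spec$box[2] / spec$n_y

  n_lip_leaf <- spec$n_x * spec$n_y
  if (spec$curve$kind == "circle") {
    period <- 2 * pi
  } else period <- spec$box[1]
  block_of <- function(uu) pmin(spec$n_blocks,
                                1L + floor(uu / (period / spec$n_blocks)))

  build_leaf <- function(sign, leaflet_name, id0) {
    P <- base + sign * (spec$h / 2) * nrm
    coords <- cbind(rep(P[, 1], each = spec$n_y),
                    rep(yy, times = spec$n_x),
                    rep(P[, 3], each = spec$n_y))
    ucol <- rep(u, each = spec$n_y)
    blk <- block_of(ucol)
    list(coords = coords,
         lipid_type = .block_type(blk, leaflet_name, spec$blocks_inverted),
         molecule_id = id0 + seq_len(n_lip_leaf) - 1L,
         u = ucol, block = blk)
  }
  up <- build_leaf(+1, "upper", 1L)
  lo <- build_leaf(-1, "lower", n_lip_leaf + 1L)

  if (is.null(chol_table)) chol_table <- .make_chol_table(spec)
  n_chol <- nrow(chol_table)
  if (n_chol > 0) {
    cb <- curve_point(spec$curve, chol_table$u)
    cn <- curve_normal(spec$curve, chol_table$u)
    sgn <- ifelse(chol_table$leaflet == "upper", 1, -1)
    off <- spec$h / 2 - spec$chol_depth
    chol_coords <- cb + (sgn * off) * cn
    chol_coords[, 2] <- chol_table$y
    chol_ids <- 2L * n_lip_leaf + seq_len(n_chol)
  } else {
    chol_coords <- matrix(numeric(0), 0, 3)
    chol_ids <- integer(0)
  }

  coords <- rbind(up$coords, lo$coords, chol_coords)
  bead_kind <- c(rep("lipid_marker", 2L * n_lip_leaf),
                 rep("chol_head", n_chol))
  lipid_type <- c(up$lipid_type, lo$lipid_type, rep(NA_character_, n_chol))
  molecule_id <- c(up$molecule_id, lo$molecule_id, chol_ids)

  set.seed(spec$seed)
  if (spec$sigma > 0) {
    coords <- coords + matrix(stats::rnorm(length(coords), 0, spec$sigma),
                              ncol = 3)
  }
  for (a in 1:3) coords[, a] <- pbc_wrap1(coords[, a], spec$box[a])

  frame <- mc_frame(coords, bead_kind, lipid_type, molecule_id,
                    spec$box, time = spec$time)

  chol_domain <- if (n_chol > 0) {
    .block_type(chol_table$block, chol_table$leaflet, spec$blocks_inverted)
  } else character(0)

  # analytic midline table sampled at the marker columns
  if (spec$curve$kind == "circle") {
    l_mid <- spec$curve$R * u
  } else {
    l_mid <- (seq_len(spec$n_x) - 1) * curve_arclength(spec$curve, spec$box[1]) / spec$n_x
  }
  truth <- list(
    molecules = data.frame(
      molecule_id = c(up$molecule_id, lo$molecule_id),
      leaflet = rep(c("upper", "lower"), each = n_lip_leaf),
      domain = c(up$lipid_type, lo$lipid_type),
      u = c(up$u, lo$u)),
    midline = data.frame(l = l_mid, x = base[, 1], z = base[, 3],
                         kappa = curve_kappa(spec$curve, u)),
    arc_length = curve_arclength(spec$curve, spec$box[1]),
    chol = if (n_chol > 0) data.frame(
      molecule_id = chol_ids, leaflet = chol_table$leaflet,
      domain = chol_domain, u = chol_table$u,
      kappa = curve_kappa(spec$curve, chol_table$u)) else NULL)

  structure(list(frame = frame, truth = truth, spec = spec,
                 chol_table = chol_table),
            class = "mc_synth")
}

#' Generate a synthetic trajectory with persistent molecules
#'
#' One frame per entry of `curves`; all frames share the marker layout,
#' molecule identity and cholesterol placements of `spec` (only the midline
#' shape and the noise realization change). A planted flip-flop schedule
#' toggles the leaflet of selected cholesterol molecules at given frames;
#' under the inverted-block construction every such leaflet toggle also
#' changes the lipid-domain type, so each planted event is a countable
#' flip-flop (with `blocks_inverted = FALSE` the domain type does not
#' change and events must be ignored by the detector).
#'
#' @param spec base [membrane_spec()].
#' @param curves list of `mc_curve`, one per frame (recycled if length 1).
#' @param n_frames number of frames.
#' @param frame_dt frame spacing (ns); default 4.
#' @param flip_schedule optional data.frame `molecule_id`, `frame`:
#'   cholesterol leaflet toggles applied at the start of the given frame.
#' @return list of class `mc_traj`: `frames`, per-frame `residence` truth,
#'   `events` (planted, with `counted` flag), `frame_dt`.
#' @export
generate_trajectory <- function(spec, curves = NULL, n_frames = length(curves),
                                frame_dt = 4, flip_schedule = NULL) {
  if (is.null(curves)) curves <- list(spec$curve)
  if (length(curves) == 1 && n_frames > 1) curves <- rep(curves, n_frames)
  if (length(curves) != n_frames) stop("generate_trajectory: one curve per frame required")
  chol_table <- .make_chol_table(spec)
  frames <- vector("list", n_frames)
  res_rows <- vector("list", n_frames)
  ev_rows <- list()

  for (f in seq_len(n_frames)) {
    if (!is.null(flip_schedule)) {
      todo <- flip_schedule[flip_schedule$frame == f, , drop = FALSE]
      n_lip <- 2L * spec$n_x * spec$n_y
      for (r in seq_len(nrow(todo))) {
        ci <- todo$molecule_id[r] - n_lip
        if (ci < 1 || ci > nrow(chol_table)) {
          stop("generate_trajectory: flip_schedule molecule_id is not a cholesterol")
        }
        old_dom <- .block_type(chol_table$block[ci], chol_table$leaflet[ci],
                               spec$blocks_inverted)
        chol_table$leaflet[ci] <- ifelse(chol_table$leaflet[ci] == "upper",
                                         "lower", "upper")
        new_dom <- .block_type(chol_table$block[ci], chol_table$leaflet[ci],
                               spec$blocks_inverted)
        ev_rows[[length(ev_rows) + 1L]] <- data.frame(
          molecule_id = todo$molecule_id[r], frame = f,
          time = (f - 1) * frame_dt, counted = old_dom != new_dom)
      }
    }
    fspec <- spec
    fspec$curve <- curves[[f]]
    fspec$seed <- spec$seed + f
    fspec$time <- (f - 1) * frame_dt
    syn <- generate_membrane(fspec, chol_table = chol_table)
    frames[[f]] <- syn$frame
    if (!is.null(syn$truth$chol)) {
      res_rows[[f]] <- cbind(frame = f, time = fspec$time,
                             syn$truth$chol[c("molecule_id", "leaflet", "domain")])
    }
  }
  structure(list(frames = frames,
                 residence = do.call(rbind, res_rows),
                 events = if (length(ev_rows)) do.call(rbind, ev_rows) else
                   data.frame(molecule_id = integer(0), frame = integer(0),
                              time = numeric(0), counted = logical(0)),
                 frame_dt = frame_dt, spec = spec),
            class = "mc_traj")
}

#' Draw inter-event intervals from an exponential mixture
#'
#' @param weights non-negative mixture weights (normalized internally).
#' @param means component means (ns), all > 0.
#' @param n number of draws.
#' @param seed RNG seed.
#' @return numeric vector of `n` intervals.
#' @export
generate_intervals <- function(weights, means, n, seed = 1) {
  if (length(weights) != length(means) || length(weights) == 0) {
    stop("generate_intervals: weights and means must have equal positive length")
  }
  if (any(weights < 0) || sum(weights) <= 0) {
    stop("generate_intervals: weights must be non-negative and sum > 0")
  }
  if (any(means <= 0)) stop("generate_intervals: means must be > 0")
  if (n == 0) return(numeric(0))
  set.seed(seed)
  comp <- sample.int(length(weights), n, replace = TRUE,
                     prob = weights / sum(weights))
  stats::rexp(n, rate = 1 / means[comp])
}

#' Built-in synthetic membrane presets
#'
#' `"flat"`: planar bilayer in a 50 nm box. `"sinusoid"`: one-period
#' sinusoid (A = 5 nm, wavelength 50 nm). `"paper"`: the full-scale
#' composition — 4032 lipids (2016 DOPC + 2016 DOPS in two inverted
#' blocks), 784 cholesterol (cholesterol/lipid ~ 0.2) placed with
#' DOPC:DOPS odds 0.65:1, on a 111 x 12.4 nm patch bent into a
#' two-period sinusoid.
#'
#' @param name one of `"flat"`, `"sinusoid"`, `"paper"`.
#' @param seed RNG seed.
#' @param ... overrides passed to [membrane_spec()].
#' @return an `mc_memspec`.
#' @export
preset_spec <- function(name = c("paper", "flat", "sinusoid"), seed = 1, ...) {
  name <- match.arg(name)
  args <- switch(name,
    flat = list(curve = curve_flat(z0 = 12.5), box = c(50, 10, 25),
                n_x = 64, n_y = 12),
    sinusoid = list(curve = curve_sinusoid(A = 5, wavelength = 50, z0 = 15),
                    box = c(50, 10, 30), n_x = 70, n_y = 12),
    paper = list(curve = curve_sinusoid(A = 6, wavelength = 55.5, z0 = 20),
                 box = c(111, 12.4, 40), n_x = 144, n_y = 14,
                 n_chol = 784, chol_odds = c(DOPC = 0.65, DOPS = 1)))
  args$seed <- seed
  over <- list(...)
  args[names(over)] <- over
  do.call(membrane_spec, args)
}
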