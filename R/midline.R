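#' Local bilayer centre and normal at a point
#'
#' `Local(p)`: collects, for each leaflet, the marker beads inside a
#' cylinder of radius `r_loc` whose axis runs through `p` along the local
#' bilayer normal, takes the per-leaflet centroids, and returns their
#' midpoint as the local bilayer centre with the unit vector from the
#' lower- to the upper-leaflet centroid (projected into the XZ working
#' plane) as the local normal. When no `axis` estimate is supplied the
#' normal direction is bootstrapped from marker patches anchored at each
#' leaflet's nearest marker to `p`, then refined once through the cylinder
#' selection; during midline tracing the previous step's normal serves as
#' the axis, keeping the selection laterally centred at `p` so the refined
#' centre varies smoothly along the trace.
#'
#' @param p length-3 query point (nm).
#' @param frame an [mc_frame()].
#' @param leaflets leaflet assignment (see [assign_leaflets()]).
#' @param r_loc cylinder radius (nm); default 3.0.
#' @param axis optional unit vector: prior estimate of the local normal.
#' @return list with `center` (length-3) and `normal` (unit length-3 with
#'   zero Y component).
#' @export
local_frame <- function(p, frame, leaflets, r_loc = 3.0, axis = NULL) {
  mi <- marker_idx(frame)
  P <- frame$coords[mi, , drop = FALSE]
  lab <- marker_leaflets(frame, leaflets)
  if (is.null(axis)) {
    axis <- .bootstrap_normal(p, P, lab, frame, r_loc)
  }
  D <- pbc_disp_mat(P, p, frame$box, frame$periodic)
  d_par <- as.numeric(D %*% axis)
  d_lat <- sqrt(pmax(rowSums(D^2) - d_par^2, 0))
  # Hann taper over the lateral distance: markers entering/leaving the
  # neighbourhood get vanishing weight, so the centre varies smoothly as p
  # moves and the discreteness of the marker lattice does not jitter the
  # trace
  w <- ifelse(d_lat < r_loc & abs(d_par) < 2 * r_loc,
              cos(pi * d_lat / (2 * r_loc))^2, 0)
  nu <- sum(w > 0 & lab == "upper")
  nl <- sum(w > 0 & lab == "lower")
  if (nu < 3 || nl < 3) {
    stop(sprintf("local_frame: only %d upper / %d lower markers in the r_loc = %g nm cylinder at (%.2f, %.2f, %.2f); need >= 3 each",
                 nu, nl, r_loc, p[1], p[2], p[3]))
  }
  wcen <- function(sel) {
    ws <- w[sel]
    colSums(D[sel, , drop = FALSE] * ws) / sum(ws)
  }
  su <- w > 0 & lab == "upper"
  sl <- w > 0 & lab == "lower"
  mu <- wcen(su)
  ml <- wcen(sl)
  cu <- p + mu
  cl <- p + ml
  # tangent from the principal XZ direction of the leaflet-centred marker
  # displacements: unbiased by the orientation of the selection cylinder,
  # unlike the inter-centroid direction, whose tangential component just
  # reproduces any axis tilt
  wctr <- function(sel, m) {
    X <- sweep(D[sel, c(1, 3), drop = FALSE], 2, m[c(1, 3)])
    X * sqrt(w[sel])
  }
  M <- rbind(wctr(su, mu), wctr(sl, ml))
  ev <- eigen(crossprod(M), symmetric = TRUE)$vectors[, 1]
  nv <- c(-ev[2], 0, ev[1])
  dcl <- cu - cl
  if (sum(nv * c(dcl[1], 0, dcl[3])) < 0) nv <- -nv
  if (sqrt(dcl[1]^2 + dcl[3]^2) < 1e-9) {
    stop("local_frame: degenerate normal (leaflet centroids coincide in XZ)")
  }
  list(center = (cu + cl) / 2, normal = nv)
}

# rough local normal from marker patches anchored at each leaflet's
# nearest marker to p; used only to orient the cylinder selection when no
# prior estimate exists
.bootstrap_normal <- function(p, P, lab, frame, r_loc) {
  cens <- list()
  d2p <- pbc_dist2_cross(matrix(p, 1), P, frame$box, frame$periodic)[1, ]
  for (li in 1:2) {
    sel_leaf <- lab == c("upper", "lower")[li]
    anchor <- P[which(sel_leaf)[which.min(d2p[sel_leaf])], ]
    anchor <- p + as.numeric(pbc_disp_mat(matrix(anchor, 1), p, frame$box,
                                          frame$periodic))
    d2a <- pbc_dist2_cross(matrix(anchor, 1), P[sel_leaf, , drop = FALSE],
                           frame$box, frame$periodic)[1, ]
    patch <- P[sel_leaf, , drop = FALSE][d2a < r_loc^2, , drop = FALSE]
    if (nrow(patch) < 1) {
      stop(sprintf("local_frame: no %s-leaflet markers within r_loc of (%.2f, %.2f, %.2f)",
                   c("upper", "lower")[li], p[1], p[2], p[3]))
    }
    Dp <- pbc_disp_mat(patch, anchor, frame$box, frame$periodic)
    cens[[li]] <- anchor + colMeans(Dp)
  }
  nv <- cens[[1]] - cens[[2]]
  nv[2] <- 0
  nn <- sqrt(sum(nv * nv))
  if (nn < 1e-9) stop("local_frame: cannot bootstrap a normal direction")
  nv / nn
}

# tangent t = n x j with j = (0,1,0): (-nz, 0, nx); unit when n is a unit
# XZ vector
.tangent_of <- function(nv) c(-nv[3], 0, nv[1])

#' Trace the closed bilayer midline in the XZ plane
#'
#' Starting at the headgroup marker of the lipid with the lowest
#' `molecule_id`, repeatedly steps a distance `s` along the local tangent
#' `t = n x j` (`j` the Y unit vector) and refines the predicted point with
#' one [local_frame()] call. The tangent sign is chosen so the first step
#' advances in +X and is kept by continuity afterwards. Tracing terminates
#' when the minimum-image distance `d` from the newly refined point to the
#' first midline point drops below `s` (with at least two steps taken): the
#' midline then covers the whole membrane and is closed. The closing point
#' itself is not stored, so consecutive stored points — including across the
#' seam — remain spaced approximately `s`, consistent with the arc-length
#' parameterization `l_i = i s` used downstream.
#'
#' @param frame an [mc_frame()].
#' @param leaflets leaflet assignment.
#' @param s midline point spacing (nm); default 1.0.
#' @param r_loc lateral radius for [local_frame()] (nm).
#' @param max_steps bail-out step limit; default `ceiling(4 * box_x / s)`.
#' @return object of class `mc_midline`: `points` (N x 3), `s`,
#'   `l` (= `(i - 1) s`), `box`, `closed`, `closure_distance`, `time`.
#' @export
trace_midline <- function(frame, leaflets, s = 1.0, r_loc = 3.0,
                          max_steps = NULL) {
  if (is.null(max_steps)) max_steps <- as.integer(ceiling(4 * frame$box[1] / s))
  mi <- marker_idx(frame)
  start_bead <- mi[which.min(frame$molecule_id[mi])]
  p0 <- frame$coords[start_bead, ]

  lf <- local_frame(p0, frame, leaflets, r_loc)
  pts <- matrix(NA_real_, max_steps + 1L, 3)
  pts[1, ] <- lf$center
  tv <- .tangent_of(lf$normal)
  if (tv[1] < 0) tv <- -tv

  closed <- FALSE
  closure_distance <- NA_real_
  k <- 1L
  while (k <= max_steps) {
    appr <- pts[k, ] + tv * s
    for (a in 1:3) if (frame$periodic[a]) appr[a] <- pbc_wrap1(appr[a], frame$box[a])
    lf <- tryCatch(local_frame(appr, frame, leaflets, r_loc, axis = lf$normal),
                   error = function(e) stop(sprintf("trace_midline: step %d: %s", k, conditionMessage(e)), call. = FALSE))
    tnew <- .tangent_of(lf$normal)
    if (sum(tnew * tv) < 0) tnew <- -tnew
    d <- minimum_image_distance(lf$center, pts[1, ], frame$box, frame$periodic)
    if (d < s && k > 1L) {
      closed <- TRUE
      closure_distance <- d
      break
    }
    pts[k + 1L, ] <- lf$center
    tv <- tnew
    k <- k + 1L
  }
  if (!closed) {
    stop(sprintf("trace_midline: midline did not close within %d steps (open or pathological midline)", max_steps))
  }
  N <- k
  structure(list(points = pts[seq_len(N), , drop = FALSE], s = s,
                 l = (seq_len(N) - 1) * s, box = frame$box,
                 periodic = frame$periodic, closed = TRUE,
                 closure_distance = closure_distance,
                 time = frame$time),
            class = "mc_midline")
}

#' Construct a midline directly from points
#'
#' Useful for feeding analytic curves (e.g. a circle) straight into the
#' spectral curvature pipeline.
#'
#' @param points N x 3 matrix of ordered midline points (nm).
#' @param s arc spacing (nm).
#' @param box box lengths (nm).
#' @param closed logical.
#' @param time frame time (ns).
#' @export
mc_midline <- function(points, s, box, closed = TRUE, time = 0) {
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("mc_midline: need at least 3 points")
  structure(list(points = points, s = s,
                 l = (seq_len(nrow(points)) - 1) * s,
                 box = as.numeric(box), periodic = c(TRUE, TRUE, TRUE),
                 closed = closed,
                 closure_distance = NA_real_, time = time),
            class = "mc_midline")
}

#' Total traced midline length
#'
#' Sum of minimum-image distances between consecutive points, plus the seam
#' gap when the midline is closed.
#'
#' @param midline an `mc_midline`.
#' @return length (nm).
#' @export
midline_length <- function(midline) {
  P <- midline$points
  N <- nrow(P)
  tot <- 0
  for (i in seq_len(N - 1)) {
    tot <- tot + minimum_image_distance(P[i, ], P[i + 1, ], midline$box,
                                        midline$periodic)
  }
  if (isTRUE(midline$closed)) {
    tot <- tot + minimum_image_distance(P[N, ], P[1, ], midline$box,
                                        midline$periodic)
  }
  tot
}

#' @export
print.mc_midline <- function(x, ...) {
  cat(sprintf("<mc_midline> %d points, s = %g nm, %s, length %.2f nm, t = %g ns\n",
              nrow(x$points), x$s,
              if (isTRUE(x$closed)) "closed" else "open",
              midline_length(x), x$time))
  invisible(x)
}
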