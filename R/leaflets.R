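#' Assign lipids to leaflets by headgroup connectivity
#'
#' Builds a graph on the lipid headgroup marker beads with an edge wherever
#' the minimum-image distance between two markers is strictly below the
#' cut-off `r_p`, and partitions the markers into the connected components.
#' A well-formed bilayer yields exactly two components, the two monolayers;
#' any other component count is treated as a data error (cut-off too large so
#' the leaflets merge, or too small so a leaflet fragments).
#'
#' The component labelled `"upper"` is the one whose markers sit, on
#' average, on the positive-Z side of their nearest marker in the other
#' component (minimum-image sense). For closed membranes where that signal
#' vanishes (e.g. a vesicle cross-section), the outer component — positive
#' radial side relative to the circular-mean centroid — is `"upper"`.
#'
#' @param frame an [mc_frame()].
#' @param r_p neighbour-graph cut-off distance (nm); default 2.0.
#' @return an object of class `mc_leaflets`: a per-lipid-molecule factor
#'   (`upper`/`lower`) named by `molecule_id`, plus component sizes and the
#'   cut-off used.
#' @export
assign_leaflets <- function(frame, r_p = 2.0) {
  mi <- marker_idx(frame)
  if (length(mi) < 2) stop("assign_leaflets: need at least 2 marker beads")
  P <- frame$coords[mi, , drop = FALSE]
  n <- nrow(P)
  r2 <- r_p^2

  # chunked pairwise adjacency (strict < r_p)
  chunk <- 256L
  ei <- vector("list", ceiling(n / chunk))
  for (ci in seq_along(ei)) {
    rows <- (((ci - 1L) * chunk + 1L):min(ci * chunk, n))
    D2 <- pbc_dist2_cross(P[rows, , drop = FALSE], P, frame$box,
                          frame$periodic)
    hit <- which(D2 < r2, arr.ind = TRUE)
    gi <- rows[hit[, 1]]
    gj <- hit[, 2]
    keep <- gi < gj
    ei[[ci]] <- cbind(gi[keep], gj[keep])
  }
  edges <- do.call(rbind, ei)
  g <- igraph::make_graph(t(edges), n = n, directed = FALSE)
  comp <- igraph::components(g)
  if (comp$no != 2) {
    stop(sprintf("assign_leaflets: marker graph has %d connected component%s (expected 2); adjust r_p = %g nm",
                 comp$no, if (comp$no == 1) "" else "s", r_p))
  }
  memb <- comp$membership

  lab <- .orient_leaflets(P, memb, frame$box, frame$periodic)
  leaflet <- ifelse(memb == lab$upper_comp, "upper", "lower")
  mol <- frame$molecule_id[mi]
  out <- structure(list(
    leaflet = stats::setNames(leaflet, as.character(mol)),
    molecule_id = mol,
    sizes = as.integer(comp$csize),
    r_p = r_p
  ), class = "mc_leaflets")
  out
}

# Decide which component is "upper": mean Z-sign of the displacement from
# each marker's nearest counterpart in the other component; radial fallback
# for closed membranes.
.orient_leaflets <- function(P, memb, box, periodic) {
  ia <- which(memb == 1)
  ib <- which(memb == 2)
  A <- P[ia, , drop = FALSE]
  B <- P[ib, , drop = FALSE]
  chunk <- 512L
  U <- matrix(0, nrow(A), 3)
  for (ci in seq_len(ceiling(nrow(A) / chunk))) {
    rows <- (((ci - 1L) * chunk + 1L):min(ci * chunk, nrow(A)))
    D2 <- pbc_dist2_cross(A[rows, , drop = FALSE], B, box, periodic)
    j <- apply(D2, 1, which.min)
    for (k in seq_along(rows)) {
      d <- A[rows[k], ] - B[j[k], ]
      for (a in 1:3) if (periodic[a]) d[a] <- pbc_disp1(d[a], box[a])
      U[rows[k], ] <- d / sqrt(sum(d * d))
    }
  }
  zscore <- mean(U[, 3])
  if (abs(zscore) >= 0.2) {
    upper_comp <- if (zscore > 0) 1L else 2L
  } else {
    ctr <- pbc_centroid(P, box, periodic)
    R <- pbc_disp_mat(A, ctr, box, periodic)
    Rn <- R / sqrt(rowSums(R^2))
    rscore <- mean(rowSums(Rn * U))
    upper_comp <- if (rscore > 0) 1L else 2L
  }
  list(upper_comp = upper_comp, zscore = zscore)
}

#' @export
print.mc_leaflets <- function(x, ...) {
  cat(sprintf("<mc_leaflets> %d + %d markers (r_p = %g nm): %d upper / %d lower\n",
              x$sizes[1], x$sizes[2], x$r_p,
              sum(x$leaflet == "upper"), sum(x$leaflet == "lower")))
  invisible(x)
}

# per-marker leaflet labels for a frame, looked up by molecule identity
# (labels are assigned once on the first frame and propagated: lipids do
# not flip between leaflets)
marker_leaflets <- function(frame, leaflets) {
  mi <- marker_idx(frame)
  lab <- leaflets$leaflet[as.character(frame$molecule_id[mi])]
  if (anyNA(lab)) stop("marker_leaflets: frame contains lipids absent from the leaflet assignment")
  unname(lab)
}

#' Per-frame cholesterol residence: leaflet and lipid domain
#'
#' Each cholesterol head bead is assigned the leaflet and the lipid-type
#' domain of its nearest lipid marker bead (minimum-image distance). Ties
#' are broken deterministically towards the lipid with the lowest
#' `molecule_id`.
#'
#' @param frame an [mc_frame()].
#' @param leaflets an [assign_leaflets()] result (typically from the first
#'   frame; labels propagate by molecule identity).
#' @return data.frame with columns `molecule_id` (cholesterol), `leaflet`,
#'   `domain` (lipid type of the nearest marker), `nearest_lipid`.
#' @export
assign_cholesterol_residence <- function(frame, leaflets) {
  mi <- marker_idx(frame)
  ci <- chol_idx(frame)
  if (length(mi) == 0) stop("assign_cholesterol_residence: frame has no lipid markers")
  if (length(ci) == 0) {
    return(data.frame(molecule_id = integer(0), leaflet = character(0),
                      domain = character(0), nearest_lipid = integer(0)))
  }
  # order markers by molecule_id so which.min resolves ties to the lowest id
  ord <- order(frame$molecule_id[mi])
  mi <- mi[ord]
  P <- frame$coords[mi, , drop = FALSE]
  mlab <- marker_leaflets(frame, leaflets)[ord]
  mtype <- frame$lipid_type[mi]
  mmol <- frame$molecule_id[mi]

  C <- frame$coords[ci, , drop = FALSE]
  chunk <- 512L
  nn <- integer(length(ci))
  for (cb in seq_len(ceiling(length(ci) / chunk))) {
    rows <- (((cb - 1L) * chunk + 1L):min(cb * chunk, length(ci)))
    D2 <- pbc_dist2_cross(C[rows, , drop = FALSE], P, frame$box,
                          frame$periodic)
    nn[rows] <- apply(D2, 1, which.min)
  }
  data.frame(molecule_id = frame$molecule_id[ci],
             leaflet = mlab[nn],
             domain = mtype[nn],
             nearest_lipid = mmol[nn])
}

#' Cholesterol residence series over a trajectory
#'
#' Applies [assign_cholesterol_residence()] to every frame, with leaflets
#' assigned once on the first frame and propagated by molecule identity.
#'
#' @param frames list of [mc_frame()] objects with consistent molecule ids.
#' @param r_p leaflet graph cut-off (nm).
#' @param leaflets optional precomputed leaflet assignment.
#' @return long data.frame: `frame`, `time`, `molecule_id`, `leaflet`,
#'   `domain`.
#' @export
residence_series <- function(frames, r_p = 2.0, leaflets = NULL) {
  if (length(frames) < 1) stop("residence_series: need at least one frame")
  if (is.null(leaflets)) leaflets <- assign_leaflets(frames[[1]], r_p)
  res <- lapply(seq_along(frames), function(i) {
    r <- assign_cholesterol_residence(frames[[i]], leaflets)
    if (nrow(r) == 0) return(NULL)
    cbind(frame = i, time = frames[[i]]$time, r[c("molecule_id", "leaflet", "domain")])
  })
  do.call(rbind, res)
}
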