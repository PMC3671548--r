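#' Construct a single-frame bead table
#'
#' A `mc_frame` holds one time point of a coarse-grained membrane system:
#' bead coordinates, per-bead kinds, per-molecule lipid types and an
#' orthorhombic periodic box. Geometry throughout the package uses only the
#' headgroup marker beads (one per lipid, e.g. the MARTINI phosphate bead)
#' and cholesterol head beads.
#'
#' @param coords n x 3 numeric matrix of bead positions (nm).
#' @param bead_kind character vector, one of `"lipid_marker"`, `"chol_head"`,
#'   `"other"` per bead.
#' @param lipid_type character vector per bead: lipid species (e.g. `"DOPC"`,
#'   `"DOPS"`) for lipid markers, `NA` otherwise allowed.
#' @param molecule_id integer vector grouping beads into molecules.
#' @param box numeric length-3 box lengths (nm), > 0.
#' @param time frame time (ns).
#' @param periodic logical length-3 periodicity flags.
#' @return an object of class `mc_frame`.
#' @export
mc_frame <- function(coords, bead_kind, lipid_type, molecule_id, box,
                     time = 0, periodic = c(TRUE, TRUE, TRUE)) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  n <- nrow(coords)
  if (ncol(coords) != 3) stop("mc_frame: coords must be n x 3")
  if (!all(is.finite(coords))) stop("mc_frame: non-finite coordinates")
  if (length(box) != 3 || !all(is.finite(box)) || any(box <= 0)) {
    stop("mc_frame: box must be three positive lengths")
  }
  bead_kind <- as.character(bead_kind)
  lipid_type <- as.character(lipid_type)
  molecule_id <- as.integer(molecule_id)
  if (length(bead_kind) != n || length(lipid_type) != n ||
      length(molecule_id) != n) {
    stop("mc_frame: per-bead vectors must match nrow(coords)")
  }
  bad <- !bead_kind %in% c("lipid_marker", "chol_head", "other")
  if (any(bad)) stop("mc_frame: unknown bead_kind: ", bead_kind[which(bad)[1]])
  mk <- bead_kind == "lipid_marker"
  if (any(mk & (is.na(lipid_type) | lipid_type == ""))) {
    stop("mc_frame: every lipid_marker bead needs a lipid_type")
  }
  structure(list(coords = coords, bead_kind = bead_kind,
                 lipid_type = lipid_type, molecule_id = molecule_id,
                 box = as.numeric(box), periodic = as.logical(periodic),
                 time = as.numeric(time)),
            class = "mc_frame")
}

#' @export
print.mc_frame <- function(x, ...) {
  cat(sprintf("<mc_frame> %d beads (%d lipid markers, %d chol heads), box %.2f x %.2f x %.2f nm, t = %g ns\n",
              nrow(x$coords), sum(x$bead_kind == "lipid_marker"),
              sum(x$bead_kind == "chol_head"),
              x$box[1], x$box[2], x$box[3], x$time))
  invisible(x)
}

# indices of lipid marker beads
marker_idx <- function(frame) which(frame$bead_kind == "lipid_marker")

# indices of cholesterol head beads
chol_idx <- function(frame) which(frame$bead_kind == "chol_head")
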