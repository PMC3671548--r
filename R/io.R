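#' Write a frame to the lightweight CSV schema
#'
#' Plain-text side-channel format: two header comment lines carrying the box
#' and time, then columns `molecule_id`, `bead_kind`, `lipid_type`, `x`,
#' `y`, `z` (nm). Coordinates are written with 17 significant digits so a
#' round trip is bit-exact.
#'
#' @param frame an [mc_frame()].
#' @param path output file.
#' @export
write_frame_csv <- function(frame, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# memcurv frame",
               sprintf("# box %.17g %.17g %.17g", frame$box[1], frame$box[2],
                       frame$box[3]),
               sprintf("# time %.17g", frame$time),
               "molecule_id,bead_kind,lipid_type,x,y,z"), con)
  writeLines(sprintf("%d,%s,%s,%.17g,%.17g,%.17g",
                     frame$molecule_id, frame$bead_kind,
                     ifelse(is.na(frame$lipid_type), "NA", frame$lipid_type),
                     frame$coords[, 1], frame$coords[, 2],
                     frame$coords[, 3]), con)
  invisible(path)
}

.parse_header_num <- function(lines, key, path) {
  hit <- grep(paste0("^# ", key, " "), lines, value = TRUE)
  if (length(hit) == 0) stop(sprintf("read: missing '# %s' header in %s", key, path))
  as.numeric(strsplit(sub(paste0("^# ", key, " "), "", hit[1]), " ")[[1]])
}

#' Read a frame from the CSV schema
#'
#' @param path input file written by [write_frame_csv()].
#' @return an [mc_frame()].
#' @export
read_frame_csv <- function(path) {
  lines <- readLines(path, n = 10)
  box <- .parse_header_num(lines, "box", path)
  time <- .parse_header_num(lines, "time", path)
  df <- utils::read.csv(path, comment.char = "#",
                        colClasses = c("integer", "character", "character",
                                       "numeric", "numeric", "numeric"))
  lt <- df$lipid_type
  lt[lt == "NA"] <- NA_character_
  mc_frame(as.matrix(df[c("x", "y", "z")]), df$bead_kind, lt,
           df$molecule_id, box, time = time[1])
}

#' Write a multi-frame trajectory to one CSV file
#'
#' Same schema as [write_frame_csv()] with additional `frame` and `time`
#' columns; the box is taken from the first frame and must be shared.
#'
#' @param frames list of [mc_frame()].
#' @param path output file.
#' @export
write_trajectory_csv <- function(frames, path) {
  box <- frames[[1]]$box
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# memcurv trajectory",
               sprintf("# box %.17g %.17g %.17g", box[1], box[2], box[3]),
               "frame,time,molecule_id,bead_kind,lipid_type,x,y,z"), con)
  for (f in seq_along(frames)) {
    fr <- frames[[f]]
    writeLines(sprintf("%d,%.17g,%d,%s,%s,%.17g,%.17g,%.17g",
                       f, fr$time, fr$molecule_id, fr$bead_kind,
                       ifelse(is.na(fr$lipid_type), "NA", fr$lipid_type),
                       fr$coords[, 1], fr$coords[, 2], fr$coords[, 3]), con)
  }
  invisible(path)
}

#' Read a multi-frame trajectory CSV
#'
#' @param path file written by [write_trajectory_csv()].
#' @return list of [mc_frame()] objects ordered by frame index.
#' @export
read_trajectory_csv <- function(path) {
  lines <- readLines(path, n = 5)
  box <- .parse_header_num(lines, "box", path)
  df <- utils::read.csv(path, comment.char = "#")
  lt <- as.character(df$lipid_type)
  lt[lt == "NA"] <- NA_character_
  df$lipid_type <- lt
  lapply(split(df, df$frame), function(d) {
    mc_frame(as.matrix(d[c("x", "y", "z")]), d$bead_kind, d$lipid_type,
             d$molecule_id, box, time = d$time[1])
  })
}

#' Write a frame as a GROMACS GRO file
#'
#' Marker beads are written as atom `PO4` of residues named by lipid type;
#' cholesterol heads as atom `ROH` of residue `CHOL`. Coordinates in nm
#' (GRO native). GRO stores 3 decimals, so round trips are exact only to
#' 0.001 nm.
#'
#' @param frame an [mc_frame()].
#' @param path output file.
#' @export
write_gro <- function(frame, path) {
  n <- nrow(frame$coords)
  resname <- ifelse(frame$bead_kind == "chol_head", "CHOL",
                    ifelse(is.na(frame$lipid_type), "UNK", frame$lipid_type))
  atom <- ifelse(frame$bead_kind == "chol_head", "ROH",
                 ifelse(frame$bead_kind == "lipid_marker", "PO4", "BD"))
  lines <- c(sprintf("memcurv frame t= %g", frame$time),
             sprintf("%d", n),
             sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     frame$molecule_id %% 100000L, resname, atom,
                     seq_len(n) %% 100000L,
                     frame$coords[, 1], frame$coords[, 2], frame$coords[, 3]),
             sprintf("%10.5f%10.5f%10.5f", frame$box[1], frame$box[2],
                     frame$box[3]))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GRO file into a frame
#'
#' @param path GRO file.
#' @param marker atom name of the lipid headgroup marker bead (default
#'   `"PO4"`).
#' @param chol atom name of the cholesterol head bead (default `"ROH"`).
#' @return an [mc_frame()]; beads with other atom names get kind `"other"`.
#' @export
read_gro <- function(path, marker = "PO4", chol = "ROH") {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[2]))
  at <- lines[3:(2 + n)]
  resid <- as.integer(substr(at, 1, 5))
  resname <- trimws(substr(at, 6, 10))
  atname <- trimws(substr(at, 11, 15))
  x <- as.numeric(substr(at, 21, 28))
  y <- as.numeric(substr(at, 29, 36))
  z <- as.numeric(substr(at, 37, 44))
  box <- as.numeric(strsplit(trimws(lines[3 + n]), "\\s+")[[1]])[1:3]
  kind <- ifelse(atname == marker, "lipid_marker",
                 ifelse(atname == chol, "chol_head", "other"))
  if (!any(kind == "lipid_marker")) {
    stop(sprintf("read_gro: no beads named '%s'; available names: %s",
                 marker, paste(unique(atname), collapse = ", ")))
  }
  lt <- ifelse(kind == "lipid_marker", resname, NA_character_)
  mc_frame(cbind(x, y, z), kind, lt, resid, box)
}

#' Read a PDB file into a frame (requires bio3d)
#'
#' Coordinates are converted from Angstrom to nm; the box is taken from the
#' CRYST1 record.
#'
#' @inheritParams read_gro
#' @export
read_pdb_frame <- function(path, marker = "PO4", chol = "ROH") {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("read_pdb_frame: the bio3d package is required for PDB input")
  }
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  kind <- ifelse(a$elety == marker, "lipid_marker",
                 ifelse(a$elety == chol, "chol_head", "other"))
  if (!any(kind == "lipid_marker")) {
    stop(sprintf("read_pdb_frame: no atoms named '%s'; available: %s",
                 marker, paste(utils::head(unique(a$elety), 20), collapse = ", ")))
  }
  cl <- grep("^CRYST1", readLines(path, warn = FALSE), value = TRUE)
  if (length(cl) == 0) stop("read_pdb_frame: PDB file has no CRYST1 box record")
  box <- as.numeric(c(substr(cl[1], 7, 15), substr(cl[1], 16, 24),
                      substr(cl[1], 25, 33))) / 10
  if (any(!is.finite(box)) || any(box <= 0)) {
    stop("read_pdb_frame: PDB file has no usable CRYST1 box")
  }
  lt <- ifelse(kind == "lipid_marker", a$resid, NA_character_)
  mc_frame(cbind(a$x, a$y, a$z) / 10, kind, lt, a$resno, box)
}

#' Read a structure file, dispatching on extension
#'
#' `.csv` via [read_frame_csv()], `.gro` via [read_gro()], `.pdb` via
#' [read_pdb_frame()].
#'
#' @inheritParams read_gro
#' @export
read_structure <- function(path, marker = "PO4", chol = "ROH") {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         csv = read_frame_csv(path),
         gro = read_gro(path, marker, chol),
         pdb = read_pdb_frame(path, marker, chol),
         stop(sprintf("read_structure: unsupported extension '.%s'", ext)))
}

# provenance header lines for CSV outputs
.prov_header <- function(params) {
  c("# memcurv output",
    sprintf("# %s = %s", names(params),
            vapply(params, function(v) paste(format(v), collapse = " "),
                   character(1))))
}

#' Write a midline to CSV
#'
#' Columns `i`, `l`, `x`, `y`, `z` with a provenance header.
#'
#' @param midline an `mc_midline`.
#' @param path output file.
#' @param params named list recorded in the provenance header.
#' @export
write_midline_csv <- function(midline, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.prov_header(c(list(s = midline$s, closed = midline$closed),
                            params)), con)
  writeLines("i,l,x,y,z", con)
  writeLines(sprintf("%d,%.6f,%.6f,%.6f,%.6f",
                     seq_len(nrow(midline$points)), midline$l,
                     midline$points[, 1], midline$points[, 2],
                     midline$points[, 3]), con)
  invisible(path)
}

#' Write a midline as a PDB of pseudo-atoms
#'
#' One pseudo-atom per midline point, with the B-factor column carrying
#' `|kappa|` when a curvature profile is supplied (visualization mirroring
#' the midline-with-curvature-spheres rendering of the analysis).
#'
#' @param midline an `mc_midline`.
#' @param path output file.
#' @param profile optional `mc_curvature` aligned with the midline.
#' @export
write_midline_pdb <- function(midline, path, profile = NULL) {
  P <- midline$points * 10  # nm -> Angstrom
  b <- if (is.null(profile)) rep(0, nrow(P)) else abs(profile$kappa)
  lines <- sprintf("ATOM  %5d  C   MID A%4d    %8.3f%8.3f%8.3f  1.00%6.2f",
                   seq_len(nrow(P)) %% 100000L, seq_len(nrow(P)) %% 10000L,
                   P[, 1], P[, 2], P[, 3], pmin(b * 100, 999))
  writeLines(c(sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                       midline$box[1] * 10, midline$box[2] * 10,
                       midline$box[3] * 10),
               lines, "END"), path)
  invisible(path)
}

#' Write a curvature profile to CSV
#'
#' Columns `time`, `i`, `l`, `x`, `z`, `kappa` with a provenance header.
#'
#' @param profile an `mc_curvature`.
#' @param path output file.
#' @param params named list recorded in the provenance header.
#' @export
write_curvature_csv <- function(profile, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.prov_header(c(list(lambda_c = profile$lambda_c), params)), con)
  writeLines("time,i,l,x,z,kappa", con)
  writeLines(sprintf("%.6g,%d,%.6f,%.6f,%.6f,%.8g",
                     profile$time, seq_along(profile$kappa), profile$l,
                     profile$x, profile$z, profile$kappa), con)
  invisible(path)
}

#' Write a curvature distribution to CSV
#'
#' @param dist an `mc_curvdist`.
#' @param path output file.
#' @param params provenance parameters.
#' @export
write_distribution_csv <- function(dist, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.prov_header(c(list(condition = dist$condition,
                                 bin_width = dist$bin_width, n = dist$n),
                            params)), con)
  writeLines("kappa_bin_center,P,n", con)
  writeLines(sprintf("%.8g,%.8g,%d", dist$mids, dist$P, dist$counts), con)
  invisible(path)
}

#' Write a free-energy profile to CSV
#'
#' @param energy an `mc_energy`.
#' @param path output file.
#' @param params provenance parameters.
#' @export
write_energy_csv <- function(energy, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.prov_header(c(list(T = energy$T, n_min = energy$n_min),
                            params)), con)
  writeLines("kappa_bin_center,E_kBT,masked", con)
  writeLines(sprintf("%.8g,%s,%d", energy$kappa,
                     ifelse(energy$masked, "NA", sprintf("%.8g", energy$E_kBT)),
                     as.integer(energy$masked)), con)
  invisible(path)
}
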