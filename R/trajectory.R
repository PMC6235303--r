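#' Construct a trajectory
#'
#' @param topology a [make_topology()] object.
#' @param coords numeric array `n_atoms x 3 x n_frames` (Angstrom).
#' @param boxes `n_frames x 3` matrix of box lengths, or a single [box()]
#'   recycled over frames.
#' @param dt time between stored frames (ps).
#' @param times optional frame times (ps); default `(0:(n-1)) * dt`.
#' @return object of class `trajectory`.
#' @export
trajectory <- function(topology, coords, boxes, dt = 1, times = NULL) {
  if (length(dim(coords)) != 3 || dim(coords)[2] != 3)
    stop("coords must be an n_atoms x 3 x n_frames array")
  nf <- dim(coords)[3]
  if (dim(coords)[1] != topology$n_atoms)
    stop("coords atom count does not match topology")
  if (inherits(boxes, "box") || (is.numeric(boxes) && length(boxes) == 3))
    boxes <- matrix(as.numeric(boxes), nf, 3, byrow = TRUE)
  boxes <- as.matrix(boxes)
  if (nrow(boxes) != nf || ncol(boxes) != 3) stop("boxes must be n_frames x 3")
  if (any(boxes <= 0)) stop("box lengths must be positive")
  if (dt <= 0) stop("dt must be positive")
  if (is.null(times)) times <- (seq_len(nf) - 1) * dt
  if (nf > 1 && any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  structure(list(topology = topology, coords = coords, boxes = boxes,
                 dt = dt, times = times),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", n_frames(x), "frames x", x$topology$n_atoms,
      "atoms, dt =", x$dt, "ps\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a [trajectory()].
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Coordinates of one frame
#' @param traj a [trajectory()].
#' @param frame frame index (1-based).
#' @return `n_atoms x 3` matrix.
#' @export
frame_coords <- function(traj, frame = 1L) traj$coords[, , frame, drop = TRUE]

#' Box of one frame
#' @inheritParams frame_coords
#' @export
frame_box <- function(traj, frame = 1L) as_box(traj$boxes[frame, ])

## ---- PDB I/O ---------------------------------------------------------------

.read_pdb_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  model <- 1L
  models <- integer(length(lines))
  cur <- 1L
  started <- FALSE
  for (i in seq_along(lines)) {
    tag <- substr(lines[i], 1, 6)
    if (startsWith(tag, "MODEL")) { if (started) cur <- cur + 1L; started <- TRUE }
    models[i] <- cur
  }
  is_atom <- substr(lines, 1, 6) %in% c("ATOM  ", "HETATM")
  al <- lines[is_atom]
  if (!length(al))
    return(list(atoms = data.frame(), boxes = NULL))
  num <- function(s) suppressWarnings(as.numeric(s))
  atoms <- data.frame(
    model = models[is_atom],
    serial = as.integer(num(substr(al, 7, 11))),
    name = trimws(substr(al, 13, 16)),
    resname = trimws(substr(al, 18, 20)),
    chain = substr(al, 22, 22),
    resid = as.integer(num(substr(al, 23, 26))),
    x = num(substr(al, 31, 38)),
    y = num(substr(al, 39, 46)),
    z = num(substr(al, 47, 54)),
    element = trimws(substr(al, 77, 78)),
    stringsAsFactors = FALSE)
  blank <- atoms$element == ""
  atoms$element[blank] <- .guess_element(atoms$name[blank])
  is_cryst <- startsWith(lines, "CRYST1")
  boxes <- NULL
  if (any(is_cryst)) {
    cl <- lines[is_cryst]
    boxes <- cbind(num(substr(cl, 7, 15)), num(substr(cl, 16, 24)),
                   num(substr(cl, 25, 33)))
    ang <- cbind(num(substr(cl, 34, 40)), num(substr(cl, 41, 47)),
                 num(substr(cl, 48, 54)))
    if (any(abs(ang - 90) > 1e-3, na.rm = TRUE))
      stop("triclinic box in ", path, ": only orthorhombic boxes are supported")
    boxes <- cbind(boxes, model = models[is_cryst])
  }
  list(atoms = atoms, boxes = boxes)
}

.fmt_pdb_atom <- function(serial, name, resname, chain, resid, xyz, element) {
  nm <- ifelse(nchar(name) < 4, sprintf(" %-3s", name), sprintf("%-4s", name))
  sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial %% 100000L, nm, resname, chain, resid %% 10000L,
          xyz[1], xyz[2], xyz[3], 1, 0, element)
}

.write_pdb <- function(traj, path, frames = seq_len(n_frames(traj))) {
  a <- traj$topology$atoms
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(frames) > 1
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    b <- traj$boxes[f, ]
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                       b[1], b[2], b[3], 90, 90, 90), con)
    if (multi) writeLines(sprintf("MODEL     %4d", fi), con)
    pos <- frame_coords(traj, f)
    writeLines(vapply(seq_len(nrow(a)), function(i)
      .fmt_pdb_atom(a$index[i], a$name[i], a$resname[i], a$chain[i],
                    a$resid[i], pos[i, ], a$element[i]), ""), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

## ---- extended XYZ I/O ------------------------------------------------------

.read_xyz_frames <- function(path) {
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("malformed XYZ atom-count line at line ", i)
    comment <- lines[i + 1L]
    toks <- strsplit(trimws(comment), "[[:space:]]+")[[1]]
    bx <- suppressWarnings(as.numeric(toks[1:3]))
    if (anyNA(bx)) stop("XYZ comment line must carry 'lx ly lz' box lengths")
    body <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(body), "[[:space:]]+")
    el <- vapply(parts, `[`, "", 1L)
    xyz <- matrix(as.numeric(unlist(lapply(parts, `[`, 2:4))), ncol = 3,
                  byrow = TRUE)
    frames[[length(frames) + 1L]] <- list(el = el, xyz = xyz, box = bx)
    i <- i + 2L + n
  }
  frames
}

.write_xyz <- function(traj, path, frames = seq_len(n_frames(traj))) {
  a <- traj$topology$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (f in frames) {
    b <- traj$boxes[f, ]
    writeLines(as.character(traj$topology$n_atoms), con)
    writeLines(sprintf("%.6f %.6f %.6f time=%.6f", b[1], b[2], b[3],
                       traj$times[f]), con)
    pos <- frame_coords(traj, f)
    writeLines(sprintf("%-2s %12.6f %12.6f %12.6f", a$element, pos[, 1],
                       pos[, 2], pos[, 3]), con)
  }
  invisible(path)
}

#' Read trajectory frames
#'
#' Frames are read from multi-model PDB files (one frame per MODEL, box from
#' the CRYST1 record) or extended XYZ files whose comment line starts with
#' the three orthorhombic box lengths `lx ly lz` (Angstrom).
#'
#' @param paths character vector of files, read in order.
#' @param topology the matching [make_topology()] topology.
#' @param dt time between stored frames in ps (used when files carry no
#'   times).
#' @return a [trajectory()].
#' @export
read_trajectory <- function(paths, topology, dt = 1) {
  pos_list <- list()
  box_list <- list()
  for (p in paths) {
    if (grepl("\\.xyz$", p, ignore.case = TRUE)) {
      for (fr in .read_xyz_frames(p)) {
        if (nrow(fr$xyz) != topology$n_atoms)
          stop("frame atom count (", nrow(fr$xyz), ") does not match topology (",
               topology$n_atoms, ") in ", p)
        pos_list[[length(pos_list) + 1L]] <- fr$xyz
        box_list[[length(box_list) + 1L]] <- fr$box
      }
    } else {
      rec <- .read_pdb_records(p)
      if (is.null(rec$boxes)) stop("no CRYST1 box record in ", p)
      for (m in sort(unique(rec$atoms$model))) {
        a <- rec$atoms[rec$atoms$model == m, , drop = FALSE]
        if (nrow(a) != topology$n_atoms)
          stop("frame atom count (", nrow(a), ") does not match topology (",
               topology$n_atoms, ") in ", p)
        bm <- rec$boxes[rec$boxes[, 4] == m, 1:3, drop = FALSE]
        if (!nrow(bm)) bm <- rec$boxes[1, 1:3, drop = FALSE]
        pos_list[[length(pos_list) + 1L]] <- as.matrix(a[, c("x", "y", "z")])
        box_list[[length(box_list) + 1L]] <- bm[1, ]
      }
    }
  }
  if (!length(pos_list)) stop("no frames read")
  nf <- length(pos_list)
  coords <- array(0, dim = c(topology$n_atoms, 3, nf))
  for (f in seq_len(nf)) coords[, , f] <- pos_list[[f]]
  trajectory(topology, coords, do.call(rbind, box_list), dt = dt)
}

#' Write a trajectory to disk
#'
#' @param traj a [trajectory()].
#' @param path output file.
#' @param format `"xyz"` (extended XYZ, box on the comment line) or `"pdb"`
#'   (multi-model with per-frame CRYST1).
#' @export
write_trajectory <- function(traj, path, format = c("xyz", "pdb")) {
  format <- match.arg(format)
  if (format == "xyz") .write_xyz(traj, path) else .write_pdb(traj, path)
}

#' Drop all molecules whose species is not in `keep`
#'
#' Used e.g. to strip crowders and salt ions before voxel-based solvation
#' analysis, which treats everything except water as part of the solute.
#'
#' @param traj a [trajectory()].
#' @param keep character vector of species classes to retain.
#' @return a new [trajectory()] over the retained atoms.
#' @export
strip_species <- function(traj, keep = c("SOLUTE", "WATER")) {
  a <- traj$topology$atoms
  sel <- which(a$species %in% keep)
  subset_trajectory(traj, sel)
}

#' Restrict a trajectory to a set of atoms
#' @param traj a [trajectory()].
#' @param atoms integer atom indices to keep.
#' @export
subset_trajectory <- function(traj, atoms) {
  a <- traj$topology$atoms[atoms, , drop = FALSE]
  remap <- match(seq_len(traj$topology$n_atoms), atoms)
  top <- make_topology(name = a$name, resname = a$resname, resid = a$resid,
                       species = a$species, element = a$element,
                       charge = a$charge, sigma = a$sigma,
                       epsilon = a$epsilon, chain = a$chain,
                       positions = traj$coords[atoms, , 1],
                       bonded_heavy = remap[a$bonded_heavy])
  trajectory(top, traj$coords[atoms, , , drop = FALSE], traj$boxes,
             dt = traj$dt, times = traj$times)
}
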