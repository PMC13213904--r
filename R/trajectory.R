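#' Coordinate ensemble of a single protein chain
#'
#' A `Trajectory` stores an ordered set of frames of atomic coordinates
#' (in nm) together with per-atom metadata and the time spacing between
#' stored frames.  All frames share one atom table; coordinates are kept
#' as an `n_frames x (3 * n_atoms)` matrix in bio3d `xyz` layout
#' (x1, y1, z1, x2, ...).
#'
#' @param xyz numeric matrix, `n_frames x (3 * n_atoms)`, coordinates in nm.
#' @param atoms data.frame with columns `name`, `element`, `resid`
#'   (integer residue index), `resname`, `chain`.
#' @param frame_interval_ns time between stored frames in ns.
#' @return An object of class `Trajectory`.
#' @export
trajectory <- function(xyz, atoms, frame_interval_ns = 1) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) %% 3L != 0L)
    stop("xyz must have 3 columns per atom")
  n_atoms <- ncol(xyz) %/% 3L
  if (nrow(atoms) != n_atoms)
    stop("atom table (", nrow(atoms), ") does not match coordinates (",
         n_atoms, " atoms)")
  if (!all(is.finite(xyz)))
    stop("coordinates contain non-finite values")
  req <- c("name", "element", "resid", "resname", "chain")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  atoms$resid <- as.integer(atoms$resid)
  rid <- unique(atoms$resid)
  if (any(diff(rid) <= 0L))
    stop("residue indices must be strictly increasing along the chain")
  structure(list(xyz = xyz, atoms = atoms,
                 frame_interval_ns = frame_interval_ns),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frame(s), %d atoms, %d residues, dt = %g ns\n",
              n_frames(x), n_atoms(x), length(unique(x$atoms$resid)),
              x$frame_interval_ns))
  invisible(x)
}

#' @rdname trajectory
#' @param traj a `Trajectory`.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' @rdname trajectory
#' @export
n_atoms <- function(traj) ncol(traj$xyz) %/% 3L

#' Coordinates of one frame as an atoms x 3 matrix (nm)
#'
#' @param traj a `Trajectory`.
#' @param i frame index.
#' @return numeric matrix `n_atoms x 3`.
#' @export
frame_coords <- function(traj, i) {
  matrix(traj$xyz[i, ], ncol = 3L, byrow = TRUE)
}

#' Residue indices present in a trajectory
#' @param traj a `Trajectory`.
#' @return sorted integer vector of residue indices.
#' @export
residue_ids <- function(traj) sort(unique(traj$atoms$resid))

# Infer element symbol from a PDB atom name ("CA" -> C, "1HG1" -> H, ...)
infer_element <- function(name) {
  vapply(name, function(nm) {
    s <- gsub("[^A-Za-z]", "", nm)
    if (!nzchar(s)) return("X")
    # two-letter elements occurring in standard residues
    up <- toupper(s)
    if (substr(up, 1, 2) %in% c("SE", "FE", "ZN", "MG", "CL", "BR", "NA"))
      return(substr(up, 1, 2))
    substr(up, 1, 1)
  }, character(1), USE.NAMES = FALSE)
}

#' Read a coordinate ensemble from disk
#'
#' Reads a (multi-model) PDB file into a [trajectory()].  Every MODEL must
#' contain the same atoms in the same order; coordinates are converted from
#' Angstrom to nm.  Missing element fields are inferred from atom names.
#'
#' @param path file path.
#' @param format `"pdb-multimodel"` (the only built-in reader) or a reader
#'   function `function(path) -> Trajectory` honouring the same contract,
#'   allowing callers to plug in binary trajectory formats.
#' @param frame_interval_ns time between models in ns (metadata only).
#' @return A [trajectory()] with one frame per model.
#' @export
read_structure_ensemble <- function(path, format = "pdb-multimodel",
                                    frame_interval_ns = 1) {
  if (is.function(format)) return(format(path))
  if (!identical(format, "pdb-multimodel"))
    stop("unknown format: ", format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) stop("empty file: ", path)
  check_model_consistency(path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  elem <- at$elesy
  if (is.null(elem)) elem <- rep(NA_character_, nrow(at))
  bad <- is.na(elem) | !nzchar(trimws(elem))
  elem[bad] <- infer_element(at$elety[bad])
  atoms <- data.frame(name = at$elety, element = trimws(elem),
                      resid = as.integer(at$resno), resname = at$resid,
                      chain = ifelse(is.na(at$chain), "A", at$chain),
                      stringsAsFactors = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  trajectory(xyz / 10, atoms, frame_interval_ns)  # Angstrom -> nm
}

# Scan MODEL blocks for per-model atom counts so that a malformed ensemble
# fails with a message naming the offending model.
check_model_consistency <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  model_starts <- grep("^MODEL", lines)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("input error: no ATOM records in ", path)
  if (length(model_starts) <= 1L) return(invisible(TRUE))
  model_ends <- grep("^ENDMDL", lines)
  if (length(model_ends) != length(model_starts))
    stop("format error: unbalanced MODEL/ENDMDL records")
  counts <- mapply(function(s, e) sum(is_atom[s:e]), model_starts, model_ends)
  if (length(unique(counts)) > 1L) {
    bad <- which(counts != counts[1])[1]
    stop(sprintf(
      "format error: model %d has %d atoms but model 1 has %d",
      bad, counts[bad], counts[1]))
  }
  invisible(TRUE)
}

#' Write a trajectory as a (multi-model) PDB file
#'
#' @param traj a [trajectory()].
#' @param path output file path.
#' @param frames frame indices to write (default all).
#' @param b per-atom values for the B-factor column (recycled), default 0.
#' @return `path`, invisibly.
#' @export
write_structure_ensemble <- function(traj, path, frames = seq_len(n_frames(traj)),
                                     b = 0) {
  at <- traj$atoms
  b <- rep_len(b, nrow(at))
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(frames) > 1L
  for (kk in seq_along(frames)) {
    f <- frames[kk]
    if (multi) writeLines(sprintf("MODEL     %4d", kk), con)
    xyz <- frame_coords(traj, f) * 10  # nm -> Angstrom
    nm <- ifelse(nchar(at$name) < 4L, paste0(" ", at$name), at$name)
    lines <- sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(at)) %% 100000L, nm, at$resname, substr(at$chain, 1, 1),
      at$resid, xyz[, 1], xyz[, 2], xyz[, 3], 1, b, at$element)
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
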