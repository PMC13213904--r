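#' Frames-by-descriptors feature table
#'
#' @param values numeric matrix, frames x descriptors, with unique column names.
#' @param units character vector of per-column units (recycled).
#' @param frame_interval_ns time between rows, ns.
#' @return An object of class `FeatureMatrix`.
#' @export
feature_matrix <- function(values, units = "nm", frame_interval_ns = 1) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("f", seq_len(ncol(values)))
  if (anyDuplicated(colnames(values))) stop("descriptor labels must be unique")
  if (any(!is.finite(values))) stop("feature values must be finite")
  structure(list(values = values,
                 units = rep_len(units, ncol(values)),
                 frame_interval_ns = frame_interval_ns),
            class = "FeatureMatrix")
}

#' @export
print.FeatureMatrix <- function(x, ...) {
  cat(sprintf("FeatureMatrix: %d frames x %d descriptors, dt = %g ns\n",
              nrow(x$values), ncol(x$values), x$frame_interval_ns))
  invisible(x)
}

#' @export
dim.FeatureMatrix <- function(x) dim(x$values)

#' Combine feature matrices column-wise
#' @param ... `FeatureMatrix` objects with equal frame counts.
#' @return a `FeatureMatrix`.
#' @export
cbind_features <- function(...) {
  xs <- list(...)
  feature_matrix(do.call(cbind, lapply(xs, `[[`, "values")),
                 units = unlist(lapply(xs, `[[`, "units")),
                 frame_interval_ns = xs[[1]]$frame_interval_ns)
}

#' Write a FeatureMatrix as CSV plus a JSON label/unit sidecar
#'
#' @param X a [feature_matrix()].
#' @param path CSV output path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(X, path) {
  utils::write.csv(as.data.frame(X$values), path, row.names = FALSE)
  side <- sprintf('{"labels": [%s], "units": [%s], "frame_interval_ns": %g}',
                  paste(sprintf('"%s"', colnames(X$values)), collapse = ", "),
                  paste(sprintf('"%s"', X$units), collapse = ", "),
                  X$frame_interval_ns)
  writeLines(side, paste0(path, ".json"))
  invisible(path)
}

# standard atomic masses (u) for elements in protein heavy atoms
.atomic_mass <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                  S = 32.06, SE = 78.971, X = 12.011)

#' Default hydrophobic residue class
#'
#' The residue set treated as hydrophobic in preset feature construction
#' and apolar scoring; configurable wherever it is used.
#' @export
hydrophobic_residues <- c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "TRP", "PRO")

# index atoms of one residue; error if residue absent
.res_atoms <- function(traj, resid) {
  idx <- which(traj$atoms$resid == resid)
  if (!length(idx)) stop("residue ", resid, " not present in trajectory")
  idx
}

# per-frame coordinates (n_frames x 3) of the mass-weighted side-chain COM
# of one residue; side chain = heavy atoms beyond C-beta inclusive.
# Glycine (or any residue without side-chain heavy atoms) falls back to CA.
.sidechain_com <- function(traj, resid) {
  idx <- .res_atoms(traj, resid)
  at <- traj$atoms[idx, ]
  bb <- c("N", "CA", "C", "O", "OXT", "OT1", "OT2")
  sc <- idx[!(at$name %in% bb) & at$element != "H"]
  if (!length(sc)) {
    ca <- idx[at$name == "CA"]
    if (!length(ca))
      stop("data error: residue ", resid, " has no side-chain heavy atoms and no CA")
    sc <- ca
  }
  m <- .atomic_mass[traj$atoms$element[sc]]
  m[is.na(m)] <- .atomic_mass[["X"]]
  cols <- as.vector(rbind(3 * sc - 2, 3 * sc - 1, 3 * sc))
  xyz <- traj$xyz[, cols, drop = FALSE]
  nf <- nrow(xyz)
  out <- matrix(0, nf, 3)
  wt <- m / sum(m)
  for (k in seq_along(sc)) {
    out <- out + wt[k] * xyz[, (3 * k - 2):(3 * k), drop = FALSE]
  }
  out
}

.atom_xyz <- function(traj, resid, name) {
  idx <- .res_atoms(traj, resid)
  a <- idx[traj$atoms$name[idx] == name]
  if (!length(a))
    stop("data error: residue ", resid, " lacks atom ", name)
  traj$xyz[, (3 * a[1] - 2):(3 * a[1]), drop = FALSE]
}

#' Pairwise residue distance features
#'
#' Computes per-frame distances between residue pairs, either between
#' side-chain centres of mass (mass-weighted heavy atoms beyond C-beta;
#' glycine falls back to its C-alpha) or between C-alpha atoms.  With
#' `pairs = NULL` all unordered pairs of the (optionally class-filtered)
#' residue set are enumerated, reproducing the exhaustive contact
#' representations used for slow-mode screening.
#'
#' @param traj a [trajectory()].
#' @param pairs two-column matrix/data.frame of residue index pairs, or
#'   `NULL` for exhaustive enumeration.
#' @param mode `"sidechain-com"` or `"calpha"`.
#' @param selection optional character vector of residue names; restricts
#'   exhaustive enumeration to residues of these types (e.g.
#'   [hydrophobic_residues]).
#' @return a [feature_matrix()] in nm, one column per pair, labelled
#'   `COM_i_j` or `CA_i_j`.
#' @export
pair_distance_features <- function(traj, pairs = NULL,
                                   mode = c("sidechain-com", "calpha"),
                                   selection = NULL) {
  mode <- match.arg(mode)
  if (is.null(pairs)) {
    res <- residue_ids(traj)
    if (!is.null(selection)) {
      rn <- traj$atoms$resname[match(res, traj$atoms$resid)]
      res <- res[rn %in% selection]
    }
    if (length(res) < 2L) stop("fewer than 2 residues to enumerate")
    pairs <- t(utils::combn(res, 2L))
  }
  pairs <- as.matrix(pairs)
  if (any(pairs[, 1] == pairs[, 2])) stop("pair with equal members")
  key <- paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  if (anyDuplicated(key)) stop("duplicate residue pair in registry")
  res_needed <- sort(unique(as.vector(pairs)))
  pos <- lapply(res_needed, function(r) {
    if (mode == "sidechain-com") .sidechain_com(traj, r) else .atom_xyz(traj, r, "CA")
  })
  names(pos) <- as.character(res_needed)
  vals <- matrix(0, n_frames(traj), nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    d <- pos[[as.character(pairs[p, 1])]] - pos[[as.character(pairs[p, 2])]]
    vals[, p] <- sqrt(rowSums(d * d))
  }
  tag <- if (mode == "sidechain-com") "COM" else "CA"
  colnames(vals) <- sprintf("%s_%d_%d", tag, pairs[, 1], pairs[, 2])
  feature_matrix(vals, units = "nm", frame_interval_ns = traj$frame_interval_ns)
}

# dihedral angle (degrees, (-180, 180]) from four point matrices (n x 3)
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  b2n <- b2 / sqrt(rowSums(b2 * b2))
  x <- rowSums(n1 * n2)
  y <- rowSums(cross(n1, n2) * b2n)
  ang <- atan2(y, x) * 180 / pi
  ang[ang <= -180] <- ang[ang <= -180] + 360
  ang
}

#' Backbone torsion features (phi/psi as cos,sin pairs)
#'
#' phi(i) = C(i-1)-N(i)-CA(i)-C(i) for residues 2..n and
#' psi(i) = N(i)-CA(i)-C(i)-N(i+1) for residues 1..n-1; each torsion is
#' encoded as a (cos, sin) column pair, giving `4 * (n_residues - 1)`
#' dimensionless columns.
#'
#' @param traj a [trajectory()] with complete N, CA, C backbone.
#' @return a [feature_matrix()], columns `phi_cos_i, phi_sin_i, psi_cos_i,
#'   psi_sin_i` ordered phi-block then psi-block.
#' @export
backbone_torsion_features <- function(traj) {
  res <- residue_ids(traj)
  n <- length(res)
  if (n < 2L) stop("need at least 2 residues for backbone torsions")
  N <- lapply(res, function(r) .atom_xyz(traj, r, "N"))
  CA <- lapply(res, function(r) .atom_xyz(traj, r, "CA"))
  C <- lapply(res, function(r) .atom_xyz(traj, r, "C"))
  cols <- list(); labs <- character(0)
  for (i in 2:n) {
    a <- .dihedral(C[[i - 1]], N[[i]], CA[[i]], C[[i]]) * pi / 180
    cols <- c(cols, list(cos(a), sin(a)))
    labs <- c(labs, sprintf("phi_cos_%d", res[i]), sprintf("phi_sin_%d", res[i]))
  }
  for (i in 1:(n - 1)) {
    a <- .dihedral(N[[i]], CA[[i]], C[[i]], N[[i + 1]]) * pi / 180
    cols <- c(cols, list(cos(a), sin(a)))
    labs <- c(labs, sprintf("psi_cos_%d", res[i]), sprintf("psi_sin_%d", res[i]))
  }
  vals <- do.call(cbind, cols)
  colnames(vals) <- labs
  feature_matrix(vals, units = "1", frame_interval_ns = traj$frame_interval_ns)
}

# ring heavy-atom names per aromatic residue type
.ring_atoms <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"))

# unit normal of the least-squares plane through points (m x 3)
.plane_normal <- function(pts) {
  ctr <- sweep(pts, 2, colMeans(pts))
  sv <- svd(ctr)
  sv$v[, 3]
}

#' Angular descriptors: C-alpha quadruple dihedrals and ring-plane angles
#'
#' Quadruple dihedrals track relative motion of secondary-structure elements
#' (e.g. the inter-helix reorientation angle); ring-plane angles quantify
#' aromatic packing as the angle between least-squares ring planes, folded
#' to \[0, 90\] degrees so it is invariant to ring flips.
#'
#' @param traj a [trajectory()].
#' @param quads matrix/data.frame with 4 columns of residue indices
#'   (C-alpha dihedrals), or `NULL`.
#' @param ring_pairs two-column matrix of aromatic residue index pairs,
#'   or `NULL`.
#' @return a [feature_matrix()] in degrees; dihedrals in (-180, 180],
#'   ring angles in \[0, 90\].
#' @export
angular_descriptors <- function(traj, quads = NULL, ring_pairs = NULL) {
  cols <- list(); labs <- character(0)
  if (!is.null(quads)) {
    quads <- as.matrix(quads)
    for (q in seq_len(nrow(quads))) {
      ca <- lapply(quads[q, ], function(r) .atom_xyz(traj, r, "CA"))
      cols <- c(cols, list(.dihedral(ca[[1]], ca[[2]], ca[[3]], ca[[4]])))
      labs <- c(labs, sprintf("DIH_%s", paste(quads[q, ], collapse = "_")))
    }
  }
  if (!is.null(ring_pairs)) {
    ring_pairs <- as.matrix(ring_pairs)
    for (p in seq_len(nrow(ring_pairs))) {
      normals <- lapply(ring_pairs[p, ], function(r) {
        idx <- .res_atoms(traj, r)
        rn <- traj$atoms$resname[idx[1]]
        if (!rn %in% names(.ring_atoms))
          stop("data error: residue ", r, " (", rn, ") is not aromatic")
        want <- .ring_atoms[[rn]]
        got <- idx[match(want, traj$atoms$name[idx])]
        if (anyNA(got))
          stop("data error: residue ", r, " has an incomplete ring")
        got
      })
      ang <- vapply(seq_len(n_frames(traj)), function(f) {
        co <- frame_coords(traj, f)
        n1 <- .plane_normal(co[normals[[1]], , drop = FALSE])
        n2 <- .plane_normal(co[normals[[2]], , drop = FALSE])
        acos(min(1, abs(sum(n1 * n2)))) * 180 / pi
      }, numeric(1))
      cols <- c(cols, list(ang))
      labs <- c(labs, sprintf("RING_%d_%d", ring_pairs[p, 1], ring_pairs[p, 2]))
    }
  }
  if (!length(cols)) stop("no descriptors requested")
  vals <- do.call(cbind, cols)
  colnames(vals) <- labs
  feature_matrix(vals, units = "deg", frame_interval_ns = traj$frame_interval_ns)
}

#' Superpose frames onto a reference and compute RMSD/RMSF
#'
#' Each frame is optimally least-squares superposed onto the reference
#' using the selected atoms; per-frame RMSD (over the selection) and
#' per-atom RMSF about the post-alignment mean are returned in nm.
#'
#' @param traj a [trajectory()].
#' @param reference a `Trajectory` (its first frame is used) sharing the
#'   atom table, or a frame index into `traj`.
#' @param atom_selection integer vector of atom indices used for fitting
#'   (default: all C-alpha atoms).
#' @return list with `rmsd` (per frame, nm), `rmsf` (per selected atom, nm),
#'   `selection`, and `aligned` (the superposed `Trajectory`).
#' @export
superpose_and_rmsf <- function(traj, reference = 1L, atom_selection = NULL) {
  if (is.null(atom_selection))
    atom_selection <- which(traj$atoms$name == "CA")
  if (length(atom_selection) < 3L)
    stop("geometry error: need at least 3 atoms for superposition")
  ref_xyz <- if (inherits(reference, "Trajectory")) reference$xyz[1, ] else traj$xyz[reference, ]
  sel3 <- as.vector(rbind(3 * atom_selection - 2, 3 * atom_selection - 1, 3 * atom_selection))
  fitted <- bio3d::fit.xyz(fixed = ref_xyz, mobile = traj$xyz,
                           fixed.inds = sel3, mobile.inds = sel3)
  if (is.null(dim(fitted))) fitted <- matrix(fitted, nrow = 1L)
  dif <- sweep(fitted[, sel3, drop = FALSE], 2, ref_xyz[sel3])
  rmsd <- sqrt(rowSums(dif^2) / length(atom_selection))
  mean_xyz <- colMeans(fitted[, sel3, drop = FALSE])
  dev <- sweep(fitted[, sel3, drop = FALSE], 2, mean_xyz)
  msd <- if (nrow(dev) > 1L) colMeans(dev^2) else rep(0, ncol(dev))
  rmsf <- sqrt(colSums(matrix(msd, nrow = 3)))
  aligned <- trajectory(fitted, traj$atoms, traj$frame_interval_ns)
  list(rmsd = rmsd, rmsf = rmsf, selection = atom_selection, aligned = aligned)
}

#' Mass-weighted radius of gyration per frame
#'
#' @param traj a [trajectory()].
#' @param heavy_only drop hydrogens before computing (default TRUE).
#' @return numeric vector, nm.
#' @export
radius_of_gyration <- function(traj, heavy_only = TRUE) {
  keep <- if (heavy_only) which(traj$atoms$element != "H") else seq_len(n_atoms(traj))
  m <- .atomic_mass[traj$atoms$element[keep]]
  m[is.na(m)] <- .atomic_mass[["X"]]
  w <- m / sum(m)
  vapply(seq_len(n_frames(traj)), function(f) {
    co <- frame_coords(traj, f)[keep, , drop = FALSE]
    ctr <- colSums(co * w)
    sqrt(sum(w * rowSums(sweep(co, 2, ctr)^2)))
  }, numeric(1))
}
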