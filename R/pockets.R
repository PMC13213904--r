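# Alpha-sphere cavity detection across an ensemble.  An alpha-sphere is
# the circumsphere of a Delaunay tetrahedron of heavy-atom centres: it
# touches four atoms and contains none, probing local voids.  Spheres are
# radius-filtered, accumulated on a grid as per-frame centre counts, and
# voxels at or above the isovalue are clustered into cavities that are
# scored by volume and mean local hydrophobic density.

#' Compute alpha-spheres for one frame
#'
#' Builds the Delaunay tetrahedralization of the heavy-atom centres,
#' takes each tetrahedron's circumsphere, and keeps spheres whose radius
#' lies in `[r_min, r_max]`.  A sphere is flagged apolar when at least 3
#' of its 4 contact atoms are carbon or sulfur.  A deterministic
#' sub-angstrom jitter breaks exact degeneracies before triangulating;
#' sphere centres and radii are recomputed from the original coordinates.
#'
#' @param traj a [trajectory()] (heavy atoms are selected internally) or a
#'   plain n x 3 coordinate matrix (nm).
#' @param frame frame index when `traj` is a `Trajectory`.
#' @param r_min,r_max radius bounds in nm (defaults 0.30 and 0.60,
#'   the usual pocket-probe range).
#' @param elements element symbols per atom (required for matrix input).
#' @return data.frame of class `AlphaSpheres`: `x`, `y`, `z`, `radius`
#'   (nm), `a1..a4` (contact atom indices), `apolar`.
#' @export
compute_alpha_spheres <- function(traj, frame = 1L, r_min = 0.30, r_max = 0.60,
                                  elements = NULL) {
  if (inherits(traj, "Trajectory")) {
    heavy <- which(traj$atoms$element != "H")
    pts <- frame_coords(traj, frame)[heavy, , drop = FALSE]
    el <- traj$atoms$element[heavy]
    orig_idx <- heavy
  } else {
    pts <- as.matrix(traj)
    el <- if (is.null(elements)) rep("C", nrow(pts)) else elements
    orig_idx <- seq_len(nrow(pts))
  }
  n <- nrow(pts)
  if (n < 4L) stop("geometry error: need at least 4 heavy atoms")
  span <- max(apply(pts, 2, function(v) diff(range(v))))
  if (span <= 0) stop("geometry error: degenerate (coincident) input")
  # deterministic jitter (LCG hash of the index) to break degeneracies
  jit <- ((seq_len(3L * n) * 2654435761) %% 97) / 96 - 0.5
  ptsj <- pts + matrix(jit, n, 3) * (1e-6 * span)
  tets <- cpp_delaunay3d(ptsj)
  if (!nrow(tets)) stop("geometry error: degenerate (coplanar) input")
  # circumspheres from the original coordinates
  sph <- t(apply(tets, 1, function(tv) {
    p <- pts[tv, , drop = FALSE]
    A <- 2 * sweep(p[2:4, , drop = FALSE], 2, p[1, ])
    rhs <- rowSums(p[2:4, , drop = FALSE]^2) - sum(p[1, ]^2)
    ctr <- tryCatch(solve(A, rhs), error = function(e) rep(NA_real_, 3))
    c(ctr, sqrt(sum((ctr - p[1, ])^2)))
  }))
  ok <- is.finite(sph[, 4]) & sph[, 4] >= r_min & sph[, 4] <= r_max
  tets <- tets[ok, , drop = FALSE]
  sph <- sph[ok, , drop = FALSE]
  apolar <- apply(tets, 1, function(tv) sum(el[tv] %in% c("C", "S")) >= 3)
  out <- data.frame(x = sph[, 1], y = sph[, 2], z = sph[, 3],
                    radius = sph[, 4],
                    a1 = orig_idx[tets[, 1]], a2 = orig_idx[tets[, 2]],
                    a3 = orig_idx[tets[, 3]], a4 = orig_idx[tets[, 4]],
                    apolar = apolar)
  class(out) <- c("AlphaSpheres", "data.frame")
  out
}

# voxel key for points on a grid anchored at the origin
.voxel_key <- function(pts, spacing) {
  ix <- floor(pts[, 1] / spacing)
  iy <- floor(pts[, 2] / spacing)
  iz <- floor(pts[, 3] / spacing)
  list(ix = ix, iy = iy, iz = iz,
       key = paste(ix, iy, iz, sep = "_"))
}

#' Alpha-sphere frequency grid and cavity selection
#'
#' Accumulates alpha-sphere centres on a cubic grid (default spacing
#' 0.2 nm, i.e. 8 cubic-Angstrom cubes) as the mean number of centres per
#' frame per voxel; voxels at or above the isovalue (default 2, so at
#' least two centres per cube per snapshot) are retained and grouped into
#' cavities by 26-connectivity.  Frames should be superposed to a common
#' reference beforehand.
#'
#' @param sphere_list list with one `AlphaSpheres` per frame.
#' @param spacing grid spacing in nm (default 0.2).
#' @param isovalue retention threshold on mean centres per frame
#'   (default 2).
#' @return object of class `CavityMap`: `voxels` (data.frame with voxel
#'   indices, frequency, cavity id), `cavities` (list of voxel-key sets),
#'   `spacing`, `isovalue`, `n_frames`, `sphere_list`.
#' @export
pocket_frequency_grid <- function(sphere_list, spacing = 0.2, isovalue = 2) {
  stopifnot(length(sphere_list) >= 1L)
  n_fr <- length(sphere_list)
  counts <- new.env(hash = TRUE)
  meta <- list()
  for (s in sphere_list) {
    if (!nrow(s)) next
    vk <- .voxel_key(cbind(s$x, s$y, s$z), spacing)
    tab <- table(vk$key)
    for (k in names(tab)) {
      prev <- if (!is.null(counts[[k]])) counts[[k]] else 0
      counts[[k]] <- prev + as.integer(tab[[k]])
    }
  }
  keys <- ls(counts)
  if (!length(keys)) {
    return(structure(list(voxels = data.frame(), cavities = list(),
                          spacing = spacing, isovalue = isovalue,
                          n_frames = n_fr, sphere_list = sphere_list),
                     class = "CavityMap"))
  }
  freq <- vapply(keys, function(k) counts[[k]] / n_fr, numeric(1))
  keep <- freq >= isovalue
  keys <- keys[keep]; freq <- freq[keep]
  if (!length(keys)) {
    return(structure(list(voxels = data.frame(), cavities = list(),
                          spacing = spacing, isovalue = isovalue,
                          n_frames = n_fr, sphere_list = sphere_list),
                     class = "CavityMap"))
  }
  idx <- do.call(rbind, strsplit(keys, "_", fixed = TRUE))
  idx <- matrix(as.integer(idx), ncol = 3)
  # cluster by 26-connectivity (Chebyshev distance 1), breadth-first
  nv <- length(keys)
  cav <- rep(0L, nv)
  cur <- 0L
  lut <- new.env(hash = TRUE)
  for (v in seq_len(nv)) lut[[keys[v]]] <- v
  for (v in seq_len(nv)) {
    if (cav[v] > 0L) next
    cur <- cur + 1L
    queue <- v
    cav[v] <- cur
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        nb <- paste(idx[u, 1] + dx, idx[u, 2] + dy, idx[u, 3] + dz, sep = "_")
        w <- lut[[nb]]
        if (!is.null(w) && cav[w] == 0L) { cav[w] <- cur; queue <- c(queue, w) }
      }
    }
  }
  vox <- data.frame(ix = idx[, 1], iy = idx[, 2], iz = idx[, 3],
                    key = keys, frequency = freq, cavity = cav,
                    stringsAsFactors = FALSE)
  cavities <- split(vox$key, vox$cavity)
  structure(list(voxels = vox, cavities = cavities, spacing = spacing,
                 isovalue = isovalue, n_frames = n_fr,
                 sphere_list = sphere_list),
            class = "CavityMap")
}

#' @export
print.CavityMap <- function(x, ...) {
  cat(sprintf("CavityMap: %d retained voxel(s) in %d cavit%s (spacing %.2g nm, isovalue %g, %d frames)\n",
              nrow(x$voxels), length(x$cavities),
              if (length(x$cavities) == 1) "y" else "ies",
              x$spacing, x$isovalue, x$n_frames))
  invisible(x)
}

# union volume (cubic Angstrom) of spheres by sub-voxel sampling
.sphere_union_volume <- function(centers, radii, sub = 0.025) {
  if (!length(radii)) return(0)
  lo <- apply(centers - radii, 2, min)
  hi <- apply(centers + radii, 2, max)
  gx <- seq(lo[1] + sub / 2, hi[1], by = sub)
  gy <- seq(lo[2] + sub / 2, hi[2], by = sub)
  gz <- seq(lo[3] + sub / 2, hi[3], by = sub)
  inside <- 0
  r2 <- radii^2
  for (z in gz) {
    # vectorized over the xy plane at height z
    plane <- matrix(FALSE, length(gx), length(gy))
    for (s in seq_along(r2)) {
      dz2 <- (z - centers[s, 3])^2
      if (dz2 > r2[s]) next
      rho2 <- r2[s] - dz2
      dx2 <- (gx - centers[s, 1])^2
      dy2 <- (gy - centers[s, 2])^2
      plane <- plane | outer(dx2, dy2, "+") <= rho2
    }
    inside <- inside + sum(plane)
  }
  inside * sub^3 * 1000  # nm^3 -> A^3
}

#' Volume and mean local hydrophobic density of a cavity
#'
#' Volume is the voxelized union volume of the cavity's alpha-spheres
#' (0.25 Angstrom sub-voxel sampling, fine enough for ~1% agreement with
#' analytic sphere unions), per frame, reported as mean and SE over
#' frames in cubic Angstrom.  The mean local hydrophobic density
#' counts, for every apolar sphere, its overlapping apolar neighbours
#' (centre distance below the sum of radii), sums over the cavity and
#' divides by the number of apolar spheres (0 when the cavity has no
#' apolar sphere).
#'
#' @param map a `CavityMap`.
#' @param cavity cavity id (index into `map$cavities`).
#' @param sub sub-voxel sampling length in nm (default 0.025 = 0.25 A).
#' @return list: `volume_A3` (mean), `volume_se`, `density` (mean),
#'   `density_se`, `n_spheres`, per-frame vectors `volume_frames`,
#'   `density_frames`.
#' @export
cavity_metrics <- function(map, cavity = 1L, sub = 0.025) {
  keys <- map$cavities[[cavity]]
  if (is.null(keys) || !length(keys)) stop("cavity ", cavity, " is empty")
  keyset <- new.env(hash = TRUE)
  for (k in keys) keyset[[k]] <- TRUE
  vol <- dens <- numeric(0)
  n_sph <- 0L
  for (s in map$sphere_list) {
    if (!nrow(s)) { vol <- c(vol, 0); dens <- c(dens, 0); next }
    vk <- .voxel_key(cbind(s$x, s$y, s$z), map$spacing)
    inc <- vapply(vk$key, function(k) !is.null(keyset[[k]]), logical(1))
    ss <- s[inc, , drop = FALSE]
    n_sph <- n_sph + nrow(ss)
    if (!nrow(ss)) { vol <- c(vol, 0); dens <- c(dens, 0); next }
    vol <- c(vol, .sphere_union_volume(cbind(ss$x, ss$y, ss$z), ss$radius, sub))
    ap <- which(ss$apolar)
    if (!length(ap)) { dens <- c(dens, 0); next }
    cnt <- cpp_overlap_counts(cbind(ss$x, ss$y, ss$z), ss$radius, ss$apolar)
    dens <- c(dens, sum(cnt[ap]) / length(ap))
  }
  se <- function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0
  list(volume_A3 = mean(vol), volume_se = se(vol),
       density = mean(dens), density_se = se(dens),
       n_spheres = n_sph, volume_frames = vol, density_frames = dens)
}

#' Cross-state cavity report relative to a reference state
#'
#' Matches cavities across per-state maps by voxel-set overlap (Jaccard
#' index >= `jaccard_min` with a reference-state cavity) and reports the
#' relative volume change `(V_state - V_ref) / V_ref`, volumes (mean,
#' SE over frames) and hydrophobic densities.  Cavities with no match
#' are listed with `matched = FALSE` rather than dropped.
#'
#' @param maps named list of `CavityMap`, one per macrostate.
#' @param reference_state name/index of the reference state in `maps`.
#' @param jaccard_min voxel-overlap threshold for cavity identity
#'   (default 0.5).
#' @return data.frame: `state`, `cavity`, `ref_cavity`, `matched`,
#'   `volume_A3`, `volume_se`, `rel_volume_change`, `density`,
#'   `density_se`.
#' @export
per_state_cavity_report <- function(maps, reference_state, jaccard_min = 0.5) {
  ref <- maps[[reference_state]]
  if (is.null(ref)) stop("reference state not present")
  ref_names <- names(maps)
  if (is.null(ref_names)) ref_names <- as.character(seq_along(maps))
  ref_metrics <- lapply(seq_along(ref$cavities), function(cv)
    cavity_metrics(ref, cv))
  rows <- list()
  for (si in seq_along(maps)) {
    mp <- maps[[si]]
    for (cv in seq_along(mp$cavities)) {
      met <- cavity_metrics(mp, cv)
      keys <- mp$cavities[[cv]]
      best <- 0; best_ref <- NA_integer_
      for (rc in seq_along(ref$cavities)) {
        rk <- ref$cavities[[rc]]
        jac <- length(intersect(keys, rk)) / length(union(keys, rk))
        if (jac > best) { best <- jac; best_ref <- rc }
      }
      matched <- is.finite(best) && best >= jaccard_min
      rel <- if (matched) {
        vr <- ref_metrics[[best_ref]]$volume_A3
        (met$volume_A3 - vr) / vr
      } else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        state = ref_names[si], cavity = cv,
        ref_cavity = if (matched) best_ref else NA_integer_,
        matched = matched, jaccard = best,
        volume_A3 = met$volume_A3, volume_se = met$volume_se,
        rel_volume_change = rel,
        density = met$density, density_se = met$density_se,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write a cavity frequency grid in OpenDX format
#'
#' @param map a `CavityMap` with retained voxels.
#' @param path output `.dx` path.
#' @return `path`, invisibly.
#' @export
write_cavity_dx <- function(map, path) {
  if (!nrow(map$voxels)) stop("empty cavity map")
  sp <- map$spacing * 10  # nm -> Angstrom for the conventional DX scale
  rx <- range(map$voxels$ix); ry <- range(map$voxels$iy); rz <- range(map$voxels$iz)
  nx <- diff(rx) + 1L; ny <- diff(ry) + 1L; nz <- diff(rz) + 1L
  grid <- array(0, c(nx, ny, nz))
  for (v in seq_len(nrow(map$voxels)))
    grid[map$voxels$ix[v] - rx[1] + 1L, map$voxels$iy[v] - ry[1] + 1L,
         map$voxels$iz[v] - rz[1] + 1L] <- map$voxels$frequency[v]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", nx, ny, nz),
    sprintf("origin %.4f %.4f %.4f", rx[1] * sp, ry[1] * sp, rz[1] * sp),
    sprintf("delta %.4f 0 0", sp),
    sprintf("delta 0 %.4f 0", sp),
    sprintf("delta 0 0 %.4f", sp),
    sprintf("object 2 class gridconnections counts %d %d %d", nx, ny, nz),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            nx * ny * nz)), con)
  # x fastest-varying last per DX convention: loop x, y, z with z fastest
  vals <- as.vector(aperm(grid, c(3, 2, 1)))  # emit with z fastest
  for (i in seq(1, length(vals), by = 3)) {
    writeLines(paste(sprintf("%.4f", vals[i:min(i + 2, length(vals))]),
                     collapse = " "), con)
  }
  writeLines('attribute "dep" string "positions"', con)
  writeLines('object "regular positions regular connections" class field', con)
  invisible(path)
}

#' Write alpha-spheres as a PDB with radii in the B-factor column
#'
#' @param spheres an `AlphaSpheres` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alpha_spheres_pdb <- function(spheres, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(spheres))) {
    writeLines(sprintf(
      "HETATM%5d  O   STP A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           O",
      i %% 100000L, i %% 10000L, spheres$x[i] * 10, spheres$y[i] * 10,
      spheres$z[i] * 10, 1, spheres$radius[i] * 10), con)
  }
  writeLines("END", con)
  invisible(path)
}
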