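# Per-macrostate structural characterization: frame assignment, backbone
# hydrogen bonds under explicit geometric windows, a reduced DSSP-like
# secondary-structure rule built on those same windows, and per-state
# summaries (secondary-structure probabilities, RMSF, radius of gyration,
# descriptor histograms, named distances).

#' Hydrogen-bond geometric criteria
#'
#' A backbone N-H...O=C contact counts as a hydrogen bond when the H...O
#' distance and the N-H...O angle (measured at the hydrogen) fall inside
#' the configured windows.
#'
#' @param d_min,d_max H...O distance window in nm (default 0.15-0.40).
#' @param angle_min,angle_max N-H...O angle window in degrees
#'   (default 100-180).
#' @return list of class `HBondCriteria`.
#' @export
hbond_criteria <- function(d_min = 0.15, d_max = 0.40,
                           angle_min = 100, angle_max = 180) {
  stopifnot(d_min < d_max, angle_min < angle_max)
  structure(list(d_min = d_min, d_max = d_max,
                 angle_min = angle_min, angle_max = angle_max),
            class = "HBondCriteria")
}

#' Assign frames to macrostates
#'
#' Each frame's macrostate is the argmax-membership state of its
#' microstate (ties resolved to the lower index); frames whose microstate
#' is outside the model's active set are `NA` (unassigned).
#'
#' @param model a `MacrostateModel`.
#' @param dtraj integer microstate sequence (1..k).
#' @return integer vector of macrostate labels (1..n_macro) with `NA`
#'   for unassigned frames.
#' @export
assign_macrostates <- function(model, dtraj) {
  k_max <- max(max(dtraj), max(model$active_set))
  lut <- rep(NA_integer_, k_max)
  lut[model$active_set] <- apply(model$memberships, 1, which.max)
  lut[dtraj]
}

# backbone geometry of one frame, with amide hydrogens constructed at
# 0.101 nm along the direction opposing the bisector of N's bonds to
# CA and the preceding C when no H is present in the structure
.backbone_frame <- function(traj, f) {
  co <- frame_coords(traj, f)
  at <- traj$atoms
  res <- residue_ids(traj)
  idx_of <- function(r, nm) {
    i <- which(at$resid == r & at$name == nm)
    if (length(i)) i[1] else NA_integer_
  }
  n <- length(res)
  N <- CA <- C <- O <- H <- matrix(NA_real_, n, 3)
  hasH <- logical(n)
  for (k in seq_len(n)) {
    iN <- idx_of(res[k], "N"); iCA <- idx_of(res[k], "CA")
    iC <- idx_of(res[k], "C"); iO <- idx_of(res[k], "O")
    if (is.na(iN) || is.na(iCA) || is.na(iC))
      stop("data error: residue ", res[k], " has an incomplete backbone")
    N[k, ] <- co[iN, ]; CA[k, ] <- co[iCA, ]; C[k, ] <- co[iC, ]
    if (!is.na(iO)) O[k, ] <- co[iO, ]
    iH <- idx_of(res[k], "H")
    if (!is.na(iH)) { H[k, ] <- co[iH, ]; hasH[k] <- TRUE }
  }
  for (k in 2:n) {
    if (!hasH[k]) {
      u1 <- N[k, ] - CA[k, ]; u1 <- u1 / sqrt(sum(u1^2))
      u2 <- N[k, ] - C[k - 1, ]; u2 <- u2 / sqrt(sum(u2^2))
      d <- u1 + u2
      nrm <- sqrt(sum(d^2))
      if (nrm > 1e-9) H[k, ] <- N[k, ] + 0.101 * d / nrm
    }
  }
  list(res = res, N = N, CA = CA, C = C, O = O, H = H)
}

#' Detect backbone hydrogen bonds in one frame
#'
#' Scans donor amide groups (N-H; the hydrogen is built at ideal geometry
#' when absent) against backbone carbonyl oxygens, excluding the donor's
#' own residue and its predecessor (whose carbonyl is covalently adjacent
#' to the amide).  A bond requires the H...O distance and N-H...O angle
#' to fall inside the [hbond_criteria()] windows.
#'
#' @param traj a [trajectory()].
#' @param frame frame index.
#' @param criteria an [hbond_criteria()].
#' @return data.frame: `donor`, `acceptor` (residue indices), `d_ho` (nm),
#'   `angle` (degrees).
#' @export
detect_hbonds <- function(traj, frame = 1L, criteria = hbond_criteria()) {
  bb <- .backbone_frame(traj, frame)
  n <- length(bb$res)
  out <- list()
  for (di in seq_len(n)) {
    if (any(is.na(bb$H[di, ]))) next
    h <- bb$H[di, ]; nn <- bb$N[di, ]
    for (ai in seq_len(n)) {
      if (ai == di || ai == di - 1L) next
      if (any(is.na(bb$O[ai, ]))) next
      o <- bb$O[ai, ]
      d <- sqrt(sum((h - o)^2))
      if (d < criteria$d_min || d > criteria$d_max) next
      v1 <- nn - h; v2 <- o - h
      ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      if (ang < criteria$angle_min || ang > criteria$angle_max) next
      out[[length(out) + 1L]] <- data.frame(
        donor = bb$res[di], acceptor = bb$res[ai], d_ho = d, angle = ang)
    }
  }
  if (!length(out))
    return(data.frame(donor = integer(0), acceptor = integer(0),
                      d_ho = numeric(0), angle = numeric(0)))
  do.call(rbind, out)
}

#' Assign reduced secondary structure (H / E / C) to one frame
#'
#' A reduced DSSP-like rule built on the same hydrogen-bond windows used
#' throughout: helix (H) for residues covered by at least two consecutive
#' i+4 -> i backbone hydrogen bonds; strand (E) for residues in ladders of
#' at least two adjacent inter-strand bonds (sequence separation >= 5,
#' which excludes helical i+3/i+4 contacts; two bonds are ladder
#' neighbours when both endpoints shift by at most 2 residues); coil (C)
#' otherwise.  Helix takes priority where the patterns overlap.
#'
#' @param traj a [trajectory()].
#' @param frame frame index.
#' @param criteria an [hbond_criteria()].
#' @return character vector (one of "H", "E", "C" per residue), named by
#'   residue index.
#' @export
assign_secondary_structure <- function(traj, frame = 1L,
                                       criteria = hbond_criteria()) {
  hb <- detect_hbonds(traj, frame, criteria)
  res <- residue_ids(traj)
  n <- length(res)
  pos <- match(hb$donor, res); apos <- match(hb$acceptor, res)
  bond <- matrix(FALSE, n, n)  # bond[d, a]: N-H of d donates to O of a
  bond[cbind(pos, apos)] <- TRUE
  ss <- rep("C", n)
  # helix: two consecutive i+4 -> i bonds cover residues i+1 .. i+4
  hstart <- which(vapply(seq_len(n - 5), function(i)
    bond[i + 4, i] && bond[i + 5, i + 1], logical(1)))
  for (i in hstart) ss[(i + 1):(i + 4)] <- "H"
  # strand ladders: inter-strand bonds (separation >= 5) whose rungs are
  # adjacent (both endpoints within 2 residues); components with >= 2
  # rungs mark the span of each contiguous strand segment as E
  ib <- which(bond & abs(row(bond) - col(bond)) >= 5, arr.ind = TRUE)
  if (nrow(ib) >= 2) {
    adj <- matrix(FALSE, nrow(ib), nrow(ib))
    for (a in seq_len(nrow(ib))) for (b in seq_len(nrow(ib))) {
      adj[a, b] <- a != b &&
        ((abs(ib[a, 1] - ib[b, 1]) <= 2 && abs(ib[a, 2] - ib[b, 2]) <= 2) ||
         (abs(ib[a, 1] - ib[b, 2]) <= 2 && abs(ib[a, 2] - ib[b, 1]) <= 2))
    }
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)$membership
    for (cmp in unique(comp)) {
      rungs <- which(comp == cmp)
      if (length(rungs) < 2) next
      resset <- sort(unique(as.vector(ib[rungs, ])))
      # split into strand segments by sequence gaps > 2, fill each span
      brk <- c(0, which(diff(resset) > 2), length(resset))
      for (s in seq_len(length(brk) - 1)) {
        seg <- resset[(brk[s] + 1):brk[s + 1]]
        idx <- seg[1]:seg[length(seg)]
        ss[idx] <- ifelse(ss[idx] == "H", "H", "E")
      }
    }
  }
  names(ss) <- res
  ss
}

#' Per-macrostate structural summaries
#'
#' For every macrostate with at least one assigned frame: per-residue
#' secondary-structure probabilities (closing to 1 with coil), per-atom
#' C-alpha RMSF after superposition onto the reference, mass-weighted
#' radius of gyration (mean, SD), normalized histograms of registry
#' descriptors, and named pair-distance statistics (mean, SD, SE).
#'
#' @param traj a [trajectory()].
#' @param labels per-frame macrostate labels ([assign_macrostates()]);
#'   `NA` frames are excluded and their fraction reported.
#' @param reference reference frame index or `Trajectory` for alignment.
#' @param registry optional list with elements `com_pairs`, `ca_pairs`
#'   (two-column matrices) whose distance distributions are summarised.
#' @param n_bins histogram bin count (default 50).
#' @return object of class `StateSummaryList`: per-state list with
#'   `ss_prob` (residues x H/E/C), `rmsf` (nm), `rg` (mean, sd),
#'   `histograms`, `distances` (mean, sd, se per named pair), `n_frames`;
#'   plus `unassigned_fraction`.
#' @export
per_state_summary <- function(traj, labels, reference = 1L, registry = NULL,
                              n_bins = 50L) {
  stopifnot(length(labels) == n_frames(traj))
  unass <- mean(is.na(labels))
  states <- sort(unique(labels[!is.na(labels)]))
  res <- residue_ids(traj)
  # descriptor features over all frames
  feats <- NULL
  if (!is.null(registry)) {
    fl <- list()
    if (!is.null(registry$com_pairs) && nrow(as.matrix(registry$com_pairs)))
      fl <- c(fl, list(pair_distance_features(traj, registry$com_pairs,
                                              mode = "sidechain-com")))
    if (!is.null(registry$ca_pairs) && nrow(as.matrix(registry$ca_pairs)))
      fl <- c(fl, list(pair_distance_features(traj, registry$ca_pairs,
                                              mode = "calpha")))
    if (length(fl)) feats <- do.call(cbind_features, fl)
  }
  rg_all <- radius_of_gyration(traj)
  out <- list()
  for (st in states) {
    fr <- which(!is.na(labels) & labels == st)
    sub <- trajectory(traj$xyz[fr, , drop = FALSE], traj$atoms,
                      traj$frame_interval_ns)
    ssm <- vapply(seq_along(fr), function(i)
      assign_secondary_structure(sub, i), character(length(res)))
    ssm <- matrix(ssm, nrow = length(res))
    ss_prob <- cbind(H = rowMeans(ssm == "H"), E = rowMeans(ssm == "E"),
                     C = rowMeans(ssm == "C"))
    rownames(ss_prob) <- res
    fit <- superpose_and_rmsf(sub, reference = if (inherits(reference, "Trajectory"))
      reference else trajectory(traj$xyz[reference, , drop = FALSE], traj$atoms))
    hists <- dists <- NULL
    if (!is.null(feats)) {
      V <- feats$values[fr, , drop = FALSE]
      hists <- lapply(seq_len(ncol(V)), function(j) {
        h <- graphics::hist(V[, j], breaks = n_bins, plot = FALSE)
        data.frame(mid = h$mids, density = h$density)
      })
      names(hists) <- colnames(V)
      dists <- data.frame(pair = colnames(V),
                          mean = colMeans(V),
                          sd = apply(V, 2, stats::sd),
                          se = apply(V, 2, stats::sd) / sqrt(nrow(V)))
    }
    out[[as.character(st)]] <- list(
      state = st, n_frames = length(fr), ss_prob = ss_prob,
      rmsf = fit$rmsf, rg = c(mean = mean(rg_all[fr]),
                              sd = stats::sd(rg_all[fr])),
      histograms = hists, distances = dists)
  }
  structure(list(states = out, unassigned_fraction = unass),
            class = "StateSummaryList")
}

#' @export
print.StateSummaryList <- function(x, ...) {
  cat(sprintf("StateSummaryList: %d state(s), %.1f%% frames unassigned\n",
              length(x$states), 100 * x$unassigned_fraction))
  for (s in x$states)
    cat(sprintf("  state %s: %d frames, Rg = %.3f +/- %.3f nm\n",
                s$state, s$n_frames, s$rg["mean"], s$rg["sd"]))
  invisible(x)
}

#' Medoid (most central) frame of a state in descriptor space
#'
#' @param feats a [feature_matrix()] over all frames.
#' @param frames frame indices belonging to the state.
#' @return the frame index of the medoid.
#' @export
medoid_frame <- function(feats, frames) {
  V <- feats$values[frames, , drop = FALSE]
  ctr <- colMeans(V)
  d2 <- rowSums(sweep(V, 2, ctr)^2)
  frames[which.min(d2)]
}
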