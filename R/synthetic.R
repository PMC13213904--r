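# Ground-truth generators: a reversible six-state hidden Markov chain with
# hub-mediated topology and Gaussian feature emissions, plus ideal 3-D
# structure fixtures (helix, hairpin, extended chain, a 78-residue chain
# with side-chain placeholders, a hollow cavity shell), so every pipeline
# stage can be exercised against known answers.

#' Default stationary distribution of the ground-truth chain
#'
#' Two dominant closed states (62% and 24%), a hub intermediate and three
#' open states splitting the remaining 14% as (5, 4, 3, 2)%.
#' @export
default_stationary <- c(S6 = 0.62, S5 = 0.24, S2 = 0.05,
                        S1 = 0.04, S3 = 0.03, S4 = 0.02)

#' Default hub-mediated transition topology
#'
#' The closed pair (S6, S5) exchanges with the hub S2, which connects to
#' all three open states (S1, S3, S4); the open states interconvert via
#' S4.
#' @export
default_topology <- matrix(c("S6", "S5",
                             "S6", "S2",
                             "S5", "S2",
                             "S2", "S1",
                             "S2", "S3",
                             "S2", "S4",
                             "S4", "S1",
                             "S4", "S3"),
                           ncol = 2, byrow = TRUE)

#' Build a reversible ground-truth Markov chain with known stationary law
#'
#' Constructs a per-step transition matrix by detailed balance from
#' symmetric exchange weights on the topology edges
#' (`T_ij = c / pi_i` for edge i-j), so the analytic stationary
#' distribution equals the requested one exactly.  When an MFPT
#' calibration is given, the per-step time unit is rescaled so the
#' analytic source-to-sink mean first-passage time equals the target.
#'
#' @param pi_star named positive vector summing to 1 (default
#'   [default_stationary]).
#' @param topology two-column matrix of state-name edges (default
#'   [default_topology]).
#' @param exchange symmetric edge weight `c` per step (default 1e-4).
#' @param time_per_step_ns physical time per chain step (default 0.1 ns).
#' @param mfpt_calibration optional `list(source=, sink=, target_ns=)`;
#'   rescales `time_per_step_ns` so that MFPT(source -> sink) equals
#'   `target_ns`.
#' @return object of class `GroundTruthChain`: `T`, `pi`, `states`,
#'   `time_per_step_ns`, `topology`, `exchange`.
#' @export
build_ground_truth_chain <- function(pi_star = default_stationary,
                                     topology = default_topology,
                                     exchange = 1e-4,
                                     time_per_step_ns = 0.1,
                                     mfpt_calibration = NULL) {
  if (any(pi_star <= 0) || abs(sum(pi_star) - 1) > 1e-12)
    stop("pi_star must be positive and sum to 1")
  states <- names(pi_star)
  if (is.null(states)) states <- paste0("S", seq_along(pi_star))
  n <- length(states)
  T <- matrix(0, n, n, dimnames = list(states, states))
  for (e in seq_len(nrow(topology))) {
    i <- topology[e, 1]; j <- topology[e, 2]
    if (!(i %in% states) || !(j %in% states))
      stop("topology references unknown state")
    T[i, j] <- T[i, j] + exchange / pi_star[[i]]
    T[j, i] <- T[j, i] + exchange / pi_star[[j]]
  }
  if (any(rowSums(T) >= 1))
    stop("exchange weight too large: negative self-transition probability")
  diag(T) <- 1 - rowSums(T)
  g <- igraph::graph_from_adjacency_matrix((T > 0) * 1, mode = "directed")
  if (igraph::components(g, mode = "strong")$no != 1L)
    stop("topology disconnect: chain is not irreducible")
  if (!is.null(mfpt_calibration)) {
    src <- match(mfpt_calibration$source, states)
    snk <- match(mfpt_calibration$sink, states)
    if (is.na(src) || is.na(snk)) stop("calibration states not found")
    nb <- setdiff(seq_len(n), snk)
    m <- solve(diag(length(nb)) - T[nb, nb, drop = FALSE], rep(1, length(nb)))
    steps <- m[match(src, nb)]
    time_per_step_ns <- mfpt_calibration$target_ns / steps
  }
  structure(list(T = T, pi = pi_star, states = states,
                 time_per_step_ns = unname(time_per_step_ns),
                 topology = topology, exchange = exchange),
            class = "GroundTruthChain")
}

#' @export
print.GroundTruthChain <- function(x, ...) {
  cat(sprintf("GroundTruthChain: %d states (%s), %g ns/step\n",
              length(x$states), paste(x$states, collapse = ", "),
              x$time_per_step_ns))
  invisible(x)
}

#' Analytic mean first-passage time of a ground-truth chain
#'
#' @param chain a `GroundTruthChain`.
#' @param source,sink state names.
#' @return MFPT in ns.
#' @export
chain_mfpt_ns <- function(chain, source, sink) {
  n <- length(chain$states)
  snk <- match(sink, chain$states)
  nb <- setdiff(seq_len(n), snk)
  m <- solve(diag(length(nb)) - chain$T[nb, nb, drop = FALSE],
             rep(1, length(nb)))
  unname(m[match(match(source, chain$states), nb)] * chain$time_per_step_ns)
}

#' Gaussian emission model in descriptor space
#'
#' Per-state mean vectors and diagonal covariance.  By default state `m`
#' is displaced by `separation` standard deviations along descriptor
#' dimension `m`, giving well-separated, distinct state means.
#'
#' @param n_states number of hidden states (default 6).
#' @param n_features descriptor-space dimension (default 18).
#' @param separation displacement of each state mean in SD units
#'   (default 6).
#' @param sd emission standard deviation (scalar or per-feature).
#' @param means optional explicit `n_states x n_features` mean matrix.
#' @return object of class `EmissionModel`.
#' @export
emission_model <- function(n_states = 6, n_features = 18, separation = 6,
                           sd = 1, means = NULL) {
  if (is.null(means)) {
    means <- matrix(0, n_states, n_features)
    for (m in seq_len(n_states)) means[m, ((m - 1) %% n_features) + 1] <- separation
  }
  sd <- rep_len(sd, n_features)
  if (any(sd <= 0)) stop("emission SDs must be positive")
  if (anyDuplicated(as.data.frame(means))) stop("state means must be distinct")
  structure(list(means = means, sd = sd, n_states = n_states,
                 n_features = n_features, separation = separation),
            class = "EmissionModel")
}

#' Sample feature trajectories from the hidden chain
#'
#' Hidden paths are drawn from the chain's transition matrix (initial
#' state from the stationary law) and observations from the per-state
#' Gaussian emissions; hidden labels are returned for recovery scoring.
#' Bit-identical for a fixed seed.
#'
#' @param chain a [build_ground_truth_chain()].
#' @param emissions an [emission_model()].
#' @param n_traj number of trajectories.
#' @param n_steps steps per trajectory (>= 2).
#' @param seed RNG seed.
#' @return list: `features` (list of [feature_matrix()]), `labels`
#'   (list of integer hidden-state vectors, indices into `chain$states`),
#'   `chain`, `emissions`, `seed`.
#' @export
sample_feature_trajectories <- function(chain, emissions, n_traj, n_steps,
                                        seed = 1L) {
  if (n_steps < 2) stop("n_steps must be >= 2")
  if (emissions$n_states != length(chain$states))
    stop("emission model has wrong number of states")
  set.seed(seed)
  feats <- vector("list", n_traj)
  labs <- vector("list", n_traj)
  d <- emissions$n_features
  for (tr in seq_len(n_traj)) {
    init <- sample.int(length(chain$states), 1, prob = chain$pi)
    path <- cpp_sample_chain(chain$T, n_steps, init)
    obs <- emissions$means[path, , drop = FALSE] +
      matrix(stats::rnorm(n_steps * d), n_steps, d) %*% diag(emissions$sd, d)
    colnames(obs) <- sprintf("feat_%02d", seq_len(d))
    feats[[tr]] <- feature_matrix(obs, units = "1",
                                  frame_interval_ns = chain$time_per_step_ns)
    labs[[tr]] <- as.integer(path)
  }
  list(features = feats, labels = labs, chain = chain,
       emissions = emissions, seed = seed)
}

# ---------------------------------------------------------------------
# structure fixtures

# place atom D bonded to C with bond length, angle B-C-D and torsion
# A-B-C-D (degrees); internal-coordinate (NeRF) chain construction
.place_atom <- function(A, B, C, bond, angle, torsion) {
  ang <- angle * pi / 180; tor <- torsion * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  C + bond * (-cos(ang) * bc + sin(ang) * (cos(tor) * m + sin(tor) * n))
}

# build an n-residue backbone (N, CA, C, O per residue, Angstrom) at
# fixed phi/psi; returns list of per-residue coordinate lists
.build_backbone <- function(n_res, phi, psi, omega = 180) {
  phi <- rep_len(phi, n_res); psi <- rep_len(psi, n_res)
  res <- vector("list", n_res)
  N <- c(0, 0, 0)
  CA <- c(1.458, 0, 0)
  ang <- 111.2 * pi / 180
  C <- CA + 1.525 * c(-cos(ang), sin(ang), 0)
  res[[1]] <- list(N = N, CA = CA, C = C)
  for (i in seq_len(n_res - 1)) {
    Np <- .place_atom(res[[i]]$N, res[[i]]$CA, res[[i]]$C, 1.329, 116.2, psi[i])
    CAn <- .place_atom(res[[i]]$CA, res[[i]]$C, Np, 1.458, 121.7, omega)
    Cn <- .place_atom(res[[i]]$C, Np, CAn, 1.525, 111.2, phi[i + 1])
    res[[i + 1]] <- list(N = Np, CA = CAn, C = Cn)
    # carbonyl O of residue i: in the sp2 plane, anti to the next N
    u1 <- res[[i]]$C - res[[i]]$CA; u1 <- u1 / sqrt(sum(u1^2))
    u2 <- res[[i]]$C - Np; u2 <- u2 / sqrt(sum(u2^2))
    d <- u1 + u2
    res[[i]]$O <- res[[i]]$C + 1.231 * d / sqrt(sum(d^2))
  }
  # last O from the psi torsion convention (anti to where next N would be)
  i <- n_res
  res[[i]]$O <- .place_atom(res[[i]]$N, res[[i]]$CA, res[[i]]$C, 1.231,
                            120.8, psi[i] + 180)
  res
}

# CB and simple planar side-chain placeholders; full planar rings for
# aromatic residues so ring-plane descriptors are computable
.sidechain_atoms <- function(bb, resname, chi1 = -65) {
  if (resname == "GLY") return(list())
  CB <- .place_atom(bb$C, bb$N, bb$CA, 1.53, 110.5, 122.7)
  out <- list(CB = CB)
  if (resname %in% c("PHE", "TYR", "TRP", "HIS")) {
    CG <- .place_atom(bb$N, bb$CA, CB, 1.50, 114, chi1)
    out$CG <- CG
    if (resname %in% c("PHE", "TYR")) {
      CD1 <- .place_atom(bb$CA, CB, CG, 1.39, 120, 90)
      CD2 <- .place_atom(bb$CA, CB, CG, 1.39, 120, -90)
      CE1 <- .place_atom(CB, CG, CD1, 1.39, 120, 180)
      CE2 <- .place_atom(CB, CG, CD2, 1.39, 120, 180)
      CZ <- .place_atom(CG, CD1, CE1, 1.39, 120, 0)
      out <- c(out, list(CD1 = CD1, CD2 = CD2, CE1 = CE1, CE2 = CE2, CZ = CZ))
    } else if (resname == "HIS") {
      ND1 <- .place_atom(bb$CA, CB, CG, 1.38, 122, 90)
      CD2 <- .place_atom(bb$CA, CB, CG, 1.36, 131, -90)
      CE1 <- .place_atom(CB, CG, ND1, 1.32, 109, 180)
      NE2 <- .place_atom(CB, CG, CD2, 1.37, 107, 180)
      out <- c(out, list(ND1 = ND1, CD2 = CD2, CE1 = CE1, NE2 = NE2))
    } else {
      CD1 <- .place_atom(bb$CA, CB, CG, 1.37, 127, 90)
      CD2 <- .place_atom(bb$CA, CB, CG, 1.43, 127, -90)
      NE1 <- .place_atom(CB, CG, CD1, 1.38, 110, 180)
      CE2 <- .place_atom(CB, CG, CD2, 1.41, 107, 180)
      CE3 <- .place_atom(CB, CG, CD2, 1.40, 234, 180)
      CZ2 <- .place_atom(CG, CD2, CE2, 1.40, 122, 180)
      CZ3 <- .place_atom(CG, CD2, CE3, 1.39, 119, 180)
      CH2 <- .place_atom(CD2, CE2, CZ2, 1.37, 117, 0)
      out <- c(out, list(CD1 = CD1, CD2 = CD2, NE1 = NE1, CE2 = CE2,
                         CE3 = CE3, CZ2 = CZ2, CZ3 = CZ3, CH2 = CH2))
    }
  }
  out
}

# assemble a Trajectory (nm) from per-residue named atom coordinate lists
.assemble_traj <- function(res_atoms, resnames, resids) {
  rows <- list(); coords <- list()
  for (i in seq_along(res_atoms)) {
    for (nm in names(res_atoms[[i]])) {
      el <- substr(gsub("[0-9]", "", nm), 1, 1)
      rows[[length(rows) + 1L]] <- data.frame(
        name = nm, element = el, resid = resids[i], resname = resnames[i],
        chain = "A", stringsAsFactors = FALSE)
      coords[[length(coords) + 1L]] <- res_atoms[[i]][[nm]]
    }
  }
  atoms <- do.call(rbind, rows)
  xyz <- matrix(unlist(coords), nrow = 1)
  trajectory(xyz / 10, atoms, frame_interval_ns = 1)  # Angstrom -> nm
}

# evenly distributed points on a sphere (Fibonacci lattice)
.fibonacci_sphere <- function(n, R) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  R * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# the fixture sequence: 78 residues numbered 77..154 with aromatic
# anchors at their conventional positions and exactly 43 residues from
# the hydrophobic class
.chain78_sequence <- function() {
  resids <- 77:154
  seqv <- rep("SER", 78)
  names(seqv) <- resids
  seqv[as.character(c(86, 92, 106, 116))] <- "PHE"
  seqv[as.character(134)] <- "TRP"
  seqv[as.character(130)] <- "HIS"
  seqv[as.character(120)] <- "GLY"
  # top up the hydrophobic class to exactly 43 members with leucines
  n_have <- sum(seqv %in% hydrophobic_residues)
  free <- which(seqv == "SER")
  take <- free[seq_len(43 - n_have)]
  seqv[take] <- "LEU"
  seqv
}

#' Build ideal structure fixtures
#'
#' Deterministic toy structures for testing the structure-facing stages:
#' * `helix`: ideal alpha-helix (phi = -57, psi = -47), backbone + O.
#' * `hairpin`: two antiparallel fully-extended strands placed so the
#'   inter-strand amide-carbonyl ladder satisfies the hydrogen-bond
#'   windows, joined by a short non-bonding linker.
#' * `extended`: a single fully extended chain (phi = psi = 180).
#' * `chain78`: a 78-residue chain (residues 77..154) with full backbone,
#'   side-chain placeholders, planar aromatic rings (PHE 86/92/106/116,
#'   TRP 134, HIS 130), one glycine, and exactly 43 hydrophobic-class
#'   residues.
#' * `cavity_shell`: a hollow two-layer carbon shell of inner radius `R`
#'   with deterministic sub-angstrom jitter.
#'
#' @param kind one of `"helix"`, `"hairpin"`, `"extended"`, `"chain78"`,
#'   `"cavity_shell"`.
#' @param n_res residue count for helix/extended (default 16).
#' @param R shell inner radius in nm (default 0.8).
#' @param strand_len residues per hairpin strand (default 6).
#' @return a single-frame [trajectory()].
#' @export
build_structure_fixtures <- function(kind = c("helix", "hairpin", "extended",
                                              "chain78", "cavity_shell"),
                                     n_res = 16, R = 0.8, strand_len = 6) {
  kind <- match.arg(kind)
  if (kind == "helix" || kind == "extended") {
    ang <- if (kind == "helix") c(-57, -47) else c(180, 180)
    bb <- .build_backbone(n_res, ang[1], ang[2])
    return(.assemble_traj(bb, rep("ALA", n_res), seq_len(n_res)))
  }
  if (kind == "hairpin") {
    # strands at (-165, 164): an (almost exactly) untwisted two-residue
    # repeat, so the antiparallel partner is a rigid two-fold image.
    # The partner is rotated 180 degrees about the sheet normal through
    # the strand centroid and shifted across the ladder; the shift
    # coefficients place the amide-carbonyl rungs at canonical hydrogen-
    # bond geometry (H...O ~ 0.25 nm, angles ~ 155-175 degrees).
    n <- strand_len
    bb1 <- .build_backbone(n, -165, 164)
    ca1 <- t(vapply(bb1, function(r) r$CA, numeric(3)))
    sdir <- ca1[n, ] - ca1[1, ]; sdir <- sdir / sqrt(sum(sdir^2))
    u1 <- bb1[[2]]$N - bb1[[2]]$CA; u1 <- u1 / sqrt(sum(u1^2))
    u2 <- bb1[[2]]$N - bb1[[1]]$C; u2 <- u2 / sqrt(sum(u2^2))
    h <- u1 + u2; h <- h - sum(h * sdir) * sdir
    side <- h / sqrt(sum(h^2))
    w <- c(sdir[2] * side[3] - sdir[3] * side[2],
           sdir[3] * side[1] - sdir[1] * side[3],
           sdir[1] * side[2] - sdir[2] * side[1])
    w <- w / sqrt(sum(w^2))
    ctr <- colMeans(ca1)
    shift <- 2.1 * side - 0.2 * w
    flip <- function(p) {
      v <- p - ctr
      2 * sum(v * w) * w - v + ctr + shift
    }
    bb2 <- lapply(bb1, function(r) lapply(r, flip))
    allres <- c(bb1, bb2)
    return(.assemble_traj(allres, rep("ALA", 2 * n), seq_len(2 * n)))
  }
  if (kind == "chain78") {
    seqv <- .chain78_sequence()
    n <- length(seqv)
    # gently curved extended-like conformation
    bb <- .build_backbone(n, -120, 130)
    res_atoms <- vector("list", n)
    for (i in seq_len(n)) {
      res_atoms[[i]] <- c(bb[[i]][c("N", "CA", "C", "O")],
                          .sidechain_atoms(bb[[i]], seqv[i]))
    }
    return(.assemble_traj(res_atoms, unname(seqv), as.integer(names(seqv))))
  }
  # cavity_shell: two concentric jittered Fibonacci layers (Angstrom work
  # units, converted on assembly)
  # lateral spacing 3.3 A with a 6 A layer gap keeps the wall tetrahedra's
  # circumspheres inside the default probe window at any shell radius
  spacing <- 3.3
  Ra <- R * 10
  layers <- list(Ra, Ra + 6)
  pts <- do.call(rbind, lapply(layers, function(rr) {
    n_pts <- max(12L, round(4 * pi * rr^2 / spacing^2))
    .fibonacci_sphere(n_pts, rr)
  }))
  jit <- ((seq_len(3 * nrow(pts)) * 1103515245) %% 89) / 88 - 0.5
  pts <- pts + matrix(jit, nrow(pts), 3) * 0.4
  res_atoms <- lapply(seq_len(nrow(pts)), function(i) {
    out <- list(pts[i, ]); names(out) <- "C"; out
  })
  .assemble_traj(res_atoms, rep("SHL", nrow(pts)), seq_len(nrow(pts)))
}
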