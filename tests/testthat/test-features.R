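test_that("exhaustive pair enumeration reproduces the printed feature counts", {
  traj <- chain78_fixture()
  expect_length(residue_ids(traj), 78L)
  all_com <- pair_distance_features(traj, mode = "sidechain-com")
  expect_equal(ncol(all_com$values), 3003L)          # C(78, 2)
  hydro <- pair_distance_features(traj, mode = "sidechain-com",
                                  selection = hydrophobic_residues)
  expect_equal(ncol(hydro$values), 903L)             # C(43, 2)
  rn <- traj$atoms$resname[match(residue_ids(traj), traj$atoms$resid)]
  expect_equal(sum(rn %in% hydrophobic_residues), 43L)
  tor <- backbone_torsion_features(traj)
  expect_equal(ncol(tor$values), 4L * 77L)           # 308
})

test_that("COM distances: direct value, symmetry, glycine fallback", {
  # two single-atom side chains at 1.2 nm separation
  at <- data.frame(name = c("N", "CA", "C", "CB", "N", "CA", "C", "CB"),
                   element = c("N", "C", "C", "C", "N", "C", "C", "C"),
                   resid = rep(1:2, each = 4), resname = "ALA", chain = "A")
  co <- rbind(c(0, 1, 0), c(0, 2, 0), c(0, 3, 0), c(0, 0, 0),
              c(5, 1, 0), c(5, 2, 0), c(5, 3, 0), c(0, 0, 1.2))
  tr <- trajectory(matrix(as.vector(t(co)), 1), at)
  d <- pair_distance_features(tr, pairs = cbind(1, 2), mode = "sidechain-com")
  expect_equal(unname(d$values[1, 1]), 1.2, tolerance = 1e-12)
  d21 <- pair_distance_features(tr, pairs = cbind(2, 1), mode = "sidechain-com")
  expect_equal(unname(d21$values[1, 1]), unname(d$values[1, 1]))
  # glycine COM equals its CA
  at$resname <- c(rep("GLY", 4), rep("ALA", 4))
  at$name[4] <- "O"  # GLY has no side-chain heavy atom
  tr2 <- trajectory(tr$xyz, at)
  com <- kinscape:::.sidechain_com(tr2, 1)
  expect_equal(as.vector(com), c(0, 2, 0))
  # duplicate and degenerate pairs rejected
  expect_error(pair_distance_features(tr, pairs = rbind(c(1, 2), c(2, 1))),
               "duplicate")
  expect_error(pair_distance_features(tr, pairs = cbind(1, 1)), "equal")
})

test_that("backbone torsions match an independent oracle and ideal geometry", {
  traj <- chain78_fixture()
  tor <- backbone_torsion_features(traj)
  co <- frame_coords(traj, 1)
  at <- traj$atoms
  res <- residue_ids(traj)
  pick <- function(r, nm) co[which(at$resid == r & at$name == nm)[1], ]
  set.seed(5)
  for (i in sample(2:77, 8)) {
    phi_o <- dihedral_oracle(pick(res[i - 1], "C"), pick(res[i], "N"),
                             pick(res[i], "CA"), pick(res[i], "C"))
    got <- atan2(tor$values[1, sprintf("phi_sin_%d", res[i])],
                 tor$values[1, sprintf("phi_cos_%d", res[i])]) * 180 / pi
    expect_equal(unname(got), phi_o, tolerance = 1e-9)
  }
  # ideal trans geometry: psi = 180 -> (cos, sin) = (-1, 0)
  ext <- build_structure_fixtures("extended", n_res = 5)
  tex <- backbone_torsion_features(ext)
  expect_equal(unname(tex$values[1, "psi_cos_2"]), -1, tolerance = 1e-9)
  expect_equal(unname(tex$values[1, "psi_sin_2"]), 0, tolerance = 1e-9)
})

test_that("angular descriptors: limiting cases and rigid-motion invariance", {
  traj <- chain78_fixture()
  ang <- angular_descriptors(traj, quads = rbind(c(86, 96, 129, 119)),
                             ring_pairs = rbind(c(92, 134)))
  expect_true(all(ang$values[, 1] > -180 & ang$values[, 1] <= 180))
  expect_true(ang$values[, 2] >= 0 && ang$values[, 2] <= 90)
  set.seed(17)
  for (rep in 1:3) {
    moved <- apply_rigid(traj, random_rigid())
    ang2 <- angular_descriptors(moved, quads = rbind(c(86, 96, 129, 119)),
                                ring_pairs = rbind(c(92, 134)))
    expect_equal(ang2$values, ang$values, tolerance = 1e-9)
  }
  # mirror reflection flips the dihedral sign
  mir <- traj
  mir$xyz[, seq(1, ncol(mir$xyz), by = 3)] <- -mir$xyz[, seq(1, ncol(mir$xyz), by = 3)]
  angm <- angular_descriptors(mir, quads = rbind(c(86, 96, 129, 119)))
  expect_equal(unname(angm$values[, 1]), -unname(ang$values[, 1]),
               tolerance = 1e-9)
  # planar cis quadruple -> 0; coplanar rings -> 0; orthogonal rings -> 90
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  expect_equal(dihedral_oracle(sq[1, ], sq[2, ], sq[3, ], sq[4, ]), 0,
               tolerance = 1e-9)
  hexagon <- function(ctr, normal_axis) {
    th <- seq(0, 2 * pi, length.out = 7)[-7]
    ring <- cbind(cos(th), sin(th), 0)
    if (normal_axis == "x") ring <- ring[, c(3, 1, 2)]
    sweep(ring, 2, ctr, "+")
  }
  n1 <- kinscape:::.plane_normal(hexagon(c(0, 0, 0), "z"))
  n2 <- kinscape:::.plane_normal(hexagon(c(5, 0, 0), "z"))
  n3 <- kinscape:::.plane_normal(hexagon(c(0, 5, 0), "x"))
  expect_equal(acos(abs(sum(n1 * n2))) * 180 / pi, 0, tolerance = 1e-9)
  expect_equal(acos(abs(sum(n1 * n3))) * 180 / pi, 90, tolerance = 1e-9)
})

test_that("superposition: RMSD/RMSF limiting cases and alignment optimality", {
  traj <- helix_fixture()
  # identical frames: all zero
  x3 <- rbind(traj$xyz, traj$xyz, traj$xyz)
  t3 <- trajectory(x3, traj$atoms)
  fit <- superpose_and_rmsf(t3, reference = 1L)
  expect_true(all(fit$rmsd < 1e-9))
  expect_true(all(fit$rmsf < 1e-9))
  # rigidly moved copy: RMSD ~ 0 after superposition
  set.seed(23)
  moved <- apply_rigid(traj, random_rigid())
  pair <- trajectory(rbind(traj$xyz, moved$xyz), traj$atoms)
  fit2 <- superpose_and_rmsf(pair, reference = 1L)
  expect_lt(fit2$rmsd[2], 1e-9)
  # superposition never increases RMSD relative to the unaligned frames
  raw <- sqrt(mean((moved$xyz[1, ] - traj$xyz[1, ])^2) * 3)
  expect_lte(fit2$rmsd[2], raw + 1e-12)
  # hand-computed RMSF: one atom at +/- 0.1 nm about its mean (many fit
  # atoms, so the superposition barely redistributes the perturbation)
  big <- chain78_fixture()
  ca <- which(big$atoms$name == "CA")
  xa <- big$xyz
  xb <- big$xyz
  col <- 3 * ca[5] - 2
  xa[col] <- xa[col] + 0.1
  xb[col] <- xb[col] - 0.1
  t2 <- trajectory(rbind(xa, xb), big$atoms)
  f <- superpose_and_rmsf(t2, reference = 1L, atom_selection = ca)
  # refitting redistributes ~1/n of the displacement across the selection
  expect_equal(f$rmsf[5], 0.1, tolerance = 0.05)
  expect_error(superpose_and_rmsf(traj, atom_selection = ca[1:2]), "3 atoms")
})

test_that("radius of gyration matches the two-point-mass hand calculation", {
  at <- data.frame(name = c("CB", "CB"), element = c("C", "C"),
                   resid = 1:2, resname = "ALA", chain = "A")
  tr <- trajectory(matrix(c(0, 0, 0, 2, 0, 0), 1), at)
  expect_equal(radius_of_gyration(tr), 1)
})
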