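regular_tetrahedron <- function(circumradius) {
  pts <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  pts / sqrt(3) * circumradius
}

test_that("alpha-spheres: closed-form circumsphere, bounds, apolar rule", {
  pts <- regular_tetrahedron(0.45)
  s <- compute_alpha_spheres(pts, r_min = 0.30, r_max = 0.60)
  expect_equal(nrow(s), 1L)
  expect_equal(unname(unlist(s[1, c("x", "y", "z")])), c(0, 0, 0),
               tolerance = 1e-9)
  expect_equal(s$radius, 0.45, tolerance = 1e-9)
  expect_true(s$apolar)  # all four contacts default to carbon
  # radius outside bounds is filtered
  expect_equal(nrow(compute_alpha_spheres(regular_tetrahedron(0.7),
                                          r_min = 0.3, r_max = 0.6)), 0L)
  expect_equal(nrow(compute_alpha_spheres(regular_tetrahedron(0.2),
                                          r_min = 0.3, r_max = 0.6)), 0L)
  # apolar flag false when two contacts are polar
  s2 <- compute_alpha_spheres(regular_tetrahedron(0.45),
                              elements = c("N", "O", "C", "C"))
  expect_false(s2$apolar)
  s3 <- compute_alpha_spheres(regular_tetrahedron(0.45),
                              elements = c("C", "S", "C", "N"))
  expect_true(s3$apolar)  # 3 of 4 carbon/sulfur
  expect_error(compute_alpha_spheres(pts[1:3, ]), "4")
})

test_that("the alpha-sphere set is invariant under rigid motion", {
  sh <- build_structure_fixtures("cavity_shell", R = 0.7)
  s0 <- compute_alpha_spheres(sh)
  set.seed(109)
  rig <- random_rigid()
  moved <- apply_rigid(sh, rig)
  s1 <- compute_alpha_spheres(moved)
  expect_equal(nrow(s1), nrow(s0))
  expect_equal(sort(s1$radius), sort(s0$radius), tolerance = 1e-6)
})

test_that("frequency grid applies the isovalue and splits disjoint clusters", {
  mk_spheres <- function(centers) {
    data.frame(x = centers[, 1], y = centers[, 2], z = centers[, 3],
               radius = 0.35, a1 = 1L, a2 = 2L, a3 = 3L, a4 = 4L,
               apolar = TRUE)
  }
  # two centres in one 0.2 nm cube: retained at isovalue 2
  two <- mk_spheres(rbind(c(0.05, 0.05, 0.05), c(0.15, 0.12, 0.08)))
  m <- pocket_frequency_grid(list(two), spacing = 0.2, isovalue = 2)
  expect_equal(nrow(m$voxels), 1L)
  expect_equal(m$voxels$frequency, 2)
  # one centre per cube: nothing retained
  one <- mk_spheres(rbind(c(0.05, 0.05, 0.05), c(0.95, 0.95, 0.95)))
  m1 <- pocket_frequency_grid(list(one), spacing = 0.2, isovalue = 2)
  expect_equal(nrow(m1$voxels), 0L)
  # two clusters separated by more than two voxels: two cavities
  far <- rbind(c(0.05, 0.05, 0.05), c(0.15, 0.12, 0.08),
               c(2.05, 0.05, 0.05), c(2.15, 0.12, 0.08))
  m2 <- pocket_frequency_grid(list(mk_spheres(far)), spacing = 0.2,
                              isovalue = 2)
  expect_equal(length(m2$cavities), 2L)
  # per-frame averaging: a voxel hit twice in one of two frames -> mean 1
  m3 <- pocket_frequency_grid(list(two, mk_spheres(rbind(c(5, 5, 5)))),
                              spacing = 0.2, isovalue = 2)
  expect_equal(nrow(m3$voxels), 0L)
})

test_that("cavity volume matches analytic sphere and two-sphere unions", {
  v1 <- kinscape:::.sphere_union_volume(rbind(c(0, 0, 0)), 0.4)
  expect_equal(v1, 4 / 3 * pi * 0.4^3 * 1000, tolerance = 0.02)
  # two equal spheres, centre distance d: union = 2V - lens overlap
  r <- 0.35; d <- 0.3
  v_int <- pi / 12 * (4 * r + d) * (2 * r - d)^2  # spherical-lens overlap
  v2 <- kinscape:::.sphere_union_volume(rbind(c(0, 0, 0), c(d, 0, 0)),
                                        c(r, r))
  expect_equal(v2, 2 * (4 / 3 * pi * r^3) * 1000 - v_int * 1000,
               tolerance = 0.02)
  # volume monotone under radius growth
  v3 <- kinscape:::.sphere_union_volume(rbind(c(0, 0, 0), c(d, 0, 0)),
                                        c(r * 1.1, r * 1.1))
  expect_gt(v3, v2)
})

test_that("mean local hydrophobic density follows the closed forms", {
  # n mutually overlapping all-apolar spheres: density n - 1
  n <- 5
  centers <- matrix(rnorm(3 * n, sd = 0.02), n, 3) + 0.1
  sph <- data.frame(x = centers[, 1], y = centers[, 2], z = centers[, 3],
                    radius = 0.4, a1 = 1L, a2 = 2L, a3 = 3L, a4 = 4L,
                    apolar = TRUE)
  m <- pocket_frequency_grid(list(sph), spacing = 0.2, isovalue = 2)
  met <- cavity_metrics(m, 1)
  expect_equal(met$density, n - 1)
  # zero apolar spheres: density 0
  sph$apolar <- FALSE
  m0 <- pocket_frequency_grid(list(sph), spacing = 0.2, isovalue = 2)
  expect_equal(cavity_metrics(m0, 1)$density, 0)
})

test_that("the hollow shell yields interior spheres and R-monotone cavities", {
  vols <- c()
  for (R in c(0.6, 0.8, 1.0)) {
    sh <- build_structure_fixtures("cavity_shell", R = R)
    sp <- compute_alpha_spheres(sh)
    expect_gt(nrow(sp), 0)
    rad <- sqrt(sp$x^2 + sp$y^2 + sp$z^2)
    if (R == 0.8) expect_gt(sum(rad < R), 0)  # interior alpha-sphere
    m <- pocket_frequency_grid(list(sp))
    expect_gte(length(m$cavities), 1L)
    big <- which.max(vapply(m$cavities, length, numeric(1)))
    vols <- c(vols, cavity_metrics(m, big)$volume_A3)
  }
  expect_true(all(diff(vols) > 0))  # cavity volume grows with R
})

test_that("the cross-state cavity report matches cavities and flags changes", {
  sh <- build_structure_fixtures("cavity_shell", R = 0.8)
  sp <- compute_alpha_spheres(sh)
  map_ref <- pocket_frequency_grid(list(sp))
  maps <- list(S6 = map_ref, S1 = map_ref)
  rep0 <- per_state_cavity_report(maps, reference_state = "S6")
  expect_true(all(abs(rep0$rel_volume_change[rep0$matched]) < 1e-12))
  expect_true(all(c("volume_se", "density_se") %in% names(rep0)))
  # enlarged ensemble: positive relative volume change
  sp_big <- sp
  sp_big$radius <- pmin(sp_big$radius * 1.2, 0.6)
  map_big <- pocket_frequency_grid(list(sp_big))
  rep1 <- per_state_cavity_report(list(S6 = map_ref, S1 = map_big), "S6")
  open_rows <- rep1[rep1$state == "S1" & rep1$matched, ]
  expect_gt(nrow(open_rows), 0)
  expect_true(any(open_rows$rel_volume_change > 0))
})

test_that("grid and sphere exports are well-formed text files", {
  sh <- build_structure_fixtures("cavity_shell", R = 0.8)
  sp <- compute_alpha_spheres(sh)
  m <- pocket_frequency_grid(list(sp))
  dx <- withr::local_tempfile(fileext = ".dx")
  write_cavity_dx(m, dx)
  lines <- readLines(dx)
  expect_match(lines[1], "gridpositions")
  counts <- as.integer(strsplit(lines[1], " +")[[1]][6:8])
  n_items <- as.integer(sub(".*items (\\d+) .*", "\\1", lines[7]))
  expect_equal(prod(counts), n_items)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_alpha_spheres_pdb(sp, pdb)
  expect_equal(sum(grepl("^HETATM", readLines(pdb))), nrow(sp))
})
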