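# Shared fixtures, built once per test run.

fixture_cache <- new.env()

get_fixture <- function(name, builder) {
  if (is.null(fixture_cache[[name]])) fixture_cache[[name]] <- builder()
  fixture_cache[[name]]
}

chain78_fixture <- function() get_fixture("chain78", function()
  build_structure_fixtures("chain78"))

helix_fixture <- function() get_fixture("helix", function()
  build_structure_fixtures("helix", n_res = 12))

hairpin_fixture <- function() get_fixture("hairpin", function()
  build_structure_fixtures("hairpin"))

# independent dihedral oracle: angle between the projections of the outer
# bonds onto the plane normal to the central bond (two-vector atan2 form)
dihedral_oracle <- function(p1, p2, p3, p4) {
  b2 <- p3 - p2
  b2 <- b2 / sqrt(sum(b2^2))
  u <- (p1 - p2) - sum((p1 - p2) * b2) * b2
  w <- (p4 - p3) - sum((p4 - p3) * b2) * b2
  x <- sum(u * w)
  y <- sum(crossprod_vec(b2, u) * w)
  atan2(y, x) * 180 / pi
}

crossprod_vec <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# random rigid transform (proper rotation + translation), seeded by caller
random_rigid <- function() {
  A <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(A)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = stats::rnorm(3, sd = 2))
}

apply_rigid <- function(traj, rigid) {
  nfr <- n_frames(traj)
  xyz <- traj$xyz
  for (f in seq_len(nfr)) {
    co <- frame_coords(traj, f) %*% t(rigid$R)
    co <- sweep(co, 2, -rigid$t)
    xyz[f, ] <- as.vector(t(co))
  }
  trajectory(xyz, traj$atoms, traj$frame_interval_ns)
}

# simple 2-state metastable chain used across statistical tests
two_state_T <- function(p = 0.05) {
  matrix(c(1 - p, p, p, 1 - p), 2, 2, byrow = TRUE)
}

# a seeded medium-size generator recovery, shared by the acceptance tests
recovery_fixture <- function() get_fixture("recovery", function() {
  chain <- build_ground_truth_chain()
  em <- emission_model()
  sim <- sample_feature_trajectories(chain, em, n_traj = 10,
                                     n_steps = 60000, seed = 101)
  fit <- estimate_pipeline(sim$features, n_micro = 100, n_macro = NULL,
                           lag_frames = 10, seed = 202, n_samples = 30)
  mt <- match_macrostates(fit, sim$labels)
  list(chain = chain, em = em, sim = sim, fit = fit, match = mt)
})
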