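test_that("TICA: white noise has no slow modes, metastable signal is recovered", {
  set.seed(31)
  X <- matrix(rnorm(20000 * 5), ncol = 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  tm <- estimate_tica(feature_matrix(X), lag_ns = 1)
  expect_true(all(abs(tm$eigenvalues) < 3 / sqrt(nrow(X) - 1)))
  expect_true(all(abs(tm$eigenvalues) <= 1 + 1e-12))
  # 2-state chain with p = 0.05: relaxation time -1/log(0.9) = 9.49 steps
  p <- 0.05
  path <- kinscape:::cpp_sample_chain(two_state_T(p), 300000, 1)
  sig <- ifelse(path == 1, 1, -1) + rnorm(length(path), sd = 0.1)
  Y <- cbind(sig = sig, noise = rnorm(length(path)))
  tm2 <- estimate_tica(feature_matrix(Y), lag_ns = 2)
  t_true <- -1 / log(1 - 2 * p)
  expect_equal(tm2$timescales_ns[1], t_true, tolerance = 0.15)
  # IC projections uncorrelated at lag 0 under the training weighting
  # (the symmetrized covariance averages the two lag-shifted segments)
  P <- project_tica(tm2, Y)
  lagf <- 2
  n <- nrow(P)
  D <- rbind(P[1:(n - lagf), ], P[(1 + lagf):n, ])
  expect_lt(abs(stats::cor(D[, 1], D[, 2])), 1e-6)
  # duplicated column leaves leading eigenvalue unchanged under the ridge
  Y2 <- cbind(Y, sig2 = Y[, 1])
  tm3 <- estimate_tica(feature_matrix(Y2), lag_ns = 2, ridge = 1e-6)
  tm2r <- estimate_tica(feature_matrix(Y), lag_ns = 2, ridge = 1e-6)
  expect_equal(tm3$eigenvalues[1], tm2r$eigenvalues[1], tolerance = 1e-6)
  # lag >= trajectory length errors
  expect_error(estimate_tica(feature_matrix(Y[1:10, ]), lag_ns = 20), "lag")
})

test_that("feature-IC correlations and threshold flags behave as specified", {
  set.seed(37)
  path <- kinscape:::cpp_sample_chain(two_state_T(0.05), 10000, 1)
  s <- ifelse(path == 1, 1, -1)
  X <- cbind(a = s + rnorm(10000, sd = 0.05), b = rnorm(10000))
  tm <- estimate_tica(feature_matrix(X), lag_ns = 1, dim = 2)
  ic1 <- project_tica(tm, X)[, 1]
  X2 <- cbind(X, ic_copy = ic1)
  tab <- feature_ic_correlation(tm, feature_matrix(X2), n_ics = 1)
  expect_equal(unname(abs(tab$cor["ic_copy", 1])), 1, tolerance = 1e-9)
  expect_lt(abs(tab$cor["b", 1]), 0.1)  # independent feature
  expect_true(tab$candidate["ic_copy"])
  expect_true(tab$strong["ic_copy"])
  expect_false(tab$candidate["b"])
  # |r| = 0.5: candidate but not strong; strong implies candidate
  fake <- tab
  expect_true(0.5 >= tab$candidate_threshold && 0.5 < tab$strong_threshold)
  expect_true(all(!tab$strong | tab$candidate))
  # constant feature warns and gets correlation 0
  X3 <- cbind(X, const = rep(1, nrow(X)))
  expect_warning(t3 <- feature_ic_correlation(tm, feature_matrix(X3), n_ics = 1),
                 "constant")
  expect_equal(unname(t3$cor["const", 1]), 0)
})

test_that("redundancy/locality pruning matches a brute-force oracle and is idempotent", {
  # stated rules on tiny cases
  sel <- prune_redundancy_locality(
    data.frame(i = c(10, 11), j = c(40, 40), score = c(0.8, 0.6)),
    res_range = c(1, 80))
  expect_equal(nrow(sel$retained), 1L)
  expect_equal(sel$retained$i, 10)
  sel2 <- prune_redundancy_locality(
    data.frame(i = 5, j = 7, score = 0.9), res_range = c(1, 80))
  expect_equal(nrow(sel2$retained), 0L)
  expect_equal(sel2$removed$reason, "near-diagonal")
  # brute-force oracle on random candidate sets
  brute <- function(cand, lo, hi, margin = 3, near = 4, half = 1) {
    ii <- pmin(cand$i, cand$j); jj <- pmax(cand$i, cand$j)
    cand$i <- ii; cand$j <- jj
    cand <- cand[!(cand$i < lo + margin | cand$j > hi - margin |
                     (cand$j - cand$i) <= near), , drop = FALSE]
    cand <- cand[order(-abs(cand$score), cand$i, cand$j), , drop = FALSE]
    kept <- cand[0, ]
    for (r in seq_len(nrow(cand))) {
      ok <- TRUE
      for (q in seq_len(nrow(kept))) {
        if (abs(kept$i[q] - cand$i[r]) <= half &&
            abs(kept$j[q] - cand$j[r]) <= half) { ok <- FALSE; break }
      }
      if (ok) kept <- rbind(kept, cand[r, ])
    }
    kept
  }
  set.seed(41)
  for (rep in 1:5) {
    cand <- data.frame(i = sample(1:60, 20, TRUE), j = sample(1:60, 20, TRUE),
                       score = round(runif(20, -1, 1), 3))
    cand <- cand[cand$i != cand$j, ]
    got <- prune_redundancy_locality(cand, res_range = c(1, 60))
    want <- brute(cand, 1, 60)
    expect_equal(got$retained[, c("i", "j", "score")], want[, c("i", "j", "score")],
                 ignore_attr = TRUE)
    # idempotence
    again <- prune_redundancy_locality(got$retained, res_range = c(1, 60))
    expect_equal(again$retained[, c("i", "j")], got$retained[, c("i", "j")],
                 ignore_attr = TRUE)
  }
  # empty input allowed
  e <- prune_redundancy_locality(data.frame(i = integer(0), j = integer(0),
                                            score = numeric(0)),
                                 res_range = c(1, 60))
  expect_equal(nrow(e$retained), 0L)
})

test_that("VAMP-2 score: analytic 2-state value, nesting, and the noise floor", {
  set.seed(43)
  p <- 0.1
  lam <- 1 - 2 * p
  path <- kinscape:::cpp_sample_chain(two_state_T(p), 200000, 1)
  X <- cbind(s1 = as.numeric(path == 1), s2 = as.numeric(path == 2))
  fm <- feature_matrix(X)
  sc <- vamp2_score(fm, lag_ns = 1, dim = 2)
  expect_equal(sc, 1 + lam^2, tolerance = 0.02)
  # nesting: score at dim k <= score at dim k+1
  Y <- cbind(X, n1 = rnorm(nrow(X)), n2 = rnorm(nrow(X)))
  fy <- feature_matrix(Y)
  s2 <- vamp2_score(fy, 1, dim = 2)
  s3 <- vamp2_score(fy, 1, dim = 3)
  s4 <- vamp2_score(fy, 1, dim = 4)
  expect_lte(s2, s3 + 1e-12)
  expect_lte(s3, s4 + 1e-12)
  # pure noise: score ~ 1
  N <- feature_matrix(matrix(rnorm(50000 * 3), ncol = 3))
  expect_equal(vamp2_score(N, 1, dim = 3), 1, tolerance = 0.01)
  expect_gte(vamp2_score(N, 1), 1)
})

test_that("a curated slow-feature subset retains the exhaustive VAMP-2 score", {
  chain <- build_ground_truth_chain()
  em <- emission_model()
  sim <- sample_feature_trajectories(chain, em, n_traj = 2, n_steps = 30000,
                                     seed = 47)
  full <- vamp2_score(sim$features, lag_ns = 1, dim = 6)
  curated <- lapply(sim$features, function(f)
    feature_matrix(f$values[, 1:6], frame_interval_ns = f$frame_interval_ns))
  sub <- vamp2_score(curated, lag_ns = 1, dim = 6)
  expect_gte(sub, 0.9 * full)
})
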