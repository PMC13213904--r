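test_that("k-means discretization is seeded, exact at k = n, and finds blobs", {
  set.seed(51)
  X <- rbind(matrix(rnorm(2000, mean = 0, sd = 0.3), ncol = 2),
             matrix(rnorm(2000, mean = 5, sd = 0.3), ncol = 2))
  d1 <- cluster_kmeans(X, k = 2, seed = 9)
  d2 <- cluster_kmeans(X, k = 2, seed = 9)
  expect_identical(d1$dtrajs, d2$dtrajs)
  mu <- d1$centers[order(d1$centers[, 1]), ]
  se <- 0.3 / sqrt(1000)
  expect_true(all(abs(mu[1, ] - 0) < 3 * se))
  expect_true(all(abs(mu[2, ] - 5) < 3 * se))
  # k equal to the number of distinct points: zero inertia
  P <- matrix(c(0, 0, 1, 0, 0, 1), ncol = 2, byrow = TRUE)
  dp <- cluster_kmeans(P, k = 3, seed = 1)
  expect_equal(dp$inertia, 0)
  expect_error(cluster_kmeans(P, k = 4, seed = 1), "distinct")
})

test_that("transition counting matches hand enumeration and trims properly", {
  d <- c(1L, 2L, 1L, 2L, 1L)
  c1 <- count_transitions(list(d), lag_frames = 1)
  expect_equal(c1$C[1, 2], 2)
  expect_equal(c1$C[2, 1], 2)
  expect_equal(sum(c1$C), 4)
  c2 <- count_transitions(list(d), lag_frames = 2)
  expect_equal(c2$C[1, 1], 2)
  expect_equal(c2$C[2, 2], 1)
  # strided counting uses disjoint windows
  c3 <- count_transitions(list(d), lag_frames = 2, mode = "strided")
  expect_equal(sum(c3$C), 2)
  # a state visited once with no return leaves the active set under trim
  d4 <- c(1L, 2L, 1L, 2L, 3L)
  c4 <- count_transitions(list(d4), lag_frames = 1, trim = TRUE)
  expect_equal(sort(c4$active_set), c(1L, 2L))
  expect_error(count_transitions(list(1:3), lag_frames = 5), "lag")
})

test_that("reversible MLE: closed form for symmetric counts, oracle otherwise", {
  Cs <- matrix(c(10, 4, 4, 6), 2, 2)
  ms <- estimate_reversible(Cs)
  expect_equal(ms$T, Cs / rowSums(Cs), tolerance = 1e-12, ignore_attr = TRUE)
  # independent oracle: direct likelihood maximization over symmetric
  # edge weights (log-parameterized, Nelder-Mead to convergence)
  C <- matrix(c(8, 2, 1, 9), 2, 2, byrow = TRUE)
  nll <- function(lx) {
    x <- matrix(0, 2, 2)
    x[upper.tri(x, diag = TRUE)] <- exp(lx)
    x[lower.tri(x)] <- t(x)[lower.tri(x)]
    Tm <- x / rowSums(x)
    -sum(C * log(Tm))
  }
  opt <- stats::optim(log(c(8, 1.5, 9)), nll, method = "Nelder-Mead",
                      control = list(maxit = 20000, reltol = 1e-14))
  x <- matrix(0, 2, 2)
  x[upper.tri(x, diag = TRUE)] <- exp(opt$par)
  x[lower.tri(x)] <- t(x)[lower.tri(x)]
  T_oracle <- x / rowSums(x)
  m <- estimate_reversible(C)
  expect_equal(m$T, T_oracle, tolerance = 1e-6, ignore_attr = TRUE)
  # detailed balance residual below estimator tolerance
  F <- m$pi * m$T
  expect_lt(max(abs(F - t(F))), 1e-8)
  expect_equal(sum(m$pi %*% m$T - m$pi), 0, tolerance = 1e-8)
  expect_equal(unname(rowSums(m$T)), c(1, 1), tolerance = 1e-10)
})

test_that("implied timescales: formula, flat-in-lag for Markovian data, flags", {
  # lambda2 = exp(-1) at tau = 10 -> t1 = 10
  Tm <- matrix(0, 2, 2)
  lam <- exp(-1)
  Tm <- 0.5 * (1 + lam) * diag(2) + 0.5 * (1 - lam) * (1 - diag(2))
  m <- kinscape:::.markov_model(Tm, 10)
  its <- implied_timescales(list(m), n = 1)
  expect_equal(its$timescale_ns[1], 10, tolerance = 1e-12)
  # exact Markov chain: ITS flat across lags within tolerance
  set.seed(53)
  path <- kinscape:::cpp_sample_chain(two_state_T(0.02), 400000, 1)
  models <- lapply(c(1, 2, 5, 10), function(lg) {
    cm <- count_transitions(list(path), lag_frames = lg)
    estimate_reversible(cm, lag_ns = lg)
  })
  tab <- implied_timescales(models, n = 1)
  t_true <- -1 / log(1 - 0.04)
  expect_true(all(abs(tab$timescale_ns - t_true) / t_true < 0.15))
  # non-positive eigenvalue flagged, not reported
  Tneg <- matrix(c(0.2, 0.8, 0.8, 0.2), 2, 2)
  mneg <- kinscape:::.markov_model(Tneg, 1)
  tneg <- implied_timescales(list(mneg), n = 1)
  expect_equal(tneg$flag[1], "non-positive")
  expect_true(is.na(tneg$timescale_ns[1]))
})

test_that("posterior sampler: contract properties and concentration", {
  set.seed(59)
  path <- kinscape:::cpp_sample_chain(two_state_T(0.05), 50000, 1)
  cm <- count_transitions(list(path), lag_frames = 1)
  post <- sample_posterior(cm, n_samples = 50, seed = 7)
  for (m in post$models[c(1, 25, 50)]) {
    expect_equal(unname(rowSums(m$T)), c(1, 1), tolerance = 1e-10)
    F <- m$pi * m$T
    expect_lt(max(abs(F - t(F))), 1e-8)
  }
  post2 <- sample_posterior(cm, n_samples = 50, seed = 7)
  expect_identical(
    vapply(post$models, function(m) m$T[1, 2], numeric(1)),
    vapply(post2$models, function(m) m$T[1, 2], numeric(1)))
  # posterior mean approaches the MLE as counts grow
  mle <- estimate_reversible(cm)
  t12 <- vapply(post$models, function(m) m$T[1, 2], numeric(1))
  expect_lt(abs(mean(t12) - mle$T[1, 2]), 3 * stats::sd(t12))
})

test_that("MFPT: geometric dwell, set conventions, Monte-Carlo agreement", {
  Tm <- matrix(c(0.9, 0.1, 0.5, 0.5), 2, 2, byrow = TRUE)
  m <- kinscape:::.markov_model(Tm, 10)
  expect_equal(mfpt(m, 1, 2), 100)
  expect_equal(mfpt(m, 1, 1), 0)
  # unreachable target is flagged infinite; reachable absorbing case solves
  Tabs <- matrix(c(1, 0, 0.5, 0.5), 2, 2, byrow = TRUE)
  mabs <- kinscape:::.markov_model(Tabs, 1)
  expect_true(is.infinite(mfpt(mabs, 1, 2)))
  expect_equal(mfpt(mabs, 2, 1), 2)
  # 3-state chain vs brute-force first-passage simulation
  T3 <- matrix(c(0.80, 0.15, 0.05,
                 0.20, 0.60, 0.20,
                 0.10, 0.30, 0.60), 3, 3, byrow = TRUE)
  m3 <- kinscape:::.markov_model(T3, 1)
  target <- mfpt(m3, 1, 3)
  set.seed(61)
  n_real <- 20000
  # simulate in blocks: long path from state 1, measure passages
  cum <- t(apply(T3, 1, cumsum))
  sim_once <- function() {
    s <- 1L; n <- 0L
    repeat {
      u <- runif(1)
      s <- which(u <= cum[s, ])[1]
      n <- n + 1L
      if (s == 3L) return(n)
    }
  }
  fp <- vapply(seq_len(n_real), function(i) sim_once(), numeric(1))
  expect_equal(target, mean(fp), tolerance = 0.02)
})
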