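test_that("coarse-graining recovers block structure of a 2-block chain", {
  # 6 microstates in two metastable blocks (intra 0.99, inter 0.01)
  k <- 6
  blocks <- rep(1:2, each = 3)
  Tm <- matrix(0, k, k)
  for (i in 1:k) for (j in 1:k) {
    Tm[i, j] <- if (blocks[i] == blocks[j]) 0.99 / 3 else 0.01 / 3
  }
  set.seed(71)
  path <- kinscape:::cpp_sample_chain(Tm, 100000, 1)
  cm <- count_transitions(list(path), lag_frames = 1)
  micro <- estimate_reversible(cm, lag_ns = 1)
  macro <- coarse_grain(list(path), micro, n_macro = 2, lag_frames = 1)
  memb <- macro$memberships
  # memberships within 0.05 of the block indicators (up to label order)
  lab <- apply(memb, 1, which.max)
  expect_true(all(lab[1:3] == lab[1]) && all(lab[4:6] == lab[4]) &&
                lab[1] != lab[4])
  expect_true(all(apply(memb, 1, max) > 0.95))
  expect_equal(unname(rowSums(memb)), rep(1, k), tolerance = 1e-9)
  expect_equal(unname(rowSums(macro$Tmacro)), rep(1, 2), tolerance = 1e-9)
  expect_equal(sum(macro$pimacro), 1, tolerance = 1e-9)
})

test_that("coarse-graining to the microstate count is the identity", {
  set.seed(73)
  path <- kinscape:::cpp_sample_chain(two_state_T(0.1), 5000, 1)
  cm <- count_transitions(list(path), lag_frames = 1)
  micro <- estimate_reversible(cm)
  macro <- coarse_grain(list(path), micro, n_macro = 2, lag_frames = 1)
  expect_equal(macro$Tmacro, micro$T, tolerance = 1e-12)
  expect_equal(macro$memberships, diag(2), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("the spectral-gap scan selects six macrostates on generator data", {
  rec <- recovery_fixture()
  expect_equal(rec$fit$macro_selection$n_macro, 6L)
  # macro ITS do not exceed micro ITS beyond statistical tolerance
  micro_its <- implied_timescales(list(rec$fit$micro_model), n = 5)
  macro <- rec$fit$macro_model
  macro_m <- kinscape:::.markov_model(macro$Tmacro, macro$lag_ns)
  macro_its <- implied_timescales(list(macro_m), n = 5)
  ok <- !is.na(macro_its$timescale_ns) & !is.na(micro_its$timescale_ns)
  expect_true(all(macro_its$timescale_ns[ok] <=
                    1.1 * micro_its$timescale_ns[ok]))
})

test_that("generator stationary populations are recovered within the 95% CI", {
  rec <- recovery_fixture()
  fit <- rec$fit
  map <- rec$match$map
  expect_gt(rec$match$accuracy, 0.9)
  # sampling CI: occupancy estimator variance inflated by the slowest
  # relaxation time of the generator (correlated frames)
  n_tot <- sum(vapply(rec$sim$labels, length, numeric(1)))
  lam2 <- sort(Re(eigen(rec$chain$T, only.values = TRUE)$values),
               decreasing = TRUE)[2]
  tau_slow <- -1 / log(lam2)
  for (g in 1:2) {  # the two dominant states
    est <- fit$macro_model$pimacro[which(map == g)]
    p0 <- unname(rec$chain$pi[g])
    se <- sqrt(p0 * (1 - p0) * 2 * tau_slow / n_tot)
    expect_lt(abs(est - p0), 1.96 * se + 0.01)
  }
})

test_that("lifetimes recover the generator dwell times within the 95% CI", {
  rec <- recovery_fixture()
  fit <- rec$fit
  map <- rec$match$map
  summ <- summarize_kinetics(fit$macro_posterior, fit$macro_model)
  # generator lifetime of each state at the model lag: tau/(1 - T_ii(lag))
  Tk <- kinscape:::.matpow(rec$chain$T, fit$lag_frames)
  for (g in seq_along(rec$chain$states)) {
    i <- which(map == g)
    truth <- fit$lag_ns / (1 - Tk[g, g])
    est <- summ$lifetimes_ns$mean[i]
    sd_ <- summ$lifetimes_ns$sd[i]
    expect_lt(abs(est - truth), 1.96 * sd_ + 0.25 * truth)
  }
  # formula check: T_ii = 0.9 at tau = 10 ns -> 100 ns
  fake <- structure(list(n_macro = 2,
                         Tmacro = matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2),
                         pimacro = c(0.5, 0.5), lag_ns = 10),
                    class = "MacrostateModel")
  s0 <- summarize_kinetics(NULL, fake)
  expect_equal(s0$lifetimes_ns$lifetime_ns, c(100, 100))
})

test_that("GMM posterior summaries recover a single Gaussian", {
  set.seed(79)
  hits <- 0
  for (rep in 1:10) {
    x <- rnorm(300, mean = 5, sd = 0.5)
    g <- kinscape:::.gmm_summary(x)
    if (g$n_components == 1) hits <- hits + 1
    expect_lt(abs(g$mean - 5), 3 * 0.5 / sqrt(300) + 0.05)
  }
  expect_gte(hits, 9)
  # degenerate posterior: single-component summary
  gd <- kinscape:::.gmm_summary(rep(2, 50))
  expect_equal(gd$n_components, 1L)
  expect_equal(gd$sd, 0)
})

test_that("CK test passes for exact macro dynamics and k = 1 is exact", {
  set.seed(83)
  Tm <- matrix(c(0.95, 0.04, 0.01,
                 0.08, 0.90, 0.02,
                 0.02, 0.02, 0.96), 3, 3, byrow = TRUE)
  path <- kinscape:::cpp_sample_chain(Tm, 200000, 1)
  cm <- count_transitions(list(path), lag_frames = 1)
  micro <- estimate_reversible(cm)
  macro <- coarse_grain(list(path), micro, n_macro = 3, lag_frames = 1)
  post <- sample_posterior(cm, n_samples = 40, seed = 5)
  mpost <- coarse_grain_posterior(post, macro)
  ck <- ck_test(macro, list(path), multiples = c(2, 3, 4, 5),
                lag_frames = 1, ensemble = mpost)
  expect_true(ck$pass)
  ck1 <- ck_test(macro, list(path), multiples = 1, lag_frames = 1)
  expect_true(all(abs(ck1$table$predicted - ck1$table$estimated) < 0.02))
})

test_that("CK test fails when metastable sets are lumped too coarsely", {
  # three metastable blocks with a fast hub (B) bridging two stable ends
  # (A, C): no two-state lumping of this chain is Markov, so a forced
  # two-macrostate model must fail the residence-probability check
  k <- 6
  blocks <- rep(1:3, each = 2)
  rate <- matrix(c(0, 0.03, 1e-4,
                   0.03, 0, 0.03,
                   1e-4, 0.03, 0), 3, 3, byrow = TRUE)
  Tm <- matrix(0, k, k)
  for (i in 1:k) for (j in 1:k) {
    if (i == j) next
    Tm[i, j] <- if (blocks[i] == blocks[j]) 0.2 else rate[blocks[i], blocks[j]] / 2
  }
  diag(Tm) <- 1 - rowSums(Tm)
  set.seed(89)
  path <- kinscape:::cpp_sample_chain(Tm, 150000, 1)
  cm <- count_transitions(list(path), lag_frames = 1)
  micro <- estimate_reversible(cm)
  macro2 <- suppressWarnings(
    coarse_grain(list(path), micro, n_macro = 2, lag_frames = 1))
  ck <- ck_test(macro2, list(path), multiples = c(5, 10, 20, 50), lag_frames = 1)
  expect_false(ck$pass)
})
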