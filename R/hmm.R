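# Metastable coarse-graining: a discrete-output hidden Markov model over
# the microstates, initialized from the spectral (metastability) structure
# of the microstate model and refined by expectation-maximization at the
# model lag.  Posterior uncertainty is propagated from microstate-level
# Bayesian samples through fixed membership weights.

# split dtrajs into runs of active-set states, remapped to 1..n_active
.active_segments <- function(dtrajs, active_set) {
  map <- rep(NA_integer_, max(unlist(lapply(dtrajs, max)), max(active_set)))
  map[active_set] <- seq_along(active_set)
  segs <- list()
  for (d in dtrajs) {
    md <- map[d]
    ok <- !is.na(md)
    if (!any(ok)) next
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (s in which(r$values)) {
      if (r$lengths[s] >= 2L) segs[[length(segs) + 1L]] <- md[starts[s]:ends[s]]
    }
  }
  segs
}

# strided subsequences: every lag-th symbol, one per offset
.strided_segments <- function(segs, lag) {
  out <- list()
  for (d in segs) {
    for (off in seq_len(min(lag, length(d)))) {
      idx <- seq(off, length(d), by = lag)
      if (length(idx) >= 2L) out[[length(out) + 1L]] <- d[idx]
    }
  }
  out
}

# crisp spectral (metastability) assignment of microstates to n groups.
# PCCA-style inner-simplex: rows of the leading right eigenvectors lie
# near a simplex with n_macro vertices (one per metastable set); vertices
# are picked greedily as maximally spread rows and every microstate is
# assigned by its simplex (barycentric) membership argmax.  Robust to
# very unequal metastable populations, unlike plain k-means on the rows.
.spectral_assignment <- function(T, n_macro) {
  e <- eigen(T)
  ord <- order(-Re(e$values))
  V <- Re(e$vectors[, ord[seq_len(n_macro)], drop = FALSE])
  n <- nrow(V)
  # greedy vertex search (inner simplex algorithm)
  verts <- integer(n_macro)
  ctr <- colMeans(V)
  d <- rowSums(sweep(V, 2, ctr)^2)
  verts[1] <- which.max(d)
  W <- sweep(V, 2, V[verts[1], ])  # affine coordinates about vertex 1
  for (k in 2:n_macro) {
    verts[k] <- which.max(rowSums(W^2))
    v <- W[verts[k], ]
    nv <- sqrt(sum(v^2))
    if (nv > 1e-300) {
      v <- v / nv
      W <- W - outer(as.vector(W %*% v), v)
    }
  }
  A <- tryCatch(solve(V[verts, , drop = FALSE]), error = function(e) NULL)
  if (is.null(A)) return(stats::cutree(stats::hclust(stats::dist(V)), n_macro))
  chi <- V %*% A  # barycentric memberships w.r.t. the simplex vertices
  cl <- max.col(chi, ties.method = "first")
  # guarantee all groups nonempty (degenerate spectra): fall back rarely
  if (length(unique(cl)) < n_macro) {
    for (k in seq_len(n_macro)) if (!any(cl == k)) cl[verts[k]] <- k
  }
  cl
}

#' Coarse-grain a microstate model into metastable macrostates
#'
#' Initializes a discrete-output hidden Markov model from the spectral
#' metastability decomposition of the microstate transition matrix and
#' refines it by expectation-maximization on the discrete trajectories
#' at the model lag (all lag offsets are used).  Returns the macrostate
#' transition matrix, its stationary distribution, and microstate-to-
#' macrostate membership weights; macrostates are relabelled by
#' decreasing stationary population.
#'
#' @param dtrajs list of microstate sequences (1..k), or a `Discretization`.
#' @param micro_model a `MarkovModel` estimated from the same dtrajs at
#'   the model lag.
#' @param n_macro number of macrostates (2 <= n_macro <= active states).
#' @param lag_frames model lag in frames (must match `micro_model`).
#' @param max_iter EM iteration cap (default 500).
#' @param tol relative log-likelihood convergence tolerance (default 1e-6).
#' @return object of class `MacrostateModel`: `n_macro`, `Tmacro`,
#'   `pimacro`, `memberships` (k x n_macro, rows sum to 1), `emission`
#'   (n_macro x k), `lag_ns`, `active_set`, `converged`, `loglik`.
#' @export
coarse_grain <- function(dtrajs, micro_model, n_macro, lag_frames,
                         max_iter = 500L, tol = 1e-6) {
  if (inherits(dtrajs, "Discretization")) dtrajs <- dtrajs$dtrajs
  if (is.numeric(dtrajs)) dtrajs <- list(as.integer(dtrajs))
  active <- micro_model$active_set
  M <- length(active)
  if (n_macro < 2L || n_macro > M)
    stop("n_macro must be in [2, ", M, "]")
  lag_frames <- as.integer(lag_frames)
  if (n_macro == M) {
    # identity coarse-graining
    memb <- diag(M)
    rownames(memb) <- as.character(active)
    return(structure(list(n_macro = M, Tmacro = micro_model$T,
                          pimacro = micro_model$pi, memberships = memb,
                          emission = diag(M), lag_ns = micro_model$lag_ns,
                          active_set = active, converged = TRUE,
                          loglik = NA_real_),
                     class = "MacrostateModel"))
  }
  segs <- .strided_segments(.active_segments(dtrajs, active), lag_frames)
  if (!length(segs)) stop("input error: no usable sequences at this lag")
  cl <- .spectral_assignment(micro_model$T, n_macro)
  pi_micro <- micro_model$pi
  # initial emissions: stationary-weighted indicator of the spectral groups
  B0 <- matrix(0, n_macro, M)
  for (m in seq_len(n_macro)) {
    w <- pi_micro * (cl == m)
    B0[m, ] <- w + 1e-8 * pi_micro
    B0[m, ] <- B0[m, ] / sum(B0[m, ])
  }
  # initial macro transitions: stationary-weighted lumping of the micro T
  A0 <- matrix(0, n_macro, n_macro)
  for (a in seq_len(n_macro)) {
    wa <- pi_micro * (cl == a)
    for (b in seq_len(n_macro))
      A0[a, b] <- sum(wa * (micro_model$T %*% (cl == b))) / sum(wa)
  }
  A0 <- A0 / rowSums(A0)
  fit <- cpp_hmm_em(lapply(segs, function(s) s - 1L), n_macro, M,
                    A0, B0, as.integer(max_iter), tol)
  if (!fit$converged)
    warning("EM did not converge in ", max_iter,
            " iterations; returning best-likelihood iterate")
  A <- fit$A
  pim <- .stationary(A)
  ord <- order(-pim)
  A <- A[ord, ord, drop = FALSE]
  pim <- pim[ord]
  B <- fit$B[ord, , drop = FALSE]
  # membership of microstate i in macrostate m: P(hidden = m | observed = i)
  memb <- t(B) * rep(pim, each = M)
  memb <- memb / pmax(rowSums(memb), 1e-300)
  rownames(memb) <- as.character(active)
  structure(list(n_macro = n_macro, Tmacro = A, pimacro = pim,
                 memberships = memb, emission = B,
                 lag_ns = micro_model$lag_ns, active_set = active,
                 converged = fit$converged,
                 loglik = utils::tail(fit$loglik, 1)),
            class = "MacrostateModel")
}

#' @export
print.MacrostateModel <- function(x, ...) {
  cat(sprintf("MacrostateModel: %d macrostates, lag %g ns; populations: %s\n",
              x$n_macro, x$lag_ns,
              paste(sprintf("%.1f%%", 100 * x$pimacro), collapse = ", ")))
  invisible(x)
}

#' Choose the number of macrostates from the spectral gap
#'
#' Scans a candidate range and selects the count `n` maximising the ratio
#' of consecutive implied timescales `t_{n-1} / t_n` of the microstate
#' model: `n` metastable states are resolved by `n - 1` slow processes
#' followed by a timescale gap.
#'
#' @param micro_model a `MarkovModel`.
#' @param range candidate macrostate counts (default 4:8).
#' @return list: `n_macro` (selected), `table` (data.frame of candidate
#'   counts, bounding timescales, and gap ratios).
#' @export
select_n_macrostates <- function(micro_model, range = 4:8) {
  lam <- Re(micro_model$eigenvalues)
  lam <- lam[lam > 0 & lam < 1 - 1e-12]
  ts <- -micro_model$lag_ns / log(lam)
  tab <- data.frame(n_macro = range,
                    t_slow = ts[range - 1],
                    t_fast = ts[range],
                    gap_ratio = ts[range - 1] / ts[range])
  list(n_macro = range[which.max(tab$gap_ratio)], table = tab)
}

#' Propagate microstate posterior samples to the macrostate level
#'
#' Each sampled microstate transition matrix is lumped through the fixed
#' membership weights of a reference macrostate model,
#' `Ttilde_ab = sum_ij m_ia pi_i T_ij m_jb / sum_i m_ia pi_i`,
#' yielding a posterior ensemble of macrostate models.
#'
#' @param ensemble a `PosteriorEnsemble` of microstate models.
#' @param macro_model the reference `MacrostateModel`.
#' @return a `PosteriorEnsemble` whose `models` are `MacrostateModel`s.
#' @export
coarse_grain_posterior <- function(ensemble, macro_model) {
  Mw <- macro_model$memberships
  models <- lapply(ensemble$models, function(m) {
    W <- Mw * m$pi            # k x n_macro, stationary-weighted memberships
    A <- t(W) %*% m$T %*% Mw  # n_macro x n_macro
    A <- A / colSums(W)
    A <- A / rowSums(A)
    structure(list(n_macro = macro_model$n_macro, Tmacro = A,
                   pimacro = .stationary(A), memberships = Mw,
                   emission = macro_model$emission, lag_ns = m$lag_ns,
                   active_set = m$active_set, converged = TRUE,
                   loglik = NA_real_),
              class = "MacrostateModel")
  })
  structure(list(models = models, seed = ensemble$seed,
                 lag_ns = ensemble$lag_ns),
            class = "PosteriorEnsemble")
}

# Wilson 95% score interval for a binomial proportion
.wilson <- function(x, n, z = 1.96) {
  if (n == 0) return(c(0, 1))
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, ctr - hw), min(1, ctr + hw))
}

#' Chapman-Kolmogorov test of a macrostate model
#'
#' Compares model-predicted residence probabilities `(Ttilde^k)_mm` with
#' residence probabilities re-estimated from the data at lag `k * tau`
#' (strided counting on the macrostate-labelled trajectories).  A state
#' passes at a multiple when the 95% intervals overlap: the estimated
#' side uses a Wilson score interval, the predicted side the posterior
#' spread when an ensemble is supplied (otherwise a point value).
#'
#' @param model a `MacrostateModel`.
#' @param dtrajs microstate sequences (1..k) or a `Discretization`.
#' @param multiples integer lag multiples to test, e.g. `c(2,3,4,5)`.
#' @param lag_frames model lag in frames.
#' @param ensemble optional macrostate `PosteriorEnsemble` for predicted
#'   intervals (see [coarse_grain_posterior()]).
#' @return object of class `CKTest`: `table` (per state and multiple:
#'   predicted, estimated, intervals, pass/indeterminate) and `pass`
#'   (TRUE when no determinate cell fails).
#' @export
ck_test <- function(model, dtrajs, multiples = c(2, 3, 4, 5), lag_frames,
                    ensemble = NULL) {
  if (inherits(dtrajs, "Discretization")) dtrajs <- dtrajs$dtrajs
  labels <- lapply(dtrajs, function(d) assign_macrostates(model, d))
  m <- model$n_macro
  rows <- list()
  for (k in multiples) {
    Tk <- .matpow(model$Tmacro, k)
    pred_int <- NULL
    if (!is.null(ensemble)) {
      diags <- vapply(ensemble$models,
                      function(s) diag(.matpow(s$Tmacro, k)), numeric(m))
      pred_int <- apply(diags, 1, stats::quantile, probs = c(0.025, 0.975),
                        na.rm = TRUE)
    }
    lagk <- lag_frames * k
    # strided macro counts at lag k*tau
    Cm <- matrix(0, m, m)
    for (lab in labels) {
      ok_len <- length(lab)
      if (ok_len <= lagk) next
      idx <- seq(1L, ok_len - lagk, by = lagk)
      a <- lab[idx]; b <- lab[idx + lagk]
      keep <- !is.na(a) & !is.na(b)
      if (!any(keep)) next
      Cm <- Cm + matrix(tabulate(a[keep] + m * (b[keep] - 1L), nbins = m * m), m, m)
    }
    for (st in seq_len(m)) {
      n_st <- sum(Cm[st, ])
      est <- if (n_st > 0) Cm[st, st] / n_st else NA_real_
      ci <- .wilson(Cm[st, st], n_st)
      plo <- if (!is.null(pred_int)) pred_int[1, st] else Tk[st, st]
      phi <- if (!is.null(pred_int)) pred_int[2, st] else Tk[st, st]
      status <- if (n_st == 0) "indeterminate" else
        if (phi >= ci[1] && plo <= ci[2]) "pass" else "fail"
      rows[[length(rows) + 1L]] <- data.frame(
        state = st, multiple = k, predicted = Tk[st, st],
        pred_lo = plo, pred_hi = phi, estimated = est,
        est_lo = ci[1], est_hi = ci[2], n = n_st, status = status,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  structure(list(table = tab, pass = !any(tab$status == "fail")),
            class = "CKTest")
}

#' @export
print.CKTest <- function(x, ...) {
  cat(sprintf("CKTest: %s (%d/%d cells pass, %d indeterminate)\n",
              if (x$pass) "PASS" else "FAIL",
              sum(x$table$status == "pass"), nrow(x$table),
              sum(x$table$status == "indeterminate")))
  invisible(x)
}

.matpow <- function(M, k) {
  out <- diag(nrow(M))
  P <- M
  while (k > 0) {
    if (k %% 2 == 1) out <- out %*% P
    P <- P %*% P
    k <- k %/% 2
  }
  out
}

# fit a 1-3 component GMM by BIC; degenerate samples get a 1-component summary
.gmm_summary <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L || stats::sd(x) < 1e-12)
    return(list(mean = mean(x), sd = 0, n_components = 1L,
                components = data.frame(mean = mean(x), sd = 0, weight = 1)))
  fit <- tryCatch(
    suppressWarnings(mclust::Mclust(x, G = 1:3, modelNames = "V",
                                    verbose = FALSE)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(mean = mean(x), sd = stats::sd(x), n_components = 1L,
                components = data.frame(mean = mean(x), sd = stats::sd(x),
                                        weight = 1)))
  list(mean = mean(x), sd = stats::sd(x), n_components = fit$G,
       components = data.frame(mean = as.vector(fit$parameters$mean),
                               sd = sqrt(as.vector(fit$parameters$variance$sigmasq)),
                               weight = as.vector(fit$parameters$pro)))
}

#' Kinetic summary of a macrostate model with posterior uncertainty
#'
#' State lifetimes `tau / (1 - Ttilde_mm)` (geometric dwell), relaxation
#' timescales from the macrostate eigenvalues, and stationary populations,
#' each summarised over the posterior ensemble by mean, standard deviation
#' and a 1-3 component Gaussian mixture selected by BIC.
#'
#' @param ensemble a macrostate `PosteriorEnsemble`
#'   ([coarse_grain_posterior()]); may be NULL for point estimates only.
#' @param model the reference `MacrostateModel`.
#' @return object of class `KineticSummary`: `lifetimes_ns`,
#'   `timescales_ns`, `populations` (data.frames with point estimate,
#'   posterior mean, sd) and `gmm` (per-quantity mixture fits).
#' @export
summarize_kinetics <- function(ensemble = NULL, model) {
  tau <- model$lag_ns
  m <- model$n_macro
  life_pt <- tau / (1 - diag(model$Tmacro))
  lam <- Re(eigen(model$Tmacro, only.values = TRUE)$values)
  lam <- sort(lam, decreasing = TRUE)[-1]
  ts_pt <- ifelse(lam > 0 & lam < 1, -tau / log(lam), NA_real_)
  pop_pt <- model$pimacro
  gmm <- list()
  if (!is.null(ensemble)) {
    life_s <- vapply(ensemble$models, function(s) tau / (1 - diag(s$Tmacro)),
                     numeric(m))
    pop_s <- vapply(ensemble$models, function(s) s$pimacro, numeric(m))
    ts_s <- vapply(ensemble$models, function(s) {
      l <- sort(Re(eigen(s$Tmacro, only.values = TRUE)$values), decreasing = TRUE)[-1]
      ifelse(l > 0 & l < 1, -tau / log(l), NA_real_)
    }, numeric(m - 1))
    if (m == 2) { life_s <- matrix(life_s, nrow = m); ts_s <- matrix(ts_s, nrow = 1) }
    life <- data.frame(state = seq_len(m), lifetime_ns = life_pt,
                       mean = rowMeans(life_s), sd = apply(life_s, 1, stats::sd))
    pops <- data.frame(state = seq_len(m), population = pop_pt,
                       mean = rowMeans(pop_s), sd = apply(pop_s, 1, stats::sd))
    ts <- data.frame(process = seq_len(m - 1), timescale_ns = ts_pt,
                     mean = rowMeans(ts_s, na.rm = TRUE),
                     sd = apply(ts_s, 1, stats::sd, na.rm = TRUE))
    gmm <- list(lifetimes = apply(life_s, 1, .gmm_summary),
                populations = apply(pop_s, 1, .gmm_summary),
                timescales = apply(ts_s, 1, .gmm_summary))
  } else {
    life <- data.frame(state = seq_len(m), lifetime_ns = life_pt,
                       mean = life_pt, sd = 0)
    pops <- data.frame(state = seq_len(m), population = pop_pt,
                       mean = pop_pt, sd = 0)
    ts <- data.frame(process = seq_len(m - 1), timescale_ns = ts_pt,
                     mean = ts_pt, sd = 0)
  }
  structure(list(lifetimes_ns = life, timescales_ns = ts,
                 populations = pops, gmm = gmm, lag_ns = tau),
            class = "KineticSummary")
}

#' @export
print.KineticSummary <- function(x, ...) {
  cat("KineticSummary (lag", x$lag_ns, "ns)\n")
  cat("Populations:\n"); print(x$populations, digits = 3)
  cat("Lifetimes (ns):\n"); print(x$lifetimes_ns, digits = 3)
  invisible(x)
}
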