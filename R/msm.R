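# Microstate Markov state model estimation: k-means discretization,
# transition counting, reversible maximum-likelihood estimation, implied
# timescales, Bayesian posterior sampling, and mean first-passage times.

#' Discretize feature space by seeded k-means
#'
#' Clusters (optionally TICA-projected) feature trajectories into `k`
#' microstates.  For large inputs the centres are fitted on a
#' deterministic subsample and all frames are then assigned to their
#' nearest centre, so the result is reproducible for a fixed seed.
#'
#' @param X a [feature_matrix()], list of them, or numeric matrix/list of
#'   matrices (e.g. IC projections).
#' @param k number of microstates.
#' @param seed integer RNG seed.
#' @param max_fit_frames subsample cap for fitting the centres
#'   (default 100000).
#' @param iter_max k-means iteration cap.
#' @return object of class `Discretization`: `centers`, `dtrajs` (list of
#'   integer vectors, states 1..k), `inertia`, `seed`.
#' @export
cluster_kmeans <- function(X, k, seed = 1L, max_fit_frames = 100000L,
                           iter_max = 100L) {
  mats <- if (is.matrix(X)) list(X) else if (inherits(X, "FeatureMatrix"))
    list(X$values) else lapply(X, function(x) if (inherits(x, "FeatureMatrix")) x$values else as.matrix(x))
  lens <- vapply(mats, nrow, integer(1))
  ntot <- sum(lens)
  all_rows <- function(idx) {
    out <- matrix(0, length(idx), ncol(mats[[1]]))
    offs <- c(0L, cumsum(lens))
    for (s in seq_along(mats)) {
      sel <- idx > offs[s] & idx <= offs[s + 1]
      if (any(sel)) out[sel, ] <- mats[[s]][idx[sel] - offs[s], , drop = FALSE]
    }
    out
  }
  set.seed(seed)
  fit_idx <- if (ntot > max_fit_frames) sort(sample.int(ntot, max_fit_frames)) else seq_len(ntot)
  Xfit <- all_rows(fit_idx)
  distinct <- unique(Xfit)
  ndist <- nrow(distinct)
  if (k > ndist)
    stop("input error: k (", k, ") exceeds number of distinct points (", ndist, ")")
  centers <- if (k == ndist) {
    distinct  # exact solution: every distinct point its own centre
  } else {
    km <- suppressWarnings(stats::kmeans(Xfit, centers = k, iter.max = iter_max,
                                         nstart = 3L))
    km$centers
  }
  dtrajs <- lapply(mats, function(M) as.integer(cpp_assign_centers(M, centers)))
  # inertia over all frames
  inertia <- 0
  for (s in seq_along(mats)) {
    d <- mats[[s]] - centers[dtrajs[[s]], , drop = FALSE]
    inertia <- inertia + sum(d * d)
  }
  structure(list(centers = centers, dtrajs = dtrajs, inertia = inertia,
                 k = k, seed = seed),
            class = "Discretization")
}

#' @export
print.Discretization <- function(x, ...) {
  cat(sprintf("Discretization: k = %d, %d trajectories, inertia = %.4g\n",
              x$k, length(x$dtrajs), x$inertia))
  invisible(x)
}

#' Count microstate transitions at a lag
#'
#' @param dtrajs list of integer state sequences (states 1..k), or a
#'   `Discretization`.
#' @param lag_frames lag in frames (>= 1, shorter than every trajectory).
#' @param mode `"sliding"` counts every (t, t+lag) pair; `"strided"`
#'   counts pairs at t = 1, 1+lag, 1+2*lag, ...
#' @param trim restrict to the largest strongly connected component
#'   (the active set); default TRUE.
#' @param k number of states (default: max observed).
#' @return object of class `CountMatrix`: `C` (k x k), `active_set`,
#'   `lag_frames`, `mode`.
#' @export
count_transitions <- function(dtrajs, lag_frames, mode = c("sliding", "strided"),
                              trim = TRUE, k = NULL) {
  mode <- match.arg(mode)
  if (inherits(dtrajs, "Discretization")) dtrajs <- dtrajs$dtrajs
  if (is.numeric(dtrajs)) dtrajs <- list(as.integer(dtrajs))
  lag_frames <- as.integer(lag_frames)
  if (lag_frames < 1L) stop("input error: lag_frames must be >= 1")
  if (is.null(k)) k <- max(vapply(dtrajs, max, integer(1)))
  C <- matrix(0, k, k)
  for (d in dtrajs) {
    Tn <- length(d)
    if (Tn <= lag_frames)
      stop("input error: lag (", lag_frames, ") >= trajectory length (", Tn, ")")
    from_idx <- if (mode == "sliding") seq_len(Tn - lag_frames) else
      seq(1L, Tn - lag_frames, by = lag_frames)
    i <- d[from_idx]; j <- d[from_idx + lag_frames]
    tab <- tabulate(i + k * (j - 1L), nbins = k * k)
    C <- C + matrix(tab, k, k)
  }
  active_set <- seq_len(k)
  if (trim) {
    g <- igraph::graph_from_adjacency_matrix((C > 0) * 1, mode = "directed")
    comp <- igraph::components(g, mode = "strong")
    sizes <- tapply(rowSums(C) + colSums(C), comp$membership, sum)
    big <- as.integer(names(sizes)[which.max(sizes)])
    active_set <- which(comp$membership == big)
    if (length(active_set) < 1L)
      stop("estimation error: no connected set of states")
  }
  structure(list(C = C, active_set = active_set, lag_frames = lag_frames,
                 mode = mode, k = k),
            class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d states (%d active), lag %d frames, %s counting, %g counts\n",
              x$k, length(x$active_set), x$lag_frames, x$mode, sum(x$C)))
  invisible(x)
}

.stationary <- function(T) {
  e <- eigen(t(T))
  i <- which.min(abs(e$values - 1))
  p <- Re(e$vectors[, i])
  p / sum(p)
}

.markov_model <- function(T, lag_ns, active_set = seq_len(nrow(T))) {
  ev <- eigen(T, only.values = TRUE)$values
  ev <- ev[order(-Re(ev))]
  structure(list(T = T, pi = .stationary(T), lag_ns = lag_ns,
                 eigenvalues = ev, active_set = active_set),
            class = "MarkovModel")
}

#' @export
print.MarkovModel <- function(x, ...) {
  cat(sprintf("MarkovModel: %d states, lag %g ns; pi range [%.4f, %.4f]\n",
              nrow(x$T), x$lag_ns, min(x$pi), max(x$pi)))
  invisible(x)
}

#' Reversible maximum-likelihood Markov model from transition counts
#'
#' Standard fixed-point iteration on symmetric edge weights `x_ij`:
#' given count matrix C with row sums `c_i`,
#' `x_ij <- (c_ij + c_ji) / (c_i / x_i + c_j / x_j)`,
#' which converges to the reversible maximum-likelihood transition matrix
#' `T_ij = x_ij / x_i` with stationary distribution `pi_i = x_i / sum(x)`.
#' For a symmetric count matrix the row-normalised counts are already the
#' fixed point.
#'
#' @param C a [count_transitions()] result (its active set is used) or a
#'   plain count matrix.
#' @param lag_ns physical lag time of the counts in ns (default: 1).
#' @param tol convergence tolerance on the max element change of T
#'   (default 1e-10).
#' @param max_iter iteration cap.
#' @return a `MarkovModel` on the active set: `T`, `pi`, `lag_ns`,
#'   `eigenvalues`, `active_set`.
#' @export
estimate_reversible <- function(C, lag_ns = 1, tol = 1e-10, max_iter = 100000L) {
  active <- NULL
  if (inherits(C, "CountMatrix")) {
    active <- C$active_set
    Cm <- C$C[active, active, drop = FALSE]
  } else {
    Cm <- as.matrix(C)
    active <- seq_len(nrow(Cm))
  }
  n <- nrow(Cm)
  ci <- rowSums(Cm)
  if (any(ci == 0)) stop("estimation error: state with no outgoing counts")
  Csym <- Cm + t(Cm)
  x <- Csym / sum(Csym)
  Tprev <- x / rowSums(x)
  for (it in seq_len(max_iter)) {
    xi <- rowSums(x)
    q <- ci / xi
    denom <- outer(q, q, "+")
    x <- Csym / denom
    x[Csym == 0] <- 0
    Tm <- x / rowSums(x)
    if (max(abs(Tm - Tprev)) < tol) {
      return(.markov_model(Tm, lag_ns, active))
    }
    Tprev <- Tm
  }
  stop("numerical error: reversible MLE did not converge in ", max_iter,
       " iterations (last delta ", format(max(abs(Tm - Tprev))), ")")
}

#' Implied timescales across lag times
#'
#' `t_i = -tau / log(lambda_{i+1})` for real eigenvalues in (0, 1);
#' non-positive or complex eigenvalues are flagged and omitted, and
#' processes faster than the lag are marked.
#'
#' @param models list of `MarkovModel` objects (one per lag, shared state
#'   space).
#' @param n number of slow processes to report.
#' @return data.frame with columns `lag_ns`, `process`, `timescale_ns`,
#'   `flag` (`"ok"`, `"below lag"`, `"non-positive"`, `"complex"`).
#' @export
implied_timescales <- function(models, n = 5) {
  do.call(rbind, lapply(models, function(m) {
    lam <- m$eigenvalues[-1]
    n_i <- min(n, length(lam))
    out <- data.frame(lag_ns = rep(m$lag_ns, n_i), process = seq_len(n_i),
                      timescale_ns = NA_real_, flag = "ok",
                      stringsAsFactors = FALSE)
    for (i in seq_len(n_i)) {
      l <- lam[i]
      if (abs(Im(l)) > 1e-10) { out$flag[i] <- "complex"; next }
      l <- Re(l)
      if (l <= 0) { out$flag[i] <- "non-positive"; next }
      if (l >= 1) { out$flag[i] <- "unit"; next }
      ts <- -m$lag_ns / log(l)
      out$timescale_ns[i] <- ts
      if (ts < m$lag_ns) out$flag[i] <- "below lag"
    }
    out
  }))
}

#' Sample the Bayesian posterior over reversible transition matrices
#'
#' Markov chain Monte Carlo over the reversible (symmetric edge weight)
#' parameterization given the observed counts; every sample is
#' row-stochastic and satisfies detailed balance with respect to its own
#' stationary distribution.  Seeded and reproducible.
#'
#' @param C a [count_transitions()] result or count matrix.
#' @param n_samples number of posterior samples.
#' @param seed RNG seed.
#' @param lag_ns physical lag of the counts, ns.
#' @param thin sweeps between retained samples (default 10).
#' @param burnin discarded initial sweeps (default 100).
#' @param step log-normal proposal scale (default 0.1).
#' @return object of class `PosteriorEnsemble`: `models` (list of
#'   `MarkovModel`), `seed`, `lag_ns`.
#' @export
sample_posterior <- function(C, n_samples = 100, seed = 1L, lag_ns = 1,
                             thin = 10L, burnin = 100L, step = 0.1) {
  active <- NULL
  if (inherits(C, "CountMatrix")) {
    active <- C$active_set
    Cm <- C$C[active, active, drop = FALSE]
  } else {
    Cm <- as.matrix(C)
    active <- seq_len(nrow(Cm))
  }
  set.seed(seed)
  arr <- cpp_sample_reversible(Cm, n_samples, as.integer(thin),
                               as.integer(burnin), step)
  models <- lapply(seq_len(n_samples), function(s)
    .markov_model(arr[, , s], lag_ns, active))
  structure(list(models = models, seed = seed, lag_ns = lag_ns),
            class = "PosteriorEnsemble")
}

#' @export
print.PosteriorEnsemble <- function(x, ...) {
  cat(sprintf("PosteriorEnsemble: %d samples, lag %g ns\n",
              length(x$models), x$lag_ns))
  invisible(x)
}

#' Mean first-passage time between state sets
#'
#' Solves the first-passage linear system `m_i = tau + sum_j T_ij m_j`
#' on the non-target states (`m = 0` on B) and returns the
#' stationary-weighted mean over the source set, in physical time.
#'
#' @param model a `MarkovModel` or `MacrostateModel`.
#' @param A source state indices.
#' @param B target state indices.
#' @return time in the model's lag units (ns); `Inf` if B is unreachable.
#' @export
mfpt <- function(model, A, B) {
  T <- if (inherits(model, "MacrostateModel")) model$Tmacro else model$T
  p <- if (inherits(model, "MacrostateModel")) model$pimacro else model$pi
  tau <- model$lag_ns
  A <- as.integer(A); B <- as.integer(B)
  if (!length(A) || !length(B)) stop("A and B must be nonempty")
  if (length(intersect(A, B))) return(0)
  n <- nrow(T)
  nb <- setdiff(seq_len(n), B)
  m <- rep(0, n)
  sol <- tryCatch(
    solve(diag(length(nb)) - T[nb, nb, drop = FALSE], rep(tau, length(nb))),
    error = function(e) NULL)
  if (is.null(sol) || any(!is.finite(sol)) || any(sol < 0)) return(Inf)
  m[nb] <- sol
  wA <- p[A]
  if (sum(wA) <= 0) wA <- rep(1, length(A))  # A unvisited at stationarity
  sum(wA * m[A]) / sum(wA)
}
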