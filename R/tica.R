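# Slow-mode estimation and feature selection.
#
# TICA solves the symmetrized generalized eigenproblem
#   C(tau) v = lambda C(0) v
# on mean-free data, where C(0) and C(tau) are the instantaneous and
# time-lagged covariance matrices accumulated over all supplied
# trajectories.  Eigenvalues are lag-tau autocorrelations of the
# independent components; implied timescales follow as -tau/log(lambda).

# normalise input to a list of plain matrices + lag in frames
.as_traj_list <- function(X) {
  if (inherits(X, "FeatureMatrix")) return(list(dt = X$frame_interval_ns, mats = list(X$values)))
  if (is.list(X) && all(vapply(X, inherits, logical(1), "FeatureMatrix")))
    return(list(dt = X[[1]]$frame_interval_ns, mats = lapply(X, `[[`, "values")))
  if (is.matrix(X)) return(list(dt = 1, mats = list(X)))
  stop("X must be a FeatureMatrix, a list of them, or a matrix")
}

.lag_frames <- function(lag_ns, dt) {
  lf <- lag_ns / dt
  if (abs(lf - round(lf)) > 1e-8 || lf < 1)
    stop("input error: lag must be a positive multiple of the frame interval")
  as.integer(round(lf))
}

# accumulate symmetrized covariances over trajectories at a lag
.covariances <- function(mats, lag) {
  d <- ncol(mats[[1]])
  s0 <- st <- rep(0, d)
  C00 <- Ctt <- C0t <- matrix(0, d, d)
  n <- 0
  for (M in mats) {
    Tn <- nrow(M)
    if (Tn <= lag) stop("input error: lag (", lag, " frames) >= trajectory length (", Tn, ")")
    A <- M[1:(Tn - lag), , drop = FALSE]
    B <- M[(1 + lag):Tn, , drop = FALSE]
    s0 <- s0 + colSums(A); st <- st + colSums(B)
    C00 <- C00 + crossprod(A); Ctt <- Ctt + crossprod(B); C0t <- C0t + crossprod(A, B)
    n <- n + nrow(A)
  }
  list(n = n, mean0 = s0 / n, meant = st / n, C00 = C00, Ctt = Ctt, C0t = C0t)
}

#' Estimate a TICA model
#'
#' Time-lagged independent component analysis on one or more feature
#' trajectories: mean-centres the data, symmetrizes the instantaneous and
#' time-lagged covariances (reversible estimate), regularizes with a small
#' ridge, and solves the generalized eigenproblem.  Zero-variance columns
#' are dropped with a log entry.  Components are ordered by decreasing
#' eigenvalue and sign-fixed so the largest-magnitude loading is positive.
#'
#' @param X a [feature_matrix()] or list of them (multiple trajectories).
#' @param lag_ns lag time in ns (positive multiple of the frame interval).
#' @param dim number of components to keep (default all).
#' @param ridge diagonal regularization added to C(0) (default 1e-8; raise
#'   to e.g. 1e-6 for heavily redundant feature sets).
#' @return object of class `TICAModel`: `components` (d x dim loading
#'   matrix), `eigenvalues`, `timescales_ns`, `means`, `lag_ns`,
#'   `kept` (retained column indices), `dropped` (zero-variance labels).
#' @export
estimate_tica <- function(X, lag_ns, dim = NULL, ridge = 1e-8) {
  inp <- .as_traj_list(X)
  lag <- .lag_frames(lag_ns, inp$dt)
  cv <- .covariances(inp$mats, lag)
  mu <- (cv$mean0 + cv$meant) / 2
  n <- cv$n
  # mean-free symmetrized covariances
  C0 <- (cv$C00 + cv$Ctt) / (2 * n) - tcrossprod(mu)
  Ct <- (cv$C0t + t(cv$C0t)) / (2 * n) - tcrossprod(mu)
  v <- diag(C0)
  labs <- colnames(inp$mats[[1]])
  if (is.null(labs)) labs <- paste0("f", seq_along(v))
  keep <- which(v > 1e-12)
  dropped <- labs[setdiff(seq_along(v), keep)]
  if (length(dropped))
    message("estimate_tica: dropped ", length(dropped), " zero-variance column(s)")
  if (!length(keep)) stop("numerical error: all features have zero variance")
  C0 <- C0[keep, keep, drop = FALSE] + ridge * diag(length(keep))
  Ct <- Ct[keep, keep, drop = FALSE]
  e0 <- eigen(C0, symmetric = TRUE)
  if (min(e0$values) <= 0)
    stop("numerical error: instantaneous covariance not positive definite")
  W <- e0$vectors %*% diag(1 / sqrt(e0$values), length(e0$values)) # whitener
  M <- crossprod(W, Ct) %*% W
  em <- eigen((M + t(M)) / 2, symmetric = TRUE)
  ord <- order(em$values, decreasing = TRUE)
  lam <- em$values[ord]
  V <- W %*% em$vectors[, ord, drop = FALSE]
  if (is.null(dim)) dim <- length(lam)
  dim <- min(dim, length(lam))
  lam <- lam[1:dim]; V <- V[, 1:dim, drop = FALSE]
  # sign convention: largest-|loading| entry positive
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  ts <- rep(NA_real_, length(lam))
  pos <- lam > 0 & lam < 1
  ts[pos] <- -lag_ns / log(lam[pos])
  structure(list(components = V, eigenvalues = lam, timescales_ns = ts,
                 means = mu[keep], lag_ns = lag_ns, kept = keep,
                 labels = labs[keep], dropped = dropped),
            class = "TICAModel")
}

#' @export
print.TICAModel <- function(x, ...) {
  cat(sprintf("TICAModel: lag %g ns, %d components; leading eigenvalues: %s\n",
              x$lag_ns, ncol(x$components),
              paste(sprintf("%.3f", utils::head(x$eigenvalues, 5)), collapse = ", ")))
  invisible(x)
}

#' Project features onto TICA independent components
#'
#' @param model a `TICAModel`.
#' @param X a [feature_matrix()] or matrix with the columns the model was
#'   trained on.
#' @return numeric matrix frames x components (the IC projections).
#' @export
project_tica <- function(model, X) {
  M <- if (inherits(X, "FeatureMatrix")) X$values else as.matrix(X)
  sweep(M[, model$kept, drop = FALSE], 2, model$means) %*% model$components
}

#' Correlate raw features with TICA independent components
#'
#' Pearson correlation of every feature with every IC projection, with
#' candidate/strong flags at the configured absolute thresholds.
#' Constant features get correlation 0 with a warning.
#'
#' @param model a `TICAModel`.
#' @param X training data ([feature_matrix()] or list of them).
#' @param n_ics number of leading ICs to use.
#' @param ics explicit IC indices (overrides `n_ics`), e.g. `c(1,2,5,6)` to
#'   restrict ranking to components describing concerted rearrangements.
#' @param candidate_threshold absolute-correlation candidate cut (default 0.45).
#' @param strong_threshold absolute-correlation strong cut (default 0.70).
#' @return object of class `CorrelationTable`: `cor` (features x ICs),
#'   `max_abs_cor`, `best_ic`, `candidate`, `strong`, thresholds.
#' @export
feature_ic_correlation <- function(model, X, n_ics = 6, ics = NULL,
                                   candidate_threshold = 0.45,
                                   strong_threshold = 0.70) {
  inp <- .as_traj_list(X)
  if (is.null(ics)) ics <- seq_len(min(n_ics, ncol(model$components)))
  if (max(ics) > ncol(model$components)) stop("requested IC beyond model components")
  M <- do.call(rbind, inp$mats)
  P <- project_tica(model, M)[, ics, drop = FALSE]
  labs <- colnames(M)
  if (is.null(labs)) labs <- paste0("f", seq_len(ncol(M)))
  sds <- apply(M, 2, stats::sd)
  const <- sds < 1e-12
  if (any(const))
    warning(sum(const), " constant feature(s); correlation set to 0")
  co <- matrix(0, ncol(M), length(ics),
               dimnames = list(labs, paste0("IC", ics)))
  ok <- which(!const)
  co[ok, ] <- stats::cor(M[, ok, drop = FALSE], P)
  mx <- apply(abs(co), 1, max)
  structure(list(cor = co, max_abs_cor = mx,
                 best_ic = ics[apply(abs(co), 1, which.max)],
                 candidate = mx >= candidate_threshold,
                 strong = mx >= strong_threshold,
                 candidate_threshold = candidate_threshold,
                 strong_threshold = strong_threshold),
            class = "CorrelationTable")
}

#' @export
print.CorrelationTable <- function(x, ...) {
  cat(sprintf("CorrelationTable: %d features x %d ICs; %d candidates (|r| >= %.2f), %d strong (|r| >= %.2f)\n",
              nrow(x$cor), ncol(x$cor), sum(x$candidate), x$candidate_threshold,
              sum(x$strong), x$strong_threshold))
  invisible(x)
}

#' Write a CorrelationTable as CSV
#' @param tab a `CorrelationTable`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_correlation_table <- function(tab, path) {
  df <- data.frame(feature = rownames(tab$cor), tab$cor,
                   max_abs_cor = tab$max_abs_cor, best_ic = tab$best_ic,
                   candidate = tab$candidate, strong = tab$strong)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Prune candidate residue pairs by redundancy and locality
#'
#' Deterministic greedy filter on candidate residue-pair features:
#' pairs touching the chain termini (within `terminal_margin` of the
#' residue range) or near the diagonal (`|i - j| <= near_window`) are
#' removed first; the survivors are visited in order of decreasing
#' absolute correlation (ties: smaller (i, j) lexicographically) and a
#' pair is retained only if no previously retained pair lies within its
#' 3 x 3 index neighbourhood (Chebyshev distance <= half-width in (i, j)
#' space, pairs normalised to i < j).
#'
#' @param candidates data.frame with columns `i`, `j` (residue indices)
#'   and `score` (signed or absolute correlation); extra columns such as
#'   `ic` are carried through.
#' @param res_range length-2 integer vector, first and last residue of
#'   the chain (used for the terminal margin).
#' @param neighborhood odd window size for redundancy collapse (default 3).
#' @param terminal_margin residues within this margin of either terminus
#'   are excluded (default 3).
#' @param near_window pairs with `|i - j| <=` this are excluded (default 4).
#' @return object of class `FeatureRegistrySelection`: `retained`
#'   data.frame (with provenance), `removed` data.frame with a `reason`
#'   column (the pruning log), and the parameters.
#' @export
prune_redundancy_locality <- function(candidates, res_range,
                                      neighborhood = 3, terminal_margin = 3,
                                      near_window = 4) {
  stopifnot(neighborhood %% 2 == 1)
  half <- (neighborhood - 1) / 2
  cand <- as.data.frame(candidates)
  if (!nrow(cand)) {
    empty_rm <- cand
    empty_rm$reason <- character(0)
    return(structure(list(retained = cand, removed = empty_rm,
                          neighborhood = neighborhood,
                          terminal_margin = terminal_margin,
                          near_window = near_window),
                     class = "FeatureRegistrySelection"))
  }
  ii <- pmin(cand$i, cand$j); jj <- pmax(cand$i, cand$j)
  cand$i <- ii; cand$j <- jj
  lo <- res_range[1] + terminal_margin; hi <- res_range[2] - terminal_margin
  terminal <- cand$i < lo | cand$j > hi
  near <- (cand$j - cand$i) <= near_window
  with_reason <- function(df, reason) {
    df$reason <- rep_len(reason, nrow(df))
    df
  }
  removed <- rbind(
    with_reason(cand[terminal, , drop = FALSE], "terminal"),
    with_reason(cand[!terminal & near, , drop = FALSE], "near-diagonal"))
  cand <- cand[!terminal & !near, , drop = FALSE]
  ord <- order(-abs(cand$score), cand$i, cand$j)
  cand <- cand[ord, , drop = FALSE]
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!any(keep)) { keep[k] <- TRUE; next }
    prev <- cand[keep, , drop = FALSE]
    clash <- abs(prev$i - cand$i[k]) <= half & abs(prev$j - cand$j[k]) <= half
    if (!any(clash)) keep[k] <- TRUE
  }
  removed <- rbind(removed,
                   with_reason(cand[!keep, , drop = FALSE], "redundant"))
  structure(list(retained = cand[keep, , drop = FALSE], removed = removed,
                 neighborhood = neighborhood, terminal_margin = terminal_margin,
                 near_window = near_window),
            class = "FeatureRegistrySelection")
}

#' @export
print.FeatureRegistrySelection <- function(x, ...) {
  cat(sprintf("FeatureRegistrySelection: %d retained, %d removed (margin %d, near window %d)\n",
              nrow(x$retained), nrow(x$removed), x$terminal_margin, x$near_window))
  invisible(x)
}

#' VAMP-2 score of a feature representation
#'
#' Sum of squared singular values of the half-weighted time-lagged
#' correlation operator `C00^{-1/2} C0t Ctt^{-1/2}` on mean-free data,
#' truncated at `dim` modes including the constant mode (so a
#' `dim`-mode score uses the `dim - 1` largest data singular values and
#' the lower bound is 1).  Higher scores mean the representation retains
#' more slow-kinetic content.
#'
#' @param X a [feature_matrix()] or list of them.
#' @param lag_ns lag time in ns.
#' @param dim number of modes including the constant (default: all).
#' @param ridge diagonal regularization (default 1e-6).
#' @return scalar score `>= 1`.
#' @export
vamp2_score <- function(X, lag_ns, dim = NULL, ridge = 1e-6) {
  inp <- .as_traj_list(X)
  lag <- .lag_frames(lag_ns, inp$dt)
  cv <- .covariances(inp$mats, lag)
  n <- cv$n
  C00 <- cv$C00 / n - tcrossprod(cv$mean0)
  Ctt <- cv$Ctt / n - tcrossprod(cv$meant)
  C0t <- cv$C0t / n - tcrossprod(cv$mean0, cv$meant)
  v0 <- diag(C00); vt <- diag(Ctt)
  keep <- which(v0 > 1e-12 & vt > 1e-12)
  if (!length(keep)) return(1)
  C00 <- C00[keep, keep, drop = FALSE] + ridge * diag(length(keep))
  Ctt <- Ctt[keep, keep, drop = FALSE] + ridge * diag(length(keep))
  C0t <- C0t[keep, keep, drop = FALSE]
  inv_sqrt <- function(S) {
    e <- eigen(S, symmetric = TRUE)
    pos <- e$values > 1e-12
    e$vectors[, pos, drop = FALSE] %*%
      diag(1 / sqrt(e$values[pos]), sum(pos)) %*% t(e$vectors[, pos, drop = FALSE])
  }
  K <- inv_sqrt(C00) %*% C0t %*% inv_sqrt(Ctt)
  s <- svd(K, nu = 0, nv = 0)$d
  if (is.null(dim)) dim <- length(s) + 1L
  k <- min(dim - 1L, length(s))
  1 + if (k > 0) sum(s[seq_len(k)]^2) else 0
}
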