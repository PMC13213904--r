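# Transition path theory on a (macro)state Markov model: forward and
# backward committors, gross/net reactive fluxes, and iterative
# bottleneck (widest-path) pathway decomposition.

#' Committors and reactive flux between two state sets
#'
#' Forward committor `q+` from the standard linear system on the
#' intermediate states; backward committor from the time-reversed chain
#' (equal to `1 - q+` for reversible models).  Gross reactive flux
#' `f_ij = pi_i q-_i T_ij q+_j` (i != j), net flux
#' `f+_ij = max(f_ij - f_ji, 0)`, and total flux `F` as the net reactive
#' flow out of A, reported per unit lag time.
#'
#' @param model a `MarkovModel` or `MacrostateModel`.
#' @param A source state indices.
#' @param B sink state indices.
#' @return object of class `FluxNetwork`: `A`, `B`, `qplus`, `qminus`,
#'   `gross` (matrix), `net` (matrix), `total_flux` (per lag),
#'   `total_flux_per_ns`, `lag_ns`.
#' @export
committors_and_flux <- function(model, A, B) {
  T <- if (inherits(model, "MacrostateModel")) model$Tmacro else model$T
  p <- if (inherits(model, "MacrostateModel")) model$pimacro else model$pi
  n <- nrow(T)
  A <- as.integer(A); B <- as.integer(B)
  if (!length(A) || !length(B) || length(intersect(A, B)))
    stop("A and B must be disjoint and nonempty")
  I <- setdiff(seq_len(n), c(A, B))
  qp <- numeric(n); qp[B] <- 1
  if (length(I)) {
    M <- diag(length(I)) - T[I, I, drop = FALSE]
    rhs <- rowSums(T[I, B, drop = FALSE])
    sol <- tryCatch(solve(M, rhs), error = function(e)
      stop("singular committor system: sink unreachable?"))
    qp[I] <- sol
  }
  # backward committor via the time-reversed chain
  Trev <- t(T) * rep(p, each = n) / p   # Trev_ij = pi_j T_ji / pi_i
  Trev <- Trev / rowSums(Trev)
  qm <- numeric(n); qm[A] <- 1
  if (length(I)) {
    M <- diag(length(I)) - Trev[I, I, drop = FALSE]
    rhs <- rowSums(Trev[I, A, drop = FALSE])
    qm[I] <- solve(M, rhs)
  }
  gross <- (p * qm) * T * rep(qp, each = n)
  diag(gross) <- 0
  net <- pmax(gross - t(gross), 0)
  total <- sum(net[A, setdiff(seq_len(n), A), drop = FALSE])
  lag_ns <- model$lag_ns
  structure(list(A = A, B = B, qplus = qp, qminus = qm, gross = gross,
                 net = net, total_flux = total,
                 total_flux_per_ns = total / lag_ns, lag_ns = lag_ns),
            class = "FluxNetwork")
}

#' @export
print.FluxNetwork <- function(x, ...) {
  cat(sprintf("FluxNetwork: %d states, A = {%s}, B = {%s}, total flux %.4g / lag (%.4g /ns)\n",
              length(x$qplus), paste(x$A, collapse = ","),
              paste(x$B, collapse = ","), x$total_flux, x$total_flux_per_ns))
  invisible(x)
}

# widest (maximum bottleneck) path from any state in A to any in B on the
# weighted directed graph W; ties broken by fewer hops, then by
# lexicographic predecessor order.  Returns NULL if no path.
.widest_path <- function(W, A, B) {
  n <- nrow(W)
  width <- rep(-Inf, n); hops <- rep(Inf, n)
  prev <- rep(NA_integer_, n)
  width[A] <- Inf; hops[A] <- 0
  done <- rep(FALSE, n)
  for (iter in seq_len(n)) {
    cand <- which(!done & width > -Inf)
    if (!length(cand)) break
    u <- cand[order(-width[cand], hops[cand], cand)][1]
    done[u] <- TRUE
    for (v in seq_len(n)) {
      if (W[u, v] <= 0 || done[v]) next
      w_new <- min(width[u], W[u, v])
      h_new <- hops[u] + 1
      better <- w_new > width[v] ||
        (w_new == width[v] && h_new < hops[v]) ||
        (w_new == width[v] && h_new == hops[v] && !is.na(prev[v]) && u < prev[v])
      if (better) { width[v] <- w_new; hops[v] <- h_new; prev[v] <- u }
    }
  }
  reach <- B[width[B] > 0]
  if (!length(reach)) return(NULL)
  b <- reach[order(-width[reach], hops[reach], reach)][1]
  path <- b
  while (!path[1] %in% A) path <- c(prev[path[1]], path)
  list(path = path, bottleneck = width[b])
}

#' Decompose a flux network into ranked pathways
#'
#' Iterative bottleneck decomposition: repeatedly extract the A-to-B path
#' whose minimum-edge net flux is maximal, subtract that bottleneck flux
#' along the path, and record its share of the total flux, stopping when
#' the cumulative share reaches `coverage_stop` or no path remains.
#' Ties are broken by shorter path, then lexicographic state order.
#'
#' @param net a `FluxNetwork`.
#' @param coverage_stop stop once cumulative flux share reaches this
#'   percentage (default 90).
#' @param max_paths safety cap on the number of extracted paths.
#' @return object of class `PathwayDecomposition`: `paths` (data.frame
#'   with `path` string, `flux`, `share_pct`, `cumulative_pct`),
#'   `total_flux`.
#' @export
decompose_pathways <- function(net, coverage_stop = 90, max_paths = 1000L) {
  stopifnot(inherits(net, "FluxNetwork"))
  W <- net$net
  total <- net$total_flux
  rows <- list()
  cum <- 0
  if (total > 0) {
    for (it in seq_len(max_paths)) {
      wp <- .widest_path(W, net$A, net$B)
      if (is.null(wp) || wp$bottleneck <= 1e-15 * total) break
      f <- wp$bottleneck
      for (e in seq_len(length(wp$path) - 1))
        W[wp$path[e], wp$path[e + 1]] <- W[wp$path[e], wp$path[e + 1]] - f
      share <- 100 * f / total
      cum <- cum + share
      rows[[length(rows) + 1L]] <- data.frame(
        path = paste(wp$path, collapse = " -> "),
        flux = f, share_pct = round(share, 2),
        cumulative_pct = round(cum, 2), stringsAsFactors = FALSE)
      if (cum >= coverage_stop) break
    }
  }
  paths <- if (length(rows)) do.call(rbind, rows) else
    data.frame(path = character(0), flux = numeric(0),
               share_pct = numeric(0), cumulative_pct = numeric(0))
  structure(list(paths = paths, total_flux = total,
                 coverage_stop = coverage_stop),
            class = "PathwayDecomposition")
}

#' @export
print.PathwayDecomposition <- function(x, ...) {
  cat(sprintf("PathwayDecomposition: %d path(s), total flux %.4g\n",
              nrow(x$paths), x$total_flux))
  if (nrow(x$paths)) print(x$paths, row.names = FALSE)
  invisible(x)
}

#' Export a flux network and kinetic annotations for plotting
#'
#' Writes a plain-text graph description: one node row per state
#' (population) and one edge row per ordered state pair (net flux, MFPT).
#'
#' @param net a `FluxNetwork`.
#' @param model the model the network was computed from.
#' @param path output file path (TSV).
#' @param state_names optional state labels.
#' @return `path`, invisibly.
#' @export
write_flux_graph <- function(net, model, path, state_names = NULL) {
  p <- if (inherits(model, "MacrostateModel")) model$pimacro else model$pi
  n <- length(p)
  if (is.null(state_names)) state_names <- paste0("S", seq_len(n))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# nodes: name\tpopulation\tqplus", con)
  writeLines(sprintf("node\t%s\t%.6g\t%.6g", state_names, p, net$qplus), con)
  writeLines("# edges: from\tto\tnet_flux\tmfpt_ns", con)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || net$net[i, j] <= 0) next
    writeLines(sprintf("edge\t%s\t%s\t%.6g\t%.6g", state_names[i],
                       state_names[j], net$net[i, j], mfpt(model, i, j)), con)
  }
  invisible(path)
}
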