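# End-to-end estimation pipeline and ground-truth recovery scoring.

#' Cluster-estimate-coarse-grain pipeline
#'
#' Runs the standard model-building sequence on feature trajectories:
#' k-means discretization into microstates, sliding-window transition
#' counting at the model lag, reversible maximum-likelihood estimation,
#' and hidden-Markov coarse-graining into macrostates.  Optionally draws
#' a Bayesian posterior ensemble for uncertainty.
#'
#' @param features list of [feature_matrix()] (or matrices).
#' @param n_micro number of microstates (default 100).
#' @param n_macro number of macrostates; `NULL` selects from the spectral
#'   gap over `macro_range`.
#' @param lag_frames model lag in frames (default 10).
#' @param seed RNG seed for clustering and posterior sampling.
#' @param n_samples posterior samples (0 to skip).
#' @param macro_range candidate macrostate counts for selection
#'   (default 4:8).
#' @param frame_interval_ns physical time per frame; default taken from
#'   the first FeatureMatrix.
#' @return list: `discretization`, `counts`, `micro_model`, `macro_model`,
#'   `macro_selection`, `posterior` (micro), `macro_posterior`,
#'   `lag_frames`, `lag_ns`.
#' @export
estimate_pipeline <- function(features, n_micro = 100, n_macro = NULL,
                              lag_frames = 10, seed = 1L, n_samples = 0,
                              macro_range = 4:8,
                              frame_interval_ns = NULL) {
  if (is.null(frame_interval_ns)) {
    frame_interval_ns <- if (inherits(features[[1]], "FeatureMatrix"))
      features[[1]]$frame_interval_ns else 1
  }
  lag_ns <- lag_frames * frame_interval_ns
  disc <- cluster_kmeans(features, k = n_micro, seed = seed)
  counts <- count_transitions(disc, lag_frames = lag_frames, mode = "sliding")
  micro <- estimate_reversible(counts, lag_ns = lag_ns)
  selection <- select_n_macrostates(micro, range = macro_range)
  if (is.null(n_macro)) n_macro <- selection$n_macro
  macro <- coarse_grain(disc, micro, n_macro = n_macro,
                        lag_frames = lag_frames)
  post <- macro_post <- NULL
  if (n_samples > 0) {
    post <- sample_posterior(counts, n_samples = n_samples, seed = seed + 1L,
                             lag_ns = lag_ns)
    macro_post <- coarse_grain_posterior(post, macro)
  }
  list(discretization = disc, counts = counts, micro_model = micro,
       macro_model = macro, macro_selection = selection,
       posterior = post, macro_posterior = macro_post,
       lag_frames = lag_frames, lag_ns = lag_ns)
}

#' Match estimated macrostates to ground-truth hidden states
#'
#' Greedy confusion-matrix matching: per-frame estimated macrostate
#' labels are crossed with the known hidden labels and (estimated, true)
#' pairs are matched in order of decreasing overlap.
#'
#' @param fit an [estimate_pipeline()] result.
#' @param labels list of hidden-state sequences (as returned by
#'   [sample_feature_trajectories()]).
#' @param n_states number of hidden states.
#' @return list: `map` (estimated index -> true index), `accuracy`
#'   (fraction of assigned frames matching after mapping), `confusion`.
#' @export
match_macrostates <- function(fit, labels, n_states = NULL) {
  est <- unlist(lapply(fit$discretization$dtrajs, function(d)
    assign_macrostates(fit$macro_model, d)))
  truth <- unlist(labels)
  if (is.null(n_states)) n_states <- max(truth)
  ok <- !is.na(est)
  conf <- matrix(0, fit$macro_model$n_macro, n_states)
  tab <- table(factor(est[ok], levels = seq_len(fit$macro_model$n_macro)),
               factor(truth[ok], levels = seq_len(n_states)))
  conf[] <- as.numeric(tab)
  map <- rep(NA_integer_, fit$macro_model$n_macro)
  used <- logical(n_states)
  Cw <- conf
  for (k in seq_len(min(dim(conf)))) {
    ij <- which(Cw == max(Cw), arr.ind = TRUE)[1, ]
    map[ij[1]] <- ij[2]
    used[ij[2]] <- TRUE
    Cw[ij[1], ] <- -1; Cw[, ij[2]] <- -1
  }
  acc <- sum(conf[cbind(seq_along(map)[!is.na(map)], map[!is.na(map)])]) /
    sum(conf)
  list(map = map, accuracy = acc, confusion = conf)
}
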