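# Surrogate null networks and statistical validation of layer partitions.

#' Degree-preserving surrogate networks
#'
#' Each surrogate shares the binary degree sequence of `W` (via
#' Maslov-Sneppen double edge swaps) and its exact multiset of edge
#' weights (shuffled over the rewired edge slots). On dense networks such
#' as all-pairs PLV layers rewiring is a no-op and the null reduces to a
#' weight shuffle, which is the intended behaviour.
#'
#' @param W symmetric weight matrix with at least 2 edges.
#' @param n_surrogates number of surrogates (100 by default).
#' @param seed integer seed.
#' @param n_swaps attempted edge swaps per surrogate (default `10 * m`).
#' @return List of surrogate matrices.
#' @export
surrogate_null <- function(W, n_surrogates = 100, seed = 1, n_swaps = NULL) {
  m <- sum(W[upper.tri(W)] != 0)
  if (m < 2L)
    stop("too few edges to build surrogates", call. = FALSE)
  if (is.null(n_swaps)) n_swaps <- 10L * m
  lapply(seq_len(n_surrogates), function(r) {
    rewire_shuffle_cpp(W, as.integer(n_swaps), seed * 100003 + r)
  })
}

# Null distribution of maximized modularity for one layer: each surrogate
# is partitioned with the same Louvain settings as the observed layer.
surrogate_q <- function(W, n_surrogates = 100, gamma = 1, seed = 1) {
  surr <- surrogate_null(W, n_surrogates, seed)
  vapply(surr, function(S) {
    modularity(S, louvain_partition(S, gamma, seed), gamma)
  }, 0)
}

#' Validate layer partitions against surrogate nulls
#'
#' Tests, per layer, whether the observed maximized modularity exceeds the
#' modularity of degree-preserving weight-shuffled surrogates; a layer is
#' flagged valid when its one-sided p-value beats the Bonferroni-corrected
#' threshold `alpha / L`.
#'
#' Two p-value estimators are available. `"empirical"` is the exceedance
#' count `p = (1 + #\{Q_surr >= Q_obs\}) / (n_surrogates + 1)`; its floor of
#' `1 / (n_surrogates + 1)` cannot resolve `alpha / L` once
#' `L > alpha * (n_surrogates + 1) - 1` (L > 4 at the defaults), so the
#' default `"gaussian"` estimator uses the upper tail of a normal fit to
#' the surrogate modularity distribution instead.
#'
#' @param net a [multilayer_network()] or list of layer matrices.
#' @param partitions list (or N x L matrix) of per-layer labels.
#' @param alpha family-wise significance level (0.05).
#' @param n_surrogates surrogates per layer (100).
#' @param gamma resolution parameter.
#' @param seed integer seed.
#' @param method `"gaussian"` (default) or `"empirical"`, see Details.
#' @return Logical vector of per-layer validity flags, with attributes
#'   `p` (per-layer p-values), `q_obs` and `q_null` (surrogate mean).
#' @export
validate_layers <- function(net, partitions, alpha = 0.05,
                            n_surrogates = 100, gamma = 1, seed = 1,
                            method = c("gaussian", "empirical")) {
  method <- match.arg(method)
  layers <- if (inherits(net, "multilayer_network")) net$layers else net
  if (is.matrix(partitions))
    partitions <- lapply(seq_len(ncol(partitions)),
                         function(s) partitions[, s])
  L <- length(layers)
  if (length(partitions) != L)
    stop("need one partition per layer", call. = FALSE)
  p <- q_obs <- q_null <- numeric(L)
  for (s in seq_len(L)) {
    q_obs[s] <- modularity(layers[[s]], partitions[[s]], gamma)
    qs <- surrogate_q(layers[[s]], n_surrogates, gamma,
                      seed = seed + 7919L * s)
    q_null[s] <- mean(qs)
    if (method == "empirical") {
      p[s] <- (1 + sum(qs >= q_obs[s])) / (n_surrogates + 1)
    } else {
      sdq <- sd(qs)
      p[s] <- if (sdq > 0)
        pnorm(q_obs[s], mean(qs), sdq, lower.tail = FALSE)
      else if (q_obs[s] > mean(qs)) .Machine$double.xmin else 1
    }
  }
  valid <- p < alpha / L
  attr(valid, "p") <- p
  attr(valid, "q_obs") <- q_obs
  attr(valid, "q_null") <- q_null
  valid
}
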