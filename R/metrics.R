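# Network reconfiguration metrics from a partition sequence.
#
# A node "moves" at transition t when its aligned community label changes
# between layers t and t+1. A move is cohesive when at least one other node
# moves to the same target community at the same transition, and disjoint
# (solo) otherwise -- every move is exactly one of the two, which makes
# flexibility = cohesive fraction + disjointedness an identity rather than
# an approximation. Transitions touching a layer that failed the surrogate
# null test are skipped and all rates renormalize by the number of used
# transitions T.

used_transitions <- function(P) {
  L <- ncol(P$labels)
  valid <- P$layer_valid
  if (is.null(valid)) valid <- rep(TRUE, L)
  which(valid[-L] & valid[-1])
}

#' Classify node moves at each usable layer transition
#'
#' @param P a [partition_sequence()] whose labels have been aligned across
#'   layers ([align_labels()]; [temporal_consensus()] output already is).
#' @return List with `used` (indices t of transitions t -> t+1 where both
#'   layers are valid) and `records`: per used transition a list with
#'   `moved` (node indices whose label changed), `target` (their new
#'   labels) and `partners` (per moved node, the co-moving nodes sharing
#'   its target community).
#' @export
classify_transitions <- function(P) {
  stopifnot(inherits(P, "partition_sequence"))
  if (is.null(attr(P$labels, "aligned")) && is.null(P$params$q_ml))
    stop("labels must be aligned across layers first (align_labels)",
         call. = FALSE)
  used <- used_transitions(P)
  if (length(used) < 1L)
    stop("no usable transitions: need >= 2 consecutive valid layers",
         call. = FALSE)
  records <- lapply(used, function(t) {
    from <- P$labels[, t]
    to <- P$labels[, t + 1L]
    moved <- unname(which(from != to))
    target <- unname(to[moved])
    partners <- lapply(seq_along(moved), function(k)
      moved[target == target[k] & moved != moved[k]])
    list(transition = t, moved = moved, target = target,
         partners = partners)
  })
  list(used = used, records = records, n_nodes = nrow(P$labels))
}

#' Node-level reconfiguration metrics
#'
#' Over the T used transitions: flexibility `f_i` = moves / T,
#' disjointedness `d_i` = solo moves / T, cohesive fraction `c_i` =
#' partnered moves / T, so `f_i = c_i + d_i` exactly.
#'
#' @inheritParams classify_transitions
#' @return Data frame with columns `node`, `flexibility`, `disjointedness`,
#'   `cohesive_fraction`.
#' @export
node_metrics <- function(P) {
  ct <- classify_transitions(P)
  N <- ct$n_nodes
  Tn <- length(ct$used)
  moves <- solo <- numeric(N)
  for (r in ct$records) {
    if (length(r$moved) == 0L) next
    moves[r$moved] <- moves[r$moved] + 1
    is_solo <- vapply(r$partners, function(p) length(p) == 0L, TRUE)
    solo[r$moved[is_solo]] <- solo[r$moved[is_solo]] + 1
  }
  nodes <- if (!is.null(P$node_labels)) P$node_labels
           else rownames(P$labels) %||% paste0("n", seq_len(N))
  d <- solo / Tn
  cf <- (moves - solo) / Tn
  # storing f as cf + d makes the additive identity bitwise exact
  data.frame(node = nodes,
             flexibility = cf + d,
             disjointedness = d,
             cohesive_fraction = cf,
             row.names = NULL, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cohesion matrix and node cohesion strength
#'
#' `counts_ij` is the number of used transitions at which nodes i and j both
#' move and share the target community; the cohesion strength of node i is
#' `s_i = sum_j counts_ij / T`. A node travelling with k - 1 steady partners
#' through every transition therefore has `s_i = k - 1`.
#'
#' @inheritParams classify_transitions
#' @return List with `counts` (N x N symmetric integer matrix, zero
#'   diagonal), `strength` (per-node `s_i`) and `n_transitions_used`.
#' @export
cohesion <- function(P) {
  ct <- classify_transitions(P)
  N <- ct$n_nodes
  Tn <- length(ct$used)
  counts <- matrix(0L, N, N)
  for (r in ct$records) {
    if (length(r$moved) < 2L) next
    for (g in split(r$moved, r$target)) {
      if (length(g) < 2L) next
      idx <- t(combn(g, 2L))
      counts[idx] <- counts[idx] + 1L
      counts[idx[, 2:1, drop = FALSE]] <- counts[idx[, 2:1, drop = FALSE]] + 1L
    }
  }
  nodes <- if (!is.null(P$node_labels)) P$node_labels
           else rownames(P$labels) %||% paste0("n", seq_len(N))
  dimnames(counts) <- list(nodes, nodes)
  list(counts = counts, strength = rowSums(counts) / Tn,
       n_transitions_used = Tn)
}

#' Community-level reconfiguration metrics
#'
#' Site-averaged summaries per subject and band: community cohesion is the
#' mean over nodes of cohesion strength `s_i`, community disjointedness the
#' mean of node disjointedness `d_i`, and community change their sum (an
#' exact additive identity).
#'
#' @param P a [partition_sequence()], or a list with elements `nodes` (from
#'   [node_metrics()]) and `strength` (from [cohesion()]).
#' @return Named numeric vector `community_cohesion`,
#'   `community_disjointedness`, `community_change`.
#' @export
community_metrics <- function(P) {
  if (inherits(P, "partition_sequence")) {
    nm <- node_metrics(P)
    s <- cohesion(P)$strength
  } else {
    nm <- P$nodes
    s <- P$strength
  }
  coh <- mean(s)
  dis <- mean(nm$disjointedness)
  c(community_cohesion = coh, community_disjointedness = dis,
    community_change = coh + dis)
}

#' All reconfiguration metrics for one partition sequence
#'
#' @inheritParams classify_transitions
#' @return List with `nodes` (node-level table including cohesion strength
#'   and node-level change), `community` (site-averaged vector) and
#'   `cohesion_matrix`.
#' @export
reconfig_metrics <- function(P) {
  nm <- node_metrics(P)
  ch <- cohesion(P)
  nm$cohesion_strength <- ch$strength
  nm$change <- ch$strength + nm$disjointedness
  list(nodes = nm,
       community = community_metrics(list(nodes = nm, strength = ch$strength)),
       cohesion_matrix = ch$counts,
       n_transitions_used = ch$n_transitions_used)
}
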