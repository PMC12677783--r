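# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: partition enumeration by restricted growth
# strings, and a direct (node, transition) enumeration of reconfiguration
# metrics.

# All set partitions of n elements (Bell(n); keep n <= 8).
all_partitions <- function(n) {
  out <- list()
  rec <- function(pref, mx) {
    if (length(pref) == n) {
      out[[length(out) + 1L]] <<- pref
      return(invisible())
    }
    for (v in seq_len(mx + 1L)) rec(c(pref, v), max(mx, v))
  }
  rec(integer(0), 0L)
  out
}

# Plain-R weighted modularity, written independently of the package.
oracle_modularity <- function(W, labels, gamma = 1) {
  m2 <- sum(W)
  k <- rowSums(W)
  q <- 0
  for (i in seq_len(nrow(W)))
    for (j in seq_len(ncol(W)))
      if (labels[i] == labels[j])
        q <- q + W[i, j] - gamma * k[i] * k[j] / m2
  q / m2
}

# Exhaustive max-modularity search.
oracle_qmax <- function(W, gamma = 1) {
  parts <- all_partitions(nrow(W))
  best <- -Inf
  for (p in parts) {
    q <- oracle_modularity(W, p, gamma)
    if (q > best) best <- q
  }
  best
}

# Brute-force reconfiguration metrics: enumerate every (node, transition)
# pair directly from the label matrix and validity flags.
oracle_reconfig <- function(labels, layer_valid = NULL) {
  N <- nrow(labels); L <- ncol(labels)
  if (is.null(layer_valid)) layer_valid <- rep(TRUE, L)
  used <- which(layer_valid[-L] & layer_valid[-1])
  Tn <- length(used)
  moves <- solo <- numeric(N)
  counts <- matrix(0L, N, N)
  for (t in used) {
    for (i in seq_len(N)) {
      if (labels[i, t] == labels[i, t + 1]) next
      moves[i] <- moves[i] + 1
      partnered <- FALSE
      for (j in seq_len(N)) {
        if (j == i) next
        if (labels[j, t] != labels[j, t + 1] &&
            labels[j, t + 1] == labels[i, t + 1]) {
          partnered <- TRUE
          counts[i, j] <- counts[i, j] + 1L
        }
      }
      if (!partnered) solo[i] <- solo[i] + 1
    }
  }
  list(flexibility = moves / Tn, disjointedness = solo / Tn,
       cohesive_fraction = (moves - solo) / Tn, counts = counts,
       strength = rowSums(counts) / Tn, T = Tn)
}

# Random aligned partition sequence for property tests.
random_partition_sequence <- function(N, L, K = 3, change_p = 0.3) {
  lab <- matrix(0L, N, L)
  lab[, 1] <- sample.int(K, N, replace = TRUE)
  for (t in 2:L) {
    lab[, t] <- lab[, t - 1]
    movers <- which(runif(N) < change_p)
    if (length(movers))
      lab[movers, t] <- sample.int(K + 1L, length(movers), replace = TRUE)
  }
  attr(lab, "aligned") <- TRUE
  partition_sequence(lab)
}

# Random symmetric weighted graph.
random_weighted_graph <- function(n, p = 0.6) {
  W <- matrix(0, n, n)
  iu <- upper.tri(W)
  w <- runif(sum(iu)) * (runif(sum(iu)) < p)
  W[iu] <- w
  W <- W + t(W)
  if (sum(W) == 0) W[1, 2] <- W[2, 1] <- 1
  W
}
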