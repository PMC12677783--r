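# Partition containers, inter-layer label alignment, partition similarity.

#' Construct a node-by-layer partition sequence
#'
#' @param labels N x L integer matrix of community labels (contiguous from 1
#'   within each layer).
#' @param layer_valid logical vector of length L: outcome of the surrogate
#'   null-model test per layer (`NULL` means not assessed, treated as all
#'   valid downstream).
#' @param quality optional per-layer modularity Q.
#' @param params list of detection parameters (gamma, omega, seeds, ...).
#' @param node_labels optional node names.
#' @return Object of class `partition_sequence`.
#' @export
partition_sequence <- function(labels, layer_valid = NULL, quality = NULL,
                               params = list(), node_labels = NULL) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  L <- ncol(labels)
  if (!is.null(layer_valid)) {
    if (length(layer_valid) != L)
      stop("layer_valid must have one flag per layer", call. = FALSE)
  }
  if (!is.null(quality) && length(quality) != L)
    stop("quality must have one value per layer", call. = FALSE)
  if (!is.null(node_labels)) rownames(labels) <- node_labels
  structure(list(labels = labels, layer_valid = layer_valid,
                 quality = quality, params = params,
                 node_labels = node_labels),
            class = "partition_sequence")
}

#' @export
print.partition_sequence <- function(x, ...) {
  cat(sprintf("<partition_sequence> %d nodes x %d layers", nrow(x$labels),
              ncol(x$labels)))
  if (!is.null(x$layer_valid))
    cat(sprintf(" (%d/%d layers valid)", sum(x$layer_valid),
                length(x$layer_valid)))
  cat("\n")
  invisible(x)
}

#' Align community labels across layers by maximal Jaccard overlap
#'
#' Relabels each layer so that every community inherits the id of the
#' previous-layer community it overlaps most (greedy matching in descending
#' Jaccard order); unmatched communities receive fresh ids. Only labels are
#' permuted -- which nodes share a community is never changed.
#'
#' @param labels N x L integer matrix, or a [partition_sequence()].
#' @return Aligned labels in the same form as the input, with attribute
#'   `aligned = TRUE`.
#' @export
align_labels <- function(labels) {
  if (inherits(labels, "partition_sequence")) {
    labels$labels <- align_labels(labels$labels)
    return(labels)
  }
  labels <- as.matrix(labels)
  L <- ncol(labels)
  if (L < 2L) stop("need at least 2 layers to align", call. = FALSE)
  out <- labels
  next_id <- max(out[, 1])
  for (t in 2:L) {
    prev <- out[, t - 1L]
    cur <- labels[, t]
    cur_ids <- sort(unique(cur))
    prev_ids <- sort(unique(prev))
    ov <- matrix(0, length(cur_ids), length(prev_ids),
                 dimnames = list(cur_ids, prev_ids))
    for (a in seq_along(cur_ids)) {
      ca <- cur == cur_ids[a]
      for (b in seq_along(prev_ids)) {
        cb <- prev == prev_ids[b]
        ov[a, b] <- sum(ca & cb) / sum(ca | cb)
      }
    }
    newlab <- integer(length(cur_ids))
    used_prev <- logical(length(prev_ids))
    done_cur <- logical(length(cur_ids))
    ord <- order(-as.vector(ov),
                 rep(seq_along(cur_ids), times = length(prev_ids)),
                 rep(seq_along(prev_ids), each = length(cur_ids)))
    for (k in ord) {
      a <- (k - 1L) %% length(cur_ids) + 1L
      b <- (k - 1L) %/% length(cur_ids) + 1L
      if (ov[a, b] <= 0) break
      if (done_cur[a] || used_prev[b]) next
      newlab[a] <- prev_ids[b]
      done_cur[a] <- TRUE
      used_prev[b] <- TRUE
    }
    for (a in which(!done_cur)) {
      next_id <- next_id + 1L
      newlab[a] <- next_id
    }
    out[, t] <- newlab[match(cur, cur_ids)]
    next_id <- max(next_id, out[, t])
  }
  attr(out, "aligned") <- TRUE
  out
}

#' Normalized mutual information between two partitions
#'
#' NMI with arithmetic-mean normalisation; 1 when the partitions are
#' identical up to relabeling, 0 under independence. Two all-singleton or
#' two one-block partitions compare as 1 when identical.
#'
#' @param a,b integer label vectors of equal length.
#' @return NMI in \[0, 1\].
#' @export
nmi <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  n <- length(a)
  tab <- table(a, b)
  pij <- tab / n
  pi_ <- rowSums(pij)
  pj_ <- colSums(pij)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi_, pj_)[nz]))
  ha <- -sum(pi_[pi_ > 0] * log(pi_[pi_ > 0]))
  hb <- -sum(pj_[pj_ > 0] * log(pj_[pj_ > 0]))
  if (ha + hb == 0) return(1) # both trivial partitions
  2 * mi / (ha + hb)
}
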