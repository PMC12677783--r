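# Phase-locking connectivity and multilayer network assembly.

# Analytic signal via FFT (Hilbert transform).
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2L == 0L) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase of band-limited signals
#'
#' Analytic-signal (Hilbert) phase per channel, wrapped to (-pi, pi].
#'
#' @param segment numeric vector or channels x samples matrix of
#'   band-limited signal.
#' @return Phase in radians, same shape as the input.
#' @export
instantaneous_phase <- function(segment) {
  phase1 <- function(x) {
    if (all(x == 0))
      stop("phase undefined for an all-zero channel", call. = FALSE)
    Arg(analytic_signal(x))
  }
  if (is.matrix(segment)) {
    out <- t(apply(segment, 1, phase1))
    rownames(out) <- rownames(segment)
    out
  } else phase1(segment)
}

#' Phase locking value between two phase series
#'
#' Modulus of the sample mean of the unit phasor of the phase difference:
#' `|mean(exp(i (phi_x - phi_y)))|`. 1 means perfect locking, values near
#' `sqrt(pi / (4 n))` are expected for independent phases.
#'
#' @param phase_x,phase_y numeric phase vectors (radians), equal length >= 2.
#' @return Scalar in \[0, 1\].
#' @export
plv <- function(phase_x, phase_y) {
  if (length(phase_x) != length(phase_y))
    stop("phase series must have equal length", call. = FALSE)
  if (length(phase_x) < 2L)
    stop("need at least 2 samples", call. = FALSE)
  min(Mod(mean(exp(1i * (phase_x - phase_y)))), 1)
}

# All-pairs PLV from a channels x samples phase matrix.
plv_matrix <- function(phase) {
  e <- exp(1i * phase)
  m <- Mod(e %*% Conj(t(e))) / ncol(phase)
  m[m > 1] <- 1
  diag(m) <- 0
  dimnames(m) <- list(rownames(phase), rownames(phase))
  m
}

#' Construct a multilayer network container
#'
#' @param layers list of symmetric non-negative N x N weight matrices with
#'   zero diagonal (one per time window).
#' @param node_labels node names.
#' @param band band name (optional).
#' @param subject_id subject identifier (optional).
#' @param window_s window length in seconds (optional).
#' @return Object of class `multilayer_network`.
#' @export
multilayer_network <- function(layers, node_labels = NULL, band = NA_character_,
                               subject_id = NA_character_, window_s = NA_real_) {
  if (length(layers) < 2L)
    stop("a multilayer network needs at least 2 layers", call. = FALSE)
  n <- nrow(layers[[1]])
  for (W in layers) {
    if (!is.matrix(W) || nrow(W) != n || ncol(W) != n)
      stop("all layers must be square matrices of identical size",
           call. = FALSE)
    if (any(!is.finite(W)) || any(W < 0))
      stop("layer weights must be finite and non-negative", call. = FALSE)
    if (max(abs(W - t(W))) > 1e-9)
      stop("layers must be symmetric", call. = FALSE)
    if (any(diag(W) != 0))
      stop("layer diagonals must be zero", call. = FALSE)
  }
  if (is.null(node_labels)) node_labels <- rownames(layers[[1]])
  if (is.null(node_labels)) node_labels <- paste0("n", seq_len(n))
  structure(list(layers = layers, node_labels = node_labels, band = band,
                 subject_id = subject_id, window_s = window_s),
            class = "multilayer_network")
}

#' @export
print.multilayer_network <- function(x, ...) {
  cat(sprintf("<multilayer_network> %d layers x %d nodes", length(x$layers),
              nrow(x$layers[[1]])))
  if (!is.na(x$band)) cat(" [", x$band, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Assemble the PLV multilayer network for one band
#'
#' The analytic phase is computed once on the full-length filtered channel
#' (avoiding Gibbs edge effects in each short segment) and sliced into the
#' window grid; layer t holds the pairwise PLV of window t. Networks stay
#' fully weighted: no thresholding or binarisation.
#'
#' @param bws a [band_window()] result.
#' @param band band name present in `bws$bands`.
#' @param edge_trim_s seconds to drop from each end of the recording before
#'   windowing, to discard Hilbert-transform edge artifacts. Default 0 keeps
#'   the layer count at `floor(duration / window_s)`.
#' @return A [multilayer_network()] with one layer per retained window.
#' @export
build_multilayer <- function(bws, band, edge_trim_s = 0) {
  stopifnot(inherits(bws, "band_windowed"))
  if (!band %in% names(bws$bands))
    stop("unknown band: ", band, call. = FALSE)
  phase <- instantaneous_phase(bws$filtered[[band]])
  wlen <- bws$window_samples
  trim <- as.integer(round(edge_trim_s * bws$fs))
  lo <- trim + 1L
  hi <- ncol(phase) - trim
  starts <- bws$starts[bws$starts >= lo & (bws$starts + wlen - 1L) <= hi]
  if (length(starts) < 2L)
    stop("fewer than 2 windows remain after edge trimming", call. = FALSE)
  layers <- lapply(starts, function(s) {
    plv_matrix(phase[, s:(s + wlen - 1L), drop = FALSE])
  })
  multilayer_network(layers, node_labels = bws$channel_labels, band = band,
                     subject_id = bws$subject_id, window_s = bws$window_s)
}
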