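# IIR filter design and zero-phase application.
#
# No DSP package ships with this stack, so the Butterworth design is done
# from first principles: analog prototype poles -> frequency transform
# (with bilinear pre-warping) -> bilinear transform -> second-order
# sections. SOS form keeps the narrow low-frequency bands (delta at
# fs = 500 Hz) numerically stable where a single degree-8 polynomial
# would not be.

# Analog Butterworth lowpass prototype poles (cutoff 1 rad/s, gain 1).
butter_prototype <- function(order) {
  k <- seq_len(order)
  exp(1i * pi * (2 * k + order - 1) / (2 * order))
}

# Pair complex poles into biquad denominators [1, a1, a2].
pole_sections <- function(poles, tol = 1e-8) {
  up <- poles[Im(poles) > tol]
  re <- sort(Re(poles[abs(Im(poles)) <= tol]))
  secs <- list()
  for (p in up) secs[[length(secs) + 1L]] <- c(1, -2 * Re(p), Mod(p)^2)
  i <- 1L
  while (i + 1L <= length(re)) {
    secs[[length(secs) + 1L]] <- c(1, -(re[i] + re[i + 1L]), re[i] * re[i + 1L])
    i <- i + 2L
  }
  if (length(re) %% 2L == 1L)
    secs[[length(secs) + 1L]] <- c(1, -re[length(re)], 0)
  secs
}

# Evaluate an SOS cascade at digital frequency f (Hz).
sos_response <- function(sos, f, fs) {
  z <- exp(-2i * pi * f / fs) # z^-1
  h <- 1 + 0i
  for (s in seq_len(nrow(sos))) {
    num <- sos[s, 1] + sos[s, 2] * z + sos[s, 3] * z^2
    den <- sos[s, 4] + sos[s, 5] * z + sos[s, 6] * z^2
    h <- h * num / den
  }
  h
}

#' Design a digital Butterworth filter in second-order sections
#'
#' Bilinear-transform design with frequency pre-warping. Band-pass designs
#' double the prototype order (an order-4 band-pass has 8 poles).
#'
#' @param order prototype order (4 by default throughout the package).
#' @param freq cutoff in Hz: a scalar for `low`/`high`, `c(low, high)` for
#'   `band`.
#' @param fs sampling rate in Hz.
#' @param type `"low"`, `"high"` or `"band"`.
#' @return Matrix with rows `b0 b1 b2 a0 a1 a2` and attribute `fs`.
#' @export
butter_sos <- function(order = 4, freq, fs, type = c("band", "low", "high")) {
  type <- match.arg(type)
  nyq <- fs / 2
  if (any(freq <= 0) || any(freq >= nyq))
    stop("filter frequencies must lie strictly inside (0, Nyquist)",
         call. = FALSE)
  proto <- butter_prototype(order)
  warp <- function(f) 2 * fs * tan(pi * f / fs)
  if (type == "band") {
    if (length(freq) != 2L || freq[1] >= freq[2])
      stop("band design needs freq = c(low, high) with low < high",
           call. = FALSE)
    w1 <- warp(freq[1]); w2 <- warp(freq[2])
    w0 <- sqrt(w1 * w2); bw <- w2 - w1
    # lowpass -> bandpass: each prototype pole maps to two poles
    pb <- proto * bw
    disc <- sqrt(as.complex(pb^2 - 4 * w0^2))
    apoles <- c((pb + disc) / 2, (pb - disc) / 2)
    num_sec <- c(1, 0, -1) # one zero at z=1 and one at z=-1 per section
    f_ref <- fs / pi * atan(w0 / (2 * fs)) # digital centre frequency
  } else {
    wc <- warp(freq[1])
    apoles <- if (type == "low") proto * wc else wc / proto
    num_sec <- if (type == "low") c(1, 2, 1) else c(1, -2, 1)
    f_ref <- if (type == "low") 0 else nyq
  }
  zpoles <- (2 * fs + apoles) / (2 * fs - apoles) # bilinear
  dens <- pole_sections(zpoles)
  sos <- do.call(rbind, lapply(dens, function(a) c(num_sec, a)))
  g <- Mod(sos_response(sos, f_ref, fs))
  sos[1, 1:3] <- sos[1, 1:3] / g
  attr(sos, "fs") <- fs
  sos
}

#' Design a second-order IIR notch filter
#'
#' Standard biquad notch with unit gain away from the notch frequency.
#'
#' @param freq notch frequency in Hz.
#' @param fs sampling rate in Hz.
#' @param q quality factor (bandwidth = freq / q).
#' @return One-row SOS matrix.
#' @export
notch_sos <- function(freq, fs, q = 30) {
  if (freq <= 0 || freq >= fs / 2)
    stop("notch frequency must lie strictly inside (0, Nyquist)",
         call. = FALSE)
  w0 <- 2 * pi * freq / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  sos <- matrix(c(b / a[1], 1, a[2] / a[1], a[3] / a[1]), nrow = 1)
  attr(sos, "fs") <- fs
  sos
}

#' Zero-phase filtering (forward-backward) of a signal or channel matrix
#'
#' Applies the SOS cascade forward and then backward so the net phase
#' response is zero, with odd-reflection padding to suppress edge
#' transients.
#'
#' @param sos SOS matrix from [butter_sos()] or [notch_sos()].
#' @param x numeric vector, or channels x samples matrix (filtered per row).
#' @return Filtered signal with the same shape as `x`.
#' @export
filtfilt_sos <- function(sos, x) {
  if (is.matrix(x))
    return(t(apply(x, 1, function(r) filtfilt_sos(sos, r))))
  n <- length(x)
  fs <- attr(sos, "fs")
  pad <- min(n - 1L, max(3L * 2L * nrow(sos),
                         if (is.null(fs)) 100L else as.integer(3 * fs)))
  if (pad < 1L) stop("signal too short to filter", call. = FALSE)
  pre <- 2 * x[1] - x[(pad + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - pad)]
  ext <- c(pre, x, post)
  ext <- sosfilt_cpp(sos, ext)
  ext <- rev(sosfilt_cpp(sos, rev(ext)))
  ext[(pad + 1L):(pad + n)]
}

#' Preprocess a recording: power-line notch and high-pass
#'
#' Removes power-line interference with a narrow IIR notch and drifts/DC
#' with a high-pass Butterworth filter, both applied zero-phase.
#'
#' @param rec a [recording()].
#' @param notch_hz power-line frequency (50 Hz default).
#' @param highpass_hz high-pass cutoff (1 Hz default).
#' @param order Butterworth order for the high-pass.
#' @param q notch quality factor.
#' @return The preprocessed `recording` (same shape and channel order).
#' @export
preprocess <- function(rec, notch_hz = 50, highpass_hz = 1, order = 4,
                       q = 30) {
  stopifnot(inherits(rec, "recording"))
  if (notch_hz >= rec$fs / 2)
    stop("notch frequency must be below Nyquist", call. = FALSE)
  x <- filtfilt_sos(notch_sos(notch_hz, rec$fs, q = q), rec$samples)
  x <- filtfilt_sos(butter_sos(order, highpass_hz, rec$fs, "high"), x)
  rec$samples <- x
  rownames(rec$samples) <- rec$channel_labels
  rec
}

#' Band-decompose a recording and segment it into non-overlapping windows
#'
#' Each band is extracted with a zero-phase Butterworth band-pass applied to
#' the full-length signal (filtering before windowing avoids per-window edge
#' transients); the filtered signal is then cut into `floor(duration /
#' window_s)` non-overlapping windows, discarding any trailing partial
#' window. Window boundaries are identical across bands.
#'
#' @param rec a [recording()].
#' @param bands named list of `c(low, high)` Hz pairs ([eeg_bands()] by
#'   default).
#' @param window_s window length in seconds (2 s default).
#' @param order Butterworth order.
#' @return An object of class `band_windowed` with elements `bands`,
#'   `filtered` (per band, channels x samples), `windows` (per band, list of
#'   channels x window_samples matrices), `starts` (window start samples),
#'   `window_s`, `fs`, `channel_labels`, `subject_id`, `group`.
#' @export
band_window <- function(rec, bands = eeg_bands(), window_s = 2, order = 4) {
  stopifnot(inherits(rec, "recording"))
  nyq <- rec$fs / 2
  hi <- max(vapply(bands, function(b) b[2], 0))
  if (hi >= nyq)
    stop("band edges must be below Nyquist", call. = FALSE)
  n <- ncol(rec$samples)
  wlen <- as.integer(round(window_s * rec$fs))
  L <- n %/% wlen
  if (L < 2L)
    stop("recording too short: need at least 2 windows for a multilayer ",
         "network", call. = FALSE)
  starts <- (seq_len(L) - 1L) * wlen + 1L
  filtered <- lapply(bands, function(b) {
    filtfilt_sos(butter_sos(order, b, rec$fs, "band"), rec$samples)
  })
  windows <- lapply(filtered, function(f) {
    lapply(starts, function(s) f[, s:(s + wlen - 1L), drop = FALSE])
  })
  structure(list(bands = bands, filtered = filtered, windows = windows,
                 starts = starts, window_samples = wlen,
                 window_s = window_s, fs = rec$fs,
                 channel_labels = rec$channel_labels,
                 subject_id = rec$subject_id, group = rec$group),
            class = "band_windowed")
}

#' @export
print.band_windowed <- function(x, ...) {
  cat(sprintf("<band_windowed> %d bands x %d windows of %g s (%d channels)\n",
              length(x$bands), length(x$starts), x$window_s,
              length(x$channel_labels)))
  invisible(x)
}
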