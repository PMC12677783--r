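#' Standard 10-20 channel labels
#'
#' The 19 scalp sites of the international 10-20 electrode placement system,
#' in the conventional anterior-to-posterior order (Fp1 ... O2).
#'
#' @return Character vector of length 19.
#' @export
channels_1020 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3", "Cz",
    "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}

#' Canonical EEG frequency bands
#'
#' delta 1-4, theta 4-8, alpha 8-13, beta 13-30, gamma 30-45 Hz.
#'
#' @return Named list of `c(low, high)` pairs in Hz.
#' @export
eeg_bands <- function() {
  list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13),
       beta = c(13, 30), gamma = c(30, 45))
}

#' Construct a multichannel recording
#'
#' @param samples numeric matrix, channels x time (signal units).
#' @param channel_labels character vector, one label per channel.
#' @param fs sampling rate in Hz.
#' @param subject_id optional subject identifier.
#' @param group optional group label.
#' @return An object of class `recording`.
#' @export
recording <- function(samples, channel_labels = NULL, fs,
                      subject_id = NA_character_, group = NA_character_) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 2L)
    stop("a recording needs at least 2 channels", call. = FALSE)
  if (any(!is.finite(samples)))
    stop("recording contains NaN/Inf samples", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a positive scalar (Hz)", call. = FALSE)
  if (is.null(channel_labels))
    channel_labels <- rownames(samples)
  if (is.null(channel_labels))
    channel_labels <- paste0("ch", seq_len(nrow(samples)))
  if (length(channel_labels) != nrow(samples))
    stop("channel_labels length must match channel count", call. = FALSE)
  rownames(samples) <- channel_labels
  structure(list(samples = samples, channel_labels = channel_labels,
                 fs = fs, subject_id = subject_id, group = group),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs))
  if (!is.na(x$subject_id)) cat("  subject:", x$subject_id, "\n")
  if (!is.na(x$group)) cat("  group:  ", x$group, "\n")
  invisible(x)
}

#' Recording duration in seconds
#' @param rec a `recording`.
#' @return Duration in seconds.
#' @export
duration <- function(rec) ncol(rec$samples) / rec$fs
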