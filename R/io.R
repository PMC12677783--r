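# Recording I/O: EDF (European Data Format, 16-bit) and delimited matrix
# files with a JSON sidecar. No EDF package exists in this R stack, so a
# minimal standard-compliant reader/writer is included: fixed 256-byte
# header + 256 bytes per signal, then data records of 2-byte little-endian
# integers scaled between the physical and digital ranges.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

#' Write a recording to an EDF file
#'
#' One data record per second; samples are quantized to the 16-bit digital
#' range spanned by each channel's physical min/max.
#'
#' @param rec a [recording()]; `fs` and the duration must give an integer
#'   number of 1-second records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  ns <- nrow(rec$samples)
  n <- ncol(rec$samples)
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9 || n %% round(fs) != 0)
    stop("EDF export needs an integer number of 1-second records",
         call. = FALSE)
  n_rec <- n %/% round(fs)
  phys_min <- apply(rec$samples, 1, min)
  phys_max <- apply(rec$samples, 1, max)
  flat <- phys_max - phys_min < 1e-12
  phys_max[flat] <- phys_min[flat] + 1
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(ifelse(is.na(rec$subject_id), "X", rec$subject_id), 80),
    edf_pad("netreconfig synthetic", 80),
    edf_pad("01.01.26", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(1, 8), edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width)
    writeChar(paste0(vapply(vals, edf_pad, "", width = width),
                     collapse = ""), con, eos = NULL)
  field(rec$channel_labels, 16)
  field(rep("", ns), 80)                       # transducer
  field(rep("uV", ns), 8)                      # physical dimension
  field(formatC(phys_min, digits = 6, format = "g"), 8)
  field(formatC(phys_max, digits = 6, format = "g"), 8)
  field(rep(-32768, ns), 8)
  field(rep(32767, ns), 8)
  field(rep("", ns), 80)                       # prefiltering
  field(rep(round(fs), ns), 8)
  field(rep("", ns), 32)                       # reserved
  scale <- (phys_max - phys_min) / 65535
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * round(fs) + 1):(r * round(fs))
    for (ch in seq_len(ns)) {
      dig <- round((rec$samples[ch, idx] - phys_min[ch]) / scale[ch]) - 32768
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' Supports the subset written by [write_edf()]: identical sampling rate on
#' every signal, no annotation channels.
#'
#' @param path EDF file path.
#' @return A [recording()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) {
    x <- readChar(con, w, useBytes = TRUE)
    if (nchar(x, type = "bytes") < w)
      stop("truncated EDF header in ", path, call. = FALSE)
    trimws(x)
  }
  rd(8)                       # version
  pid <- rd(80); rd(80); rd(8); rd(8)
  rd(8)                       # header bytes
  rd(44)
  n_rec <- suppressWarnings(as.integer(rd(8)))
  dur <- suppressWarnings(as.numeric(rd(8)))
  ns <- suppressWarnings(as.integer(rd(4)))
  if (is.na(ns) || ns < 1 || is.na(n_rec) || is.na(dur))
    stop("malformed EDF header (record/signal counts) in ", path,
         call. = FALSE)
  rdn <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- rdn(16)
  rdn(80); rdn(8)
  phys_min <- as.numeric(rdn(8)); phys_max <- as.numeric(rdn(8))
  dmin <- as.numeric(rdn(8)); dmax <- as.numeric(rdn(8))
  rdn(80)
  spr <- as.integer(rdn(8))   # samples per record
  rdn(32)
  if (any(is.na(c(phys_min, phys_max, dmin, dmax, spr))))
    stop("malformed EDF signal header in ", path, call. = FALSE)
  if (length(unique(spr)) != 1L)
    stop("EDF signals with differing sampling rates are not supported",
         call. = FALSE)
  fs <- spr[1] / dur
  total <- n_rec * ns * spr[1]
  raw <- readBin(con, "integer", n = total, size = 2, endian = "little")
  if (length(raw) < total)
    stop("truncated EDF data section in ", path, call. = FALSE)
  x <- matrix(0, ns, n_rec * spr[1])
  pos <- 0L
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      idx <- ((r - 1) * spr[1] + 1):(r * spr[1])
      x[ch, idx] <- raw[pos + seq_len(spr[1])]
      pos <- pos + spr[1]
    }
  }
  for (ch in seq_len(ns))
    x[ch, ] <- phys_min[ch] + (x[ch, ] - dmin[ch]) *
      (phys_max[ch] - phys_min[ch]) / (dmax[ch] - dmin[ch])
  recording(x, labels, fs, subject_id = if (nzchar(pid)) pid else NA_character_)
}

#' Write a recording as a delimited matrix with JSON sidecar
#'
#' Line 1 is a tab-separated header of channel labels; each following line
#' holds one channel's samples. A `<path>.json` sidecar stores `fs`,
#' `subject_id` and `group`.
#'
#' @param rec a [recording()].
#' @param path output path (e.g. `subject.tsv`).
#' @return `path`, invisibly.
#' @export
write_recording_matrix <- function(rec, path) {
  con <- file(path, "w")
  writeLines(paste(rec$channel_labels, collapse = "\t"), con)
  utils::write.table(format(rec$samples, digits = 10, trim = TRUE,
                            scientific = TRUE),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  close(con)
  jsonlite::write_json(list(fs = rec$fs, subject_id = rec$subject_id,
                            group = rec$group),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a recording from EDF or delimited-matrix format
#'
#' @param path file path.
#' @param format `"edf"` or `"matrix"`.
#' @param fs sampling rate for matrix input when no `<path>.json` sidecar
#'   exists.
#' @return A [recording()].
#' @export
read_recording <- function(path, format = c("edf", "matrix"), fs = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "edf") return(read_edf(path))
  lines <- readLines(path)
  if (length(lines) < 3L)
    stop("matrix file needs a header and >= 2 channel rows", call. = FALSE)
  labels <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  x <- do.call(rbind, lapply(lines[-1], function(l)
    as.numeric(strsplit(l, "\t", fixed = TRUE)[[1]])))
  if (nrow(x) != length(labels))
    stop("channel count mismatch between header (", length(labels),
         ") and data rows (", nrow(x), ")", call. = FALSE)
  if (any(!is.finite(x)))
    stop("non-numeric or missing sample values in ", path, call. = FALSE)
  sidecar <- paste0(path, ".json")
  sid <- NA_character_; grp <- NA_character_
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    fs <- fs %||% meta$fs
    sid <- meta$subject_id %||% NA_character_
    grp <- meta$group %||% NA_character_
  }
  if (is.null(fs))
    stop("sampling rate missing: supply fs= or a JSON sidecar", call. = FALSE)
  recording(x, labels, fs,
            subject_id = if (is.null(sid)) NA_character_ else sid,
            group = if (is.null(grp)) NA_character_ else grp)
}

#' Write a partition sequence as TSV with JSON sidecar
#'
#' Rows are nodes, columns layers; the sidecar stores gamma, omega, seeds,
#' per-layer Q, p-values and validity flags when present.
#'
#' @param P a [partition_sequence()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_partition_tsv <- function(P, path) {
  lab <- P$labels
  df <- data.frame(node = rownames(lab) %||% paste0("n", seq_len(nrow(lab))),
                   lab, check.names = FALSE)
  colnames(df) <- c("node", paste0("layer", seq_len(ncol(lab))))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- P$params
  meta$quality <- P$quality
  meta$layer_valid <- P$layer_valid
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Write a synthetic cohort to disk
#'
#' Recordings go to `<dir>/<subject>.tsv` (matrix format; or `.edf`),
#' ground-truth partitions to `<dir>/<subject>_truth.tsv`, and a manifest
#' CSV (subject_id, group, file, seed) to `<dir>/manifest.csv`.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @param format `"matrix"` or `"edf"`.
#' @return Manifest data frame, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("matrix", "edf")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- attr(cohort, "manifest")
  manifest$file <- NA_character_
  for (k in seq_along(cohort)) {
    rec <- cohort[[k]]$recording
    ext <- if (format == "edf") ".edf" else ".tsv"
    f <- file.path(dir, paste0(rec$subject_id, ext))
    if (format == "edf") write_edf(rec, f) else write_recording_matrix(rec, f)
    truth <- expand_schedule(cohort[[k]]$schedule)
    utils::write.table(truth, file.path(dir, paste0(rec$subject_id,
                                                    "_truth.tsv")),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
    manifest$file[k] <- f
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Write a multilayer network to a layered text container
#'
#' Layers are stacked row-blocks in one TSV (N rows per layer); a JSON
#' sidecar records band, window length, node labels and layer count.
#'
#' @param net a [multilayer_network()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_multilayer <- function(net, path) {
  stopifnot(inherits(net, "multilayer_network"))
  stacked <- do.call(rbind, net$layers)
  utils::write.table(format(stacked, digits = 10, trim = TRUE),
                     path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(band = net$band, subject_id = net$subject_id,
                            window_s = net$window_s,
                            node_labels = net$node_labels,
                            n_layers = length(net$layers)),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Read a multilayer network written by [write_multilayer()]
#'
#' @param path TSV path (with its `.json` sidecar alongside).
#' @return A [multilayer_network()].
#' @export
read_multilayer <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  x <- as.matrix(utils::read.table(path, sep = "\t"))
  N <- length(meta$node_labels)
  L <- meta$n_layers
  if (nrow(x) != N * L)
    stop("layer container has ", nrow(x), " rows, expected ", N * L,
         call. = FALSE)
  layers <- lapply(seq_len(L), function(s) {
    W <- unname(x[(s - 1L) * N + seq_len(N), , drop = FALSE])
    W <- (W + t(W)) / 2 # symmetrize away text round-off
    dimnames(W) <- NULL
    W
  })
  multilayer_network(layers,
                     node_labels = unlist(meta$node_labels),
                     band = meta$band %||% NA_character_,
                     subject_id = meta$subject_id %||% NA_character_,
                     window_s = meta$window_s %||% NA_real_)
}

#' Write a cohesion matrix as TSV with node labels
#'
#' @param counts cohesion count matrix (from [cohesion()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohesion_tsv <- function(counts, path) {
  df <- data.frame(node = rownames(counts) %||%
                     paste0("n", seq_len(nrow(counts))),
                   counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
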