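# Preprocessing, band decomposition and recording I/O.

fs <- 500

test_that("recording constructor enforces its invariants", {
  x <- matrix(rnorm(4 * 100), 4)
  expect_s3_class(recording(x, fs = fs), "recording")
  expect_error(recording(x[1, , drop = FALSE], fs = fs), "2 channels")
  x[2, 5] <- NaN
  expect_error(recording(x, fs = fs), "NaN")
  expect_error(recording(matrix(0, 3, 10) + 1, fs = -1), "positive")
})

test_that("preprocess attenuates the notch frequency and DC, passes 10 Hz", {
  t <- seq_len(10 * fs) / fs
  mk <- function(sig) recording(rbind(sig, sig), fs = fs)
  rms <- function(x) sqrt(mean(x^2))

  r50 <- preprocess(mk(sin(2 * pi * 50 * t)))
  expect_lt(rms(r50$samples[1, ]), 0.1 * rms(sin(2 * pi * 50 * t)))

  rdc <- preprocess(mk(rep(1, length(t))))
  expect_lt(rms(rdc$samples[1, ]), 1e-3)

  r10 <- preprocess(mk(sin(2 * pi * 10 * t)))
  expect_equal(rms(r10$samples[1, ]), rms(sin(2 * pi * 10 * t)),
               tolerance = 0.05)

  # shape and channel order unchanged
  expect_identical(dim(r10$samples), c(2L, length(t)))
  expect_error(preprocess(mk(t), notch_hz = 400), "Nyquist")
})

test_that("band_window window count, truncation and band selectivity", {
  set.seed(1)
  rec60 <- recording(matrix(rnorm(2 * 60 * fs), 2), fs = fs)
  bw <- band_window(rec60)
  expect_length(bw$windows$alpha, 30L)
  expect_identical(ncol(bw$windows$delta[[1]]), 1000L)

  rec61 <- recording(matrix(rnorm(2 * 61 * fs), 2), fs = fs)
  expect_length(band_window(rec61)$windows$theta, 30L)

  t <- seq_len(20 * fs) / fs
  rec10 <- recording(rbind(sin(2 * pi * 10 * t), cos(2 * pi * 10 * t)),
                     fs = fs)
  bw10 <- band_window(rec10)
  rms <- function(m) sqrt(mean(m^2))
  expect_gt(rms(bw10$filtered$alpha), 10 * rms(bw10$filtered$beta))

  expect_error(band_window(recording(matrix(rnorm(2 * fs * 3), 2), fs = fs),
                           window_s = 2.5), "2 windows")
})

test_that("filtering is linear and windows tile the filtered signal", {
  set.seed(2)
  x <- matrix(rnorm(2 * 12 * fs), 2)
  reca <- recording(x, fs = fs)
  recb <- recording(3.7 * x, fs = fs)
  bwa <- band_window(reca)
  bwb <- band_window(recb)
  expect_equal(bwb$filtered$alpha, 3.7 * bwa$filtered$alpha,
               tolerance = 1e-9)
  tiled <- do.call(cbind, bwa$windows$beta)
  expect_identical(tiled, bwa$filtered$beta[, seq_len(ncol(tiled))])
})

test_that("EDF round trip preserves samples within 16-bit quantization", {
  set.seed(3)
  rec <- recording(matrix(rnorm(3 * 2 * fs), 3), c("A", "B", "C"), fs,
                   subject_id = "s7")
  f <- tempfile(fileext = ".edf")
  write_edf(rec, f)
  back <- read_edf(f)
  expect_identical(back$channel_labels, rec$channel_labels)
  expect_equal(back$fs, fs)
  rng <- apply(rec$samples, 1, function(r) diff(range(r)))
  expect_lt(max(abs(back$samples - rec$samples)), max(rng) / 65535 * 2)

  # truncated file -> parse error
  sz <- file.size(f)
  con <- file(f, "rb"); raw <- readBin(con, "raw", sz); close(con)
  con <- file(f, "wb"); writeBin(raw[1:(sz / 2)], con); close(con)
  expect_error(read_edf(f), "truncated")
})

test_that("matrix format round trip and error contracts", {
  set.seed(4)
  rec <- recording(matrix(rnorm(19 * 300), 19), channels_1020(), fs,
                   subject_id = "m1", group = "control")
  f <- tempfile(fileext = ".tsv")
  write_recording_matrix(rec, f)
  back <- read_recording(f, "matrix")
  expect_equal(back$samples, rec$samples, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_identical(back$channel_labels, channels_1020())
  expect_identical(back$group, "control")

  # header/data mismatch
  lines <- readLines(f)
  writeLines(lines[-3], f)
  file.remove(paste0(f, ".json"))
  expect_error(read_recording(f, "matrix", fs = fs), "mismatch")
  expect_error(read_recording(tempfile(), "matrix"), "not found")
})

test_that("multilayer network round-trips through the layered container", {
  set.seed(5)
  layers <- lapply(1:4, function(i) {
    W <- matrix(runif(25), 5, 5)
    W <- (W + t(W)) / 2; diag(W) <- 0; W
  })
  net <- multilayer_network(layers, node_labels = paste0("e", 1:5),
                            band = "alpha", subject_id = "s9",
                            window_s = 2)
  f <- tempfile(fileext = ".tsv")
  write_multilayer(net, f)
  back <- read_multilayer(f)
  expect_identical(back$band, "alpha")
  expect_length(back$layers, 4L)
  expect_equal(back$layers[[3]], layers[[3]], tolerance = 1e-8,
               ignore_attr = TRUE)
  # truncated container -> error
  lines <- readLines(f)
  writeLines(lines[1:10], f)
  expect_error(read_multilayer(f), "expected")
})
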