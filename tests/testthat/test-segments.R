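test_that("segment fixtures round-trip through CSV + JSON sidecar", {
  x <- tiny_pool()
  x$provenance <- list(pooled = c("O1", "O2"))
  path <- file.path(withr::local_tempdir(), "tiny.csv")
  write_segments(x, path)
  y <- read_segments(path)
  expect_identical(y$data, unname(x$data))
  expect_equal(y$fs, x$fs)
  expect_equal(y$t_start_ms, x$t_start_ms)
  expect_equal(y$subject_id, "tiny")
  expect_equal(nrow(y$data), 3L)
  expect_equal(ncol(y$data), 5L)

  # full double precision survives the text format
  z <- x
  z$data[] <- z$data + pi * 1e-8
  write_segments(z, path)
  expect_identical(read_segments(path)$data, unname(z$data))
})

test_that("malformed fixtures are rejected with a named reason", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "bad.csv")
  writeLines(c("1,2,3", "4,5"), path)
  jsonlite::write_json(list(fs = 10, t_start_ms = -200), snrlb:::sidecar_path(path),
                       auto_unbox = TRUE)
  expect_error(read_segments(path), "ragged")

  writeLines(c("1,2,3", "4,x,6"), path)
  expect_error(read_segments(path), "non-numeric")

  writeLines(c("1,2,3", "4,5,6"), path)
  jsonlite::write_json(list(fs = 0, t_start_ms = -200), snrlb:::sidecar_path(path),
                       auto_unbox = TRUE)
  expect_error(read_segments(path), "fs must be positive")

  jsonlite::write_json(list(t_start_ms = -200), snrlb:::sidecar_path(path),
                       auto_unbox = TRUE)
  expect_error(read_segments(path), "missing required field 'fs'")

  file.remove(snrlb:::sidecar_path(path))
  expect_error(read_segments(path), "sidecar")
})

test_that("baseline correction zeroes the pre-stimulus mean and is idempotent", {
  x <- tiny_pool()
  b <- time_window(-200, 0)
  y <- baseline_correct(x, b)
  idx <- 1:2  # samples at -200 and -100 ms
  expect_equal(unname(rowMeans(y$data[, idx])), c(0, 0, 0))
  # constant 5 uV segment becomes all-zero
  z <- baseline_correct(segment_set(matrix(5, 1, 5), 10, -200), b)
  expect_equal(as.vector(z$data), rep(0, 5))
  # arithmetic: baseline mean 2, post value 7 -> 5
  expect_equal(baseline_correct(
    segment_set(matrix(c(2, 2, 7, 7, 7), 1), 10, -200), b)$data[1, 3], 5)
  # idempotent
  expect_identical(baseline_correct(y, b)$data, y$data)
})

test_that("linear detrending matches the least-squares oracle", {
  # pure line -> zero
  k <- 0:49
  x <- segment_set(rbind(3 + 0.01 * k, rep(0, 50)), fs = 100,
                   t_start_ms = -200)
  y <- linear_detrend(x)
  expect_lt(max(abs(y$data)), 1e-9)

  # line + sine: residual equals the lm() residual, per segment
  set.seed(1)
  w <- 2 - 0.03 * k + sin(2 * pi * k / 12)
  v <- rnorm(50)
  x2 <- linear_detrend(segment_set(rbind(w, v), 100, -200))
  expect_equal(unname(x2$data[1, ]), unname(resid(lm(w ~ k))))
  expect_equal(unname(x2$data[2, ]), unname(resid(lm(v ~ k))))
})

test_that("artifact rejection drops strictly exceeding segments only", {
  mk <- function(peaks) {
    t(vapply(peaks, function(p) c(0, p, 0, 0, 0), numeric(5)))
  }
  x <- segment_set(mk(c(100, -200, 149)), 10, -200)
  y <- reject_artifacts(x, 150)
  expect_equal(nrow(y$data), 2L)
  expect_equal(y$provenance$n_rejected, 1L)
  # boundary: exactly 150 uV is retained
  y2 <- reject_artifacts(segment_set(mk(150), 10, -200), 150)
  expect_equal(nrow(y2$data), 1L)
  # brute-force survivor check on a random pool with planted spikes
  set.seed(7)
  pool <- matrix(rnorm(60 * 20, sd = 60), 60)
  pool[sample(60, 12), 5] <- 400
  x3 <- segment_set(pool, 250, -200)
  y3 <- reject_artifacts(x3, 150)
  keep <- vapply(seq_len(60), function(i) all(abs(pool[i, ]) <= 150),
                 logical(1))
  expect_identical(y3$data, pool[keep, , drop = FALSE])
  expect_equal(y3$provenance$n_rejected + nrow(y3$data), 60L)
  # an emptied pool is allowed but refused downstream
  y4 <- reject_artifacts(x3, 1e-12)
  expect_equal(nrow(y4$data), 0L)
  expect_error(bootstrap_snr(y4, quick_cfg()), "empty")
})

test_that("channel pooling averages trials or defers to per-channel SNR", {
  a <- quick_subject(10, seed = 1, n_segments = 40)
  a$channel_label <- "O1"
  b <- a
  b$channel_label <- "O2"
  avg <- pool_channels(list(a, b))
  expect_equal(avg$data, a$data)
  expect_equal(avg$channel_label, "O1+O2")
  # polarity reversal cancels under channel averaging...
  neg <- a
  neg$data <- -neg$data
  expect_equal(max(abs(pool_channels(list(a, neg))$data)), 0)
  # ...which motivates the average-snr mode
  cs <- pool_channels(list(a, neg), mode = "average-snr")
  expect_s3_class(cs, "channel_set")
  cfg <- quick_cfg(seed = 3)
  d <- bootstrap_snr(cs, cfg)
  # SNR is invariant to sign, so per-channel SNRs agree with the
  # single-channel run under the same seed
  expect_equal(d$snr_values, bootstrap_snr(a, cfg)$snr_values)
  # three channels: per-trial mean equals element-wise brute force
  c3 <- a
  c3$data <- a$data * 0.5 + 1
  pooled <- pool_channels(list(a, b, c3))
  expect_equal(pooled$data, (a$data + b$data + c3$data) / 3)
  # mismatched shapes refuse to pool
  short <- segment_set(a$data[, 1:10], a$fs, a$t_start_ms)
  expect_error(pool_channels(list(a, short)), "differ")
})

test_that("noise mixing degrades exactly the requested fraction", {
  sig <- quick_subject(10, seed = 21, n_segments = 40)
  noi <- quick_subject(10, signal_present = FALSE, seed = 22,
                       n_segments = 40)
  expect_error(mix_noise_segments(sig, noi, 1.2), "proportion")
  # proportion 0: identical
  expect_equal(mix_noise_segments(sig, noi, 0)$data, sig$data)
  # proportion 1 with exact negatives: all-zero pool
  neg <- sig
  neg$data <- -neg$data
  mixed <- mix_noise_segments(sig, neg, 1, seed = 5)
  # each row is sig[i,] + (-sig[j,]) for a permutation j; with n_mix = n
  # and without-replacement draws every noise row is used once, so row
  # sums cancel in aggregate
  expect_equal(colSums(mixed$data), rep(0, ncol(sig$data)))
  # untouched segments are bit-identical, and exactly n - round(p*n)
  for (p in c(0.25, 0.5)) {
    m <- mix_noise_segments(sig, noi, p, seed = 9)
    untouched <- vapply(seq_len(40), function(i)
      identical(m$data[i, ], sig$data[i, ]), logical(1))
    expect_equal(sum(untouched), 40 - round(p * 40))
    expect_equal(m$provenance$n_mixed, round(p * 40))
  }
})

test_that("expected SNR_LB decreases with the mixed-noise proportion", {
  cfg <- quick_cfg(S = 50, B = 499)
  props <- c(0, 0.5, 1)
  set.seed(31)
  means <- sapply(props, function(p) {
    mean(replicate(8, {
      sig <- quick_subject(8)
      noi <- quick_subject(25, signal_present = FALSE)
      snr_lb(mix_noise_segments(sig, noi, p), cfg)
    }))
  })
  expect_true(all(diff(means) < 0))
})
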