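test_that("rms matches closed forms", {
  # constant 2 uV over any window
  expect_equal(rms(rep(2, 10), time_window(-200, 800), 10, -200), 2)
  # [3, -4] -> sqrt(12.5)
  expect_equal(rms(c(3, -4), time_window(0, 2), 1000, 0), sqrt(12.5))
  # unit sine over an integer number of periods -> 1/sqrt(2)
  k <- 0:999
  w <- sin(2 * pi * 10 * k / 1000)
  expect_equal(rms(w, time_window(0, 1000), 1000, 0), 1 / sqrt(2),
               tolerance = 1e-3)
  # empty window is refused
  expect_error(rms(1:10, time_window(10, 40), 10, -200), "no samples")
})

test_that("snr_erp reproduces the dB identities and scale invariance", {
  b <- time_window(-200, 0)
  i <- time_window(0, 200)
  fs <- 10  # 100 ms per sample: 2 baseline, 2 post samples
  mk <- function(pre, post) c(pre, -pre, post, -post)
  # equal RMS -> 0 dB
  expect_equal(snr_erp(mk(3, 3), b, i, fs, -200), 0)
  # RMS_post = 10 x RMS_pre -> 20 dB
  expect_equal(snr_erp(mk(1, 10), b, i, fs, -200), 20)
  # RMS_post = 0.5 x RMS_pre -> -6.0206 dB
  expect_equal(snr_erp(mk(2, 1), b, i, fs, -200), -20 * log10(2),
               tolerance = 1e-6)
  expect_equal(snr_erp(mk(2, 1), b, i, fs, -200), -6.0206,
               tolerance = 1e-4)
  # scale invariance under any c > 0
  w <- c(0.3, -1.2, 4.5, 2.2)
  for (c_ in c(1e-3, 0.5, 7, 1e4)) {
    expect_equal(snr_erp(c_ * w, b, i, fs, -200),
                 snr_erp(w, b, i, fs, -200))
  }
  # flat baseline has no noise estimate
  expect_error(snr_erp(c(0, 0, 1, 2), b, i, fs, -200), "degenerate")
})

test_that("percentile CI matches the linear-interpolation quantile oracle", {
  # values 1..100 at level 0.90: order-statistic interpolation gives
  # 1 + 0.05 * 99 = 5.95 and 1 + 0.95 * 99 = 95.05
  ci <- snr_ci(1:100, level = 0.90)
  expect_equal(ci$lower_db, 5.95)
  expect_equal(ci$upper_db, 95.05)
  expect_equal(ci$mean_db, 50.5)
  # agreement with stats::quantile type 7 on arbitrary draws
  set.seed(4)
  v <- rnorm(501)
  ci2 <- snr_ci(v, level = 0.80)
  expect_equal(c(ci2$lower_db, ci2$upper_db),
               unname(quantile(v, c(0.10, 0.90), type = 7)))
  # all values equal -> zero-width interval
  ci3 <- snr_ci(rep(3.3, 50))
  expect_equal(ci3$lower_db, 3.3)
  expect_equal(ci3$upper_db, 3.3)
})

test_that("identical segments give a degenerate bootstrap distribution", {
  seg <- c(1, -2, 5, 3, -1)
  x <- segment_set(matrix(seg, 8, 5, byrow = TRUE), 10, -200)
  d <- bootstrap_snr(x, bootstrap_config(S = 3, B = 200,
                                         interest = time_window(0, 300),
                                         seed = 1))
  expect_equal(length(unique(d$snr_values)), 1L)
  ci <- snr_ci(d)
  expect_equal(ci$upper_db - ci$lower_db, 0)
  # and the value agrees with the direct single-waveform statistic
  w <- seg - mean(seg[1:2])
  expect_equal(d$snr_values[1],
               snr_erp(w, time_window(-200, 0), time_window(0, 300),
                       10, -200))
})

test_that("bootstrap SNR frequencies match exhaustive enumeration for tiny pools", {
  # N = 3, S = 2: 9 equally likely ordered resamples
  set.seed(42)
  segs <- matrix(rnorm(3 * 6), 3, 6)
  x <- segment_set(segs, fs = 10, t_start_ms = -200)
  b <- time_window(-200, 0)
  i <- time_window(0, 400)
  # oracle: enumerate all ordered pairs directly
  snr_of <- function(idx) {
    w <- colMeans(segs[idx, , drop = FALSE])
    w <- w - mean(w[1:2])
    snr_erp(w, b, i, 10, -200)
  }
  pairs <- expand.grid(a = 1:3, b = 1:3)
  exact <- mapply(function(a, b_) snr_of(c(a, b_)), pairs$a, pairs$b)
  exact_tab <- table(round(exact, 10)) / length(exact)

  B <- 2e5
  d <- bootstrap_snr(x, bootstrap_config(S = 2, B = B, baseline = b,
                                         interest = i, seed = 9))
  emp_tab <- table(round(d$snr_values, 10)) / B
  expect_setequal(names(emp_tab), names(exact_tab))
  for (v in names(exact_tab)) {
    p <- exact_tab[[v]]
    se <- sqrt(p * (1 - p) / B)
    expect_lt(abs(emp_tab[[v]] - p), 3 * se + 1e-12)
  }
})

test_that("bootstrap runs are reproducible and windows are validated", {
  x <- quick_subject(15, seed = 2)
  cfg <- quick_cfg(seed = 77)
  d1 <- bootstrap_snr(x, cfg)
  d2 <- bootstrap_snr(x, cfg)
  expect_identical(d1$snr_values, d2$snr_values)
  expect_identical(d1$median_erp, d2$median_erp)
  # median ERP is one of the bootstrap ERPs, at the median SNR
  expect_equal(
    snr_erp(d1$median_erp, cfg$baseline, cfg$interest, x$fs,
            x$t_start_ms),
    d1$snr_values[which.min(abs(d1$snr_values -
                                  median(d1$snr_values)))])
  # SNR_LB <= median <= upper bound at level 0.90
  ci <- snr_ci(d1)
  expect_lte(ci$lower_db, median(d1$snr_values))
  expect_lte(median(d1$snr_values), ci$upper_db)
  # overlapping windows are refused
  expect_error(
    bootstrap_snr(x, bootstrap_config(S = 10, B = 9,
                                      baseline = time_window(-200, 0),
                                      interest = time_window(-50, 800))),
    "overlap")
  # S may exceed N (resampling with replacement from the full pool)
  small <- segment_set(x$data[1:4, ], x$fs, x$t_start_ms)
  d3 <- bootstrap_snr(small, quick_cfg(S = 20, B = 50, seed = 1))
  expect_length(d3$snr_values, 50L)
})

test_that("subject classification applies the tie rule and 0 dB warning", {
  expect_false(classify_subject(-0.37, 3.0))
  expect_true(classify_subject(3.31, 3.0))
  expect_true(classify_subject(3.0, 3.0))   # ties pass
  expect_true(classify_subject(12.68, 3.0))
  expect_warning(classify_subject(1, -0.5), "below 0 dB")
})

test_that("sample summaries report the six statistics and failure count", {
  s <- sample_summary(c(1, 2, 3), criterion = 3)
  expect_equal(s$mean, 2)
  expect_equal(s$median, 2)
  expect_equal(s$min, 1)
  expect_equal(s$max, 3)
  expect_equal(s$n_failing, 2L)
  # single value: sd and iqr are 0
  s1 <- sample_summary(5)
  expect_equal(s1$sd, 0)
  expect_equal(s1$iqr, 0)
  # spreadsheet-style recomputation on a fixed list
  v <- c(-0.37, 2.1, 3.31, 5.2, 6.96, 7.4, 9.8, 12.68)
  s2 <- sample_summary(v, criterion = 3)
  expect_equal(s2$mean, sum(v) / length(v))
  expect_equal(s2$median, (5.2 + 6.96) / 2)
  expect_equal(s2$sd, sqrt(sum((v - mean(v))^2) / (length(v) - 1)))
  expect_equal(s2$iqr, unname(diff(quantile(v, c(0.25, 0.75)))))
  expect_equal(s2$n_failing, 2L)
  expect_error(sample_summary(numeric(0)), "non-empty")
})

test_that("choose_S follows the per-condition trial count rules", {
  expect_identical(choose_S(rep(100, 8)), 100L)      # 800 / 8
  expect_identical(choose_S(rep(112, 16)), 112L)
  expect_identical(choose_S(c(200, 200, 50, 52), balanced = FALSE), 51L)
  # balanced rule equals round(N / n_conditions)
  expect_identical(choose_S(c(90, 100, 110)), 100L)
  # rounding is half away from zero
  expect_identical(choose_S(c(100, 101)), 101L)
  expect_error(choose_S(numeric(0)), "non-empty")
  expect_error(choose_S(c(10, 0)), ">= 1")
})
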