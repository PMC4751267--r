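#' Configuration of the bootstrap SNR-CI procedure
#'
#' @param S Number of segments averaged into each bootstrap ERP. Should
#'   equal the number of trials that will form each condition mean; see
#'   [choose_S()].
#' @param B Number of bootstrap iterations (default 9999, the count at
#'   which the run-to-run error of the lower bound falls below about
#'   0.1 dB).
#' @param ci_level Confidence level of the percentile interval (default
#'   0.90).
#' @param baseline Pre-stimulus [time_window()] supplying the noise RMS
#'   (default -200 to 0 ms).
#' @param interest Post-stimulus [time_window()] of interest supplying
#'   the signal RMS (default 0 to 800 ms).
#' @param seed Optional RNG seed; `NULL` draws from the current stream.
#' @return An object of class `bootstrap_config`.
#' @export
bootstrap_config <- function(S, B = 9999, ci_level = 0.90,
                             baseline = time_window(-200, 0),
                             interest = time_window(0, 800),
                             seed = NULL) {
  stopifnot(is.numeric(S), length(S) == 1L, S >= 1,
            is.numeric(B), length(B) == 1L, B >= 1,
            is.numeric(ci_level), length(ci_level) == 1L,
            ci_level > 0, ci_level < 1)
  baseline <- as_time_window(baseline)
  interest <- as_time_window(interest)
  structure(list(S = as.integer(S), B = as.integer(B),
                 ci_level = ci_level, baseline = baseline,
                 interest = interest, seed = seed),
            class = "bootstrap_config")
}

#' Root mean square of a waveform over a time window
#'
#' @param w Numeric waveform (microvolts), one value per sample.
#' @param window A [time_window()] in ms; half-open `[start, end)`.
#' @param fs Sampling rate in Hz.
#' @param t_start_ms Time of the first sample in ms.
#' @return RMS voltage over the window.
#' @export
rms <- function(w, window, fs, t_start_ms) {
  idx <- window_samples(window, length(w), fs, t_start_ms)
  sqrt(mean(w[idx]^2))
}

#' ERP signal-to-noise ratio in decibels
#'
#' `SNR = 20 * log10(RMS_post / RMS_pre)`: the RMS voltage of the
#' post-stimulus window of interest relative to the RMS of the
#' pre-stimulus baseline, for a baseline-corrected waveform. 0 dB means
#' the post-stimulus interval carries no more amplitude than baseline
#' noise.
#'
#' @param w Baseline-corrected waveform (microvolts).
#' @param baseline Pre-stimulus [time_window()].
#' @param interest Post-stimulus [time_window()].
#' @param fs Sampling rate in Hz.
#' @param t_start_ms Time of the first sample in ms.
#' @return SNR in dB. Scaling `w` by any positive constant leaves the
#'   value unchanged.
#' @export
snr_erp <- function(w, baseline, interest, fs, t_start_ms) {
  rms_pre <- rms(w, baseline, fs, t_start_ms)
  if (rms_pre == 0)
    stop("degenerate baseline: RMS of the baseline window is zero, ",
         "no noise estimate is possible", call. = FALSE)
  20 * log10(rms(w, interest, fs, t_start_ms) / rms_pre)
}

# B columns of segment-index counts: each column tabulates S indices
# drawn uniformly with replacement from 1..N.
resample_counts <- function(N, S, B) {
  idx <- sample.int(N, S * B, replace = TRUE)
  cnt <- tabulate(idx + N * rep.int(0:(B - 1L), rep.int(S, B)),
                  nbins = N * B)
  matrix(as.double(cnt), nrow = N, ncol = B)
}

#' Bootstrap the SNR distribution of a subject's segment pool
#'
#' For each of `B` iterations, `S` segments are drawn uniformly with
#' replacement from the full pool of `N` segments, signal averaged,
#' baseline corrected, and scored with [snr_erp()] over the configured
#' windows. The resulting `B` SNR values form the distribution from
#' which the SNR-CI and its lower bound are taken, and the bootstrap
#' ERP whose SNR sits at the distribution median is retained as a
#' representative waveform.
#'
#' For a `channel_set` (see [pool_channels()] mode `"average-snr"`),
#' the same resampled trial indices are applied to every channel, SNR
#' is computed per channel, and the per-iteration SNR is the mean
#' across channels; the representative waveform is the across-channel
#' mean ERP at the median-SNR iteration.
#'
#' @param x A `segment_set` or `channel_set`.
#' @param cfg A [bootstrap_config()].
#' @param truth Optional reference waveform (one value per sample).
#'   When supplied, the squared Pearson correlation between each
#'   bootstrap ERP and `truth` over the full epoch is returned as
#'   `r2_values` (used by the simulation studies, where the underlying
#'   waveform is known).
#' @return An object of class `snr_distribution` with elements
#'   `snr_values` (length `B`, dB), `median_erp`, `config`, `n_pool`,
#'   `fs`, `t_start_ms` and optionally `r2_values`.
#' @export
bootstrap_snr <- function(x, cfg, truth = NULL) {
  stopifnot(inherits(cfg, "bootstrap_config"))
  channels <- if (inherits(x, "channel_set")) unclass(x) else list(x)
  for (ch in channels) stopifnot(inherits(ch, "segment_set"))
  ref <- channels[[1L]]
  N <- nrow(ref$data)
  if (N < 1L) stop("segment pool is empty", call. = FALSE)
  n <- ncol(ref$data)
  bidx <- window_samples(cfg$baseline, n, ref$fs, ref$t_start_ms)
  iidx <- window_samples(cfg$interest, n, ref$fs, ref$t_start_ms)
  if (length(intersect(bidx, iidx)))
    stop("baseline and interest windows overlap", call. = FALSE)

  with_seed(cfg$seed, {
    counts <- resample_counts(N, cfg$S, cfg$B)
    snr_mat <- matrix(NA_real_, cfg$B, length(channels))
    erp_sum <- 0
    for (ci in seq_along(channels)) {
      erps <- crossprod(counts, channels[[ci]]$data) / cfg$S
      erps <- erps - rowMeans(erps[, bidx, drop = FALSE])
      rpre <- sqrt(rowMeans(erps[, bidx, drop = FALSE]^2))
      if (any(rpre == 0))
        stop("degenerate baseline: a bootstrap ERP has zero baseline ",
             "RMS", call. = FALSE)
      rpost <- sqrt(rowMeans(erps[, iidx, drop = FALSE]^2))
      snr_mat[, ci] <- 20 * log10(rpost / rpre)
      erp_sum <- erp_sum + erps
    }
    erps <- erp_sum / length(channels)
    snr_values <- rowMeans(snr_mat)
    med_i <- which.min(abs(snr_values - stats::median(snr_values)))
    r2_values <- NULL
    if (!is.null(truth)) {
      stopifnot(length(truth) == n)
      tc <- truth - mean(truth)
      tss <- sum(tc^2)
      if (tss == 0)
        stop("undefined fit: reference waveform has zero variance",
             call. = FALSE)
      ec <- erps - rowMeans(erps)
      ess <- rowSums(ec^2)
      if (any(ess == 0))
        stop("undefined fit: a bootstrap ERP has zero variance",
             call. = FALSE)
      r2_values <- as.vector((ec %*% tc)^2 / (ess * tss))
    }
    structure(
      list(snr_values = snr_values, median_erp = erps[med_i, ],
           r2_values = r2_values, config = cfg, n_pool = N,
           fs = ref$fs, t_start_ms = ref$t_start_ms),
      class = "snr_distribution")
  })
}

#' @export
print.snr_distribution <- function(x, ...) {
  ci <- snr_ci(x)
  cat(sprintf(
    "<snr_distribution: B = %d, N = %d, S = %d; mean %.2f dB, %d%% CI [%.2f, %.2f] dB>\n",
    length(x$snr_values), x$n_pool, x$config$S, ci$mean_db,
    round(100 * ci$level), ci$lower_db, ci$upper_db))
  invisible(x)
}

#' Percentile confidence interval of a bootstrap SNR distribution
#'
#' Equal-tailed percentile interval with linear interpolation between
#' order statistics (the default empirical quantile definition,
#' [stats::quantile()] type 7). The lower bound is the SNR_LB
#' statistic.
#'
#' @param d An `snr_distribution` from [bootstrap_snr()], or a numeric
#'   vector of SNR values.
#' @param level Confidence level; defaults to the level in the
#'   distribution's config (0.90 for a plain vector).
#' @return An object of class `snr_ci` with `mean_db`, `lower_db`,
#'   `upper_db` and `level`.
#' @export
snr_ci <- function(d, level = NULL) {
  values <- if (inherits(d, "snr_distribution")) d$snr_values else d
  if (is.null(level))
    level <- if (inherits(d, "snr_distribution")) d$config$ci_level
             else 0.90
  stopifnot(is.numeric(values), length(values) >= 1L,
            level > 0, level < 1)
  alpha <- (1 - level) / 2
  q <- stats::quantile(values, probs = c(alpha, 1 - alpha), names = FALSE,
                       type = 7)
  structure(list(mean_db = mean(values), lower_db = q[1L],
                 upper_db = q[2L], level = level),
            class = "snr_ci")
}

#' @export
print.snr_ci <- function(x, ...) {
  cat(sprintf("<snr_ci: mean %.3f dB, %d%% CI [%.3f, %.3f] dB>\n",
              x$mean_db, round(100 * x$level), x$lower_db, x$upper_db))
  invisible(x)
}

#' Lower bound of the bootstrap SNR confidence interval (SNR_LB)
#'
#' Convenience wrapper: runs [bootstrap_snr()] and returns the lower
#' bound of the percentile interval, the subject-exclusion statistic.
#'
#' @param x A `segment_set` or `channel_set`.
#' @param cfg A [bootstrap_config()].
#' @return SNR_LB in dB.
#' @export
snr_lb <- function(x, cfg) {
  snr_ci(bootstrap_snr(x, cfg))$lower_db
}

#' Classify a subject against an SNR_LB criterion
#'
#' A subject passes when its SNR_LB meets or exceeds the criterion
#' (ties pass). The recommended minimum criterion is 3.0 dB; criteria
#' below 0 dB are accepted with a warning, since 0 dB is the absolute
#' statistical minimum for the presence of an evoked response.
#'
#' @param snr_lb SNR_LB in dB (vectorised).
#' @param criterion Criterion in dB (default 3.0).
#' @return Logical: `TRUE` = pass (retain), `FALSE` = fail (exclude).
#' @export
classify_subject <- function(snr_lb, criterion = 3.0) {
  stopifnot(is.numeric(snr_lb), is.numeric(criterion),
            length(criterion) == 1L, is.finite(criterion))
  if (criterion < 0)
    warning("criterion ", criterion, " dB is below 0 dB, the absolute ",
            "statistical minimum for the presence of an evoked response",
            call. = FALSE)
  snr_lb >= criterion
}

#' Summary statistics of a sample's SNR_LB values
#'
#' The recommended report for an ERP sample: mean, median, SD,
#' inter-quartile range, minimum and maximum of the per-subject SNR_LB,
#' plus the number of subjects failing a stated criterion.
#'
#' @param snr_lbs Numeric vector of per-subject SNR_LB values (dB).
#' @param criterion Exclusion criterion in dB (default 3.0).
#' @return An object of class `sample_summary`.
#' @export
sample_summary <- function(snr_lbs, criterion = 3.0) {
  if (!is.numeric(snr_lbs) || length(snr_lbs) < 1L)
    stop("snr_lbs must be a non-empty numeric vector", call. = FALSE)
  structure(
    list(mean = mean(snr_lbs), median = stats::median(snr_lbs),
         sd = if (length(snr_lbs) > 1L) stats::sd(snr_lbs) else 0,
         iqr = stats::IQR(snr_lbs), min = min(snr_lbs),
         max = max(snr_lbs), n_subjects = length(snr_lbs),
         criterion = criterion,
         n_failing = sum(!classify_subject(snr_lbs, criterion))),
    class = "sample_summary")
}

#' @export
print.sample_summary <- function(x, ...) {
  cat(sprintf(
    paste0("<sample_summary: n = %d; mean %.2f, median %.2f, SD %.2f, ",
           "IQR %.2f, range [%.2f, %.2f] dB; %d failing %.1f dB>\n"),
    x$n_subjects, x$mean, x$median, x$sd, x$iqr, x$min, x$max,
    x$n_failing, x$criterion))
  invisible(x)
}

round_half_up <- function(x) floor(x + 0.5)

#' Choose the number of segments per bootstrap average
#'
#' `S` should equal the number of trials that will enter each condition
#' mean after artifact rejection. For balanced designs this is the mean
#' trial count across conditions (equivalently `N / n_conditions`).
#' For unbalanced designs `S` should reflect the conditions with the
#' fewest trials: the mean over the minimum-trial group, defined here
#' as all conditions within 10% of the smallest count. Results are
#' rounded to the nearest integer (halves away from zero).
#'
#' @param trials_per_condition Vector of per-condition trial counts
#'   surviving artifact rejection.
#' @param balanced `TRUE` for a balanced design (mean over all
#'   conditions), `FALSE` to average only the minimum-trial group.
#' @return Integer `S`.
#' @examples
#' choose_S(rep(100, 8))                    # 800 trials, 8 conditions -> 100
#' choose_S(c(200, 200, 50, 52), balanced = FALSE)  # -> 51
#' @export
choose_S <- function(trials_per_condition, balanced = TRUE) {
  if (!is.numeric(trials_per_condition) ||
      length(trials_per_condition) < 1L)
    stop("trials_per_condition must be a non-empty numeric vector",
         call. = FALSE)
  if (any(trials_per_condition < 1))
    stop("all trial counts must be >= 1", call. = FALSE)
  counts <- if (balanced) trials_per_condition
            else trials_per_condition[
              trials_per_condition <= 1.1 * min(trials_per_condition)]
  as.integer(round_half_up(mean(counts)))
}
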