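#' Sweep a dB criterion grid into an ROC analysis
#'
#' Classifies each score as positive when it meets or exceeds a
#' criterion, for every criterion on the grid, and accumulates the
#' resulting true- and false-positive rates into an ROC curve. The
#' area under the curve is computed by trapezoidal integration over
#' the swept points with the endpoints (0,0) and (1,1) appended.
#' Accuracy at each criterion is balanced accuracy, the mean of the
#' true-positive and true-negative rates; the reported peak criterion
#' is the median of the grid values attaining the maximum (ties occur
#' whenever accuracy plateaus at the grid resolution).
#'
#' @param scores Numeric scores (e.g. per-subject SNR_LB, dB).
#' @param labels Logical vector: `TRUE` for the positive class.
#' @param criteria Criterion grid (default 401 criteria from -20 to
#'   +20 dB in 0.1 dB steps).
#' @return An object of class `roc_study` with `criteria`, `tpr`,
#'   `fpr`, `accuracy`, `auc`, `peak_criterion`, `peak_accuracy`,
#'   and the inputs `scores` and `labels`.
#' @export
roc_study <- function(scores, labels,
                      criteria = seq(-20, 20, by = 0.1)) {
  stopifnot(is.numeric(scores), is.logical(labels),
            length(scores) == length(labels), length(scores) >= 1L)
  pos <- scores[labels]
  neg <- scores[!labels]
  tpr <- vapply(criteria, function(cr) mean(pos >= cr), numeric(1L))
  fpr <- vapply(criteria, function(cr) mean(neg >= cr), numeric(1L))
  if (length(pos) && length(neg)) {
    ord <- order(fpr, tpr)
    xs <- c(0, fpr[ord], 1)
    ys <- c(0, tpr[ord], 1)
    auc <- sum(diff(xs) * (ys[-1L] + ys[-length(ys)]) / 2)
    accuracy <- (tpr + (1 - fpr)) / 2
  } else {
    # degenerate single-class input: no ROC, accuracy over the class
    # that is present
    auc <- NA_real_
    accuracy <- if (length(pos)) tpr else 1 - fpr
  }
  peak_i <- which(accuracy == max(accuracy))
  peak_criterion <- stats::median(criteria[peak_i])
  structure(
    list(criteria = criteria, tpr = tpr, fpr = fpr,
         accuracy = accuracy, auc = auc,
         peak_criterion = peak_criterion,
         peak_accuracy = max(accuracy),
         scores = scores, labels = labels),
    class = "roc_study")
}

#' @export
print.roc_study <- function(x, ...) {
  cat(sprintf(
    "<roc_study: %d scores, AUC %.3f, peak accuracy %.1f%% at %.2f dB>\n",
    length(x$scores), x$auc, 100 * x$peak_accuracy, x$peak_criterion))
  invisible(x)
}

# Generate one synthetic subject and bootstrap it in the current RNG
# stream; returns SNR_LB, and optionally the distribution object.
synth_snr_lb <- function(multiplier, cfg, n_segments, fs,
                         signal_present = TRUE, truth = NULL,
                         keep = FALSE) {
  x <- synth_subject(synthetic_spec(
    n_segments = n_segments, fs = fs, noise_multiplier = multiplier,
    signal_present = signal_present))
  d <- bootstrap_snr(x, cfg, truth = truth)
  if (keep) d else snr_ci(d)$lower_db
}

canonical_truth <- function(fs, epoch = time_window(-200, 800)) {
  n <- round((epoch$end_ms - epoch$start_ms) / 1000 * fs)
  canonical_waveform(
    (epoch$start_ms + (seq_len(n) - 1L) * 1000 / fs) / 1000)
}

#' Run-to-run error of SNR_LB as a function of bootstrap count
#'
#' Measures how the Monte Carlo error of the SNR_LB estimate shrinks
#' as the number of bootstrap iterations grows. For each synthetic
#' subject and each value of `B`, SNR_LB is recomputed `n_repeats`
#' times with fresh resampling; the per-subject SDs of these repeats
#' are pooled across subjects as their root mean square, and the 90%
#' run-to-run interval half-width is `qnorm(0.95)` times the pooled SD
#' (normal approximation).
#'
#' @param n_subjects Number of synthetic subjects (noise multipliers
#'   drawn uniformly from `multiplier_range`).
#' @param n_repeats Repeated SNR_LB estimates per subject and `B`.
#' @param b_grid Ascending bootstrap counts to test.
#' @param S Segments per bootstrap average.
#' @param ci_level Confidence level of the SNR interval.
#' @param n_segments,fs Synthetic subject size and sampling rate.
#' @param multiplier_range Range of the uniform noise-multiplier draw.
#' @param seed RNG seed for the whole study.
#' @return A data.frame with columns `B`, `pooled_sd` and
#'   `ci_halfwidth` (dB).
#' @export
bootstrap_count_study <- function(n_subjects = 10, n_repeats = 10,
                                  b_grid = c(199, 499, 999, 1999,
                                             4999, 9999, 19999, 39999),
                                  S = 200, ci_level = 0.90,
                                  n_segments = 800, fs = 1000,
                                  multiplier_range = c(5, 35),
                                  seed = NULL) {
  stopifnot(n_repeats >= 2, !is.unsorted(b_grid))
  with_seed(seed, {
    sds <- matrix(NA_real_, n_subjects, length(b_grid))
    for (si in seq_len(n_subjects)) {
      m <- stats::runif(1, multiplier_range[1L], multiplier_range[2L])
      x <- synth_subject(synthetic_spec(
        n_segments = n_segments, fs = fs, noise_multiplier = m))
      for (bi in seq_along(b_grid)) {
        cfg <- bootstrap_config(S = S, B = b_grid[bi],
                                ci_level = ci_level)
        reps <- replicate(n_repeats, snr_ci(bootstrap_snr(x, cfg))$lower_db)
        sds[si, bi] <- stats::sd(reps)
      }
    }
    pooled <- sqrt(colMeans(sds^2))
    data.frame(B = b_grid, pooled_sd = pooled,
               ci_halfwidth = stats::qnorm(0.95) * pooled)
  })
}

#' Presence study: classify signal-present vs signal-absent subjects
#'
#' Generates equal numbers of synthetic subjects with and without an
#' underlying ERP, computes SNR_LB for each, and sweeps a dB criterion
#' grid into an ROC analysis of how well SNR_LB separates the two
#' classes.
#'
#' @param n_per_class Subjects per class.
#' @param cfg A [bootstrap_config()] (typically `S = 200`).
#' @param n_segments,fs Synthetic subject size and sampling rate.
#' @param multiplier_range Range of the uniform noise-multiplier draw
#'   (applied to both classes; SNR is scale invariant, so the
#'   multiplier of a pure-noise subject is immaterial).
#' @param criteria Criterion grid in dB.
#' @param seed RNG seed for the whole study.
#' @return A [roc_study()] result; positives are signal-present
#'   subjects.
#' @export
presence_roc <- function(n_per_class = 200,
                         cfg = bootstrap_config(S = 200, B = 1999),
                         n_segments = 800, fs = 1000,
                         multiplier_range = c(5, 35),
                         criteria = seq(-20, 20, by = 0.1),
                         seed = NULL) {
  stopifnot(n_per_class >= 2)
  with_seed(seed, {
    labels <- rep(c(TRUE, FALSE), each = n_per_class)
    scores <- vapply(labels, function(present) {
      m <- stats::runif(1, multiplier_range[1L], multiplier_range[2L])
      synth_snr_lb(m, cfg, n_segments, fs, signal_present = present)
    }, numeric(1L))
    roc_study(scores, labels, criteria)
  })
}

#' Squared Pearson correlation between a waveform and a reference
#'
#' The fit statistic used to grade simulated ERPs against the known
#' underlying waveform. Invariant under affine transforms of either
#' waveform.
#'
#' @param erp Waveform (e.g. a bootstrap ERP).
#' @param truth Reference waveform of equal length.
#' @param window Optional [time_window()] restricting the comparison;
#'   default full epoch.
#' @param fs,t_start_ms Timing metadata, required when `window` is
#'   given.
#' @return R-squared in `[0, 1]`.
#' @export
fit_r2 <- function(erp, truth, window = NULL, fs = NULL,
                   t_start_ms = NULL) {
  stopifnot(length(erp) == length(truth))
  if (!is.null(window)) {
    idx <- window_samples(window, length(erp), fs, t_start_ms)
    erp <- erp[idx]
    truth <- truth[idx]
  }
  if (stats::sd(erp) == 0 || stats::sd(truth) == 0)
    stop("undefined fit: an input waveform has zero variance",
         call. = FALSE)
  stats::cor(erp, truth)^2
}

#' Correlation between SNR_LB and fit to the true waveform
#'
#' Generates synthetic subjects across the noise-multiplier range;
#' for each, records SNR_LB and the mean over all bootstrap iterations
#' of the R-squared between the bootstrap ERP and the canonical
#' waveform. Reports the Spearman rank correlation between the two
#' across subjects — the evidence that SNR_LB tracks true signal
#' quality.
#'
#' @param n_subjects Number of subjects (at least 10).
#' @param cfg A [bootstrap_config()].
#' @param n_segments,fs Synthetic subject size and sampling rate.
#' @param multiplier_range Range of the uniform noise-multiplier draw.
#' @param seed RNG seed.
#' @return A list with `rho` (Spearman) and `subjects`, a data.frame
#'   of `multiplier`, `snr_lb` and `mean_r2`.
#' @export
fit_correlation_study <- function(n_subjects = 300,
                                  cfg = bootstrap_config(S = 200,
                                                         B = 1999),
                                  n_segments = 800, fs = 1000,
                                  multiplier_range = c(5, 35),
                                  seed = NULL) {
  stopifnot(n_subjects >= 10)
  truth <- canonical_truth(fs)
  with_seed(seed, {
    rows <- lapply(seq_len(n_subjects), function(i) {
      m <- stats::runif(1, multiplier_range[1L], multiplier_range[2L])
      d <- synth_snr_lb(m, cfg, n_segments, fs, truth = truth,
                        keep = TRUE)
      c(multiplier = m, snr_lb = snr_ci(d)$lower_db,
        mean_r2 = mean(d$r2_values))
    })
    subjects <- as.data.frame(do.call(rbind, rows))
    list(rho = stats::cor(subjects$snr_lb, subjects$mean_r2,
                          method = "spearman"),
         subjects = subjects)
  })
}

#' Calibrate the noise multiplier at which mean SNR_LB crosses zero
#'
#' Iterative grid-refinement search: the mean SNR_LB over `n_probe`
#' synthetic subjects is probed on a multiplier grid spanning
#' `bounds`, the sign change is bracketed, and the bracket is refined
#' on successively finer grids until the probed mean at the
#' interpolated crossing is within `tolerance_db` of zero.
#'
#' @param bounds Multiplier interval that must bracket the zero
#'   crossing of mean SNR_LB.
#' @param tolerance_db Absolute tolerance on the mean SNR_LB at the
#'   returned multiplier (default 0.05 dB).
#' @param n_probe Subjects per probe level.
#' @param cfg A [bootstrap_config()] (a modest `B` such as 999
#'   suffices here).
#' @param n_levels Grid points in the first round (later rounds use 5).
#' @param n_segments,fs Synthetic subject size and sampling rate.
#' @param max_rounds Maximum refinement rounds.
#' @param seed RNG seed.
#' @return A list of class `zero_calibration` with `multiplier`, the
#'   probed `mean_snr_lb` at that multiplier, and the probe `trace`.
#' @export
calibrate_zero_noise <- function(bounds = c(5, 60),
                                 tolerance_db = 0.05, n_probe = 50,
                                 cfg = bootstrap_config(S = 200,
                                                        B = 999),
                                 n_levels = 10, n_segments = 800,
                                 fs = 1000, max_rounds = 6,
                                 seed = NULL) {
  stopifnot(length(bounds) == 2L, bounds[1L] < bounds[2L],
            n_probe >= 2, n_levels >= 3)
  probe <- function(m) {
    mean(replicate(n_probe,
                   synth_snr_lb(m, cfg, n_segments, fs)))
  }
  with_seed(seed, {
    lo <- bounds[1L]; hi <- bounds[2L]
    trace <- list()
    est <- NA_real_; m_est <- NA_real_
    for (round in seq_len(max_rounds)) {
      k <- if (round == 1L) n_levels else 5L
      grid <- seq(lo, hi, length.out = k)
      means <- vapply(grid, probe, numeric(1L))
      trace[[round]] <- data.frame(round = round, multiplier = grid,
                                   mean_snr_lb = means)
      cross <- which(means[-k] > 0 & means[-1L] <= 0)
      if (!length(cross))
        stop("mean SNR_LB does not change sign inside [", lo, ", ",
             hi, "]; widen the bounds", call. = FALSE)
      i <- cross[1L]
      lo <- grid[i]; hi <- grid[i + 1L]
      # linear interpolation of the crossing inside the bracket
      est <- lo + (hi - lo) * means[i] / (means[i] - means[i + 1L])
      m_est <- probe(est)
      trace[[round]] <- rbind(
        trace[[round]],
        data.frame(round = round, multiplier = est,
                   mean_snr_lb = m_est))
      if (abs(m_est) <= tolerance_db) break
    }
    structure(list(multiplier = est, mean_snr_lb = m_est,
                   tolerance_db = tolerance_db,
                   trace = do.call(rbind, trace)),
              class = "zero_calibration")
  })
}

#' @export
print.zero_calibration <- function(x, ...) {
  cat(sprintf(
    "<zero_calibration: multiplier %.2f (probed mean SNR_LB %+.3f dB, tolerance %.2f dB)>\n",
    x$multiplier, x$mean_snr_lb, x$tolerance_db))
  invisible(x)
}

#' Generate and score a cohort at the zero-SNR noise level
#'
#' Builds the reference cohort used to define the fit threshold:
#' subjects whose noise multiplier is drawn normally around the
#' zero-calibrated level (SD 0.25), so the cohort's mean SNR_LB is
#' approximately 0 dB. For each subject the study records SNR_LB and
#' the mean bootstrap R-squared against the canonical waveform. The
#' 95th percentile of the cohort's mean-R-squared distribution (the
#' upper bound of its 90% equal-tailed interval) is returned as
#' `threshold_r2`: the minimum fit a subject must beat to count as
#' better than waveforms at the statistical boundary of signal and
#' noise.
#'
#' @param multiplier Zero-calibrated noise multiplier (see
#'   [calibrate_zero_noise()]).
#' @param multiplier_sd SD of the normal draw around `multiplier`
#'   (default 0.25).
#' @param n_subjects Cohort size.
#' @param cfg A [bootstrap_config()].
#' @param n_segments,fs Synthetic subject size and sampling rate.
#' @param seed RNG seed.
#' @return A list of class `zero_cohort` with `subjects` (data.frame
#'   of `multiplier`, `snr_lb`, `mean_r2`), `snr_mean`, `snr_ci`,
#'   `r2_mean`, `r2_ci` (90% equal-tailed, across subjects) and
#'   `threshold_r2`.
#' @export
zero_cohort_study <- function(multiplier, multiplier_sd = 0.25,
                              n_subjects = 300,
                              cfg = bootstrap_config(S = 200,
                                                     B = 1999),
                              n_segments = 800, fs = 1000,
                              seed = NULL) {
  truth <- canonical_truth(fs)
  with_seed(seed, {
    rows <- lapply(seq_len(n_subjects), function(i) {
      m <- stats::rnorm(1, multiplier, multiplier_sd)
      m <- max(m, 1e-6)
      d <- synth_snr_lb(m, cfg, n_segments, fs, truth = truth,
                        keep = TRUE)
      c(multiplier = m, snr_lb = snr_ci(d)$lower_db,
        mean_r2 = mean(d$r2_values))
    })
    subjects <- as.data.frame(do.call(rbind, rows))
    snr_q <- stats::quantile(subjects$snr_lb, c(0.05, 0.95),
                             names = FALSE, type = 7)
    r2_q <- stats::quantile(subjects$mean_r2, c(0.05, 0.95),
                            names = FALSE, type = 7)
    structure(list(subjects = subjects,
                   snr_mean = mean(subjects$snr_lb), snr_ci = snr_q,
                   r2_mean = mean(subjects$mean_r2), r2_ci = r2_q,
                   threshold_r2 = r2_q[2L]),
              class = "zero_cohort")
  })
}

#' @export
print.zero_cohort <- function(x, ...) {
  cat(sprintf(
    paste0("<zero_cohort: n = %d; mean SNR_LB %+.3f dB, 90%% CI ",
           "[%.3f, %.3f]; mean R2 %.4f, 90%% CI [%.4f, %.4f]; ",
           "threshold R2 %.4f>\n"),
    nrow(x$subjects), x$snr_mean, x$snr_ci[1L], x$snr_ci[2L],
    x$r2_mean, x$r2_ci[1L], x$r2_ci[2L], x$threshold_r2))
  invisible(x)
}

#' Quality study: classify subjects passing vs failing a fit threshold
#'
#' Generates synthetic subjects across the noise-multiplier range and
#' labels each as passing when the lower bound of the 90% percentile
#' interval of its per-bootstrap R-squared values strictly exceeds
#' `threshold_r2` (the zero-cohort fit threshold). SNR_LB is then
#' swept over the criterion grid into an ROC analysis of how well it
#' recovers the pass/fail labels — the study behind the recommended
#' 3.0 dB exclusion criterion.
#'
#' @param n_subjects Number of subjects.
#' @param threshold_r2 Fit threshold in `(0, 1)`; see
#'   [zero_cohort_study()].
#' @param cfg A [bootstrap_config()].
#' @param n_segments,fs Synthetic subject size and sampling rate.
#' @param multiplier_range Range of the uniform noise-multiplier draw.
#' @param criteria Criterion grid in dB.
#' @param r2_ci_level Level of the per-subject R-squared percentile
#'   interval (default 0.90).
#' @param seed RNG seed.
#' @return A [roc_study()] result; positives are passing subjects.
#'   `$n_pass` gives the number of passing subjects.
#' @export
quality_roc <- function(n_subjects = 400, threshold_r2,
                        cfg = bootstrap_config(S = 200, B = 1999),
                        n_segments = 800, fs = 1000,
                        multiplier_range = c(5, 35),
                        criteria = seq(-20, 20, by = 0.1),
                        r2_ci_level = 0.90, seed = NULL) {
  stopifnot(is.numeric(threshold_r2), threshold_r2 >= 0,
            threshold_r2 < 1)
  truth <- canonical_truth(fs)
  with_seed(seed, {
    rows <- lapply(seq_len(n_subjects), function(i) {
      m <- stats::runif(1, multiplier_range[1L], multiplier_range[2L])
      d <- synth_snr_lb(m, cfg, n_segments, fs, truth = truth,
                        keep = TRUE)
      r2_lb <- stats::quantile(d$r2_values, (1 - r2_ci_level) / 2,
                               names = FALSE, type = 7)
      c(snr_lb = snr_ci(d)$lower_db, r2_lb = r2_lb)
    })
    tab <- as.data.frame(do.call(rbind, rows))
    res <- roc_study(tab$snr_lb, tab$r2_lb > threshold_r2, criteria)
    res$threshold_r2 <- threshold_r2
    res$n_pass <- sum(res$labels)
    res
  })
}

#' Sweep the per-average segment count S on a fixed pool
#'
#' Recomputes SNR_LB on one segment pool for each value of `S` and
#' reports, for each dB threshold, the smallest `S` at which SNR_LB
#' first meets the threshold together with that run's median-SNR
#' bootstrap ERP — illustrating how quality criteria translate into
#' required trial counts.
#'
#' @param x A `segment_set` (or `channel_set`).
#' @param s_grid Ascending values of `S` to test.
#' @param thresholds_db dB thresholds to resolve.
#' @param cfg A [bootstrap_config()]; its `S` is ignored in favour of
#'   `s_grid`.
#' @param seed RNG seed for the whole sweep.
#' @return A list with `per_s` (data.frame of `S`, `snr_lb`), `table`
#'   (data.frame of `threshold_db`, `first_S`, `snr_lb`; `first_S` is
#'   `NA` when no tested `S` reaches the threshold) and `median_erps`
#'   (one waveform per achieved threshold).
#' @export
s_sweep <- function(x, s_grid, thresholds_db,
                    cfg = bootstrap_config(S = 2, B = 1999),
                    seed = NULL) {
  stopifnot(!is.unsorted(s_grid), length(s_grid) >= 1L)
  with_seed(seed, {
    lbs <- numeric(length(s_grid))
    erps <- vector("list", length(s_grid))
    for (i in seq_along(s_grid)) {
      cfg_i <- bootstrap_config(S = s_grid[i], B = cfg$B,
                                ci_level = cfg$ci_level,
                                baseline = cfg$baseline,
                                interest = cfg$interest)
      d <- bootstrap_snr(x, cfg_i)
      lbs[i] <- snr_ci(d)$lower_db
      erps[[i]] <- d$median_erp
    }
    first <- vapply(thresholds_db, function(thr) {
      hit <- which(lbs >= thr)
      if (length(hit)) hit[1L] else NA_integer_
    }, integer(1L))
    list(per_s = data.frame(S = s_grid, snr_lb = lbs),
         table = data.frame(
           threshold_db = thresholds_db,
           first_S = ifelse(is.na(first), NA_integer_, s_grid[first]),
           snr_lb = ifelse(is.na(first), NA_real_, lbs[first])),
         median_erps = stats::setNames(
           erps[first[!is.na(first)]],
           thresholds_db[!is.na(first)]))
  })
}
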