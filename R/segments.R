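#' Construct a pool of stimulus-locked EEG segments
#'
#' A `segment_set` holds every usable segment (trial) from one subject
#' at one (possibly pooled) channel: a rectangular matrix of voltages in
#' microvolts, one row per segment, plus the timing metadata needed to
#' map time windows onto samples. Sample k (0-based) of every segment
#' sits at `t_start_ms + k * 1000 / fs` milliseconds relative to
#' stimulus onset.
#'
#' @param data Numeric matrix, `n_segments x n_samples`, in microvolts.
#' @param fs Sampling rate in Hz.
#' @param t_start_ms Epoch start in ms relative to stimulus onset
#'   (negative for a pre-stimulus baseline).
#' @param subject_id Subject label.
#' @param channel_label Label of the (pooled) channel.
#' @param provenance Free-form list of metadata (pooled electrodes,
#'   simulation parameters, rejection counts, ...).
#' @return An object of class `segment_set`.
#' @seealso [read_segments()], [baseline_correct()], [bootstrap_snr()]
#' @export
segment_set <- function(data, fs, t_start_ms, subject_id = "subject",
                        channel_label = "pooled", provenance = list()) {
  new_segment_set(data, fs, t_start_ms, subject_id, channel_label,
                  provenance, allow_empty = FALSE)
}

# Internal constructor; artifact rejection may legitimately empty a pool.
new_segment_set <- function(data, fs, t_start_ms, subject_id,
                            channel_label, provenance,
                            allow_empty = FALSE) {
  if (!is.matrix(data)) data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (anyNA(data)) stop("data contains non-numeric or missing cells",
                        call. = FALSE)
  if (!allow_empty && nrow(data) < 1L)
    stop("data must contain at least one segment", call. = FALSE)
  if (ncol(data) < 2L)
    stop("data must contain at least two samples per segment",
         call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be positive", call. = FALSE)
  if (!is.numeric(t_start_ms) || length(t_start_ms) != 1L ||
      !is.finite(t_start_ms))
    stop("t_start_ms must be a finite number", call. = FALSE)
  structure(
    list(data = data, fs = fs, t_start_ms = t_start_ms,
         subject_id = as.character(subject_id)[1L],
         channel_label = as.character(channel_label)[1L],
         provenance = provenance),
    class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf(
    "<segment_set '%s' @ %s: %d segments x %d samples, fs %g Hz, epoch [%g, %g) ms>\n",
    x$subject_id, x$channel_label, nrow(x$data), ncol(x$data), x$fs,
    x$t_start_ms, x$t_start_ms + ncol(x$data) * 1000 / x$fs))
  invisible(x)
}

#' Number of segments in a pool
#' @param x A `segment_set`.
#' @return Integer count of segments.
#' @export
n_segments <- function(x) {
  stopifnot(inherits(x, "segment_set"))
  nrow(x$data)
}

#' Epoch time axis in milliseconds
#' @param x A `segment_set`.
#' @return Numeric vector of sample times in ms relative to stimulus.
#' @export
time_axis <- function(x) {
  stopifnot(inherits(x, "segment_set"))
  x$t_start_ms + (seq_len(ncol(x$data)) - 1L) * 1000 / x$fs
}

sidecar_path <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    sub("\\.csv$", ".json", path, ignore.case = TRUE)
  } else {
    paste0(path, ".json")
  }
}

#' Read a segment pool from a CSV matrix plus JSON sidecar
#'
#' The fixture format is a headerless comma-delimited matrix (rows =
#' segments, columns = samples, microvolts) together with a JSON sidecar
#' named after the CSV (`.csv` replaced by `.json`) carrying at least
#' `fs` and `t_start_ms`, optionally `subject_id`, `channel_label` and
#' `provenance`.
#'
#' @param path Path to the CSV matrix.
#' @return A validated [segment_set()] whose matrix dimensions match the
#'   sidecar.
#' @seealso [write_segments()]
#' @export
read_segments <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  side <- sidecar_path(path)
  if (!file.exists(side))
    stop("missing JSON sidecar: ", side, call. = FALSE)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  for (field in c("fs", "t_start_ms")) {
    if (is.null(meta[[field]]))
      stop("sidecar is missing required field '", field, "'",
           call. = FALSE)
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L) stop("CSV matrix is empty", call. = FALSE)
  parts <- strsplit(lines, ",", fixed = TRUE)
  lens <- lengths(parts)
  if (length(unique(lens)) != 1L)
    stop("ragged rows: segment rows have differing sample counts",
         call. = FALSE)
  vals <- suppressWarnings(as.numeric(unlist(parts, use.names = FALSE)))
  if (anyNA(vals))
    stop("data contains non-numeric or missing cells", call. = FALSE)
  mat <- matrix(vals, nrow = length(lines), ncol = lens[1L], byrow = TRUE)
  if (!is.null(meta$n_segments) && meta$n_segments != nrow(mat))
    stop("sidecar n_segments (", meta$n_segments,
         ") does not match matrix rows (", nrow(mat), ")", call. = FALSE)
  if (!is.null(meta$n_samples) && meta$n_samples != ncol(mat))
    stop("sidecar n_samples (", meta$n_samples,
         ") does not match matrix columns (", ncol(mat), ")",
         call. = FALSE)
  segment_set(
    mat, fs = meta$fs, t_start_ms = meta$t_start_ms,
    subject_id = meta$subject_id %||% "subject",
    channel_label = meta$channel_label %||% "pooled",
    provenance = if (is.null(meta$provenance)) list()
                 else as.list(meta$provenance))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a segment pool to a CSV matrix plus JSON sidecar
#'
#' Values are written with 17 significant digits so a
#' [read_segments()] round trip reproduces the matrix bit for bit.
#'
#' @param x A `segment_set`.
#' @param path Output CSV path; the sidecar is written alongside.
#' @return `path`, invisibly.
#' @export
write_segments <- function(x, path) {
  stopifnot(inherits(x, "segment_set"))
  txt <- sprintf("%.17g", x$data)
  dim(txt) <- dim(x$data)
  writeLines(apply(txt, 1L, paste, collapse = ","), path)
  meta <- list(fs = x$fs, t_start_ms = x$t_start_ms,
               subject_id = x$subject_id,
               channel_label = x$channel_label,
               n_segments = nrow(x$data), n_samples = ncol(x$data))
  if (length(x$provenance)) meta$provenance <- x$provenance
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Baseline-correct every segment
#'
#' Subtracts from each segment its mean voltage over the baseline
#' window, so the pre-stimulus interval of every segment averages zero.
#' The operation is idempotent.
#'
#' @param x A `segment_set`.
#' @param baseline A [time_window()] inside the epoch (default the
#'   conventional pre-stimulus interval, -200 to 0 ms).
#' @return The corrected `segment_set`.
#' @export
baseline_correct <- function(x, baseline = time_window(-200, 0)) {
  stopifnot(inherits(x, "segment_set"))
  idx <- window_samples(baseline, ncol(x$data), x$fs, x$t_start_ms)
  x$data <- x$data - rowMeans(x$data[, idx, drop = FALSE])
  x
}

#' Remove a least-squares linear trend from every segment
#'
#' Fits and subtracts an ordinary least-squares line over the full
#' epoch, per segment, as is common before baseline correction when
#' slow drifts contaminate epochs.
#'
#' @param x A `segment_set`.
#' @return The detrended `segment_set`.
#' @export
linear_detrend <- function(x) {
  stopifnot(inherits(x, "segment_set"))
  n <- ncol(x$data)
  X <- cbind(1, seq_len(n) - 1)
  coef <- solve(crossprod(X), crossprod(X, t(x$data)))
  x$data <- x$data - t(X %*% coef)
  x
}

#' Reject segments exceeding an absolute voltage threshold
#'
#' Drops every segment whose absolute voltage strictly exceeds
#' `threshold_uv` at any sample (a segment peaking exactly at the
#' threshold is retained). Survivor order is preserved and the number
#' of rejected segments is recorded in `provenance$n_rejected`. The
#' result may be an empty pool; downstream operations refuse empty
#' pools.
#'
#' @param x A `segment_set`.
#' @param threshold_uv Positive rejection threshold in microvolts
#'   (default 150).
#' @return The surviving `segment_set`.
#' @export
reject_artifacts <- function(x, threshold_uv = 150) {
  stopifnot(inherits(x, "segment_set"))
  if (!is.numeric(threshold_uv) || length(threshold_uv) != 1L ||
      threshold_uv <= 0)
    stop("threshold_uv must be positive", call. = FALSE)
  peak <- apply(abs(x$data), 1L, max)
  keep <- peak <= threshold_uv
  prov <- x$provenance
  prov$n_rejected <- sum(!keep)
  prov$artifact_threshold_uv <- threshold_uv
  new_segment_set(x$data[keep, , drop = FALSE], x$fs, x$t_start_ms,
                  x$subject_id, x$channel_label, prov,
                  allow_empty = TRUE)
}

#' Pool segment sets recorded at several electrodes
#'
#' Two pooling strategies are supported. `"average-channel"` collapses
#' the channels into a single virtual electrode by averaging, trial by
#' trial, across channels; this is the usual choice when the component
#' has the same polarity at every pooled site. `"average-snr"` keeps
#' the channels separate and returns them as a `channel_set`:
#' [bootstrap_snr()] then resamples the same trial indices in every
#' channel, computes SNR per channel, and averages the SNRs within each
#' bootstrap iteration — appropriate when a component reverses polarity
#' between electrodes, where channel-averaging would cancel the signal.
#'
#' @param channels List of `segment_set`s over identical trials (same
#'   trial count, sampling rate and epoch).
#' @param mode `"average-channel"` or `"average-snr"`.
#' @return A `segment_set` (`"average-channel"`) or a `channel_set`
#'   (`"average-snr"`).
#' @export
pool_channels <- function(channels,
                          mode = c("average-channel", "average-snr")) {
  mode <- match.arg(mode)
  stopifnot(is.list(channels), length(channels) >= 1L)
  if (!all(vapply(channels, inherits, logical(1L), "segment_set")))
    stop("channels must be a list of segment_set objects", call. = FALSE)
  ref <- channels[[1L]]
  for (ch in channels[-1L]) {
    if (!identical(dim(ch$data), dim(ref$data)) ||
        ch$fs != ref$fs || ch$t_start_ms != ref$t_start_ms)
      stop("channels differ in trial count, sample count, fs or epoch",
           call. = FALSE)
  }
  labels <- vapply(channels, `[[`, character(1L), "channel_label")
  if (mode == "average-snr") {
    return(structure(channels, class = "channel_set",
                     pooling = "average-snr"))
  }
  pooled <- Reduce(`+`, lapply(channels, `[[`, "data")) / length(channels)
  segment_set(pooled, ref$fs, ref$t_start_ms, ref$subject_id,
              channel_label = paste(labels, collapse = "+"),
              provenance = c(ref$provenance,
                             list(pooled_channels = labels,
                                  pooling = "average-channel")))
}

#' @export
print.channel_set <- function(x, ...) {
  cat(sprintf("<channel_set: %d channels, pooling '%s'>\n", length(x),
              attr(x, "pooling")))
  invisible(x)
}

#' Degrade a pool by summing noise segments into a fraction of trials
#'
#' Emulates a controlled loss of signal quality: a uniformly random
#' subset of `round(proportion * n)` signal segments is summed,
#' element-wise, with noise segments (EEG drawn from arbitrary,
#' non-stimulus-locked time points). Noise segments are drawn without
#' replacement, recycling with replacement when the noise pool is
#' smaller than the subset. The remaining segments pass through
#' unchanged.
#'
#' @param signal A `segment_set` of stimulus-locked segments.
#' @param noise A `segment_set` of signal-absent segments with the same
#'   sampling rate and epoch.
#' @param proportion Fraction of segments to degrade, in `[0, 1]`.
#' @param seed Optional RNG seed for the subset draw.
#' @return The mixed `segment_set`; `provenance$mix_proportion` records
#'   the level.
#' @export
mix_noise_segments <- function(signal, noise, proportion, seed = NULL) {
  stopifnot(inherits(signal, "segment_set"))
  if (!is.numeric(proportion) || length(proportion) != 1L ||
      is.na(proportion) || proportion < 0 || proportion > 1)
    stop("proportion must lie in [0, 1]", call. = FALSE)
  n <- nrow(signal$data)
  n_mix <- round(proportion * n)
  if (n_mix > 0L) {
    stopifnot(inherits(noise, "segment_set"))
    if (nrow(noise$data) < 1L)
      stop("noise pool is empty", call. = FALSE)
    if (!identical(ncol(noise$data), ncol(signal$data)) ||
        noise$fs != signal$fs || noise$t_start_ms != signal$t_start_ms)
      stop("signal and noise pools differ in sample count, fs or epoch",
           call. = FALSE)
    signal$data <- with_seed(seed, {
      pick <- sample.int(n, n_mix)
      src <- if (nrow(noise$data) >= n_mix) {
        sample.int(nrow(noise$data), n_mix)
      } else {
        sample.int(nrow(noise$data), n_mix, replace = TRUE)
      }
      out <- signal$data
      out[pick, ] <- out[pick, , drop = FALSE] +
        noise$data[src, , drop = FALSE]
      out
    })
  }
  signal$provenance$mix_proportion <- proportion
  signal$provenance$n_mixed <- n_mix
  signal
}
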