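#' Define a time window relative to stimulus onset
#'
#' Windows are expressed in milliseconds relative to stimulus onset
#' (negative values are pre-stimulus). When mapped onto a sampled epoch
#' the window is half-open, `[start_ms, end_ms)`, so that the sample at
#' a shared boundary (typically 0 ms) is counted in exactly one of two
#' adjacent windows.
#'
#' @param start_ms Window start in ms (inclusive).
#' @param end_ms Window end in ms (exclusive).
#' @return An object of class `time_window`.
#' @examples
#' baseline <- time_window(-200, 0)
#' interest <- time_window(0, 800)
#' @export
time_window <- function(start_ms, end_ms) {
  stopifnot(is.numeric(start_ms), is.numeric(end_ms),
            length(start_ms) == 1L, length(end_ms) == 1L,
            is.finite(start_ms), is.finite(end_ms))
  if (start_ms >= end_ms) {
    stop("time_window: start_ms (", start_ms, ") must be < end_ms (",
         end_ms, ")", call. = FALSE)
  }
  structure(list(start_ms = start_ms, end_ms = end_ms),
            class = "time_window")
}

#' @export
print.time_window <- function(x, ...) {
  cat(sprintf("<time_window [%g, %g) ms>\n", x$start_ms, x$end_ms))
  invisible(x)
}

as_time_window <- function(x) {
  if (inherits(x, "time_window")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(time_window(x[1L], x[2L]))
  stop("expected a time_window or a numeric vector of length 2",
       call. = FALSE)
}

# Map a window to 1-based sample indices of an epoch whose sample k
# (0-based) sits at t_start_ms + k * 1000 / fs.  Half-open [start, end).
window_samples <- function(window, n_samples, fs, t_start_ms) {
  window <- as_time_window(window)
  tol <- 1e-9
  k0 <- ceiling((window$start_ms - t_start_ms) * fs / 1000 - tol)
  k1 <- ceiling((window$end_ms - t_start_ms) * fs / 1000 - tol) - 1
  t_end_ms <- t_start_ms + n_samples * 1000 / fs
  if (window$start_ms < t_start_ms - tol || window$end_ms > t_end_ms + tol) {
    stop(sprintf(
      "window [%g, %g) ms lies outside the epoch [%g, %g) ms",
      window$start_ms, window$end_ms, t_start_ms, t_end_ms), call. = FALSE)
  }
  if (k1 < k0) {
    stop(sprintf("window [%g, %g) ms contains no samples at fs = %g Hz",
                 window$start_ms, window$end_ms, fs), call. = FALSE)
  }
  seq.int(k0 + 1L, k1 + 1L)
}

# Evaluate a seeded expression without disturbing the caller's RNG
# stream; seed = NULL runs in the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
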