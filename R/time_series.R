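#' Construct a subject time-series object
#'
#' Wraps one subject's region-of-interest signals as a node-by-time matrix
#' with its sampling interval (repetition time, TR).
#'
#' @param data Numeric matrix, nodes in rows, time points in columns.
#' @param subject_id Subject identifier.
#' @param tr_seconds Sampling interval in seconds (positive).
#' @return An object of class `"subject_time_series"`.
#' @export
subject_time_series <- function(data, subject_id, tr_seconds) {
  if (!is.matrix(data) || !is.numeric(data)) {
    abort("`data` must be a numeric matrix (nodes x time).")
  }
  if (nrow(data) < 2 || ncol(data) < 2) {
    abort("`data` needs at least 2 nodes and 2 time points.")
  }
  if (anyNA(data)) abort("`data` contains missing values.")
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1 || tr_seconds <= 0) {
    abort("`tr_seconds` must be a single positive number.")
  }
  structure(
    list(
      subject_id = as.character(subject_id),
      data = data,
      tr_seconds = as.numeric(tr_seconds)
    ),
    class = "subject_time_series"
  )
}

#' @export
print.subject_time_series <- function(x, ...) {
  cat(
    "<subject_time_series> ", x$subject_id, ": ",
    nrow(x$data), " nodes x ", ncol(x$data), " time points, TR = ",
    x$tr_seconds, " s\n",
    sep = ""
  )
  invisible(x)
}

#' Sliding-window specification
#'
#' Converts a window length and step given in seconds into sample counts
#' (by truncation towards zero) and enumerates the window start offsets.
#' Windows are anchored at the first sample and any incomplete trailing
#' window is dropped, so the number of windows is
#' `W = floor((T - L) / S) + 1` for `T` time points, window length `L`
#' and step `S` in samples. With the defaults used throughout
#' (window 100 s, step 6 s at TR 2 s) a 240-volume series yields 64
#' windows of 50 samples stepping by 3.
#'
#' @param n_timepoints Number of time points `T` in the series.
#' @param tr_seconds Sampling interval in seconds.
#' @param length_seconds Window length in seconds (default 100).
#' @param step_seconds Window step in seconds (default 6).
#' @return An object of class `"window_spec"` with elements
#'   `length_samples`, `step_samples`, `n_windows`, `window_starts`
#'   (0-based sample offsets), and the generating arguments.
#' @export
#' @examples
#' make_windows(240, 2)            # 64 windows of 50 samples, step 3
#' make_windows(20, 1, 10, 5)      # 3 windows: starts 0, 5, 10
make_windows <- function(n_timepoints, tr_seconds,
                         length_seconds = 100, step_seconds = 6) {
  if (n_timepoints < 2) abort("`n_timepoints` must be at least 2.")
  if (tr_seconds <= 0) abort("`tr_seconds` must be positive.")
  if (length_seconds <= 0) abort("`length_seconds` must be positive.")
  if (step_seconds <= 0) abort("`step_seconds` must be positive.")
  length_samples <- floor(length_seconds / tr_seconds)
  step_samples <- floor(step_seconds / tr_seconds)
  if (length_samples < 2) {
    abort("window shorter than 2 samples; increase `length_seconds`.")
  }
  if (step_samples < 1) {
    abort("window step shorter than 1 sample; increase `step_seconds`.")
  }
  if (length_samples > n_timepoints) {
    abort(paste0(
      "window of ", length_samples, " samples does not fit in a series of ",
      n_timepoints, " time points."
    ))
  }
  n_windows <- floor((n_timepoints - length_samples) / step_samples) + 1L
  structure(
    list(
      n_timepoints = as.integer(n_timepoints),
      tr_seconds = tr_seconds,
      length_seconds = length_seconds,
      step_seconds = step_seconds,
      length_samples = as.integer(length_samples),
      step_samples = as.integer(step_samples),
      n_windows = as.integer(n_windows),
      window_starts = as.integer(step_samples * (seq_len(n_windows) - 1L))
    ),
    class = "window_spec"
  )
}

#' @export
print.window_spec <- function(x, ...) {
  cat(
    "<window_spec> ", x$n_windows, " windows of ", x$length_samples,
    " samples (", x$length_seconds, " s), step ", x$step_samples,
    " samples (", x$step_seconds, " s) over ", x$n_timepoints,
    " time points\n",
    sep = ""
  )
  invisible(x)
}
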