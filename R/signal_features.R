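#' Multichannel surface-EMG stream
#'
#' Container for a time-ordered block of raw surface-EMG samples. The
#' reference configuration is an eight-electrode armband sampled at 200 Hz,
#' but any positive channel count and sample rate are accepted.
#'
#' Sample `k` (1-based) is taken at time `(k - 1) / sample_rate` seconds
#' from stream start.
#'
#' @param samples Numeric matrix, one row per sample frame, one column per
#'   channel. All values must be finite.
#' @param sample_rate Sampling frequency in Hz (default 200).
#' @return An object of class `emg_stream` with elements `samples`,
#'   `sample_rate` and `channel_count`.
#' @examples
#' s <- emg_stream(matrix(rnorm(80 * 8), 80, 8))
#' s
#' @seealso [sliding_features()], [read_emg_csv()]
#' @export
emg_stream <- function(samples, sample_rate = 200) {
  if (is.data.frame(samples)) samples <- as.matrix(samples)
  if (!is.matrix(samples) || !is.numeric(samples)) {
    stop("`samples` must be a numeric matrix (rows = frames, cols = channels)",
         call. = FALSE)
  }
  if (ncol(samples) < 1L) stop("`samples` must have at least one channel", call. = FALSE)
  if (any(!is.finite(samples))) stop("`samples` contains non-finite values", call. = FALSE)
  if (!is_scalar_number(sample_rate) || sample_rate <= 0) {
    stop("`sample_rate` must be a single positive number", call. = FALSE)
  }
  structure(
    list(samples = unname(samples),
         sample_rate = sample_rate,
         channel_count = ncol(samples)),
    class = "emg_stream"
  )
}

#' @export
print.emg_stream <- function(x, ...) {
  cat(sprintf("<emg_stream> %d samples x %d channels @ %g Hz (%.2f s)\n",
              nrow(x$samples), x$channel_count, x$sample_rate,
              nrow(x$samples) / x$sample_rate))
  invisible(x)
}

#' Sliding-window configuration
#'
#' Window length and hop for feature extraction. Defaults follow the
#' standard real-time myocontrol setting: 200 ms windows advanced every
#' 40 ms, i.e. 40-sample windows with an 8-sample hop at 200 Hz. Both
#' durations must convert to whole sample counts at the stream's sample
#' rate.
#'
#' @param window_duration Window length in seconds (default 0.200).
#' @param hop_duration Window increment in seconds (default 0.040); must
#'   satisfy `0 < hop_duration <= window_duration`.
#' @return An object of class `windowing_config`.
#' @export
windowing_config <- function(window_duration = 0.200, hop_duration = 0.040) {
  if (!is_scalar_number(window_duration) || window_duration <= 0) {
    stop("`window_duration` must be a single positive number", call. = FALSE)
  }
  if (!is_scalar_number(hop_duration) || hop_duration <= 0 ||
      hop_duration > window_duration + 1e-12) {
    stop("`hop_duration` must satisfy 0 < hop <= window", call. = FALSE)
  }
  structure(list(window_duration = window_duration, hop_duration = hop_duration),
            class = "windowing_config")
}

# Convert a duration to a whole number of samples, failing loudly if it is
# not one (within floating-point slop).
duration_to_samples <- function(duration, sample_rate, what = "duration") {
  n <- duration * sample_rate
  if (abs(n - round(n)) > 1e-6) {
    stop(sprintf("%s (%g s) is not a whole number of samples at %g Hz",
                 what, duration, sample_rate), call. = FALSE)
  }
  as.integer(round(n))
}

#' Per-channel RMS of one EMG window
#'
#' Computes the root mean square of each channel over a block of samples —
#' the amplitude feature driving the linear decoder. RMS is a standard
#' proxy for muscle activation level.
#'
#' @param segment Numeric matrix (rows = sample frames, cols = channels)
#'   with at least one row.
#' @return Numeric vector of non-negative per-channel RMS values.
#' @examples
#' rms_window(matrix(c(3, -3, 3, -3), 4, 1))  # constant magnitude -> 3
#' @export
rms_window <- function(segment) {
  if (is.data.frame(segment)) segment <- as.matrix(segment)
  if (is.list(segment) && !is.matrix(segment)) {
    lens <- lengths(segment)
    if (length(unique(lens)) > 1L) {
      stop("ragged segment: frames have differing channel counts", call. = FALSE)
    }
    segment <- do.call(rbind, segment)
  }
  if (!is.matrix(segment) || !is.numeric(segment) || nrow(segment) < 1L) {
    stop("`segment` must be a non-empty numeric matrix", call. = FALSE)
  }
  sqrt(colMeans(segment^2))
}

#' Sliding-window RMS features from an EMG stream
#'
#' Frames the stream into windows aligned to sample 1, advancing by the hop,
#' and emits one RMS feature vector per complete window. Partial trailing
#' windows are dropped so every feature summarizes a full window. The
#' feature timestamp is the window END time — the instant at which a causal
#' real-time system could first compute it.
#'
#' For `N` samples, window `W` and hop `H` (in samples) the number of
#' features is `floor((N - W) / H) + 1` when `N >= W`, else zero.
#'
#' @param stream An [emg_stream()].
#' @param cfg A [windowing_config()].
#' @return An object of class `emg_features`: list with `x` (features
#'   matrix, one row per window, one column per channel) and `time`
#'   (numeric vector of window end times in seconds).
#' @export
sliding_features <- function(stream, cfg = windowing_config()) {
  stopifnot(inherits(stream, "emg_stream"), inherits(cfg, "windowing_config"))
  fs <- stream$sample_rate
  W <- duration_to_samples(cfg$window_duration, fs, "window_duration")
  H <- duration_to_samples(cfg$hop_duration, fs, "hop_duration")
  N <- nrow(stream$samples)
  M <- stream$channel_count
  if (N < W) {
    warning(sprintf("stream (%d samples) shorter than one window (%d); no features",
                    N, W), call. = FALSE)
    return(structure(list(x = matrix(numeric(0), 0, M), time = numeric(0)),
                     class = "emg_features"))
  }
  K <- (N - W) %/% H + 1L
  x <- matrix(NA_real_, K, M)
  tt <- numeric(K)
  for (k in seq_len(K)) {
    start <- (k - 1L) * H + 1L
    x[k, ] <- rms_window(stream$samples[start:(start + W - 1L), , drop = FALSE])
    tt[k] <- (start + W - 1L) / fs
  }
  structure(list(x = x, time = tt), class = "emg_features")
}

#' @export
print.emg_features <- function(x, ...) {
  cat(sprintf("<emg_features> %d windows x %d channels", nrow(x$x), ncol(x$x)))
  if (nrow(x$x) > 0) cat(sprintf(", t = [%.3f, %.3f] s", x$time[1], x$time[length(x$time)]))
  cat("\n")
  invisible(x)
}

#' Read / write EMG recordings as delimited text
#'
#' Recordings are CSV with a header row and columns `t, ch1..chM`: one row
#' per sample, `t` in seconds. The reader validates the column layout and
#' that time is strictly increasing, and infers the sample rate from the
#' median sample spacing.
#'
#' @param path File path.
#' @return `read_emg_csv()` returns an [emg_stream()]; `write_emg_csv()`
#'   returns `path` invisibly.
#' @export
read_emg_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2L || names(df)[1] != "t" ||
      !all(grepl("^ch[0-9]+$", names(df)[-1]))) {
    stop("EMG CSV must have columns t, ch1..chM", call. = FALSE)
  }
  if (nrow(df) < 2L) stop("EMG CSV needs at least two samples", call. = FALSE)
  tt <- df$t
  if (any(diff(tt) <= 0)) stop("EMG CSV time column must be strictly increasing", call. = FALSE)
  fs <- 1 / stats::median(diff(tt))
  emg_stream(as.matrix(df[, -1, drop = FALSE]), sample_rate = round(fs, 6))
}

#' @rdname read_emg_csv
#' @param stream An [emg_stream()] to write.
#' @export
write_emg_csv <- function(stream, path) {
  stopifnot(inherits(stream, "emg_stream"))
  n <- nrow(stream$samples)
  df <- data.frame(t = (seq_len(n) - 1) / stream$sample_rate)
  mat <- stream$samples
  colnames(mat) <- paste0("ch", seq_len(ncol(mat)))
  utils::write.csv(cbind(df, mat), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
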