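#' NLMS adaptation configuration
#'
#' Settings for the normalized least-mean-squares (NLMS) decoder update.
#' NLMS is the canonical stochastic minimizer of the instantaneous squared
#' error for a linear map, with a step size normalized by input power so
#' adaptation speed is insensitive to overall EMG amplitude.
#'
#' @param learning_rate Initial NLMS step `mu`, dimensionless; must lie
#'   in the stability range `(0, 2)`. Default 0.5.
#' @param regularizer Small positive constant `eps` added to the input
#'   power in the NLMS denominator so silent windows cannot divide by
#'   zero. Default 1e-6.
#' @param ramp_duration Optional linear onset ramp (seconds) applied to
#'   the desired target at each prompt start during training; 0 (default)
#'   uses the prompted target as a step function.
#' @param step_halflife Step-annealing halflife in UPDATES: the effective
#'   step at update `k` is `mu / (1 + (k - 1) / step_halflife)` — the
#'   standard stochastic-approximation schedule, so a training session
#'   adapts fast early and converges (low steady-state misadjustment
#'   against feature sampling noise) by the time the decoder is frozen
#'   for testing. Default 500 updates (20 s of features at the default
#'   hop). `Inf` gives a constant step — the pure tracking behaviour.
#' @return An object of class `adaptation_config`.
#' @export
adaptation_config <- function(learning_rate = 0.5, regularizer = 1e-6,
                              ramp_duration = 0, step_halflife = 500) {
  if (!is_scalar_number(learning_rate) || learning_rate < 0 || learning_rate >= 2) {
    stop("`learning_rate` must lie in [0, 2); 0 freezes the decoder", call. = FALSE)
  }
  if (!is_scalar_number(regularizer) || regularizer <= 0) {
    stop("`regularizer` must be a single positive number", call. = FALSE)
  }
  if (!is_scalar_number(ramp_duration) || ramp_duration < 0) {
    stop("`ramp_duration` must be a single non-negative number", call. = FALSE)
  }
  if (!(is.numeric(step_halflife) && length(step_halflife) == 1L &&
        !is.na(step_halflife) && step_halflife > 0)) {
    stop("`step_halflife` must be a single positive number (Inf allowed)",
         call. = FALSE)
  }
  structure(list(learning_rate = learning_rate, regularizer = regularizer,
                 ramp_duration = ramp_duration, step_halflife = step_halflife),
            class = "adaptation_config")
}

#' Zero-initialized decoder coefficient matrix
#'
#' The decoder state is a `dof_count` x `channel_count` real matrix `B`;
#' entry `(i, j)` weights channel `j`'s RMS in the estimate of DoF `i`.
#' Weights start at zero: symmetric, reproducible, and mapping resting
#' (near-zero RMS) input to the rest position. The model carries no
#' intercept term for the same reason.
#'
#' @param dof_count Number of output degrees of freedom (default 3).
#' @param channel_count Number of EMG channels (default 8).
#' @return A numeric matrix of zeros.
#' @export
zero_coefficients <- function(dof_count = 3, channel_count = 8) {
  matrix(0, dof_count, channel_count)
}

# Effective config at update index k under the annealing schedule.
annealed_cfg <- function(cfg, k) {
  if (is.finite(cfg$step_halflife)) {
    cfg$learning_rate <- cfg$learning_rate / (1 + (k - 1) / cfg$step_halflife)
  }
  cfg
}

check_coefficients <- function(B) {
  if (!is.matrix(B) || !is.numeric(B)) {
    stop("`B` must be a numeric matrix (DoFs x channels)", call. = FALSE)
  }
  if (any(!is.finite(B))) stop("`B` has non-finite entries", call. = FALSE)
  invisible(B)
}

#' Linear decoder prediction
#'
#' The simultaneous proportional control law: DoF estimate
#' `y_i = sum_j B[i, j] * x[j]` — each degree of freedom an independent
#' linear readout of the same RMS feature vector. Pure function; no state
#' is touched.
#'
#' @param B Coefficient matrix (DoFs x channels), see [zero_coefficients()].
#' @param x Feature vector of per-channel RMS values, length equal to
#'   `ncol(B)`.
#' @return Numeric vector of length `nrow(B)`.
#' @export
predict_dof <- function(B, x) {
  check_coefficients(B)
  x <- as.numeric(x)
  if (length(x) != ncol(B)) {
    stop(sprintf("feature length %d does not match %d decoder channels",
                 length(x), ncol(B)), call. = FALSE)
  }
  as.vector(B %*% x)
}

#' One NLMS coefficient update
#'
#' Per degree of freedom `i`, independently:
#' `e_i = d_i - (B x)_i`; `B'[i, ] = B[i, ] + mu * e_i * x / (eps + ||x||^2)`.
#' All rows share the same input vector and normalization; a zero-error
#' input leaves `B` exactly unchanged. Non-finite inputs skip the update
#' with a warning rather than poisoning the weights.
#'
#' @param B Coefficient matrix.
#' @param x Feature vector (length `ncol(B)`).
#' @param d Desired DoF vector (length `nrow(B)`).
#' @param cfg An [adaptation_config()].
#' @return The updated coefficient matrix.
#' @export
nlms_update <- function(B, x, d, cfg = adaptation_config()) {
  check_coefficients(B)
  stopifnot(inherits(cfg, "adaptation_config"))
  x <- as.numeric(x); d <- as.numeric(d)
  if (length(x) != ncol(B) || length(d) != nrow(B)) {
    stop("dimension mismatch between B, x and d", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(!is.finite(d))) {
    warning("non-finite input to nlms_update; update skipped", call. = FALSE)
    return(B)
  }
  e <- d - as.vector(B %*% x)
  B + (cfg$learning_rate / (cfg$regularizer + sum(x^2))) * tcrossprod(e, x)
}

#' Open-loop (offline-capable) NLMS training
#'
#' Runs the NLMS update sequentially over recorded (feature, target)
#' pairs, starting from zero weights. Deterministic given the pair order,
#' so an open-loop session replayed offline reproduces the online result
#' exactly.
#'
#' @param x Feature matrix, one row per pair (columns = channels), or an
#'   `emg_features` object.
#' @param d Target matrix, one row per pair (columns = DoFs); a vector is
#'   taken as a single pair.
#' @param cfg An [adaptation_config()]. The step-annealing index runs
#'   over the whole fit, so a multi-pass refit keeps annealing across
#'   passes and approaches the least-squares solution.
#' @param passes Number of sequential passes over the pairs (default 1).
#' @return An object of class `open_loop_fit`: list with `weights` (final
#'   coefficient matrix), `sq_error` (pre-update squared prediction error
#'   per step), `cfg` and `passes`.
#' @examples
#' G <- matrix(rnorm(24), 3, 8)
#' X <- matrix(abs(rnorm(800)), 100, 8)
#' fit <- train_open_loop(X, X %*% t(G), passes = 5)
#' max(abs(fit$weights - G)) < 0.05
#' @export
train_open_loop <- function(x, d, cfg = adaptation_config(), passes = 1) {
  if (inherits(x, "emg_features")) x <- x$x
  x <- as.matrix(x)
  if (is.null(dim(d))) d <- matrix(as.numeric(d), nrow = 1)
  d <- as.matrix(d)
  if (nrow(x) < 1L) stop("need at least one (feature, target) pair", call. = FALSE)
  if (nrow(x) != nrow(d)) stop("x and d must have the same number of rows", call. = FALSE)
  stopifnot(inherits(cfg, "adaptation_config"))
  passes <- as.integer(passes)
  if (passes < 1L) stop("`passes` must be >= 1", call. = FALSE)

  B <- zero_coefficients(ncol(d), ncol(x))
  sq_err <- numeric(nrow(x) * passes)
  step <- 0L
  for (p in seq_len(passes)) {
    for (k in seq_len(nrow(x))) {
      step <- step + 1L
      e <- d[k, ] - as.vector(B %*% x[k, ])
      sq_err[step] <- sum(e^2)
      B <- nlms_update(B, x[k, ], d[k, ], annealed_cfg(cfg, step))
    }
  }
  structure(list(weights = B, sq_error = sq_err, cfg = cfg, passes = passes),
            class = "open_loop_fit")
}

#' @export
print.open_loop_fit <- function(x, ...) {
  n <- length(x$sq_error)
  tail_mse <- mean(x$sq_error[max(1, n - 49):n])
  cat(sprintf("<open_loop_fit> %d x %d weights; %d updates (%d pass(es)); tail MSE %.3g\n",
              nrow(x$weights), ncol(x$weights), n, x$passes, tail_mse))
  invisible(x)
}

#' Serialize / restore decoder coefficients as CSV
#'
#' The coefficient matrix is written as plain CSV (one row per DoF, one
#' column per channel) with an optional JSON sidecar (`<path>.json`)
#' carrying adaptation config and session metadata.
#'
#' @param B Coefficient matrix.
#' @param path CSV file path.
#' @param metadata Optional named list stored in the sidecar.
#' @return `write_coefficients_csv()` returns `path` invisibly;
#'   `read_coefficients_csv()` returns the matrix.
#' @export
write_coefficients_csv <- function(B, path, metadata = NULL) {
  check_coefficients(B)
  utils::write.table(B, path, sep = ",", row.names = FALSE, col.names = FALSE)
  if (!is.null(metadata)) {
    jsonlite::write_json(c(metadata, list(digest = config_digest(metadata))),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_coefficients_csv
#' @export
read_coefficients_csv <- function(path) {
  unname(as.matrix(utils::read.csv(path, header = FALSE)))
}
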