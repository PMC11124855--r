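#' Target-acquisition task configuration
#'
#' Settings for the virtual 3-D target-acquisition test: the cursor must
#' come within the hit radius of the target and stay there for
#' `hold_duration` seconds, completing within `timeout` seconds. The hit
#' radius is `hit_fraction` of the workspace scale; by default the scale
#' is the workspace DIAGONAL — the largest possible 3-D distance,
#' `2 * sqrt(3) * workspace_half_range` — because a single scalar
#' normalizer is the only way a "fraction of 3-D distance" criterion is
#' well-defined for all targets including rest. At the defaults the
#' radius is `0.10 * 2 * sqrt(3) ~= 0.346` normalized units. The
#' alternative `"axis"` normalizer (per-axis range, `2 * half_range`) is
#' available as a knob.
#'
#' @param timeout Trial time limit, seconds (default 20).
#' @param hold_duration Required in-radius hold, seconds (default 1).
#' @param hit_fraction Radius as a fraction of the normalizer (default 0.10).
#' @param workspace_half_range Per-DoF half range of the workspace
#'   (default 1: each DoF spans `[-1, 1]`).
#' @param cursor_clip Per-DoF cursor clipping bound (default 1.5), keeping
#'   an untrained decoder from leaving the neighbourhood of the workspace.
#' @param tick Control/display tick in seconds (default 0.040, the
#'   feature hop).
#' @param radius_normalizer `"diagonal"` (default) or `"axis"`.
#' @param reset_cursor Reset the cursor to the origin between trials?
#'   Default `FALSE`: the cursor carries over, as in a continuous
#'   real-time session.
#' @return An object of class `task_config`.
#' @export
task_config <- function(timeout = 20, hold_duration = 1, hit_fraction = 0.10,
                        workspace_half_range = 1, cursor_clip = 1.5,
                        tick = 0.040, radius_normalizer = c("diagonal", "axis"),
                        reset_cursor = FALSE) {
  radius_normalizer <- match.arg(radius_normalizer)
  if (!is_scalar_number(timeout) || timeout <= 0) {
    stop("`timeout` must be positive", call. = FALSE)
  }
  if (!is_scalar_number(hold_duration) || hold_duration <= 0 ||
      hold_duration > timeout) {
    stop("`hold_duration` must be positive and <= timeout", call. = FALSE)
  }
  if (!is_scalar_number(hit_fraction) || hit_fraction <= 0) {
    stop("`hit_fraction` must be positive", call. = FALSE)
  }
  if (!is_scalar_number(tick) || tick <= 0) stop("`tick` must be positive", call. = FALSE)
  structure(list(timeout = timeout, hold_duration = hold_duration,
                 hit_fraction = hit_fraction,
                 workspace_half_range = workspace_half_range,
                 cursor_clip = cursor_clip, tick = tick,
                 radius_normalizer = radius_normalizer,
                 reset_cursor = reset_cursor),
            class = "task_config")
}

#' @rdname task_config
#' @param cfg A `task_config`.
#' @return `hit_radius()` returns the hit radius in normalized workspace
#'   units.
#' @export
hit_radius <- function(cfg) {
  stopifnot(inherits(cfg, "task_config"))
  norm <- switch(cfg$radius_normalizer,
                 diagonal = 2 * sqrt(3) * cfg$workspace_half_range,
                 axis = 2 * cfg$workspace_half_range)
  cfg$hit_fraction * norm
}

#' Hit detection on a recorded trajectory
#'
#' A trial is a hit iff some contiguous run of trajectory samples strictly
#' inside the hit radius spans at least `hold_duration` AND that hold
#' completes at or before `timeout` (a hold may not straddle the
#' timeout). `time_to_hit` is the end time of the first qualifying hold,
#' i.e. the first run's entry time plus `hold_duration`. `entrances`
#' counts outside-to-inside transitions over the whole trial; a
#' trajectory that starts inside counts its initial sample as one
#' entrance.
#'
#' @param trajectory Numeric T x 3 matrix of cursor positions.
#' @param target Length-3 target position.
#' @param cfg A [task_config()].
#' @param time Optional strictly increasing sample times (seconds);
#'   defaults to `(0:(T-1)) * cfg$tick`.
#' @return List with elements `hit` (logical), `time_to_hit` (seconds, or
#'   `NA` on a miss) and `entrances` (integer).
#' @export
detect_hit <- function(trajectory, target, cfg = task_config(), time = NULL) {
  trajectory <- as.matrix(trajectory)
  if (nrow(trajectory) < 1L || ncol(trajectory) != 3L ||
      !is.numeric(trajectory)) {
    stop("`trajectory` must be a non-empty numeric T x 3 matrix", call. = FALSE)
  }
  stopifnot(inherits(cfg, "task_config"), length(target) == 3L)
  if (is.null(time)) time <- (seq_len(nrow(trajectory)) - 1) * cfg$tick
  if (length(time) != nrow(trajectory) || any(diff(time) <= 0)) {
    stop("`time` must be strictly increasing and match the trajectory",
         call. = FALSE)
  }
  r <- hit_radius(cfg)
  d <- sqrt(rowSums(sweep(trajectory, 2, as.numeric(target))^2))
  inside <- d < r

  runs <- rle(inside)
  entrances <- sum(runs$values)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L

  hit <- FALSE
  time_to_hit <- NA_real_
  eps <- 1e-9
  for (i in seq_along(runs$values)) {
    if (!runs$values[i]) next
    span <- time[ends[i]] - time[starts[i]]
    complete_at <- time[starts[i]] + cfg$hold_duration
    if (span >= cfg$hold_duration - eps && complete_at <= cfg$timeout + eps) {
      hit <- TRUE
      time_to_hit <- complete_at
      break
    }
  }
  list(hit = hit, time_to_hit = time_to_hit, entrances = as.integer(entrances))
}

#' Run the 27-target acquisition test
#'
#' Presents all 27 targets (rest plus the 26 non-rest lattice targets) in
#' seeded pseudo-random order against a FROZEN decoder. Per control tick
#' the user — who can see the cursor — emits one EMG window for its
#' feedback-corrected intent, the RMS features are extracted, and the
#' cursor becomes the clipped decoder output. A trial ends at the first
#' completed hold or at the timeout; the cursor then carries over to the
#' next trial unless `cfg$reset_cursor` is set. No adaptation happens
#' during testing.
#'
#' @param B Trained coefficient matrix (any finite matrix accepted).
#' @param user A [virtual_user()].
#' @param seed Integer seed covering both the target order and the user's
#'   EMG noise.
#' @param cfg A [task_config()].
#' @param windowing A [windowing_config()]; its hop must equal `cfg$tick`.
#' @param sample_rate EMG sample rate in Hz (default 200).
#' @return An object of class `test_session`: list with `trials` (a list
#'   of 27 trial records, each with `target`, `trajectory`, `time`,
#'   `hit`, `time_to_hit`, `entrances`, `path_length`), `order`, `seed`
#'   and `cfg`.
#' @export
run_test <- function(B, user, seed, cfg = task_config(),
                     windowing = windowing_config(), sample_rate = 200) {
  check_coefficients(B)
  stopifnot(inherits(user, "virtual_user"), inherits(cfg, "task_config"))
  if (abs(windowing$hop_duration - cfg$tick) > 1e-9) {
    stop("windowing hop must equal the task tick", call. = FALSE)
  }
  W <- duration_to_samples(windowing$window_duration, sample_rate, "window_duration")
  H <- duration_to_samples(windowing$hop_duration, sample_rate, "hop_duration")
  r <- hit_radius(cfg)
  max_ticks <- as.integer(round(cfg$timeout / cfg$tick))
  eps <- 1e-9

  targets <- all_targets()
  trials <- vector("list", nrow(targets))
  cursor <- c(0, 0, 0)
  buf <- NULL  # trailing W samples shared across trials (continuous session)

  ord <- integer(0)
  with_seed(seed, {
    ord <- sample.int(nrow(targets))
    for (trial_i in seq_along(ord)) {
      target <- as.numeric(targets[ord[trial_i], ])
      if (cfg$reset_cursor) cursor <- c(0, 0, 0)
      user <- drift_user(user, cfg$tick)

      traj <- matrix(NA_real_, max_ticks + 1L, 3)
      traj[1L, ] <- cursor
      n_rows <- 1L
      run_start <- if (sqrt(sum((cursor - target)^2)) < r) 0 else NA_real_

      for (k in seq_len(max_ticks)) {
        intent <- closed_loop_intent(user, target, cursor, feedback = TRUE)
        buf <- slide_buffer(buf, emit_emg(user, intent, H), W)
        if (nrow(buf) >= W) {
          cursor <- clip_dof(as.vector(B %*% rms_window(buf)), cfg$cursor_clip)
        }  # else: cursor holds until the first full window is available
        t_k <- k * cfg$tick
        n_rows <- n_rows + 1L
        traj[n_rows, ] <- cursor
        if (sqrt(sum((cursor - target)^2)) < r) {
          if (is.na(run_start)) run_start <- t_k
          if (t_k - run_start >= cfg$hold_duration - eps) break
        } else {
          run_start <- NA_real_
        }
      }

      traj <- traj[seq_len(n_rows), , drop = FALSE]
      tt <- (seq_len(n_rows) - 1) * cfg$tick
      # the user keeps learning from what it saw during the trial
      user <- consolidate_correction(user, target,
                                     colMeans(sweep(traj, 2, target, `-`)) * -1)
      dh <- detect_hit(traj, target, cfg, time = tt)
      steps <- diff(traj)
      trials[[trial_i]] <- list(
        target = target, trajectory = traj, time = tt,
        hit = dh$hit, time_to_hit = dh$time_to_hit,
        entrances = dh$entrances,
        path_length = sum(sqrt(rowSums(steps^2)))
      )
    }
  })

  structure(list(trials = trials, order = ord, seed = seed, cfg = cfg,
                 user = user),
            class = "test_session")
}

#' @export
print.test_session <- function(x, ...) {
  hits <- sum(vapply(x$trials, `[[`, logical(1), "hit"))
  cat(sprintf("<test_session> %d targets, %d hits (CR = %.2f), seed %s\n",
              length(x$trials), hits, hits / length(x$trials), format(x$seed)))
  invisible(x)
}

#' Write test-session trial logs
#'
#' `write_session_jsonl()` writes one JSON record per trial (target, hit,
#' time_to_hit, entrances, path_length, optionally the full trajectory).
#' `write_trial_summary_csv()` writes the compact one-row-per-trial CSV.
#'
#' @param session A `test_session` from [run_test()].
#' @param path File path.
#' @param trajectories Include full trajectories in the JSON lines?
#'   Default `FALSE`.
#' @return `path`, invisibly.
#' @export
write_session_jsonl <- function(session, path, trajectories = FALSE) {
  stopifnot(inherits(session, "test_session"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (tr in session$trials) {
    rec <- list(target = tr$target, hit = tr$hit,
                time_to_hit = tr$time_to_hit, entrances = tr$entrances,
                path_length = tr$path_length,
                path_efficiency = path_efficiency(tr))
    if (trajectories) rec$trajectory <- tr$trajectory
    writeLines(as.character(jsonlite::toJSON(rec, auto_unbox = TRUE,
                                             digits = NA, na = "null")), con)
  }
  invisible(path)
}

#' @rdname write_session_jsonl
#' @export
write_trial_summary_csv <- function(session, path) {
  stopifnot(inherits(session, "test_session"))
  df <- do.call(rbind, lapply(seq_along(session$trials), function(i) {
    tr <- session$trials[[i]]
    data.frame(trial = i, d1 = tr$target[1], d2 = tr$target[2],
               d3 = tr$target[3], hit = tr$hit,
               time_to_hit = tr$time_to_hit, entrances = tr$entrances,
               path_length = tr$path_length,
               path_efficiency = path_efficiency(tr))
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
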