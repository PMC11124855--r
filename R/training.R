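#' Run a training session against a virtual user
#'
#' Simulates a complete training session at the real-time control tick
#' (one tick per feature hop, 40 ms by default). At every tick the user
#' emits one hop of fresh EMG samples for its current intent; the
#' per-channel RMS is computed over the trailing full window (so
#' consecutive features overlap, exactly as in the real-time system), the
#' decoder is updated by NLMS against the prompted target, and the cursor
#' estimate is refreshed from the updated weights. The feature buffer
#' restarts at each prompt, so no training window mixes samples from two
#' prompts; each prompt's first update comes one window length after its
#' onset. When a prompt's feedback flag is on, the user's intent is the
#' feedback-corrected one (see [closed_loop_intent()]) — this is the
#' co-adaptive loop in which the human and the decoder adapt to each other
#' simultaneously, and the user consolidates what it learns (see
#' `retention` in [virtual_user()]). With all feedback flags off
#' (Protocols I and II) the
#' session is open-loop: the recorded (feature, target) pairs fully
#' determine the result and can be re-fit offline with
#' [replay_open_loop()]. Closed-loop sessions are inherently online —
#' the user's EMG depends on the evolving decoder — and are flagged
#' non-replayable.
#'
#' @param protocol A [protocol_sequence()] (or any data frame with columns
#'   `d1, d2, d3, duration, feedback`).
#' @param user A [virtual_user()]; needs a feedback model if any prompt
#'   has `feedback = TRUE`.
#' @param cfg An [adaptation_config()].
#' @param windowing A [windowing_config()]; the hop is the control tick.
#' @param sample_rate EMG sample rate in Hz (default 200).
#' @param seed Integer seed for the user's EMG noise during this session.
#' @return An object of class `training_session`: list with `weights`
#'   (final coefficient matrix), `pairs` (data frame `t, x1..xM, d1..d3`
#'   of every recorded feature/target pair in order), `sq_error`
#'   (pre-update squared error trace), `user` (the user as it leaves the
#'   session, including any intent calibrations retained from feedback
#'   prompts — pass THIS user to [run_test()] to model the same person
#'   taking the test), `closed_loop` (flag), `protocol_id`, `seed` and
#'   `cfg`.
#' @examples
#' u <- make_virtual_user(1, "easy")
#' p <- protocol_sequence("I", seed = 1, prompt_duration = 0.4, rest_duration = 0.2)
#' s <- train_closed_loop(p, u, seed = 2)
#' s
#' @export
train_closed_loop <- function(protocol, user, cfg = adaptation_config(),
                              windowing = windowing_config(),
                              sample_rate = 200, seed = 1) {
  stopifnot(is.data.frame(protocol), inherits(user, "virtual_user"),
            inherits(cfg, "adaptation_config"),
            inherits(windowing, "windowing_config"))
  if (any(protocol$feedback) && is.na(user$feedback_gain)) {
    stop("protocol requests feedback but the user has no feedback model",
         call. = FALSE)
  }
  W <- duration_to_samples(windowing$window_duration, sample_rate, "window_duration")
  H <- duration_to_samples(windowing$hop_duration, sample_rate, "hop_duration")
  tick <- windowing$hop_duration
  M <- user$channel_count

  n_ticks_per_prompt <- vapply(protocol$duration,
                               function(d) max(1L, as.integer(round(d / tick))),
                               integer(1))
  warmup <- as.integer(ceiling(W / H)) - 1L  # buffer-fill ticks per prompt
  total <- sum(pmax(0L, n_ticks_per_prompt - warmup))
  X <- matrix(NA_real_, total, M)
  D <- matrix(NA_real_, total, 3)
  tt <- numeric(total)
  sq_err <- numeric(total)

  B <- zero_coefficients(3, M)
  cursor <- c(0, 0, 0)
  t_now <- 0
  row <- 0L

  with_seed(seed, {
    for (p in seq_len(nrow(protocol))) {
      d <- as.numeric(protocol[p, c("d1", "d2", "d3")])
      fb <- isTRUE(protocol$feedback[p])
      user <- drift_user(user, protocol$duration[p])
      # The feature buffer restarts at every prompt so no training window
      # mixes samples from two prompts; the first feature (and update) of
      # a prompt arrives once one full window has accumulated.
      buf <- NULL
      err_sum <- c(0, 0, 0)
      err_n <- 0L
      for (k in seq_len(n_ticks_per_prompt[p])) {
        t_now <- t_now + tick
        intent <- closed_loop_intent(user, d, cursor, feedback = fb)
        buf <- slide_buffer(buf, emit_emg(user, intent, H), W)
        if (fb) {
          err_sum <- err_sum + (d - cursor)
          err_n <- err_n + 1L
        }
        if (nrow(buf) < W) next
        row <- row + 1L
        x <- rms_window(buf)
        d_t <- if (cfg$ramp_duration > 0) {
          d * min(1, (k * tick) / cfg$ramp_duration)
        } else d
        e <- d_t - as.vector(B %*% x)
        sq_err[row] <- sum(e^2)
        B <- nlms_update(B, x, d_t, annealed_cfg(cfg, row))
        cursor <- clip_dof(as.vector(B %*% x), 1.5)
        X[row, ] <- x
        D[row, ] <- d_t
        tt[row] <- t_now
      }
      if (fb && err_n > 0L) {
        user <- consolidate_correction(user, d, err_sum / err_n)
      }
    }
  })

  if (total == 0L) {
    warning("every prompt is shorter than one feature window; no updates made",
            call. = FALSE)
  }
  X <- X[seq_len(row), , drop = FALSE]
  D <- D[seq_len(row), , drop = FALSE]
  tt <- tt[seq_len(row)]
  sq_err <- sq_err[seq_len(row)]

  pairs <- data.frame(t = tt)
  Xdf <- as.data.frame(X); names(Xdf) <- paste0("x", seq_len(M))
  Ddf <- as.data.frame(D); names(Ddf) <- paste0("d", 1:3)
  pairs <- cbind(pairs, Xdf, Ddf)

  structure(
    list(weights = B, pairs = pairs, sq_error = sq_err, user = user,
         closed_loop = any(protocol$feedback),
         protocol_id = attr(protocol, "protocol_id") %||% NA_character_,
         seed = seed, cfg = cfg, windowing = windowing,
         sample_rate = sample_rate),
    class = "training_session"
  )
}

#' @export
print.training_session <- function(x, ...) {
  n <- length(x$sq_error)
  cat(sprintf("<training_session> Protocol %s (%s), %d updates, tail MSE %.3g\n",
              x$protocol_id,
              if (x$closed_loop) "closed-loop, online only" else "open-loop, replayable",
              n, mean(x$sq_error[max(1, n - 49):n])))
  invisible(x)
}

#' Write / read recorded training pairs as CSV
#'
#' The pair log (`t, x1..xM, d1..d3`) is the offline-retraining format.
#' `write_training_pairs_csv()` also writes a JSON sidecar
#' (`<path>.json`) with the session seed, adaptation config, closed-loop
#' flag and a config digest, so provenance travels with the recording.
#'
#' @param session A `training_session` from [train_closed_loop()].
#' @param path CSV file path.
#' @return `write_training_pairs_csv()` returns `path` invisibly;
#'   `read_training_pairs_csv()` returns the pair data frame.
#' @export
write_training_pairs_csv <- function(session, path) {
  stopifnot(inherits(session, "training_session"))
  utils::write.csv(session$pairs, path, row.names = FALSE, quote = FALSE)
  meta <- list(protocol_id = session$protocol_id, seed = session$seed,
               closed_loop = session$closed_loop,
               learning_rate = session$cfg$learning_rate,
               regularizer = session$cfg$regularizer,
               ramp_duration = session$cfg$ramp_duration,
               step_halflife = session$cfg$step_halflife)
  meta$digest <- config_digest(meta)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_training_pairs_csv
#' @export
read_training_pairs_csv <- function(path) {
  df <- tryCatch(utils::read.csv(path),
                 error = function(e) stop(sprintf("cannot parse '%s': %s",
                                                  path, conditionMessage(e)),
                                          call. = FALSE))
  if (nrow(df) == 0L) stop(sprintf("'%s' contains no pairs", path), call. = FALSE)
  if (names(df)[1] != "t" ||
      !any(grepl("^x[0-9]+$", names(df))) ||
      !all(paste0("d", 1:3) %in% names(df))) {
    stop("training-pair CSV must have columns t, x1..xM, d1..d3", call. = FALSE)
  }
  bad <- which(!stats::complete.cases(df) | !apply(df, 1, function(r) all(is.finite(r))))
  if (length(bad) > 0L) {
    stop(sprintf("malformed value in '%s' at data line %d", path, bad[1]),
         call. = FALSE)
  }
  df
}

#' Offline re-training from a recorded open-loop session
#'
#' Re-fits the decoder from a pair recording (a `training_session`, a pair
#' data frame, or a CSV path written by [write_training_pairs_csv()]).
#' Rows are ordered by timestamp before fitting, so a shuffled file
#' reproduces the original result. Given the same pairs and config, the
#' offline result equals the online open-loop weights bit for bit.
#' Closed-loop recordings are refused: their EMG depended on the evolving
#' decoder, so re-fitting them offline would not reproduce the session
#' (the interaction is personal and non-transferable).
#'
#' @param recording A `training_session`, a pair data frame, or a CSV path.
#' @param cfg An [adaptation_config()]; should match the one used online.
#' @param passes Sequential passes over the pairs (default 1, matching the
#'   online session).
#' @return An `open_loop_fit` (see [train_open_loop()]).
#' @export
replay_open_loop <- function(recording, cfg = adaptation_config(), passes = 1) {
  if (inherits(recording, "training_session")) {
    if (recording$closed_loop) {
      stop("closed-loop sessions are online-only and cannot be replayed",
           call. = FALSE)
    }
    df <- recording$pairs
  } else if (is.character(recording) && length(recording) == 1L) {
    sidecar <- paste0(recording, ".json")
    if (file.exists(sidecar)) {
      meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
      if (isTRUE(meta$closed_loop)) {
        stop("recording is flagged closed-loop; online-only, cannot be replayed",
             call. = FALSE)
      }
    }
    df <- read_training_pairs_csv(recording)
  } else if (is.data.frame(recording)) {
    df <- recording
  } else {
    stop("`recording` must be a training_session, data frame or CSV path",
         call. = FALSE)
  }
  df <- df[order(df$t), , drop = FALSE]
  xcols <- grep("^x[0-9]+$", names(df), value = TRUE)
  xcols <- xcols[order(as.integer(sub("x", "", xcols)))]
  train_open_loop(as.matrix(df[, xcols, drop = FALSE]),
                  as.matrix(df[, paste0("d", 1:3), drop = FALSE]),
                  cfg = cfg, passes = passes)
}
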