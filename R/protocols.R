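#' Enumerate the discrete target space
#'
#' Targets live on the lattice `{-1, 0, +1}^3` in the order
#' (flexion-extension, radial-ulnar deviation, open-close): 27 vectors in
#' all — the rest position, 6 one-DoF, 12 two-DoF and 8 three-DoF targets.
#' `enumerate_targets(k)` returns those with exactly `k` active
#' (non-zero) components, in lexicographic order; `all_targets()` returns
#' the full 27-row lattice, lexicographically.
#'
#' @param active_dofs Number of active DoFs, an integer in `0..3`.
#' @return Numeric matrix with columns `d1, d2, d3`, one row per target.
#' @examples
#' nrow(enumerate_targets(1))  # 6
#' nrow(enumerate_targets(2))  # 12
#' @export
enumerate_targets <- function(active_dofs) {
  if (!is_scalar_number(active_dofs) || active_dofs != round(active_dofs) ||
      active_dofs < 0 || active_dofs > 3) {
    stop("`active_dofs` must be an integer in 0..3", call. = FALSE)
  }
  g <- all_targets()
  g[rowSums(g != 0) == active_dofs, , drop = FALSE]
}

#' @rdname enumerate_targets
#' @export
all_targets <- function() {
  g <- as.matrix(expand.grid(d3 = c(-1, 0, 1), d2 = c(-1, 0, 1),
                             d1 = c(-1, 0, 1)))[, 3:1]
  rownames(g) <- NULL
  g
}

prompt_frame <- function(targets, duration, feedback, phase) {
  data.frame(d1 = targets[, 1], d2 = targets[, 2], d3 = targets[, 3],
             duration = duration, feedback = feedback, phase = phase,
             stringsAsFactors = FALSE)
}

# Interleave each target row with a rest prompt.
with_rests <- function(targets, prompt_duration, rest_duration, feedback, phase) {
  out <- vector("list", 2L * nrow(targets))
  rest <- matrix(0, 1, 3)
  for (i in seq_len(nrow(targets))) {
    out[[2L * i - 1L]] <- prompt_frame(targets[i, , drop = FALSE],
                                       prompt_duration, feedback, phase)
    out[[2L * i]] <- prompt_frame(rest, rest_duration, feedback, "rest")
  }
  do.call(rbind, out)
}

#' One training lap
#'
#' A lap visits each of the 6 one-DoF targets once, in seeded
#' pseudo-random order, with a rest prompt after each — 12 prompts total.
#'
#' @param seed Integer seed for the Fisher-Yates shuffle of target order.
#' @param prompt_duration,rest_duration Prompt lengths in seconds
#'   (defaults 3 and 2).
#' @param feedback Feedback flag applied to every prompt in the lap
#'   (default `FALSE`: blind).
#' @return A prompt data frame (columns `d1, d2, d3, duration, feedback,
#'   phase`).
#' @export
make_lap <- function(seed, prompt_duration = 3, rest_duration = 2,
                     feedback = FALSE) {
  one <- enumerate_targets(1)
  ord <- with_seed(seed, sample.int(nrow(one)))
  with_rests(one[ord, , drop = FALSE], prompt_duration, rest_duration,
             feedback, "lap")
}

#' Generate a training protocol prompt sequence
#'
#' Three training paradigms over the discrete target space, all blind
#' except where noted:
#'
#' * **Protocol I** (base): five laps of the 6 one-DoF targets — 60
#'   prompts, no feedback, no combined targets.
#' * **Protocol II** (open-loop): one lap, then each of the 20 combined
#'   targets (12 two-DoF + 8 three-DoF) once in seeded order, a rest after
#'   each — 52 prompts, no feedback.
#' * **Protocol III** (closed-loop, co-adaptive): identical target
#'   ordering to Protocol II at the same seed, but every prompt after the
#'   initial lap carries `feedback = TRUE` — the user sees the decoded
#'   cursor while the decoder keeps adapting. Rest prompts in the
#'   feedback block also show the cursor (the user watches it return to
#'   center).
#'
#' The sequence is a pure function of `(protocol_id, seed, durations)`:
#' the same seed yields the same order for every simulated participant.
#'
#' @param protocol_id `"I"`, `"II"` or `"III"`.
#' @param seed Integer seed for the pseudo-random target orders.
#' @param prompt_duration Active-target prompt length, seconds (default 3).
#' @param rest_duration Rest prompt length, seconds (default 2).
#' @return A data frame of class `protocol_sequence` with columns
#'   `d1, d2, d3, duration, feedback, phase` and attributes `protocol_id`
#'   and `seed`.
#' @examples
#' p <- protocol_sequence("II", seed = 7)
#' nrow(p)             # 52
#' sum(p$feedback)     # 0
#' @export
protocol_sequence <- function(protocol_id = c("I", "II", "III"), seed,
                              prompt_duration = 3, rest_duration = 2) {
  protocol_id <- as.character(protocol_id[1])
  if (!protocol_id %in% c("I", "II", "III")) {
    stop(sprintf("unknown protocol_id '%s' (use \"I\", \"II\" or \"III\")",
                 protocol_id), call. = FALSE)
  }
  if (!is_scalar_number(prompt_duration) || prompt_duration <= 0 ||
      !is_scalar_number(rest_duration) || rest_duration <= 0) {
    stop("prompt and rest durations must be positive", call. = FALSE)
  }

  if (protocol_id == "I") {
    laps <- lapply(1:5, function(l) {
      make_lap(derive_seed(seed, l), prompt_duration, rest_duration, FALSE)
    })
    out <- do.call(rbind, laps)
  } else {
    feedback_after_lap <- protocol_id == "III"
    lap <- make_lap(derive_seed(seed, 1), prompt_duration, rest_duration, FALSE)
    combined <- rbind(enumerate_targets(2), enumerate_targets(3))
    ord <- with_seed(derive_seed(seed, 100), sample.int(nrow(combined)))
    block <- with_rests(combined[ord, , drop = FALSE], prompt_duration,
                        rest_duration, feedback_after_lap, "combined")
    out <- rbind(lap, block)
  }
  rownames(out) <- NULL
  structure(out, protocol_id = protocol_id, seed = seed,
            class = c("protocol_sequence", "data.frame"))
}

#' @export
print.protocol_sequence <- function(x, ...) {
  cat(sprintf("<protocol_sequence> Protocol %s, seed %s: %d prompts (%d rest, %d with feedback), %.1f s total\n",
              attr(x, "protocol_id"), format(attr(x, "seed")), nrow(x),
              sum(x$phase == "rest"), sum(x$feedback), sum(x$duration)))
  invisible(x)
}

#' Export a protocol sequence as CSV
#'
#' Columns: `index, d1, d2, d3, duration_s, feedback, phase_label` — the
#' audit format, also consumable for offline re-training.
#'
#' @param protocol A [protocol_sequence()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_protocol_csv <- function(protocol, path) {
  stopifnot(inherits(protocol, "protocol_sequence"))
  df <- data.frame(index = seq_len(nrow(protocol)),
                   d1 = protocol$d1, d2 = protocol$d2, d3 = protocol$d3,
                   duration_s = protocol$duration,
                   feedback = protocol$feedback,
                   phase_label = protocol$phase)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
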