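#' Virtual EMG user
#'
#' A simulated subject that converts a 3-component motor intent into
#' multichannel surface EMG, and — when it can see the decoded cursor —
#' corrects its intent toward the prompted target. The model is the
#' standard amplitude-modulated envelope view of surface EMG: each channel
#' is zero-mean noise whose standard deviation equals a rectified linear
#' function of intent,
#'
#'   a = max(0, S d + baseline),
#'
#' where `S` is an M x 3 muscle-synergy matrix. A window of such samples
#' has expected RMS approximately `a`, which is exactly the statistical
#' structure the RMS feature + linear decoder pipeline assumes. No
#' motor-unit-level physiology is modeled; the pipeline only ever consumes
#' window RMS.
#'
#' @param synergy M x 3 numeric matrix mapping intent to per-channel mean
#'   RMS amplitude.
#' @param baseline Length-M non-negative resting activation (signal units).
#' @param noise_scale Multiplicative amplitude jitter half-width: each
#'   emitted window scales every channel amplitude by `1 + U(-ns, +ns)`.
#' @param feedback_gain Proportional correction gain `g` in `[0, 1]` used
#'   by [closed_loop_intent()]; `NA` marks a user with no feedback
#'   behaviour (cannot run closed-loop protocols).
#' @param adaptation_rate Per-prompt random drift scale of the synergy
#'   matrix, emulating fatigue / non-stationarity. Default 0 (stationary).
#' @param retention Consolidation fraction in `[0, 1]` of the user's
#'   motor learning (default 0.5): after a prompt performed WITH visible
#'   feedback, the user retains `retention * feedback_gain` times the
#'   average correction that prompt required as a per-target intent
#'   calibration, applied on later feedback encounters of the same
#'   target. This is the mechanism by which closed-loop training improves
#'   the user — and not just the decoder; it is what makes a co-adaptive
#'   session personal and non-transferable. Scaled by `feedback_gain`, so
#'   a `feedback_gain = 0` user neither reacts to nor learns from
#'   feedback.
#' @param seed Integer recorded for provenance (the seed the user was
#'   drawn from, if any).
#' @return An object of class `virtual_user`.
#' @seealso [make_virtual_user()], [emit_emg()], [closed_loop_intent()]
#' @export
virtual_user <- function(synergy, baseline = rep(0.05, nrow(synergy)),
                         noise_scale = 0.1, feedback_gain = 0.5,
                         adaptation_rate = 0, retention = 0.5,
                         seed = NA_integer_) {
  synergy <- as.matrix(synergy)
  if (!is.numeric(synergy) || ncol(synergy) != 3L || nrow(synergy) < 3L) {
    stop("`synergy` must be a numeric M x 3 matrix with M >= 3", call. = FALSE)
  }
  if (any(!is.finite(synergy))) stop("`synergy` has non-finite entries", call. = FALSE)
  M <- nrow(synergy)
  baseline <- as.numeric(baseline)
  if (length(baseline) == 1L) baseline <- rep(baseline, M)
  if (length(baseline) != M || any(baseline < 0) || any(!is.finite(baseline))) {
    stop("`baseline` must be M non-negative finite values", call. = FALSE)
  }
  if (!is_scalar_number(noise_scale) || noise_scale < 0) {
    stop("`noise_scale` must be a single non-negative number", call. = FALSE)
  }
  if (!(length(feedback_gain) == 1L &&
        (is.na(feedback_gain) ||
         (is.numeric(feedback_gain) && feedback_gain >= 0 && feedback_gain <= 1)))) {
    stop("`feedback_gain` must be in [0, 1] or NA", call. = FALSE)
  }
  if (!is_scalar_number(adaptation_rate) || adaptation_rate < 0) {
    stop("`adaptation_rate` must be a single non-negative number", call. = FALSE)
  }
  if (!is_scalar_number(retention) || retention < 0 || retention > 1) {
    stop("`retention` must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(synergy = unname(synergy), baseline = baseline,
         noise_scale = noise_scale, feedback_gain = as.numeric(feedback_gain),
         adaptation_rate = adaptation_rate, retention = retention,
         correction = list(), seed = seed,
         channel_count = M),
    class = "virtual_user"
  )
}

#' @export
print.virtual_user <- function(x, ...) {
  cat(sprintf(paste0("<virtual_user> %d channels; noise_scale = %g, ",
                     "feedback_gain = %s, adaptation_rate = %g\n"),
              x$channel_count, x$noise_scale,
              ifelse(is.na(x$feedback_gain), "NA", format(x$feedback_gain)),
              x$adaptation_rate))
  cat(sprintf("  synergy condition number: %.2f; seed: %s\n",
              kappa(x$synergy, exact = TRUE),
              ifelse(is.na(x$seed), "none", format(x$seed))))
  invisible(x)
}

#' Draw a random virtual user
#'
#' Generates a user whose synergy matrix mimics an armband over antagonist
#' muscle groups: channels come in agonist/antagonist pairs, one pair
#' dominating each degree of freedom (channels 1-2 for flexion-extension,
#' 3-4 for radial-ulnar deviation, 5-6 for open-close), plus two residual
#' channels with small mixed non-negative loadings. On top of that clean
#' structure a difficulty-dependent random cross-talk perturbation is
#' added, and the difficulty also sets the amplitude jitter:
#'
#' Difficulty controls how much each electrode mixes muscle groups.
#' Cross-talk is drawn sign-symmetric and scaled relative to the
#' channel's dominant gain; combined with the rectification
#' `max(0, S d + baseline)` this makes the set of silent channels differ
#' between one-DoF targets and combined (orthant) targets, so EMG for
#' combined intents is NOT linearly predictable from one-DoF EMG alone —
#' the non-trained-region phenomenon that makes combined-target training
#' protocols matter.
#'
#' * `easy`:   no cross-talk, `noise_scale = 0.05` — every one-DoF intent
#'   activates a distinct channel subset and an exact linear decoder exists.
#' * `medium`: cross-talk up to 0.4 of the dominant gain, `noise_scale = 0.10`.
#' * `hard`:   cross-talk up to 0.7 of the dominant gain, `noise_scale = 0.20`.
#'
#' The synergy always has full column rank (so the three intents are
#' decodable from the M channels); generation is retried in the measure-zero
#' event it does not. Deterministic given `seed`.
#'
#' @param seed Integer seed.
#' @param difficulty `"easy"`, `"medium"` (default) or `"hard"`.
#' @param noise_scale,baseline Optional overrides of the
#'   difficulty-implied jitter and the default resting activation (0.05
#'   per channel, equal within antagonist pairs). Set both to 0 for a
#'   noiseless, rest-silent user.
#' @param feedback_gain,adaptation_rate,retention Passed to
#'   [virtual_user()].
#' @return A `virtual_user`.
#' @examples
#' u <- make_virtual_user(1, "easy")
#' qr(u$synergy)$rank  # 3
#' @export
make_virtual_user <- function(seed, difficulty = c("medium", "easy", "hard"),
                              noise_scale = NULL, baseline = NULL,
                              feedback_gain = 0.5, adaptation_rate = 0,
                              retention = 0.5) {
  difficulty <- match.arg(difficulty)
  pars <- switch(difficulty,
                 easy   = list(xt = 0.0, ns = 0.05),
                 medium = list(xt = 0.4, ns = 0.10),
                 hard   = list(xt = 0.7, ns = 0.20))
  with_seed(seed, {
    repeat {
      gains <- stats::runif(3, 0.5, 1.5)
      S <- matrix(0, 8, 3)
      for (k in 1:3) {
        S[2 * k - 1, k] <- gains[k]   # agonist channel
        S[2 * k, k] <- -gains[k]      # antagonist channel
      }
      # residual channels: weak mixed non-negative loadings
      S[7, ] <- stats::runif(3, 0, 0.3)
      S[8, ] <- stats::runif(3, 0, 0.3)
      if (pars$xt > 0) {
        # sign-mixed secondary loadings, relative to the dominant gain:
        # each pair channel also senses the other two DoFs
        for (k in 1:3) {
          others <- setdiff(1:3, k)
          S[2 * k - 1, others] <- gains[k] * stats::runif(2, -pars$xt, pars$xt)
          S[2 * k, others] <- -gains[k] * stats::runif(2, -pars$xt, pars$xt)
        }
      }
      if (qr(S)$rank == 3L) break
    }
    virtual_user(
      synergy = S,
      baseline = baseline %||% rep(0.05, 8),
      noise_scale = noise_scale %||% pars$ns,
      feedback_gain = feedback_gain,
      adaptation_rate = adaptation_rate,
      retention = retention,
      seed = seed
    )
  })
}

#' Expected per-channel RMS for an intent
#'
#' The noiseless amplitude profile `a = max(0, S d + baseline)`: the mean
#' RMS the user's EMG approaches as windows accumulate. Useful as an
#' analytical oracle when constructing ideal decoders.
#'
#' @param user A [virtual_user()].
#' @param intent Length-3 numeric motor intent.
#' @return Length-M non-negative numeric vector.
#' @export
expected_rms <- function(user, intent) {
  stopifnot(inherits(user, "virtual_user"), length(intent) == 3L)
  pmax(0, as.vector(user$synergy %*% as.numeric(intent)) + user$baseline)
}

#' Synthesize one block of EMG samples
#'
#' Emits `n_samples` frames of M-channel EMG for a fixed motor intent.
#' Per channel the samples are zero-mean Gaussian with standard deviation
#' `a_j * (1 + jitter_j)`, `jitter_j ~ U(-noise_scale, +noise_scale)`
#' drawn once per channel per call (i.e. per window), with
#' `a_j = max(0, (S intent + baseline)_j)`. Consumes the current R random
#' stream; seed at the session level for reproducibility.
#'
#' @param user A [virtual_user()].
#' @param intent Length-3 numeric motor intent.
#' @param n_samples Number of frames to emit (default 40, one 200 ms
#'   window at 200 Hz).
#' @return Numeric `n_samples` x M matrix.
#' @export
emit_emg <- function(user, intent, n_samples = 40) {
  stopifnot(inherits(user, "virtual_user"))
  if (!is_scalar_number(n_samples) || n_samples < 1) {
    stop("`n_samples` must be a positive number", call. = FALSE)
  }
  n <- as.integer(n_samples)
  a <- expected_rms(user, intent)
  if (user$noise_scale > 0) {
    a <- a * (1 + stats::runif(length(a), -user$noise_scale, user$noise_scale))
  }
  M <- user$channel_count
  z <- matrix(stats::rnorm(n * M), n, M)
  sweep(z, 2, a, `*`)
}

#' Feedback-corrected motor intent
#'
#' The user's closed-loop behaviour model: seeing the cursor at `cursor`
#' while prompted toward `prompt`, the user exaggerates the contraction in
#' the direction of the residual error,
#'
#'   intent = prompt + g (prompt - cursor),
#'
#' clipped component-wise to `[-1.5, 1.5]` (contractions saturate). With
#' feedback off (or `g = 0`) the intent is the prompt itself, reducing
#' closed-loop sessions to open-loop behaviour.
#'
#' The rest prompt `(0, 0, 0)` is the one exception: humans return a
#' cursor to center by relaxing, not by counter-contracting against it,
#' so for an all-zero prompt the intent is zero regardless of the cursor.
#'
#' @param user A [virtual_user()]; must have a non-`NA` `feedback_gain`
#'   when `feedback = TRUE`.
#' @param prompt Length-3 prompted target.
#' @param cursor Length-3 current cursor estimate.
#' @param feedback Is the cursor visible to the user? Default `TRUE`.
#' @return Length-3 intent vector.
#' @export
closed_loop_intent <- function(user, prompt, cursor, feedback = TRUE) {
  stopifnot(inherits(user, "virtual_user"),
            length(prompt) == 3L, length(cursor) == 3L)
  if (!feedback) return(as.numeric(prompt))
  if (is.na(user$feedback_gain)) {
    stop("user has no feedback model (feedback_gain is NA); cannot run closed-loop",
         call. = FALSE)
  }
  prompt <- as.numeric(prompt)
  if (all(prompt == 0)) return(prompt)  # rest: relax, don't counter-push
  retained <- user$correction[[target_key(prompt)]] %||% c(0, 0, 0)
  clip_dof(prompt + user$feedback_gain * (prompt - as.numeric(cursor)) + retained,
           1.5)
}

target_key <- function(target) paste(as.numeric(target), collapse = ",")

# Motor-learning consolidation after a feedback prompt: the user retains
# retention * feedback_gain of the average correction the prompt required,
# as a persistent per-target intent calibration (capped at +/- 0.5 per
# component; motor memories saturate). No-op for rest prompts, users
# without feedback reactions, or retention = 0.
consolidate_correction <- function(user, target, mean_error) {
  if (is.na(user$feedback_gain) || user$feedback_gain <= 0 ||
      user$retention <= 0 || all(target == 0)) {
    return(user)
  }
  key <- target_key(target)
  old <- user$correction[[key]] %||% c(0, 0, 0)
  user$correction[[key]] <- clip_dof(
    old + user$retention * user$feedback_gain * mean_error, 0.5)
  user
}

# Random-walk drift of the synergy matrix over `duration` seconds; models
# slow fatigue / electrode-shift non-stationarity. Identity when
# adaptation_rate == 0.
drift_user <- function(user, duration) {
  if (user$adaptation_rate <= 0) return(user)
  step <- matrix(stats::rnorm(length(user$synergy), 0,
                              user$adaptation_rate * sqrt(duration)),
                 nrow(user$synergy), ncol(user$synergy))
  user$synergy <- user$synergy + step
  user
}

#' Serialize / restore a virtual user as JSON
#'
#' Writes the full user state (synergy, baseline, gains, seed) so any
#' experiment is reconstructible from text files.
#'
#' @param user A [virtual_user()].
#' @param path File path.
#' @return `write_virtual_user_json()` returns `path` invisibly;
#'   `read_virtual_user_json()` returns the restored `virtual_user`.
#' @export
write_virtual_user_json <- function(user, path) {
  stopifnot(inherits(user, "virtual_user"))
  obj <- list(synergy = user$synergy, baseline = user$baseline,
              noise_scale = user$noise_scale, feedback_gain = user$feedback_gain,
              adaptation_rate = user$adaptation_rate,
              retention = user$retention, correction = user$correction,
              seed = user$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_virtual_user_json
#' @export
read_virtual_user_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  u <- virtual_user(synergy = obj$synergy, baseline = obj$baseline,
                    noise_scale = obj$noise_scale,
                    feedback_gain = obj$feedback_gain %||% NA_real_,
                    adaptation_rate = obj$adaptation_rate %||% 0,
                    retention = obj$retention %||% 0.5,
                    seed = obj$seed %||% NA_integer_)
  if (length(obj$correction) > 0) {
    u$correction <- lapply(obj$correction, as.numeric)
  }
  u
}
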