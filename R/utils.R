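# Internal helpers shared across modules. Nothing here is exported.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards so seeded sessions never perturb the
# user's random stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  genv <- globalenv()
  has_old <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(as.integer(seed %% 2147483647))
  force(expr)
}

# Deterministic sub-seed derivation: one top-level seed fans out into
# independent streams (user draw, prompt order, session noise, test order).
# Kept inside 32-bit range; exact in double arithmetic (< 2^53).
derive_seed <- function(seed, stream) {
  ((seed %% 2147483647) * 69621 + stream * 9973) %% 2147483647
}

# Component-wise clipping to a symmetric box.
clip_dof <- function(v, bound) {
  pmin(pmax(v, -bound), bound)
}

# Short provenance digest of any jsonlite-serializable object (rolling
# polynomial hash; for audit trails, not cryptography).
config_digest <- function(x) {
  s <- as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Append new sample frames to a trailing buffer, keeping the last W rows.
# This realizes the sliding window of the real-time system: per control
# tick only one hop of fresh samples arrives, so consecutive windows
# overlap by W - H samples.
slide_buffer <- function(buf, new_frames, W) {
  buf <- if (is.null(buf)) new_frames else rbind(buf, new_frames)
  n <- nrow(buf)
  if (n > W) buf <- buf[(n - W + 1L):n, , drop = FALSE]
  buf
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
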