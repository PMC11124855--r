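# Independent brute-force oracles and small fixture builders shared across
# the test files. Oracles are deliberately written as naive loops so they
# share no code path with the implementation they check.

# Per-channel RMS by explicit double loop.
brute_rms <- function(segment) {
  M <- ncol(segment)
  out <- numeric(M)
  for (j in seq_len(M)) {
    acc <- 0
    for (i in seq_len(nrow(segment))) acc <- acc + segment[i, j]^2
    out[j] <- sqrt(acc / nrow(segment))
  }
  out
}

# Linear prediction by explicit double loop.
brute_predict <- function(B, x) {
  out <- numeric(nrow(B))
  for (i in seq_len(nrow(B))) {
    s <- 0
    for (j in seq_len(ncol(B))) s <- s + B[i, j] * x[j]
    out[i] <- s
  }
  out
}

# Number of complete windows by enumerating start indices.
brute_window_count <- function(N, W, H) {
  count <- 0L
  s <- 1L
  while (s + W - 1L <= N) {
    count <- count + 1L
    s <- s + H
  }
  count
}

# Hit detection by enumerating every contiguous within-radius run.
brute_detect_hit <- function(trajectory, target, cfg, time = NULL) {
  if (is.null(time)) time <- (seq_len(nrow(trajectory)) - 1) * cfg$tick
  r <- hit_radius(cfg)
  inside <- logical(nrow(trajectory))
  for (i in seq_len(nrow(trajectory))) {
    inside[i] <- sqrt(sum((trajectory[i, ] - target)^2)) < r
  }
  entrances <- 0L
  prev <- FALSE
  for (i in seq_along(inside)) {
    if (inside[i] && !prev) entrances <- entrances + 1L
    prev <- inside[i]
  }
  hit <- FALSE
  time_to_hit <- NA_real_
  i <- 1L
  n <- length(inside)
  while (i <= n) {
    if (inside[i]) {
      j <- i
      while (j < n && inside[j + 1L]) j <- j + 1L
      span <- time[j] - time[i]
      complete <- time[i] + cfg$hold_duration
      if (span >= cfg$hold_duration - 1e-9 && complete <= cfg$timeout + 1e-9) {
        hit <- TRUE
        time_to_hit <- complete
        break
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  list(hit = hit, time_to_hit = time_to_hit, entrances = entrances)
}

# Fabricate a trial record from a trajectory matrix (tick-spaced).
make_trial <- function(trajectory, target, cfg = task_config(),
                       tick = cfg$tick) {
  trajectory <- as.matrix(trajectory)
  time <- (seq_len(nrow(trajectory)) - 1) * tick
  dh <- detect_hit(trajectory, target, cfg, time = time)
  steps <- diff(trajectory)
  list(target = as.numeric(target), trajectory = trajectory, time = time,
       hit = dh$hit, time_to_hit = dh$time_to_hit, entrances = dh$entrances,
       path_length = sum(sqrt(rowSums(steps^2))))
}

# A clean noiseless, rest-silent virtual user (exactly decodable synergy).
noiseless_user <- function(seed) {
  make_virtual_user(seed, "easy", noise_scale = 0, baseline = 0)
}

# Random 3-D rotation matrix.
random_rotation <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
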