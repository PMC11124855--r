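test_that("hit radius is 10% of the workspace diagonal by default", {
  cfg <- task_config()
  expect_equal(hit_radius(cfg), 0.10 * 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(hit_radius(task_config(radius_normalizer = "axis")), 0.2)
})

test_that("detect_hit handles the ideal and hopeless cases", {
  cfg <- task_config()
  target <- c(1, 0, 0)

  # constantly at the target for 2 s: hit at exactly the hold duration
  traj <- matrix(rep(target, each = 51), 51, 3)
  r <- detect_hit(traj, target, cfg)
  expect_true(r$hit)
  expect_equal(r$entrances, 1L)
  expect_equal(r$time_to_hit, cfg$hold_duration)

  # never within the radius
  far <- matrix(rep(c(-1, 0, 0), each = 51), 51, 3)
  r2 <- detect_hit(far, target, cfg)
  expect_false(r2$hit)
  expect_equal(r2$entrances, 0L)
  expect_true(is.na(r2$time_to_hit))
})

test_that("a short visit then a qualifying revisit gives two entrances", {
  cfg <- task_config()
  target <- c(0, 0, 0)
  inside <- c(0.1, 0, 0)   # dist 0.1 < radius
  outside <- c(1, 1, 1)    # far outside
  # 10 ticks out, 13 in (span 0.48 s, too short), 25 out, 31 in (span 1.2 s)
  traj <- rbind(matrix(rep(outside, each = 10), 10, 3),
                matrix(rep(inside, each = 13), 13, 3),
                matrix(rep(outside, each = 25), 25, 3),
                matrix(rep(inside, each = 31), 31, 3))
  r <- detect_hit(traj, target, cfg)
  expect_true(r$hit)
  expect_equal(r$entrances, 2L)
  # second run enters at sample index 49 (0-based 48) -> t = 1.92 s
  expect_equal(r$time_to_hit, 48 * cfg$tick + cfg$hold_duration)
  ro <- brute_detect_hit(traj, target, cfg)
  expect_equal(r, ro)
})

test_that("the qualifying hold must complete before the timeout", {
  cfg <- task_config(timeout = 2, hold_duration = 1)
  target <- c(0, 0, 0)
  n <- 76  # samples out to t = 3 s, past the 2 s timeout
  traj <- matrix(rep(c(1, 1, 1), each = n), n, 3)
  enter_at <- 41L  # t = 1.6 s; inside until 3 s (span 1.4 s >= hold)
  traj[enter_at:n, ] <- 0
  r <- detect_hit(traj, target, cfg)
  expect_false(r$hit)  # the hold would only complete at 2.6 s > timeout
  expect_equal(r$entrances, 1L)
})

test_that("detect_hit agrees with the brute-force run-length oracle", {
  cfg <- task_config(timeout = 4)
  set.seed(301)
  for (rep in 1:200) {
    target <- as.numeric(all_targets()[sample(27, 1), ])
    n <- sample(5:101, 1)
    # random walk hovering near the target so runs of both kinds occur
    traj <- matrix(rep(target, each = n), n, 3) +
      apply(matrix(rnorm(n * 3, 0, 0.15), n, 3), 2, cumsum)
    r <- detect_hit(traj, target, cfg)
    ro <- brute_detect_hit(traj, target, cfg)
    expect_equal(r, ro)
  }
})

test_that("shrinking the hit radius never converts a miss into a hit", {
  set.seed(302)
  big <- task_config()
  small <- task_config(hit_fraction = 0.05)
  hits_small <- hits_big <- 0L
  for (rep in 1:50) {
    n <- 80
    target <- c(1, 0, -1)
    traj <- matrix(rep(target, each = n), n, 3) +
      apply(matrix(rnorm(n * 3, 0, 0.1), n, 3), 2, cumsum)
    s <- detect_hit(traj, target, small)$hit
    b <- detect_hit(traj, target, big)$hit
    if (s) expect_true(b)
    hits_small <- hits_small + s
    hits_big <- hits_big + b
  }
  expect_lte(hits_small, hits_big)
  expect_gt(hits_big, 0)  # the construction does produce hits to compare
})

test_that("run_test presents all 27 targets and respects the zero decoder", {
  u <- make_virtual_user(7, "medium")
  cfg <- task_config(timeout = 1.6, hold_duration = 1)
  ts <- run_test(zero_coefficients(), u, seed = 5, cfg = cfg)
  expect_length(ts$trials, 27L)
  shown <- t(vapply(ts$trials, `[[`, numeric(3), "target"))
  expect_setequal(apply(shown, 1, paste, collapse = ","),
                  apply(all_targets(), 1, paste, collapse = ","))
  # cursor pinned at origin: rest is hit, every non-rest target missed
  for (tr in ts$trials) {
    if (all(tr$target == 0)) expect_true(tr$hit) else expect_false(tr$hit)
  }
})

test_that("test sessions are deterministic under seeding and bounded in length", {
  u <- make_virtual_user(8, "medium")
  B <- matrix(rnorm(24, 0, 0.2), 3, 8)
  cfg <- task_config(timeout = 1.2, hold_duration = 0.6)
  a <- run_test(B, u, seed = 9, cfg = cfg)
  b <- run_test(B, u, seed = 9, cfg = cfg)
  expect_identical(a$trials, b$trials)
  expect_false(identical(a$trials,
                         run_test(B, u, seed = 10, cfg = cfg)$trials))
  max_len <- ceiling(cfg$timeout / cfg$tick) + 1
  for (tr in a$trials) expect_lte(nrow(tr$trajectory), max_len)
})

test_that("a decoder matching the user's synergy inverse hits all 27 targets", {
  u <- noiseless_user(11)
  E <- t(apply(all_targets(), 1, function(d) expected_rms(u, d)))
  Bstar <- t(qr.solve(crossprod(E) + 1e-9 * diag(8), crossprod(E, all_targets())))
  # exact decodability of the clean antagonist synergy
  for (i in 1:27) {
    expect_equal(predict_dof(Bstar, E[i, ]), as.numeric(all_targets()[i, ]),
                 tolerance = 1e-3)
  }
  ts <- run_test(Bstar, u, seed = 12)
  expect_equal(completion_rate(ts), 1.0)
})

test_that("session logs are written as JSON lines and CSV summaries", {
  u <- make_virtual_user(7, "medium")
  ts <- run_test(zero_coefficients(), u, seed = 5,
                 cfg = task_config(timeout = 1.6, hold_duration = 1))
  jl <- withr::local_tempfile(fileext = ".jsonl")
  cs <- withr::local_tempfile(fileext = ".csv")
  write_session_jsonl(ts, jl)
  write_trial_summary_csv(ts, cs)
  lines <- readLines(jl)
  expect_length(lines, 27L)
  rec <- jsonlite::fromJSON(lines[1])
  expect_true(all(c("target", "hit", "entrances", "path_length") %in% names(rec)))
  df <- read.csv(cs)
  expect_equal(nrow(df), 27L)
  expect_equal(sum(df$hit), sum(vapply(ts$trials, `[[`, logical(1), "hit")))
})
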