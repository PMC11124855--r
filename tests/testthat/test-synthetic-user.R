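test_that("virtual users are deterministic given the seed", {
  expect_identical(make_virtual_user(3, "medium"), make_virtual_user(3, "medium"))
  expect_false(identical(make_virtual_user(3, "medium")$synergy,
                         make_virtual_user(4, "medium")$synergy))
})

test_that("generated synergies have full column rank and easy users are well conditioned", {
  for (seed in 1:20) {
    u <- make_virtual_user(seed, "easy")
    expect_equal(qr(u$synergy)$rank, 3L)
    expect_lt(kappa(u$synergy, exact = TRUE), 10)
  }
  for (seed in 1:10) {
    expect_equal(qr(make_virtual_user(seed, "hard")$synergy)$rank, 3L)
  }
})

test_that("difficulty orders the amplitude jitter", {
  e <- make_virtual_user(1, "easy")$noise_scale
  m <- make_virtual_user(1, "medium")$noise_scale
  h <- make_virtual_user(1, "hard")$noise_scale
  expect_true(e <= m && m <= h)
})

test_that("a rest-silent user at rest emits exact silence", {
  u <- noiseless_user(2)
  block <- emit_emg(u, c(0, 0, 0), 40)
  expect_equal(block, matrix(0, 40, 8))
  expect_equal(expected_rms(u, c(0, 0, 0)), rep(0, 8))
})

test_that("window RMS concentrates around the amplitude profile", {
  u <- noiseless_user(3)
  intent <- c(1, 0, 0)
  a <- expected_rms(u, intent)
  active <- which(a > 1e-9)
  set.seed(501)
  n_win <- 1000
  rms <- t(replicate(n_win, rms_window(emit_emg(u, intent, 40))))
  for (j in active) {
    rel <- rms[, j] / a[j]
    # chi-distribution concentration at n = 40: the vast majority of
    # windows within 25%, the mean within 2%
    expect_gt(mean(abs(rel - 1) < 0.25), 0.9)
    expect_equal(mean(rel), 1, tolerance = 0.02)
  }
})

test_that("mean RMS is linear in intent on the unrectified region", {
  u <- noiseless_user(4)
  set.seed(502)
  a1 <- expected_rms(u, c(0.5, 0, 0))
  active <- which(a1 > 1e-9)
  m1 <- colMeans(t(replicate(500, rms_window(emit_emg(u, c(0.5, 0, 0), 40)))))
  m2 <- colMeans(t(replicate(500, rms_window(emit_emg(u, c(1.0, 0, 0), 40)))))
  expect_equal(m2[active] / m1[active], rep(2, length(active)), tolerance = 0.03)
})

test_that("closed-loop intent applies proportional correction with clipping", {
  u <- make_virtual_user(5, "medium")  # feedback_gain 0.5
  prompt <- c(1, 0, 0)
  expect_equal(closed_loop_intent(u, prompt, prompt), prompt)
  expect_equal(closed_loop_intent(u, prompt, c(0, 0, 0)), c(1.5, 0, 0))
  expect_equal(closed_loop_intent(u, prompt, c(-9, 0, 0)), c(1.5, 0, 0))  # clipped
  expect_equal(closed_loop_intent(u, prompt, c(2, 2, 2), feedback = FALSE), prompt)
  # the rest prompt means relaxing, wherever the cursor is
  expect_equal(closed_loop_intent(u, c(0, 0, 0), c(1, -1, 0.5)), c(0, 0, 0))

  g0 <- make_virtual_user(5, "medium", feedback_gain = 0)
  expect_equal(closed_loop_intent(g0, prompt, c(-1, 2, 0)), prompt)

  nofb <- make_virtual_user(5, "medium", feedback_gain = NA)
  expect_error(closed_loop_intent(nofb, prompt, c(0, 0, 0)), "feedback model")
})

test_that("feedback training with zero gain reduces Protocol III to Protocol II data", {
  u0 <- make_virtual_user(6, "medium", feedback_gain = 0)
  p2 <- protocol_sequence("II", seed = 21, prompt_duration = 0.6, rest_duration = 0.4)
  p3 <- protocol_sequence("III", seed = 21, prompt_duration = 0.6, rest_duration = 0.4)
  s2 <- train_closed_loop(p2, u0, seed = 22)
  s3 <- train_closed_loop(p3, u0, seed = 22)
  expect_equal(s3$pairs, s2$pairs, tolerance = 1e-12)
  expect_equal(s3$weights, s2$weights, tolerance = 1e-12)
  expect_identical(s3$user$correction, list())  # no learning without gain
})

test_that("users retain per-target calibrations only from feedback practice", {
  u <- make_virtual_user(7, "medium")
  p1 <- protocol_sequence("I", seed = 23, prompt_duration = 0.6, rest_duration = 0.4)
  p3 <- protocol_sequence("III", seed = 23, prompt_duration = 0.6, rest_duration = 0.4)
  s1 <- train_closed_loop(p1, u, seed = 24)
  s3 <- train_closed_loop(p3, u, seed = 24)
  expect_identical(s1$user$correction, list())
  expect_equal(length(s3$user$correction), 20L)  # the combined targets
  caps <- unlist(s3$user$correction)
  expect_true(all(abs(caps) <= 0.5 + 1e-12))
})

test_that("virtual users serialize to JSON and back", {
  u <- make_virtual_user(8, "hard", adaptation_rate = 0.01)
  u$correction[["1,1,0"]] <- c(0.1, -0.2, 0)
  path <- withr::local_tempfile(fileext = ".json")
  write_virtual_user_json(u, path)
  v <- read_virtual_user_json(path)
  expect_equal(v$synergy, u$synergy, tolerance = 1e-12)
  expect_equal(v$baseline, u$baseline)
  expect_equal(v$noise_scale, u$noise_scale)
  expect_equal(v$feedback_gain, u$feedback_gain)
  expect_equal(v$adaptation_rate, u$adaptation_rate)
  expect_equal(v$correction, u$correction, tolerance = 1e-12)
})

test_that("an exact linear decoder exists for a clean noiseless user", {
  u <- noiseless_user(9)
  E <- t(apply(all_targets(), 1, function(d) expected_rms(u, d)))
  B <- t(qr.solve(crossprod(E) + 1e-9 * diag(8), crossprod(E, all_targets())))
  err <- max(abs(E %*% t(B) - all_targets()))
  expect_lt(err, 1e-3)
})
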