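# End-to-end session behaviour: training loops, offline replay, cohort
# experiments. Short prompt durations keep these fast; full-length
# sessions are exercised in test-acceptance.R.

short_protocol <- function(id, seed = 31) {
  protocol_sequence(id, seed = seed, prompt_duration = 0.6, rest_duration = 0.4)
}

test_that("training sessions are deterministic and record one pair per update", {
  u <- make_virtual_user(11, "medium")
  p <- short_protocol("II")
  a <- train_closed_loop(p, u, seed = 32)
  b <- train_closed_loop(p, u, seed = 32)
  expect_identical(a$weights, b$weights)
  expect_identical(a$pairs, b$pairs)
  expect_false(identical(a$weights, train_closed_loop(p, u, seed = 33)$weights))
  # 15-tick prompts and 10-tick rests, minus the 4 buffer-fill ticks each
  expect_equal(nrow(a$pairs), 26 * (15 - 4) + 26 * (10 - 4))
  expect_true(all(is.finite(a$weights)))
  expect_false(a$closed_loop)
  expect_true(train_closed_loop(short_protocol("III"), u, seed = 32)$closed_loop)
})

test_that("training squared error decreases over an open-loop session", {
  u <- make_virtual_user(12, "medium")
  s <- train_closed_loop(short_protocol("I"), u, seed = 34)
  n <- length(s$sq_error)
  early <- mean(s$sq_error[1:50])
  late <- mean(s$sq_error[(n - 49):n])
  expect_lt(late, early)
})

test_that("a feedback protocol requires a user with a feedback model", {
  nofb <- make_virtual_user(13, "medium", feedback_gain = NA)
  expect_error(train_closed_loop(short_protocol("III"), nofb, seed = 1),
               "feedback")
  # open-loop protocols are fine for the same user
  expect_s3_class(train_closed_loop(short_protocol("I"), nofb, seed = 1),
                  "training_session")
})

test_that("offline replay reproduces the online open-loop weights exactly", {
  u <- make_virtual_user(14, "medium")
  s <- train_closed_loop(short_protocol("I"), u, seed = 35)
  fit <- replay_open_loop(s)
  expect_identical(fit$weights, s$weights)   # bit-for-bit

  # through the CSV recording (text round-trip: near-exact)
  path <- withr::local_tempfile(fileext = ".csv")
  write_training_pairs_csv(s, path)
  fit2 <- replay_open_loop(path)
  expect_equal(fit2$weights, s$weights, tolerance = 1e-12)

  # shuffled rows re-sorted by timestamp give the same result
  df <- read_training_pairs_csv(path)
  fit3 <- replay_open_loop(df[sample(nrow(df)), ])
  expect_identical(fit3$weights, fit2$weights)
})

test_that("closed-loop recordings are refused for replay", {
  u <- make_virtual_user(15, "medium")
  s3 <- train_closed_loop(short_protocol("III"), u, seed = 36)
  expect_error(replay_open_loop(s3), "online-only|cannot be replayed")
  path <- withr::local_tempfile(fileext = ".csv")
  write_training_pairs_csv(s3, path)
  expect_error(replay_open_loop(path), "closed-loop")
})

test_that("malformed recordings raise parse errors", {
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines(character(0), empty)
  expect_error(replay_open_loop(empty), "parse|no pairs")

  header_only <- withr::local_tempfile(fileext = ".csv")
  writeLines("t,x1,x2,x3,x4,x5,x6,x7,x8,d1,d2,d3", header_only)
  expect_error(replay_open_loop(header_only), "no pairs")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,x1,x2,x3,x4,x5,x6,x7,x8,d1,d2,d3",
               "0.2,1,2,3,4,5,6,7,8,0,0,1",
               "0.24,1,2,oops,4,5,6,7,8,0,0,1"), bad)
  expect_error(replay_open_loop(bad), "line")
})

test_that("experiment configs validate fields by name", {
  expect_error(experiment_config(protocols = "IV"), "protocols")
  expect_error(experiment_config(cohort_size = 0), "cohort_size")
  expect_error(experiment_config(difficulty = "impossible"), "difficulty")
  expect_error(experiment_config(prompt_duration = -1), "prompt_duration")
})

test_that("run_experiment is deterministic down to its output files", {
  base <- experiment_config(protocols = c("I", "III"), cohort_size = 2,
                            seed = 7, difficulty = "medium",
                            prompt_duration = 0.6, rest_duration = 0.4,
                            task = task_config(timeout = 3, hold_duration = 1))
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  cfg1 <- base; cfg1$out_dir <- dir1
  cfg2 <- base; cfg2$out_dir <- dir2
  r1 <- run_experiment(cfg1)
  r2 <- run_experiment(cfg2)
  expect_equal(r1$per_user, r2$per_user)
  expect_equal(r1$summary, r2$summary)
  files <- sort(list.files(dir1))
  expect_identical(files, sort(list.files(dir2)))
  expect_true(all(c("cohort_summary.csv", "per_user_metrics.csv",
                    "metadata.json") %in% files))
  for (f in files) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)), info = f)
  }
})

test_that("cohort reports carry per-user strata and a Friedman comparison", {
  cfg <- experiment_config(protocols = c("I", "II"), cohort_size = 3,
                           seed = 9, difficulty = "medium",
                           prompt_duration = 0.6, rest_duration = 0.4,
                           task = task_config(timeout = 3, hold_duration = 1))
  r <- run_experiment(cfg)
  expect_equal(nrow(r$per_user), 3 * 2 * 5)  # users x protocols x strata
  expect_equal(nrow(r$summary), 2 * 5)
  expect_true(all(c("completion_rate_mean", "completion_rate_sd",
                    "path_efficiency_mean", "attempt_ratio_mean")
                  %in% names(r$summary)))
  expect_false(is.null(r$friedman$overall))
  expect_s3_class(r$friedman$overall, "htest")
})
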