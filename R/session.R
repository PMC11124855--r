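#' Experiment configuration
#'
#' Bundles every knob of a simulated cohort experiment: which training
#' protocols to run, how many virtual users, their difficulty, and the
#' adaptation / task / windowing settings. Every random decision in a run
#' derives deterministically from the single `seed`, and all seeds are
#' recorded in the outputs.
#'
#' @param protocols Character vector of protocol ids among
#'   `"I", "II", "III"`.
#' @param cohort_size Number of simulated users (default 1).
#' @param seed Master integer seed.
#' @param difficulty Virtual-user difficulty: `"easy"`, `"medium"` or
#'   `"hard"`.
#' @param adaptation An [adaptation_config()].
#' @param task A [task_config()].
#' @param windowing A [windowing_config()].
#' @param prompt_duration,rest_duration Training prompt lengths in
#'   seconds (defaults 3 and 2).
#' @param out_dir Optional output directory for logs and summaries.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(protocols = "II", cohort_size = 1, seed = 1,
                              difficulty = "medium",
                              adaptation = adaptation_config(),
                              task = task_config(),
                              windowing = windowing_config(),
                              prompt_duration = 3, rest_duration = 2,
                              out_dir = NULL) {
  bad <- function(field, why) {
    stop(sprintf("invalid experiment config: `%s` %s", field, why), call. = FALSE)
  }
  if (!is.character(protocols) || length(protocols) < 1L ||
      !all(protocols %in% c("I", "II", "III"))) {
    bad("protocols", "must be a subset of {\"I\", \"II\", \"III\"}")
  }
  if (anyDuplicated(protocols)) bad("protocols", "has duplicates")
  if (!is_scalar_number(cohort_size) || cohort_size < 1 ||
      cohort_size != round(cohort_size)) {
    bad("cohort_size", "must be a positive integer")
  }
  if (!is_scalar_number(seed)) bad("seed", "must be a single number")
  if (!is.character(difficulty) || length(difficulty) != 1L ||
      !difficulty %in% c("easy", "medium", "hard")) {
    bad("difficulty", "must be \"easy\", \"medium\" or \"hard\"")
  }
  if (!inherits(adaptation, "adaptation_config")) bad("adaptation", "is not an adaptation_config")
  if (!inherits(task, "task_config")) bad("task", "is not a task_config")
  if (!inherits(windowing, "windowing_config")) bad("windowing", "is not a windowing_config")
  if (!is_scalar_number(prompt_duration) || prompt_duration <= 0) {
    bad("prompt_duration", "must be positive")
  }
  if (!is_scalar_number(rest_duration) || rest_duration <= 0) {
    bad("rest_duration", "must be positive")
  }
  structure(list(protocols = protocols, cohort_size = as.integer(cohort_size),
                 seed = seed, difficulty = difficulty, adaptation = adaptation,
                 task = task, windowing = windowing,
                 prompt_duration = prompt_duration,
                 rest_duration = rest_duration, out_dir = out_dir),
            class = "experiment_config")
}

config_metadata <- function(config) {
  meta <- list(protocols = config$protocols, cohort_size = config$cohort_size,
               seed = config$seed, difficulty = config$difficulty,
               learning_rate = config$adaptation$learning_rate,
               regularizer = config$adaptation$regularizer,
               prompt_duration = config$prompt_duration,
               rest_duration = config$rest_duration,
               timeout = config$task$timeout,
               hold_duration = config$task$hold_duration,
               hit_fraction = config$task$hit_fraction)
  meta$digest <- config_digest(meta)
  meta
}

#' Run a simulated cohort experiment
#'
#' The full pipeline: for each virtual user in the cohort and each
#' configured protocol, train a decoder from scratch under that protocol
#' ([train_closed_loop()]), run the frozen-decoder 27-target test
#' ([run_test()]), and compute stratified metrics ([session_metrics()]).
#' Seeds are shared across protocols — the same users, prompt orders and
#' test orders — so protocol comparisons are paired, mirroring a
#' within-subject design. When at least two protocols are configured, a
#' Friedman test (standard `stats::friedman.test`) compares per-user
#' completion rates across protocols, overall and for the 3-DoF stratum.
#'
#' With `out_dir` set, writes per-user JSON-lines trial logs, a per-user
#' metrics CSV, a cohort summary CSV and a metadata JSON embedding the
#' config digest and all seeds. Outputs contain no timestamps: identical
#' configs produce byte-identical files.
#'
#' @param config An [experiment_config()].
#' @return An object of class `cohort_report`: list with `per_user`
#'   (long data frame: user, protocol, stratum, metrics), `summary`
#'   (mean and sd per protocol x stratum), `friedman` (list of test
#'   results or `NULL`), and `config`.
#' @examples
#' \donttest{
#' cfg <- experiment_config(protocols = c("I", "III"), cohort_size = 2,
#'                          seed = 1, prompt_duration = 1, rest_duration = 0.6,
#'                          task = task_config(timeout = 6))
#' rep <- run_experiment(cfg)
#' rep$summary
#' }
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  seed <- config$seed
  rows <- list()

  for (u in seq_len(config$cohort_size)) {
    user <- make_virtual_user(derive_seed(seed, u), config$difficulty)
    for (p in config$protocols) {
      prot <- protocol_sequence(p, derive_seed(seed, 1000),
                                prompt_duration = config$prompt_duration,
                                rest_duration = config$rest_duration)
      sess <- train_closed_loop(prot, user, cfg = config$adaptation,
                                windowing = config$windowing,
                                seed = derive_seed(seed, 2000 + u))
      test <- run_test(sess$weights, sess$user,
                       seed = derive_seed(seed, 3000 + u),
                       cfg = config$task, windowing = config$windowing)
      m <- session_metrics(test)
      m$user <- u
      m$protocol <- p
      rows[[length(rows) + 1L]] <- m

      if (!is.null(config$out_dir)) {
        dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
        stem <- file.path(config$out_dir, sprintf("user%02d_protocol%s", u, p))
        write_session_jsonl(test, paste0(stem, "_trials.jsonl"))
        write_coefficients_csv(sess$weights, paste0(stem, "_weights.csv"))
      }
    }
  }

  per_user <- do.call(rbind, rows)
  per_user <- per_user[, c("user", "protocol", "stratum", "n_trials", "n_hits",
                           "completion_rate", "path_efficiency", "attempt_ratio")]
  class(per_user) <- "data.frame"

  agg <- function(metric) {
    mean_df <- stats::aggregate(per_user[[metric]],
                                by = list(protocol = per_user$protocol,
                                          stratum = per_user$stratum),
                                FUN = function(v) mean(v, na.rm = TRUE))
    sd_df <- stats::aggregate(per_user[[metric]],
                              by = list(protocol = per_user$protocol,
                                        stratum = per_user$stratum),
                              FUN = function(v) stats::sd(v, na.rm = TRUE))
    names(mean_df)[3] <- paste0(metric, "_mean")
    names(sd_df)[3] <- paste0(metric, "_sd")
    merge(mean_df, sd_df, by = c("protocol", "stratum"))
  }
  summary <- Reduce(function(a, b) merge(a, b, by = c("protocol", "stratum")),
                    lapply(c("completion_rate", "path_efficiency",
                             "attempt_ratio"), agg))
  summary <- summary[order(summary$protocol,
                           match(summary$stratum,
                                 c("all", "rest", "1-DoF", "2-DoF", "3-DoF"))), ]
  rownames(summary) <- NULL

  friedman <- NULL
  if (length(config$protocols) >= 2L && config$cohort_size >= 2L) {
    cr_matrix <- function(stratum) {
      sub <- per_user[per_user$stratum == stratum, ]
      m <- matrix(NA_real_, config$cohort_size, length(config$protocols),
                  dimnames = list(NULL, config$protocols))
      for (i in seq_len(nrow(sub))) {
        m[sub$user[i], sub$protocol[i]] <- sub$completion_rate[i]
      }
      m
    }
    friedman <- list(
      overall = tryCatch(stats::friedman.test(cr_matrix("all")),
                         error = function(e) NULL),
      three_dof = tryCatch(stats::friedman.test(cr_matrix("3-DoF")),
                           error = function(e) NULL)
    )
  }

  report <- structure(list(per_user = per_user, summary = summary,
                           friedman = friedman, config = config),
                      class = "cohort_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(per_user, file.path(config$out_dir, "per_user_metrics.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(summary, file.path(config$out_dir, "cohort_summary.csv"),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(config_metadata(config),
                         file.path(config$out_dir, "metadata.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d user(s), protocol(s) %s, difficulty %s, seed %s\n",
              x$config$cohort_size, paste(x$config$protocols, collapse = "/"),
              x$config$difficulty, format(x$config$seed)))
  print.data.frame(x$summary, digits = 3, row.names = FALSE)
  if (!is.null(x$friedman) && !is.null(x$friedman$three_dof)) {
    cat(sprintf("Friedman test, 3-DoF CR across protocols: p = %.3g\n",
                x$friedman$three_dof$p.value))
  }
  invisible(x)
}
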