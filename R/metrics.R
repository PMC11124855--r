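# Real-time task performance metrics: CR, PE, AR. Error-style offline
# metrics (R^2, correlation) are deliberately not provided — they do not
# describe whole-system real-time performance.

# Accept a test_session or a bare list of trial records.
as_trials <- function(x) {
  if (inherits(x, "test_session")) return(x$trials)
  if (is.list(x) && length(x) > 0 && !is.null(x[[1]]$target)) return(x)
  if (is.list(x) && length(x) == 0) return(x)
  stop("expected a test_session or a list of trial records", call. = FALSE)
}

#' Completion rate
#'
#' Fraction of test targets acquired: hits (target reached within the hit
#' radius and held for the required duration before timeout) over the
#' total number of trials. Higher is better.
#'
#' @param trials A `test_session` or list of trial records.
#' @return A fraction in `[0, 1]`.
#' @export
completion_rate <- function(trials) {
  trials <- as_trials(trials)
  if (length(trials) < 1L) stop("need at least one trial", call. = FALSE)
  mean(vapply(trials, `[[`, logical(1), "hit"))
}

#' Path efficiency of one trial
#'
#' Straight-line distance from the trial's actual starting cursor
#' position to the target, divided by the distance the cursor actually
#' traveled. On a hit, travel is measured up to the completion of the
#' hold; on a miss, over the whole trial. 1 means a perfectly straight
#' approach. The starting position is the carry-over cursor from the
#' previous trial, since the shortest path premise is motion from
#' wherever the cursor was. Undefined (NA) when the trial starts already
#' at the target (zero required displacement) or when the cursor never
#' moved on a miss; numerically degenerate cases where travel is shorter
#' than the straight line are capped at 1.
#'
#' @param trial One trial record (see [run_test()]).
#' @return A fraction in `(0, 1]`, or `NA` where undefined.
#' @export
path_efficiency <- function(trial) {
  if (is.null(trial$trajectory) || is.null(trial$target)) {
    stop("`trial` must be a trial record with trajectory and target", call. = FALSE)
  }
  traj <- trial$trajectory
  if (nrow(traj) < 2L) stop("trial needs at least two trajectory samples", call. = FALSE)
  start <- traj[1L, ]
  required <- sqrt(sum((start - trial$target)^2))
  if (required < 1e-12) return(NA_real_)
  if (isTRUE(trial$hit) && !is.na(trial$time_to_hit) && !is.null(trial$time)) {
    keep <- trial$time <= trial$time_to_hit + 1e-9
    traj <- traj[keep, , drop = FALSE]
  }
  steps <- diff(traj)
  travel <- sum(sqrt(rowSums(steps^2)))
  if (travel < 1e-12) return(NA_real_)
  min(1, required / travel)
}

#' Attempt ratio
#'
#' Total target entrances across the trials divided by the number of hit
#' trials: the average number of attempts needed per successful
#' acquisition. At least 1 whenever hits exist (a hit requires an
#' entrance); undefined (NA) when no target was hit.
#'
#' @param trials A `test_session` or list of trial records.
#' @return A number `>= 1`, or `NA` when there are no hits.
#' @export
attempt_ratio <- function(trials) {
  trials <- as_trials(trials)
  if (length(trials) < 1L) stop("need at least one trial", call. = FALSE)
  hits <- sum(vapply(trials, `[[`, logical(1), "hit"))
  if (hits == 0L) return(NA_real_)
  sum(vapply(trials, function(tr) as.numeric(tr$entrances), numeric(1))) / hits
}

#' Stratum label of a target
#'
#' Targets are grouped by their number of active (non-zero) DoFs:
#' `"rest"`, `"1-DoF"`, `"2-DoF"` or `"3-DoF"`.
#'
#' @param target Length-3 target vector.
#' @return A character label.
#' @export
dof_stratum <- function(target) {
  c("rest", "1-DoF", "2-DoF", "3-DoF")[sum(target != 0) + 1L]
}

#' Stratified session metrics
#'
#' Computes CR, mean per-trial PE and AR overall and per target stratum
#' (rest / 1-DoF / 2-DoF / 3-DoF). PE is averaged over the trials of the
#' stratum with undefined trials dropped; set `pe_pooled = TRUE` to
#' instead pool distances (total straight-line / total traveled).
#'
#' @param trials A `test_session` or list of trial records.
#' @param pe_pooled Pool PE distances instead of averaging per-trial
#'   ratios? Default `FALSE`.
#' @return A data frame of class `session_metrics` with columns
#'   `stratum, n_trials, n_hits, completion_rate, path_efficiency,
#'   attempt_ratio`.
#' @export
session_metrics <- function(trials, pe_pooled = FALSE) {
  trials <- as_trials(trials)
  if (length(trials) < 1L) stop("need at least one trial", call. = FALSE)
  strata <- vapply(trials, function(tr) dof_stratum(tr$target), character(1))
  levels <- c("all", "rest", "1-DoF", "2-DoF", "3-DoF")

  one_stratum <- function(keep, label) {
    sub <- trials[keep]
    if (length(sub) == 0L) {
      return(data.frame(stratum = label, n_trials = 0L, n_hits = 0L,
                        completion_rate = NA_real_, path_efficiency = NA_real_,
                        attempt_ratio = NA_real_))
    }
    pe <- if (pe_pooled) {
      req <- trav <- 0
      for (tr in sub) {
        p <- path_efficiency(tr)
        if (is.na(p)) next
        start <- tr$trajectory[1L, ]
        r <- sqrt(sum((start - tr$target)^2))
        req <- req + r
        trav <- trav + r / p
      }
      if (trav > 0) req / trav else NA_real_
    } else {
      vals <- vapply(sub, path_efficiency, numeric(1))
      if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
    }
    data.frame(stratum = label, n_trials = length(sub),
               n_hits = sum(vapply(sub, `[[`, logical(1), "hit")),
               completion_rate = completion_rate(sub),
               path_efficiency = pe,
               attempt_ratio = attempt_ratio(sub))
  }

  out <- rbind(
    one_stratum(rep(TRUE, length(trials)), "all"),
    do.call(rbind, lapply(levels[-1], function(l) one_stratum(strata == l, l)))
  )
  rownames(out) <- NULL
  structure(out, class = c("session_metrics", "data.frame"))
}

#' @export
print.session_metrics <- function(x, ...) {
  cat("Session metrics (CR = completion rate, PE = path efficiency, AR = attempt ratio)\n")
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Write a stratified metrics table as CSV
#'
#' @param metrics A [session_metrics()] data frame.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
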