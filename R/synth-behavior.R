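#' Behavioral record of one subject
#'
#' Per-stage operation times (seconds) for the four docking phases and their
#' total. The total always equals the sum of the four stages.
#'
#' @param subject_id Identifier.
#' @param times Named numeric vector with entries `O, LM, FO, D` (> 0).
#' @return An object of class `behavior_record`.
#' @export
behavior_record <- function(subject_id, times) {
  need <- c("O", "LM", "FO", "D")
  if (!all(need %in% names(times)))
    stop_invalid("times needs entries O, LM, FO, D")
  times <- as.numeric(times[need]); names(times) <- need
  if (any(!is.finite(times) | times <= 0))
    stop_invalid("stage durations must be positive")
  structure(list(subject_id = as.character(subject_id), times = times,
                 total = sum(times)),
            class = "behavior_record")
}

#' @export
print.behavior_record <- function(x, ...) {
  cat(sprintf("<behavior_record> %s: O %.2f, LM %.2f, FO %.2f, D %.2f; total %.2f s\n",
              x$subject_id, x$times["O"], x$times["LM"], x$times["FO"],
              x$times["D"], x$total))
  invisible(x)
}

#' Default behavioral stage-time parameters
#'
#' Group mean (sd) operation times in seconds for the four docking stages:
#' HC 10.91 (2.6), 20.52 (3.2), 19.31 (1.9), 24.22 (3.8);
#' DE 11.53 (3.0), 25.68 (2.9), 26.47 (2.2), 25.75 (4.3).
#' With sd = 0 the HC total is 74.96 s and the DE total 89.43 s.
#'
#' @return Nested list `group -> list(mean, sd)`, each a named vector over
#'   `O, LM, FO, D`.
#' @export
default_behavior_params <- function() {
  st <- c("O", "LM", "FO", "D")
  nm <- function(x) { names(x) <- st; x }
  list(
    HC = list(mean = nm(c(10.91, 20.52, 19.31, 24.22)),
              sd = nm(c(2.6, 3.2, 1.9, 3.8))),
    DE = list(mean = nm(c(11.53, 25.68, 26.47, 25.75)),
              sd = nm(c(3.0, 2.9, 2.2, 4.3)))
  )
}

#' Simulate a subject's behavioral stage times
#'
#' Draws the four stage times independently from truncated-at-zero normal
#' distributions with the subject's group parameters; the total time is their
#' sum. With all sds zero the record reproduces the group means exactly.
#' Reproducible from `subject$seed`.
#'
#' @param subject A [subject_spec()].
#' @param group_params See [default_behavior_params()].
#' @return A [behavior_record()].
#' @export
simulate_behavior <- function(subject, group_params = default_behavior_params()) {
  if (!inherits(subject, "subject_spec"))
    stop_invalid("subject must be a subject_spec")
  p <- group_params[[subject$group]]
  if (is.null(p)) stop_invalid("no behavior parameters for group %s",
                               subject$group)
  st <- c("O", "LM", "FO", "D")
  if (!all(st %in% names(p$mean)) || !all(st %in% names(p$sd)))
    stop_invalid("group_params need mean and sd for O, LM, FO, D")
  if (any(p$mean[st] <= 0)) stop_invalid("stage means must be positive")
  if (any(p$sd[st] < 0)) stop_invalid("stage sds must be non-negative")
  set.seed(subject$seed + 1L)
  times <- vapply(st, function(s)
    rtruncnorm1(1, p$mean[[s]], p$sd[[s]], lo = 1e-3), 0)
  behavior_record(subject$subject_id, times)
}

#' Simulate a per-trial event log
#'
#' Emits the five ordered events of each docking trial (start, first
#' whole-arm move, first fine adjustment, second whole-arm move, dock
#' complete) at absolute times, with per-trial stage durations jittered
#' around the subject's stage times by a truncated normal with sd
#' `within_sd`.
#'
#' @param subject A [subject_spec()].
#' @param record The subject's [behavior_record()]; default simulates one.
#' @param n_trials Number of trials (canonical 16).
#' @param within_sd Within-subject between-trial sd, seconds.
#' @param rest_s Inter-trial rest inserted between trials, seconds.
#' @return Data frame with columns `subject_id, trial, event, time_s`.
#' @export
simulate_event_log <- function(subject, record = NULL, n_trials = 16,
                               within_sd = 2, rest_s = 60) {
  if (is.null(record)) record <- simulate_behavior(subject)
  set.seed(subject$seed + 2L)
  events <- c("start", "move_arm", "fine_adjust", "move_arm_again", "dock")
  rows <- list()
  t0 <- 0
  for (tr in seq_len(n_trials)) {
    d <- vapply(c("O", "LM", "FO", "D"), function(s)
      rtruncnorm1(1, record$times[[s]], within_sd, lo = 0.5), 0)
    times <- t0 + c(0, cumsum(d))
    rows[[tr]] <- data.frame(subject_id = subject$subject_id, trial = tr,
                             event = events, time_s = times)
    t0 <- times[5] + rest_s
  }
  do.call(rbind, rows)
}
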