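#' Subject specification
#'
#' Encodes the screening outcome of one participant. Inclusion criteria:
#' the depressive-emotion (DE) group requires CES-D > 16 and BDI-II <= 13;
#' healthy controls (HC) require CES-D < 16 and BDI-II <= 13.
#'
#' @param subject_id Identifier string.
#' @param group `"DE"` or `"HC"`.
#' @param cesd CES-D score, integer 0-60.
#' @param bdi BDI-II score, integer 0-63.
#' @param seed Integer seed driving all of this subject's simulated data.
#' @return An object of class `subject_spec`.
#' @export
subject_spec <- function(subject_id, group, cesd, bdi, seed) {
  group <- match.arg(group, c("DE", "HC"))
  cesd <- as.integer(cesd); bdi <- as.integer(bdi)
  if (is.na(cesd) || cesd < 0 || cesd > 60)
    stop_invalid("cesd must be an integer in 0-60")
  if (is.na(bdi) || bdi < 0 || bdi > 63)
    stop_invalid("bdi must be an integer in 0-63")
  if (bdi > 13)
    stop_invalid("inclusion criteria require BDI-II <= 13 (got %d)", bdi)
  if (group == "DE" && cesd <= 16)
    stop_invalid("DE inclusion requires CES-D > 16 (got %d)", cesd)
  if (group == "HC" && cesd >= 16)
    stop_invalid("HC inclusion requires CES-D < 16 (got %d)", cesd)
  seed <- as.integer(seed)
  if (is.na(seed)) stop_invalid("seed must be an integer")
  structure(list(subject_id = as.character(subject_id), group = group,
                 cesd = cesd, bdi = bdi, seed = seed),
            class = "subject_spec")
}

#' @export
print.subject_spec <- function(x, ...) {
  cat(sprintf("<subject_spec> %s [%s] CES-D %d, BDI-II %d, seed %d\n",
              x$subject_id, x$group, x$cesd, x$bdi, x$seed))
  invisible(x)
}

#' Default depression-scale score parameters
#'
#' Group means (sd) of the screening scales: DE CES-D 24.8 (4.2), BDI-II
#' 10.9 (2.6); HC CES-D 14.6 (3.4), BDI-II 8.2 (2.1).
#'
#' @return Nested list `group -> scale -> c(mean, sd)`.
#' @export
default_score_params <- function() {
  list(DE = list(cesd = c(mean = 24.8, sd = 4.2), bdi = c(mean = 10.9, sd = 2.6)),
       HC = list(cesd = c(mean = 14.6, sd = 3.4), bdi = c(mean = 8.2, sd = 2.1)))
}

# Rounded truncated-normal score draw, resampled until the inclusion criteria
# for `group` hold.
draw_scores <- function(group, params) {
  p <- params[[group]]
  for (i in 1:10000) {
    cesd <- round(rtruncnorm1(1, p$cesd["mean"], p$cesd["sd"], 0, 60))
    bdi <- round(rtruncnorm1(1, p$bdi["mean"], p$bdi["sd"], 0, 63))
    ok <- bdi <= 13 &&
      ((group == "DE" && cesd > 16) || (group == "HC" && cesd < 16))
    if (ok) return(c(cesd = cesd, bdi = bdi))
  }
  stop_invalid("could not draw scores meeting inclusion criteria for %s", group)
}

# Truncated-at-[lo,hi] normal via rejection; sd = 0 returns the mean.
rtruncnorm1 <- function(n, mean, sd, lo = 0, hi = Inf) {
  if (sd < 0) stop_invalid("sd must be >= 0 (got %g)", sd)
  if (sd == 0) {
    if (mean < lo || mean > hi)
      stop_invalid("degenerate truncated normal: mean %g outside [%g, %g]",
                   mean, lo, hi)
    return(rep(as.numeric(mean), n))
  }
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2L * (n - length(out)) + 10L, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Simulate a screened cohort
#'
#' Draws `n_per_group` DE and HC subjects with depression-scale scores from
#' rounded truncated normals matched to the group screening statistics,
#' resampling until the inclusion criteria hold, and assigns each subject a
#' derived seed so every downstream simulation is reproducible.
#'
#' @param n_per_group Subjects per group (study value: 15).
#' @param seed Cohort seed.
#' @param score_params See [default_score_params()].
#' @return List of [subject_spec()] objects (DE first, then HC), with a
#'   `subject_table` attribute (data.frame: subject_id, group, cesd, bdi, seed).
#' @export
simulate_cohort <- function(n_per_group = 15, seed = 1,
                            score_params = default_score_params()) {
  n_per_group <- as.integer(n_per_group)
  if (is.na(n_per_group) || n_per_group < 1)
    stop_invalid("n_per_group must be >= 1")
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max - 1L, 2L * n_per_group)
  subjects <- vector("list", 2L * n_per_group)
  k <- 0L
  for (group in c("DE", "HC")) {
    for (i in seq_len(n_per_group)) {
      k <- k + 1L
      sc <- draw_scores(group, score_params)
      subjects[[k]] <- subject_spec(sprintf("%s%02d", group, i), group,
                                    sc["cesd"], sc["bdi"], seeds[k])
    }
  }
  tab <- do.call(rbind, lapply(subjects, function(s)
    data.frame(subject_id = s$subject_id, group = s$group, cesd = s$cesd,
               bdi = s$bdi, seed = s$seed)))
  attr(subjects, "subject_table") <- tab
  subjects
}

#' Write / read a subject table
#'
#' @param subjects Cohort list from [simulate_cohort()] or a subject table
#'   data frame.
#' @param path CSV path.
#' @return `write_subject_table` returns `path` invisibly; `read_subject_table`
#'   returns a list of [subject_spec()] with a `subject_table` attribute.
#' @export
write_subject_table <- function(subjects, path) {
  tab <- if (is.data.frame(subjects)) subjects else attr(subjects, "subject_table")
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_subject_table
#' @export
read_subject_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  subjects <- lapply(seq_len(nrow(tab)), function(i)
    subject_spec(tab$subject_id[i], tab$group[i], tab$cesd[i], tab$bdi[i],
                 tab$seed[i]))
  attr(subjects, "subject_table") <- tab
  subjects
}
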