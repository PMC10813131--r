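# Study-level experiments: cohort-scale simulations that exercise the whole
# pipeline under the default study conditions. These back the package's
# validation claims (planted-effect recovery, null FDR control, behavioral
# power) and are also what the acceptance script reruns.

#' Planted-effect recovery study
#'
#' Simulates a DE/HC cohort with the default group-difference coupling plans
#' (weaker DE frontoparietal coupling in theta/alpha at rest; stronger DE
#' left-frontoparietal coupling in delta/beta/gamma during the LM and FO task
#' stages; planted |dPLV| ~ 0.3), runs the full preprocessing + PLV +
#' edgewise-contrast pipeline, and scores how many planted edges are
#' recovered as FDR-significant with the planted sign.
#'
#' @param n_per_group Subjects per group (study value 15).
#' @param seed Cohort seed.
#' @param duration Seconds per stage (default 120 = 60 two-second epochs).
#' @param epoch_s Epoch length, seconds.
#' @param alpha FDR threshold.
#' @return List with overall `sensitivity`, `wrong_sign` count, a per-combo
#'   data frame `detail` (band, stage, hits, planted, off-target significant
#'   edge count), and the `contrasts`.
#' @export
planted_recovery_study <- function(n_per_group = 15, seed = 1, duration = 120,
                                   epoch_s = 2, alpha = 0.05) {
  subjects <- simulate_cohort(n_per_group, seed)
  groups <- vapply(subjects, function(s) s$group, "")
  combos <- list(RS = c("theta", "alpha"),
                 LM = c("delta", "beta", "gamma"),
                 FO = c("delta", "beta", "gamma"))
  durations <- stats::setNames(rep(duration, 3), names(combos))
  mats <- list()
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    rec <- simulate_recording(s, default_coupling_plans(s$group),
                              durations = durations)
    for (st in names(combos)) {
      ms <- stage_connectivity(rec, st, canonical_bands()[combos[[st]]],
                               epoch_s)
      for (bn in names(ms)) mats[[paste(st, bn)]][[i]] <- ms[[bn]]
    }
  }
  pe <- list(RS = planted_edges("rs_frontoparietal"),
             LM = planted_edges("task_left_frontoparietal"),
             FO = planted_edges("task_left_frontoparietal"))
  want_sign <- c(RS = -1, LM = 1, FO = 1)  # DE weaker at rest, stronger in task
  detail <- list(); contrasts <- list()
  hits <- planted <- wrong <- 0
  for (key in names(mats)) {
    st <- strsplit(key, " ")[[1]][1]
    ec <- edgewise_contrast(mats[[key]][groups == "DE"],
                            mats[[key]][groups == "HC"], alpha = alpha)
    contrasts[[key]] <- ec
    ij <- cbind(match(pe[[st]]$ch_i, ec$channels),
                match(pe[[st]]$ch_j, ec$channels))
    h <- sum(ec$sign[ij] == want_sign[[st]])
    w <- sum(ec$sign[ij] == -want_sign[[st]])
    hits <- hits + h; wrong <- wrong + w; planted <- planted + nrow(ij)
    detail[[key]] <- data.frame(
      stage = st, band = strsplit(key, " ")[[1]][2], hits = h,
      planted = nrow(ij), wrong_sign = w,
      total_significant = sum(ec$sign[upper.tri(ec$sign)] != 0))
  }
  detail <- do.call(rbind, detail)
  rownames(detail) <- NULL
  list(sensitivity = hits / planted, wrong_sign = wrong, detail = detail,
       contrasts = contrasts)
}

# Compact 16-channel montage used by the null-control study (a subset of the
# packaged layout covering all 10 regions).
null_study_montage <- function() {
  m <- default_montage()
  keep <- c("F3", "F4", "F7", "F8", "C3", "C4", "T7", "T8",
            "P3", "P4", "P7", "P8", "O1", "O2", "CP3", "CP4")
  as_montage(as.data.frame(m)[match(keep, m$name), ])
}

#' Null-control FDR study
#'
#' Repeatedly simulates cohorts in which both groups share *identical*
#' coupling (the complete null for the group contrast: coupling is present
#' but carries no group difference) and measures the proportion of
#' FDR-significant edges per edgewise contrast. Under Benjamini-Hochberg
#' control this proportion is small on average (the FDR bound applies to
#' discoveries; under the complete null the expected proportion of rejected
#' edges is well below alpha). Problem sizes are reduced (16 channels, 20
#' epochs, theta + alpha) since FDR behavior does not depend on montage
#' size.
#'
#' @param n_reps Simulation replicates (>= 20 for a stable average).
#' @param seed Integer seed.
#' @param n_per_group Subjects per group per replicate.
#' @param duration Seconds of resting state per subject.
#' @param alpha FDR threshold.
#' @return List with `mean_proportion`, per-replicate `proportions`, and the
#'   number of edge tests per contrast.
#' @export
null_fdr_study <- function(n_reps = 20, seed = 1, n_per_group = 8,
                           duration = 40, alpha = 0.05) {
  mont <- null_study_montage()
  shared <- list(
    coupling_plan("theta", "RS",
                  data.frame(ch_i = c("F3", "F4", "F7", "F8"),
                             ch_j = c("P3", "P4", "P7", "P8"), c = 0.5)),
    coupling_plan("alpha", "RS",
                  data.frame(ch_i = c("F3", "F4", "F7", "F8"),
                             ch_j = c("P3", "P4", "P7", "P8"), c = 0.5)))
  bands <- canonical_bands()[c("theta", "alpha")]
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  props <- numeric(0)
  for (r in seq_len(n_reps)) {
    subjects <- simulate_cohort(n_per_group, rep_seeds[r])
    groups <- vapply(subjects, function(s) s$group, "")
    mats <- list()
    for (i in seq_along(subjects)) {
      rec <- simulate_recording(subjects[[i]], shared, mont,
                                durations = c(RS = duration), bands = bands)
      ms <- stage_connectivity(rec, "RS", bands)
      for (bn in names(ms)) mats[[bn]][[i]] <- ms[[bn]]
    }
    for (bn in names(bands)) {
      ec <- edgewise_contrast(mats[[bn]][groups == "DE"],
                              mats[[bn]][groups == "HC"], alpha = alpha)
      props <- c(props, mean(ec$sign[upper.tri(ec$sign)] != 0))
    }
  }
  list(mean_proportion = mean(props), proportions = props,
       n_tests = choose(nrow(mont), 2))
}

#' Behavioral power study
#'
#' Repeatedly simulates DE/HC cohorts from the default stage-time parameters
#' and records how often each stage contrast (and the total time) rejects at
#' `alpha` with the exact rank-sum test. Under the default group parameters
#' the LM, FO and total-time contrasts are powered while O and D are not,
#' reproducing the qualitative significance pattern of the behavioral data.
#'
#' @param n_reps Simulation replicates.
#' @param seed Integer seed.
#' @param n_per_group Subjects per group.
#' @param alpha Significance threshold.
#' @return List with `rates` (named rejection proportions for O, LM, FO, D,
#'   total) and `n_reps`.
#' @export
behavior_power_study <- function(n_reps = 100, seed = 1, n_per_group = 15,
                                 alpha = 0.05) {
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  rej <- matrix(FALSE, n_reps, 5,
                dimnames = list(NULL, c("O", "LM", "FO", "D", "total")))
  for (r in seq_len(n_reps)) {
    set.seed(rep_seeds[r])
    subj_seeds <- sample.int(.Machine$integer.max - 1L, 2 * n_per_group)
    de <- lapply(seq_len(n_per_group), function(i)
      simulate_behavior(subject_spec(paste0("DE", i), "DE", 25, 10,
                                     subj_seeds[i])))
    hc <- lapply(seq_len(n_per_group), function(i)
      simulate_behavior(subject_spec(paste0("HC", i), "HC", 10, 8,
                                     subj_seeds[n_per_group + i])))
    out <- behavior_contrast(de, hc, alpha = alpha)
    rej[r, ] <- out$p_value < alpha
  }
  list(rates = colMeans(rej), n_reps = n_reps)
}
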