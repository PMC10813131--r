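test_that("trial schedule crosses obstacles with perspectives exactly once", {
  sched <- make_trial_schedule(2, 8, seed = 3)
  expect_equal(nrow(sched), 16)
  expect_setequal(unique(sched$obstacle), c("bar", "frame"))
  expect_setequal(unique(sched$angle_deg), seq(30, 240, by = 30))

  expect_equal(nrow(make_trial_schedule(1, 1, 0)), 1)

  # 3 x 4: a permutation of the full factorial
  s34 <- make_trial_schedule(3, 4, seed = 7)
  expect_equal(nrow(s34), 12)
  got <- sort(paste(s34$obstacle, s34$angle_deg))
  want <- sort(paste(rep(paste0("type", 1:3), times = 4),
                     rep(seq(30, 120, by = 30), each = 3)))
  expect_equal(got, want)

  expect_identical(make_trial_schedule(2, 8, seed = 5),
                   make_trial_schedule(2, 8, seed = 5))
  expect_error(make_trial_schedule(0, 8), "n_obstacle_types")
  expect_error(make_trial_schedule(2, -1), "n_perspectives")
})

test_that("subject specs enforce the screening criteria", {
  expect_silent(subject_spec("a", "DE", 25, 10, 1))
  expect_silent(subject_spec("b", "HC", 12, 8, 2))
  expect_error(subject_spec("c", "DE", 16, 10, 3), "CES-D > 16")
  expect_error(subject_spec("d", "HC", 16, 10, 4), "CES-D < 16")
  expect_error(subject_spec("e", "DE", 25, 14, 5), "BDI-II")
})

test_that("simulated cohorts meet inclusion criteria and are reproducible", {
  coh <- simulate_cohort(5, seed = 9)
  expect_length(coh, 10)
  tab <- attr(coh, "subject_table")
  expect_equal(table(tab$group), table(rep(c("DE", "HC"), each = 5)),
               ignore_attr = TRUE)
  expect_true(all(tab$cesd[tab$group == "DE"] > 16))
  expect_true(all(tab$cesd[tab$group == "HC"] < 16))
  expect_true(all(tab$bdi <= 13))
  tab2 <- attr(simulate_cohort(5, seed = 9), "subject_table")
  expect_identical(tab, tab2)
})

test_that("a fully coupled pair yields PLV 1 and recordings are deterministic", {
  s <- subject_spec("t1", "HC", 10, 5, 42)
  plan <- coupling_plan("alpha", "RS", data.frame(ch_i = "ch1", ch_j = "ch2", c = 1))
  args <- list(s, list(plan), toy_montage(3), fs = 200,
               durations = c(RS = 20), bands = canonical_bands()["alpha"],
               noise_sd = 0)
  rec <- do.call(simulate_recording, args)
  ep <- band_filter(segment(rec, "RS", 2), "alpha")
  ph <- instantaneous_phase(ep)
  expect_equal(plv(as.vector(ph[, 1, ]), as.vector(ph[, 2, ])), 1,
               tolerance = 1e-6)
  # third, uncoupled channel stays far from 1
  expect_lt(build_matrix(ep)$values[1, 3], 0.95)
  # bitwise determinism from the subject seed
  rec2 <- do.call(simulate_recording, args)
  expect_identical(rec$data, rec2$data)
})

test_that("uncoupled channels match the independent-phase Monte-Carlo null", {
  # Monte-Carlo oracle: epoch-averaged PLV of independent random-walk phases
  fs <- 200; dur <- 60; spe <- 2 * fs
  f0 <- 10.5; freq_sd <- max(0.25 * 5, 1.2)
  set.seed(77)
  null_plv <- replicate(300, {
    phi <- oracle_phase_pair(dur * fs, fs, f0, freq_sd)
    oracle_epoch_plv(phi, spe)
  })
  s <- subject_spec("t0", "HC", 10, 5, 4242)
  rec <- simulate_recording(s, list(), toy_montage(2), fs = fs,
                            durations = c(RS = dur),
                            bands = canonical_bands()["alpha"], noise_sd = 0,
                            heterogeneity = NULL)
  # phase read off the raw epochs: the single-band clean signal is already
  # narrowband, so no re-filtering that would bias the comparison
  ph <- instantaneous_phase(segment(rec, "RS", 2))
  got <- mean(vapply(seq_len(dim(ph)[1]), function(e)
    plv(ph[e, 1, ], ph[e, 2, ]), 0))
  expect_lt(abs(got - mean(null_plv)), 3 * sd(null_plv))
})

test_that("recording simulation validates arguments", {
  s <- subject_spec("t1", "HC", 10, 5, 1)
  expect_error(simulate_recording(s, list(), toy_montage(2), fs = 80),
               "Nyquist")
  expect_error(simulate_recording(s, list(), toy_montage(1)), "2 channels")
  expect_error(coupling_plan("alpha", "RS",
                             data.frame(ch_i = "a", ch_j = "a", c = 1)),
               "distinct")
  expect_error(coupling_plan("alpha", "RS",
                             data.frame(ch_i = c("a", "b"), ch_j = c("b", "a"),
                                        c = 0.5)),
               "duplicate")
  plan <- coupling_plan("alpha", "RS", data.frame(ch_i = "no_such",
                                                  ch_j = "ch1", c = 0.5))
  expect_error(simulate_recording(s, list(plan), toy_montage(2), fs = 200,
                                  durations = c(RS = 4),
                                  bands = canonical_bands()["alpha"]),
               "no_such")
})

test_that("coupling calibration is monotone and ordered at the extremes", {
  cal <- calibrate_coupling(c(0, 0.5, 1), band = "alpha", fs = 200,
                            duration = 12, n_rep = 10, seed = 5)
  expect_equal(cal$c, c(0, 0.5, 1))
  expect_gt(cal$plv_mean[3], cal$plv_mean[1])
  # non-decreasing within 2 Monte-Carlo sds
  for (k in 2:3)
    expect_gt(cal$plv_mean[k] - cal$plv_mean[k - 1],
              -2 * max(cal$plv_sd[k], cal$plv_sd[k - 1]))
  expect_error(calibrate_coupling(c(0, 1), n_rep = 0), "n_rep")
})

test_that("behavior simulation reproduces the group means at sd = 0", {
  zero_sd <- default_behavior_params()
  zero_sd$HC$sd[] <- 0; zero_sd$DE$sd[] <- 0
  hc <- simulate_behavior(subject_spec("h", "HC", 10, 5, 1), zero_sd)
  expect_equal(unname(hc$times), c(10.91, 20.52, 19.31, 24.22))
  expect_equal(hc$total, 74.96)
  de <- simulate_behavior(subject_spec("d", "DE", 25, 10, 2), zero_sd)
  expect_equal(de$total, 89.43)

  bad <- default_behavior_params()
  bad$HC$sd["O"] <- -1
  expect_error(simulate_behavior(subject_spec("h", "HC", 10, 5, 1), bad),
               "non-negative")
})

test_that("behavioral stage means match their targets over many subjects", {
  p <- default_behavior_params()
  n <- 1000
  set.seed(60)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  times <- vapply(seq_len(n), function(i)
    simulate_behavior(subject_spec("h", "HC", 10, 5, seeds[i]))$times,
    numeric(4))
  for (st in c("O", "LM", "FO", "D")) {
    sem <- p$HC$sd[[st]] / sqrt(n)
    expect_lt(abs(mean(times[st, ]) - p$HC$mean[[st]]), 3 * sem)
  }
})

test_that("event logs round-trip through stage_durations", {
  s <- subject_spec("s1", "DE", 25, 10, 33)
  rec <- simulate_behavior(s)
  log <- simulate_event_log(s, rec, n_trials = 16, within_sd = 1)
  expect_equal(nrow(log), 16 * 5)
  back <- stage_durations(log)
  # trial means concentrate near the subject's stage times
  expect_lt(max(abs(back$times - rec$times)), 1.5)
  expect_equal(back$total, sum(back$times))
})
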