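#' Pairwise phase-coupling plan for one band and stage
#'
#' A coupling plan lists channel pairs whose narrowband phases are mixed with
#' a shared driver: for coupling strength `c` in \[0, 1\] a planted channel's
#' phase is `c * phi_driver(t) + (1 - c) * psi(t)` with `psi` an independent
#' band-limited random phase, so the expected PLV of a planted pair increases
#' monotonically with `c` (see [calibrate_coupling()]). Unlisted pairs couple
#' at `baseline_c` (default 0 = independent).
#'
#' @param band Band name or [band_spec()].
#' @param stage Stage code (`"RS"`, `"O"`, `"LM"`, `"FO"`, `"D"`).
#' @param edges Data frame with columns `ch_i, ch_j, c`.
#' @param baseline_c Coupling of all unlisted pairs, in \[0, 1\].
#' @return An object of class `coupling_plan`.
#' @export
coupling_plan <- function(band, stage, edges, baseline_c = 0) {
  band <- as_band(band)
  stage <- match.arg(stage, STAGES)
  edges <- as.data.frame(edges)
  if (!all(c("ch_i", "ch_j", "c") %in% names(edges)))
    stop_invalid("edges need columns ch_i, ch_j, c")
  edges$ch_i <- as.character(edges$ch_i)
  edges$ch_j <- as.character(edges$ch_j)
  if (any(edges$ch_i == edges$ch_j))
    stop_invalid("coupling edges must join two distinct channels")
  key <- paste(pmin(edges$ch_i, edges$ch_j), pmax(edges$ch_i, edges$ch_j))
  if (anyDuplicated(key))
    stop_invalid("duplicate unordered channel pair in coupling plan")
  if (any(!is.finite(edges$c) | edges$c < 0 | edges$c > 1))
    stop_invalid("coupling strengths must be in [0, 1]")
  if (!is.finite(baseline_c) || baseline_c < 0 || baseline_c > 1)
    stop_invalid("baseline_c must be in [0, 1]")
  structure(list(band = band, stage = stage,
                 edges = edges[, c("ch_i", "ch_j", "c")],
                 baseline_c = baseline_c),
            class = "coupling_plan")
}

#' @export
print.coupling_plan <- function(x, ...) {
  cat(sprintf("<coupling_plan> %s @ %s: %d edges, baseline_c = %g\n",
              x$band$name, x$stage, nrow(x$edges), x$baseline_c))
  invisible(x)
}

# Planted coupling strengths per band, chosen once by calibrating coupling
# against PLV measured through the full analysis path (band filter, analytic
# phase, epochwise PLV, average reference) so a planted edge differs from
# baseline by ~0.3 in expected PLV under the default generator settings.
PLANTED_C <- c(delta = 0.72, theta = 0.70, alpha = 0.65,
               beta = 0.70, gamma = 0.70)

#' Designated planted edge sets
#'
#' The two edge sets used by the default study conditions: 10 bilateral
#' frontoparietal pairs (resting-state contrast) and 10 left-frontoparietal
#' pairs (task-stage contrast). The montage has only 7 left-frontal
#' electrodes, so three of the left edges share a frontal endpoint.
#'
#' @param set `"rs_frontoparietal"` or `"task_left_frontoparietal"`.
#' @return Data frame with columns `ch_i, ch_j`.
#' @export
planted_edges <- function(set = c("rs_frontoparietal",
                                  "task_left_frontoparietal")) {
  set <- match.arg(set)
  if (set == "rs_frontoparietal") {
    data.frame(
      ch_i = c("F7", "F5", "F3", "F1", "AF7", "F8", "F6", "F4", "F2", "AF8"),
      ch_j = c("P7", "P5", "P3", "P1", "PO7", "P8", "P6", "P4", "P2", "PO8"))
  } else {
    data.frame(
      ch_i = c("FP1", "AF7", "AF3", "F7", "F5", "F3", "F1", "F7", "F5", "F3"),
      ch_j = c("P1", "P7", "P3", "P5", "CP5", "CP3", "CP1", "PO7", "PO5", "PO3"))
  }
}

#' Default study-condition coupling plans
#'
#' Encodes the group-difference structure the pipeline is designed to detect:
#' in resting state (RS) the DE group couples *weaker* than HC on 10
#' frontoparietal edges in theta and alpha; in the task stages (LM, FO) the
#' DE group couples *stronger* than HC on 10 left-frontoparietal edges in
#' delta, beta and gamma. Planted strengths come from `PLANTED_C`
#' (calibrated to ~0.3 expected PLV difference); the opposite group sits at
#' baseline 0.
#'
#' @param group `"DE"` or `"HC"`.
#' @return List of [coupling_plan()] objects.
#' @export
default_coupling_plans <- function(group = c("DE", "HC")) {
  group <- match.arg(group)
  plans <- list()
  rs <- planted_edges("rs_frontoparietal")
  for (band in c("theta", "alpha")) {
    rs$c <- if (group == "HC") unname(PLANTED_C[band]) else 0
    plans[[length(plans) + 1L]] <- coupling_plan(band, "RS", rs)
  }
  task <- planted_edges("task_left_frontoparietal")
  for (stage in c("LM", "FO")) {
    for (band in c("delta", "beta", "gamma")) {
      task$c <- if (group == "DE") unname(PLANTED_C[band]) else 0
      plans[[length(plans) + 1L]] <- coupling_plan(band, stage, task)
    }
  }
  plans
}

# ---- phase-process machinery -------------------------------------------------

# Column-wise cumulative sums (in-place loop; fast at the low-rate grid).
col_cumsum <- function(m) {
  for (j in seq_len(ncol(m))) m[, j] <- cumsum(m[, j])
  m
}

# Linear interpolation of low-rate columns onto n samples at rate fs.
upsample_linear <- function(th, n, fs, fs_low) {
  t_hi <- (0:(n - 1)) / fs * fs_low + 1
  i0 <- pmin(floor(t_hi), nrow(th) - 1L)
  w <- t_hi - i0
  th[i0, , drop = FALSE] * (1 - w) + th[i0 + 1L, , drop = FALSE] * w
}

# Band-limited random-walk phase deviations: instantaneous-frequency
# deviations with sd freq_sd (Hz), sampled at fs_low and linearly
# interpolated. The floor max(0.25*bw, 1.2) Hz makes slow bands decohere
# within a 2-s epoch so planted coupling has headroom in every band.
band_freq_sd <- function(bw) max(0.25 * bw, 1.2)

# Generate mixed phases for one band/stage: n samples, C channels.
# c_ch: per-channel coupling strength; driver_idx: per-channel driver id
# (1 = ambient driver shared by all baseline channels). ambient_c applies a
# second, subject-level mixing of every channel toward the ambient driver
# (between-subject heterogeneity in global synchrony).
gen_band_phases <- function(n, fs, band, C, c_ch, driver_idx, fs_low = 25,
                            ambient_c = 0) {
  f0 <- (band$low_hz + band$high_hz) / 2
  bw <- band$high_hz - band$low_hz
  sigma <- 2 * pi * band_freq_sd(bw) / fs_low
  n_low <- ceiling(n / fs * fs_low) + 2L
  n_drv <- max(driver_idx)
  th <- matrix(rnorm(n_low * (C + n_drv), sd = sigma), n_low, C + n_drv)
  th <- col_cumsum(th)
  th <- sweep(th, 2, runif(C + n_drv, 0, 2 * pi), "+")
  mixed <- sweep(th[, seq_len(C), drop = FALSE], 2, 1 - c_ch, "*") +
    sweep(th[, C + driver_idx, drop = FALSE], 2, c_ch, "*")
  if (ambient_c > 0)
    mixed <- (1 - ambient_c) * mixed + ambient_c * th[, C + 1L]
  phi <- upsample_linear(mixed, n, fs, fs_low)
  phi + 2 * pi * f0 * (0:(n - 1)) / fs
}

# Resolve a plan's edges into per-channel coupling strengths and driver ids.
# Edges are grouped into connected components, one driver per component; a
# channel's strength is the max over its incident edges. Channels without a
# planted edge share the ambient driver (id 1) at baseline_c.
plan_drivers <- function(plan, channels) {
  C <- length(channels)
  c_ch <- rep(plan$baseline_c, C)
  driver_idx <- rep(1L, C)
  if (nrow(plan$edges)) {
    missing <- setdiff(unique(c(plan$edges$ch_i, plan$edges$ch_j)), channels)
    if (length(missing))
      stop_invalid("coupling plan references channels not in montage: %s",
                   paste(missing, collapse = ", "))
    g <- igraph::graph_from_data_frame(plan$edges[, c("ch_i", "ch_j")],
                                       directed = FALSE,
                                       vertices = data.frame(name = channels))
    comp <- igraph::components(g)$membership
    planted <- unique(c(plan$edges$ch_i, plan$edges$ch_j))
    comp_ids <- sort(unique(comp[planted]))
    for (k in seq_along(comp_ids)) {
      ch_k <- names(comp)[comp == comp_ids[k]]
      ch_k <- intersect(ch_k, planted)
      driver_idx[match(ch_k, channels)] <- k + 1L
    }
    for (r in seq_len(nrow(plan$edges))) {
      for (ch in c(plan$edges$ch_i[r], plan$edges$ch_j[r])) {
        i <- match(ch, channels)
        c_ch[i] <- max(c_ch[i], plan$edges$c[r])
      }
    }
  }
  list(c_ch = c_ch, driver_idx = driver_idx)
}

#' Default subject-level heterogeneity parameters
#'
#' Between-subject random effects of the EEG generator: a per-subject
#' ambient global-synchrony level (truncated normal, mean 0.10, sd 0.05,
#' capped at 0.25) and log-normal multipliers (sdlog 0.2) on band amplitudes
#' and broadband noise.
#'
#' @return A list understood by [simulate_recording()]'s `heterogeneity`.
#' @export
default_heterogeneity <- function() {
  list(ambient_mean = 0.10, ambient_sd = 0.05, ambient_max = 0.25,
       amp_sdlog = 0.2, noise_sdlog = 0.2)
}

#' Default per-band oscillation amplitudes (microvolts)
#'
#' Amplitudes decline mildly with frequency (with the usual posterior alpha
#' prominence). The ladder is kept gentle on purpose: bands abut, every
#' oscillator has spectral tails past its band edge, and a large amplitude
#' disparity would let a neighboring band's tail dominate a band's PLV
#' estimate.
#'
#' @return Named numeric vector.
#' @export
default_band_amplitudes <- function() {
  c(delta = 12, theta = 10, alpha = 12, beta = 8, gamma = 6)
}

#' Simulate a multichannel EEG recording
#'
#' For each requested stage, every channel's signal is a sum of narrowband
#' oscillations `amp_b * cos(phi_b(t))` over the requested bands plus white
#' broadband noise. Within a band, phases follow the phase-mixing model of
#' [coupling_plan()]: planted pairs share a component driver with strength
#' `c`, all other channels evolve independently. The whole recording is
#' reproducible from `subject$seed`.
#'
#' @param subject A [subject_spec()].
#' @param plans List of [coupling_plan()] (e.g. [default_coupling_plans()]).
#' @param montage Montage data frame (default: the packaged 62-channel
#'   layout).
#' @param fs Sampling rate, samples/s (study value 600). Must be at least
#'   twice the highest band edge.
#' @param durations Named vector, stage -> seconds. Default
#'   `c(RS = 120, LM = 120, FO = 120)`: the 2-min eyes-closed rest plus two
#'   task stages of 60 two-second epochs each.
#' @param bands Bands present in the signal (default all five canonical).
#' @param amplitudes Named per-band amplitudes, microvolts.
#' @param noise_sd Broadband white-noise sd, microvolts.
#' @param heterogeneity Subject-level random effects, or `NULL` to disable:
#'   a list with `ambient_mean, ambient_sd, ambient_max` (a per-subject
#'   global-synchrony level: every channel is additionally mixed toward the
#'   band's ambient driver by a truncated-normal draw) and `amp_sdlog,
#'   noise_sdlog` (log-normal per-subject multipliers on band amplitudes and
#'   noise). These reproduce the between-subject variability of summary PLV
#'   that real cohorts show; without them all subjects are i.i.d. and even
#'   negligible systematic effects become group-significant.
#' @return An [eeg_recording()] with one annotation span per stage.
#' @export
simulate_recording <- function(subject, plans = list(),
                               montage = default_montage(), fs = 600,
                               durations = c(RS = 120, LM = 120, FO = 120),
                               bands = canonical_bands(),
                               amplitudes = default_band_amplitudes(),
                               noise_sd = 5,
                               heterogeneity = default_heterogeneity()) {
  if (!inherits(subject, "subject_spec"))
    stop_invalid("subject must be a subject_spec")
  montage <- as_montage(montage)
  channels <- montage$name
  if (length(channels) < 2L) stop_invalid("montage must have >= 2 channels")
  bands <- lapply(bands, as_band)
  hi <- max(vapply(bands, function(b) b$high_hz, 0))
  if (fs < 2 * hi)
    stop_invalid("fs = %g is below Nyquist for band edge %g Hz", fs, hi)
  for (p in plans) {
    if (!inherits(p, "coupling_plan")) stop_invalid("plans must be coupling_plan objects")
    plan_drivers(p, channels)  # validates edge channels
  }
  stages <- names(durations)
  bad <- setdiff(stages, STAGES)
  if (length(bad)) stop_invalid("unknown stages in durations: %s",
                                paste(bad, collapse = ", "))
  if (any(!is.finite(durations) | durations <= 0))
    stop_invalid("durations must be positive seconds")
  stages <- STAGES[STAGES %in% stages]  # canonical order
  C <- length(channels)

  set.seed(subject$seed)
  # subject-level random effects, drawn once per subject
  n_b <- length(bands)
  if (is.null(heterogeneity)) {
    ambient <- 0; amp_mult <- rep(1, n_b); noise_mult <- 1
  } else {
    h <- heterogeneity
    ambient <- rtruncnorm1(1, h$ambient_mean, h$ambient_sd, 0, h$ambient_max)
    amp_mult <- exp(rnorm(n_b, 0, h$amp_sdlog))
    noise_mult <- exp(rnorm(1, 0, h$noise_sdlog))
  }
  seg <- list()
  ann <- list()
  t0 <- 0
  for (stage in stages) {
    n <- round(durations[[stage]] * fs)
    sig <- matrix(0, n, C)
    for (bi in seq_along(bands)) {
      b <- bands[[bi]]
      plan_here <- NULL
      for (p in plans)
        if (p$band$name == b$name && p$stage == stage) plan_here <- p
      pd <- if (is.null(plan_here)) list(c_ch = rep(0, C),
                                         driver_idx = rep(1L, C))
            else plan_drivers(plan_here, channels)
      amp <- if (b$name %in% names(amplitudes)) amplitudes[[b$name]] else 10
      phi <- gen_band_phases(n, fs, b, C, pd$c_ch, pd$driver_idx,
                             ambient_c = ambient)
      sig <- sig + amp * amp_mult[bi] * cos(phi)
    }
    if (noise_sd > 0)
      sig <- sig + matrix(rnorm(n * C, sd = noise_sd * noise_mult), n, C)
    seg[[stage]] <- sig
    ann[[stage]] <- data.frame(stage = stage, start_s = t0,
                               end_s = t0 + n / fs)
    t0 <- t0 + n / fs
  }
  eeg_recording(t(do.call(rbind, seg)), fs, channels, do.call(rbind, ann),
                subject$subject_id)
}

#' Empirical coupling-to-PLV calibration curve
#'
#' Simulates two-channel recordings coupled at each strength in `c_grid`,
#' runs them through the measurement path (2-s segmentation, zero-phase
#' Chebyshev band filter, analytic-signal phase, epochwise PLV) and returns
#' the mean and sd of the PLV across replicates. The mean response is
#' non-decreasing in `c`, which is what licenses planting group differences
#' through coupling strengths.
#'
#' @param c_grid Coupling strengths in \[0, 1\].
#' @param band Band name or [band_spec()].
#' @param fs Sampling rate.
#' @param duration Seconds per replicate recording.
#' @param n_rep Replicates per grid point (>= 10).
#' @param seed Integer seed.
#' @param epoch_s Epoch length, seconds.
#' @param amplitude Oscillation amplitude, microvolts.
#' @param noise_sd Broadband noise sd, microvolts.
#' @return Data frame with columns `c, plv_mean, plv_sd`.
#' @export
calibrate_coupling <- function(c_grid, band = "alpha", fs = 600, duration = 30,
                               n_rep = 20, seed = 1, epoch_s = 2,
                               amplitude = NULL, noise_sd = 5) {
  if (any(!is.finite(c_grid) | c_grid < 0 | c_grid > 1))
    stop_invalid("c_grid values must be in [0, 1]")
  n_rep <- as.integer(n_rep)
  if (is.na(n_rep) || n_rep < 10)
    stop_invalid("n_rep must be >= 10 (got %s)", n_rep)
  band <- as_band(band)
  if (is.null(amplitude)) {
    amps <- default_band_amplitudes()
    amplitude <- if (band$name %in% names(amps)) amps[[band$name]] else 10
  }
  n <- round(duration * fs)
  set.seed(as.integer(seed))
  out <- matrix(0, n_rep, length(c_grid))
  for (r in seq_len(n_rep)) {
    for (k in seq_along(c_grid)) {
      cc <- c_grid[k]
      phi <- gen_band_phases(n, fs, band, 2L, c(cc, cc), c(2L, 2L))
      x <- amplitude * cos(phi)
      if (noise_sd > 0) x <- x + matrix(rnorm(2 * n, sd = noise_sd), n, 2)
      rec <- eeg_recording(t(x), fs, c("ch1", "ch2"),
                           data.frame(stage = "RS", start_s = 0,
                                      end_s = duration))
      ep <- segment(rec, "RS", epoch_s)
      ep <- band_filter(ep, band)
      ph <- instantaneous_phase(ep)
      pl <- vapply(seq_len(dim(ph)[1]), function(e)
        plv(ph[e, 1, ], ph[e, 2, ]), 0)
      out[r, k] <- mean(pl)
    }
  }
  data.frame(c = c_grid, plv_mean = colMeans(out),
             plv_sd = apply(out, 2, sd))
}
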