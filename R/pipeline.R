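#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]. All parameters have the
#' study defaults; any can be overridden, and a configuration can also be
#' read from YAML with [read_pipeline_config()].
#'
#' @param out_dir Output run directory (created if needed).
#' @param seed Cohort seed; drives every random draw downstream.
#' @param n_per_group Subjects per group.
#' @param fs Sampling rate, samples/s.
#' @param epoch_s Epoch length, seconds.
#' @param durations Named stage -> seconds vector for the simulated
#'   recordings.
#' @param stages Stages to analyze.
#' @param bands Band names to analyze.
#' @param stage_bands Optional named list stage -> band names, restricting
#'   the analysis per stage (default: all `bands` in every stage).
#' @param alpha FDR / significance threshold, in (0, 1).
#' @param metric_mode `"weighted"` or `"proportional_threshold"`.
#' @param density Edge density for threshold mode.
#' @param ica Run FastICA artifact removal on the continuous recordings
#'   (default off for synthetic data).
#' @param ica_kurtosis_z Component-rejection threshold.
#' @param exact_tests Use exact rank-sum enumeration instead of the normal
#'   approximation in the group contrasts.
#' @param noise_sd Generator broadband noise sd, microvolts.
#' @param montage Montage data frame or CSV path (default packaged 62-channel
#'   layout).
#' @param atlas Region atlas or CSV path (default packaged 10-region atlas).
#' @param plans `"default"` (group-difference structure of
#'   [default_coupling_plans()]), `"none"` (no coupling anywhere), or a list
#'   `list(DE = plans, HC = plans)` of [coupling_plan()] lists.
#' @param behavior_params See [default_behavior_params()].
#' @param score_params See [default_score_params()].
#' @param n_trials Trials per subject in the event logs.
#' @param write_matrices Write per-subject PLV matrices as TSV.
#' @param write_recordings Write simulated recordings in the portable
#'   container (off by default; they are large).
#' @param input_dir Optional directory with `subjects.csv` and
#'   `recordings/<subject_id>` containers to ingest instead of simulating.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1,
                            n_per_group = 15,
                            fs = 600,
                            epoch_s = 2,
                            durations = c(RS = 120, LM = 120, FO = 120),
                            stages = c("RS", "LM", "FO"),
                            bands = c("delta", "theta", "alpha", "beta", "gamma"),
                            stage_bands = NULL,
                            alpha = 0.05,
                            metric_mode = c("weighted", "proportional_threshold"),
                            density = 0.2,
                            ica = FALSE,
                            ica_kurtosis_z = 5,
                            exact_tests = FALSE,
                            noise_sd = 5,
                            montage = NULL,
                            atlas = NULL,
                            plans = "default",
                            behavior_params = NULL,
                            score_params = NULL,
                            n_trials = 16,
                            write_matrices = TRUE,
                            write_recordings = FALSE,
                            input_dir = NULL) {
  metric_mode <- match.arg(metric_mode)
  if (missing(out_dir) || !is.character(out_dir) || !nzchar(out_dir))
    stop_invalid("out_dir is required")
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop_invalid("alpha must be in (0, 1) (got %g)", alpha)
  if (!is.finite(epoch_s) || epoch_s <= 0) stop_invalid("epoch_s must be > 0")
  if (is.character(montage) && length(montage) == 1L) montage <- read_montage(montage)
  if (is.null(montage)) montage <- default_montage()
  montage <- as_montage(montage)
  if (is.character(atlas) && length(atlas) == 1L) atlas <- read_atlas(atlas)
  if (is.null(atlas)) atlas <- build_region_atlas(montage)
  atlas <- as_region_atlas(atlas, montage)
  band_objs <- lapply(bands, as_band)
  names(band_objs) <- vapply(band_objs, function(b) b$name, "")
  hi <- max(vapply(band_objs, function(b) b$high_hz, 0))
  if (fs < 2 * hi)
    stop_invalid("fs = %g below Nyquist for band edge %g Hz", fs, hi)
  bad <- setdiff(stages, STAGES)
  if (length(bad)) stop_invalid("unknown stages: %s", paste(bad, collapse = ", "))
  if (!all(stages %in% names(durations)))
    stop_invalid("durations must cover all analyzed stages")
  if (is.null(stage_bands)) {
    stage_bands <- stats::setNames(rep(list(names(band_objs)), length(stages)),
                                   stages)
  } else {
    if (!all(stages %in% names(stage_bands)))
      stop_invalid("stage_bands must name every analyzed stage")
    for (s in stages)
      if (!all(stage_bands[[s]] %in% names(band_objs)))
        stop_invalid("stage_bands for %s outside the configured bands", s)
  }
  if (is.character(plans)) {
    plans <- match.arg(plans, c("default", "none"))
  } else if (is.list(plans)) {
    if (!all(c("DE", "HC") %in% names(plans)))
      stop_invalid("custom plans must be list(DE = ..., HC = ...)")
  } else stop_invalid("plans must be 'default', 'none', or a DE/HC list")
  if (!is.null(input_dir) && !dir.exists(input_dir))
    stop_invalid("input_dir does not exist: %s", input_dir)
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              n_per_group = as.integer(n_per_group), fs = fs,
              epoch_s = epoch_s, durations = durations, stages = stages,
              bands = band_objs, stage_bands = stage_bands, alpha = alpha,
              metric_mode = metric_mode, density = density, ica = ica,
              ica_kurtosis_z = ica_kurtosis_z, exact_tests = exact_tests,
              noise_sd = noise_sd, montage = montage, atlas = atlas,
              plans = plans,
              behavior_params = if (is.null(behavior_params))
                default_behavior_params() else behavior_params,
              score_params = if (is.null(score_params))
                default_score_params() else score_params,
              n_trials = as.integer(n_trials),
              write_matrices = isTRUE(write_matrices),
              write_recordings = isTRUE(write_recordings),
              input_dir = input_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields map directly to [pipeline_config()] arguments; `durations`
#' and `stage_bands` may be YAML mappings.
#'
#' @param path YAML file.
#' @param ... Overrides applied on top of the file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  if (!file.exists(path)) stop_invalid("config file not found: %s", path)
  y <- yaml::read_yaml(path)
  if (!is.null(y$durations)) y$durations <- unlist(y$durations)
  if (!is.null(y$bands)) y$bands <- unlist(y$bands)
  if (!is.null(y$stages)) y$stages <- unlist(y$stages)
  over <- list(...)
  y[names(over)] <- over
  do.call(pipeline_config, y)
}

config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$out_dir <- cfg$input_dir <- NULL  # hash the analysis, not its location
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(cfg), tmp)
  unname(tools::md5sum(tmp))
}

band_name <- function(b) if (is.list(b)) b$name else as.character(b)

#' Run the full analysis pipeline
#'
#' Executes simulate/ingest -> preprocess -> connectivity -> graph metrics ->
#' group statistics -> report tables, writing all artifacts into the run
#' directory. Re-running with the same configuration reproduces every
#' numeric output bitwise. Outputs: `subjects.csv`, `behavior.csv`,
#' `behavior_tests.csv`, `event_logs.csv`, `matrices/` (per-subject PLV
#' TSVs), `metrics.csv` (long format), `contrasts/` (edge lists, signed
#' matrices, nodewise CC tables), `correlations.csv` (region x band x stage
#' Spearman vs CES-D), `provenance.json` and `STATUS`.
#'
#' @param config A `pipeline_config`, or a path to a YAML config file.
#' @return Invisibly, a list with the run directory, subjects, connectivity
#'   matrices, metrics, contrasts, correlation and behavior tables.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config"))
    stop_invalid("config must be a pipeline_config or a YAML path")
  cfg <- config
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out, "contrasts"), showWarnings = FALSE)
  if (cfg$write_matrices) dir.create(file.path(out, "matrices"), showWarnings = FALSE)
  if (cfg$write_recordings) dir.create(file.path(out, "recordings"), showWarnings = FALSE)
  writeLines("INCOMPLETE", file.path(out, "STATUS"))
  prov <- list(package = "plvnet",
               version = as.character(utils::packageVersion("plvnet")),
               seed = cfg$seed, config_md5 = config_hash(cfg))
  jsonlite::write_json(prov, file.path(out, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)

  run_stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", what,
                   conditionMessage(e)), call. = FALSE))
  }

  # -- cohort -----------------------------------------------------------------
  subjects <- run_stage("cohort", {
    if (!is.null(cfg$input_dir)) {
      read_subject_table(file.path(cfg$input_dir, "subjects.csv"))
    } else {
      simulate_cohort(cfg$n_per_group, cfg$seed, cfg$score_params)
    }
  })
  write_subject_table(subjects, file.path(out, "subjects.csv"))
  groups <- vapply(subjects, function(s) s$group, "")

  # -- behavior ---------------------------------------------------------------
  behavior <- run_stage("behavior", {
    recs <- lapply(subjects, simulate_behavior, group_params = cfg$behavior_params)
    logs <- do.call(rbind, lapply(seq_along(subjects), function(i)
      simulate_event_log(subjects[[i]], recs[[i]], n_trials = cfg$n_trials)))
    write_event_log(logs, file.path(out, "event_logs.csv"))
    tab <- do.call(rbind, lapply(recs, function(r)
      data.frame(subject_id = r$subject_id, t(r$times), total = r$total)))
    tab$group <- groups
    utils::write.csv(tab, file.path(out, "behavior.csv"), row.names = FALSE)
    tests <- behavior_contrast(recs[groups == "DE"], recs[groups == "HC"],
                               alpha = cfg$alpha, mode = "exact")
    utils::write.csv(tests, file.path(out, "behavior_tests.csv"),
                     row.names = FALSE)
    list(records = recs, table = tab, tests = tests)
  })

  # -- connectivity + graph metrics ------------------------------------------
  plans_for <- function(group) {
    if (identical(cfg$plans, "default")) default_coupling_plans(group)
    else if (identical(cfg$plans, "none")) list()
    else cfg$plans[[group]]
  }
  mats <- list()     # mats[[stage]][[band]][[subject_idx]]
  metrics <- list()
  region_cc <- list()
  metric_rows <- list()
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    rec <- run_stage(sprintf("simulate/ingest (%s)", s$subject_id), {
      if (!is.null(cfg$input_dir)) {
        read_recording(file.path(cfg$input_dir, "recordings", s$subject_id))
      } else {
        simulate_recording(s, plans_for(s$group), cfg$montage, cfg$fs,
                           cfg$durations[cfg$stages], cfg$bands,
                           noise_sd = cfg$noise_sd)
      }
    })
    if (cfg$write_recordings)
      write_recording(rec, file.path(out, "recordings", s$subject_id))
    if (cfg$ica)
      rec <- run_stage(sprintf("ica (%s)", s$subject_id),
                       remove_artifacts_ica(rec, cfg$ica_kurtosis_z))
    for (stage in cfg$stages) {
      bl <- cfg$bands[cfg$stage_bands[[stage]]]
      ms <- run_stage(sprintf("connectivity (%s @ %s)", s$subject_id, stage),
                      stage_connectivity(rec, stage, bl, cfg$epoch_s))
      for (bn in names(ms)) {
        M <- ms[[bn]]
        mats[[stage]][[bn]][[i]] <- M
        if (cfg$write_matrices)
          write_matrix_tsv(M, file.path(out, "matrices",
                                        sprintf("%s_%s_%s.tsv",
                                                s$subject_id, bn, stage)))
        gm <- run_stage(sprintf("graph (%s %s @ %s)", s$subject_id, bn, stage),
                        compute_metrics(M, cfg$metric_mode, cfg$density))
        metrics[[stage]][[bn]][[i]] <- gm
        region_cc[[stage]][[bn]][[i]] <- region_average(gm$cc, cfg$atlas)
        metric_rows[[length(metric_rows) + 1L]] <- data.frame(
          subject_id = s$subject_id, group = s$group, band = bn,
          stage = stage,
          scope = c(rep("node", length(gm$cc)), "global", "global"),
          node = c(names(gm$cc), NA, NA),
          metric = c(rep("cc", length(gm$cc)), "cpl", "ge"),
          value = c(unname(gm$cc), gm$cpl, gm$ge))
      }
    }
  }
  utils::write.csv(do.call(rbind, metric_rows), file.path(out, "metrics.csv"),
                   row.names = FALSE)

  # -- group statistics -------------------------------------------------------
  de_idx <- which(groups == "DE"); hc_idx <- which(groups == "HC")
  test_mode <- if (cfg$exact_tests) "exact" else "normal_approx"
  contrasts <- list()
  cors <- list()
  cesd <- vapply(subjects, function(s) s$cesd, 0)
  for (stage in cfg$stages) {
    for (bn in cfg$stage_bands[[stage]]) {
      key <- paste(bn, stage, sep = "_")
      ec <- run_stage(sprintf("stats edgewise (%s @ %s)", bn, stage),
                      edgewise_contrast(mats[[stage]][[bn]][de_idx],
                                        mats[[stage]][[bn]][hc_idx],
                                        alpha = cfg$alpha, mode = test_mode))
      nc <- run_stage(sprintf("stats nodewise (%s @ %s)", bn, stage),
                      nodewise_cc_contrast(metrics[[stage]][[bn]][de_idx],
                                           metrics[[stage]][[bn]][hc_idx],
                                           alpha = cfg$alpha, mode = test_mode))
      contrasts[[key]] <- list(edgewise = ec, nodewise = nc)
      ut <- which(upper.tri(ec$sign), arr.ind = TRUE)
      edge_df <- data.frame(ch_i = ec$channels[ut[, 1]],
                            ch_j = ec$channels[ut[, 2]],
                            stat = ec$statistic[ut], p = ec$p[ut],
                            q = ec$q[ut], sign = ec$sign[ut])
      utils::write.csv(edge_df,
                       file.path(out, "contrasts",
                                 sprintf("edges_%s.csv", key)),
                       row.names = FALSE)
      write_matrix_tsv(ec$sign, file.path(out, "contrasts",
                                          sprintf("signed_%s.tsv", key)))
      utils::write.csv(data.frame(channel = nc$channels, stat = nc$statistic,
                                  p = nc$p, q = nc$q, sign = nc$sign),
                       file.path(out, "contrasts",
                                 sprintf("nodewise_cc_%s.csv", key)),
                       row.names = FALSE)
      rc <- do.call(rbind, region_cc[[stage]][[bn]])
      sp <- run_stage(sprintf("stats spearman (%s @ %s)", bn, stage),
                      spearman_region_cesd(rc, cesd))
      sp <- data.frame(stage = stage, band = bn, sp,
                       significant = !is.na(sp$p_value) & sp$p_value < cfg$alpha)
      cors[[key]] <- sp
    }
  }
  cor_tab <- do.call(rbind, cors)
  rownames(cor_tab) <- NULL
  utils::write.csv(cor_tab, file.path(out, "correlations.csv"),
                   row.names = FALSE)
  writeLines("COMPLETE", file.path(out, "STATUS"))
  invisible(list(out_dir = out, subjects = subjects, behavior = behavior,
                 matrices = mats, metrics = metrics, contrasts = contrasts,
                 correlations = cor_tab))
}
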