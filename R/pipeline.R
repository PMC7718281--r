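#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with the study's
#' analytic defaults: high-pass cutoff 0.01 Hz, 8 discarded volumes,
#' coherence threshold 0.2, phase window (0, pi), AMI constant 0.2,
#' validity rates 0.75/0.50, trial-type mixture 40/40/10/10\%. Simulation
#' scale (runs, voxels) defaults to desk-scale values; the study itself
#' used 14 runs x 3 sessions per attention condition and whole visual
#' areas.
#'
#' @param participants Number of participants (default 5).
#' @param n_runs,trials_per_run Event-related runs per attention condition
#'   and trials per run.
#' @param observer Arguments for [observer_model()].
#' @param exclusion_rate Fixation-break rate (default 0.13).
#' @param staircase_trials Staircase length used to titrate tilt.
#' @param profiles Ground-truth modulation profile per attention type and
#'   cue epoch (the four-regime structure under study: endogenous-pre
#'   increasing, exogenous-pre flat, endogenous-post flat, exogenous-post
#'   null).
#' @param slope_per_rank,flat_effect Effect-size parameters of
#'   [ground_truth_effects()].
#' @param participant_effect_sd SD of the per-participant multiplicative
#'   gain on effect sizes.
#' @param noise [noise_params()] list.
#' @param n_voxels_per_roi,prop_responsive Voxel grid parameters.
#' @param n_localizer_runs,localizer_amp Localizer runs per participant
#'   and responsive-voxel amplitude.
#' @param coherence_min,phase_window,highpass_hz,n_discard,ami_constant
#'   Analysis thresholds.
#' @param seed Master seed; all stage seeds derive from it.
#' @param ... Overrides merged into the config.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(participants = 5L, n_runs = 2L,
                            trials_per_run = 40L,
                            observer = list(), exclusion_rate = 0.13,
                            staircase_trials = 400L,
                            profiles = list(
                              endogenous = c(pre = "increasing", post = "flat"),
                              exogenous = c(pre = "flat", post = "null")),
                            slope_per_rank = 0.05, flat_effect = 0.15,
                            participant_effect_sd = 0.15,
                            noise = noise_params(),
                            n_voxels_per_roi = 20L, prop_responsive = 0.8,
                            n_localizer_runs = 2L, localizer_amp = 1.5,
                            coherence_min = 0.2, phase_window = c(0, pi),
                            highpass_hz = 0.01, n_discard = 8L,
                            ami_constant = 0.2, seed = 1L, ...) {
  cfg <- list(participants = as.integer(participants),
              n_runs = as.integer(n_runs),
              trials_per_run = as.integer(trials_per_run),
              observer = observer, exclusion_rate = exclusion_rate,
              staircase_trials = as.integer(staircase_trials),
              profiles = profiles, slope_per_rank = slope_per_rank,
              flat_effect = flat_effect,
              participant_effect_sd = participant_effect_sd,
              noise = noise, n_voxels_per_roi = as.integer(n_voxels_per_roi),
              prop_responsive = prop_responsive,
              n_localizer_runs = as.integer(n_localizer_runs),
              localizer_amp = localizer_amp, coherence_min = coherence_min,
              phase_window = phase_window, highpass_hz = highpass_hz,
              n_discard = as.integer(n_discard), ami_constant = ami_constant,
              seed = as.integer(seed))
  cfg <- modifyList(cfg, list(...))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline configuration as JSON
#'
#' The config round-trips through serialization unchanged (up to numeric
#' type coercions applied on read).
#'
#' @param config A `pipeline_config`.
#' @param path JSON path.
#' @export
write_config_json <- function(config, path) {
  cfg <- unclass(config)
  cfg$noise <- unclass(cfg$noise)
  cfg$profiles <- lapply(cfg$profiles, as.list)  # keep epoch names in JSON
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config_json
#' @export
read_config_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$noise <- do.call(noise_params, as.list(raw$noise))
  raw$profiles <- lapply(raw$profiles, unlist)
  do.call(pipeline_config, raw)
}

# deterministic derived seeds, kept well below 2^31
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  s <- 0
  for (p in parts) s <- (s * 131 + as.numeric(p)) %% 2147483629
  as.integer(s) + 1L
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> localize -> preprocess/GLM -> AMI -> statistics
#' for every participant and attention condition of a
#' [pipeline_config()], entirely in memory. Stages fail loudly with the
#' stage name; results are deterministic given the config.
#'
#' @param config A `pipeline_config`.
#' @param output_dir If non-NULL, result tables are written there as CSV
#'   (with a provenance JSON sidecar).
#' @param quiet Suppress progress messages.
#' @return An `attnmod_results` bundle: `behavior` (summary + ANOVA),
#'   `selection_reports`, `amplitudes` (condition-amplitude table),
#'   `ami` (records), `hierarchy` (four regressions), `roi_tests`,
#'   `ami_vs_one`, `lmm_pre`, `lmm_post`, `laterality`, `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir = NULL,
                         quiet = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  observer <- do.call(observer_model, config$observer)
  pids <- sprintf("P%02d", seq_len(config$participants))
  sessions <- list()
  amp_rows <- list()
  sel_reports <- list()

  for (i in seq_along(pids)) {
    pid <- pids[i]
    say("participant ", pid)
    set.seed(derive_seed(config$seed, i, 99))
    gain <- max(0.2, 1 + config$participant_effect_sd * rnorm(1))
    voxels <- voxel_grid(config$n_voxels_per_roi, config$prop_responsive)

    # localizer: simulate, average, sinusoid fit, voxel selection
    sel <- stage("localize", {
      loc_runs <- lapply(seq_len(config$n_localizer_runs), function(r)
        simulate_localizer_run(voxels, amp = config$localizer_amp,
                               noise = config$noise,
                               seed = derive_seed(config$seed, i, 500 + r)))
      loc_runs <- lapply(loc_runs, preprocess_run,
                         highpass_hz = config$highpass_hz, n_discard = 0L)
      fits <- fit_sinusoid(average_runs(loc_runs),
                           stimulus_frequency = 1 / 17.5,
                           reference_phase = pi / 2)
      select_voxels(fits, voxels, phase_window = config$phase_window,
                    coherence_min = config$coherence_min)
    })
    rep_i <- sel$roi_report
    rep_i$participant <- pid
    sel_reports[[pid]] <- rep_i

    for (att in .attention_types()) {
      session <- stage("trial_design",
        generate_session(att, n_runs = config$n_runs,
                         trials_per_run = config$trials_per_run,
                         seed = derive_seed(config$seed, i, att == "exogenous")))
      session <- stage("behavior", {
        sc <- run_staircase(observer, n_trials = config$staircase_trials,
                            seed = derive_seed(config$seed, i, 10,
                                               att == "exogenous"))
        simulate_responses(session, observer, tilt = sc$tilt,
                           exclusion_rate = config$exclusion_rate,
                           seed = derive_seed(config$seed, i, 20,
                                              att == "exogenous"))
      })
      sessions[[paste(pid, att, sep = "_")]] <- session

      gt <- ground_truth_effects(att, profiles = config$profiles[[att]],
                                 slope_per_rank = config$slope_per_rank * gain,
                                 flat_effect = config$flat_effect * gain)
      runs <- stage("bold_synth", lapply(seq_len(config$n_runs), function(r)
        simulate_attention_run(session, r, gt, noise = config$noise,
                               voxels = voxels,
                               seed = derive_seed(config$seed, i, 100 + r,
                                                  att == "exogenous"))))
      runs <- stage("preprocess", lapply(runs, preprocess_run,
                                         highpass_hz = config$highpass_hz,
                                         n_discard = config$n_discard))
      amp_rows[[paste(pid, att, sep = "_")]] <- stage("glm",
        condition_amplitudes(runs, session, sel, participant = pid))
    }
  }

  # participant labels must repeat across the two sessions of each person
  behavior <- stage("behavior_summary", {
    labs <- sub("_(endogenous|exogenous)$", "", names(sessions))
    s <- summarize_behavior(setNames(sessions, labs))
    list(summary = s, anova_dprime = behavior_anova(s, "d_prime"),
         anova_rt = behavior_anova(s, "median_rt_s"))
  })
  amplitudes <- do.call(rbind, amp_rows)
  rownames(amplitudes) <- NULL
  stats <- stage("attn_stats", {
    records <- ami_table(amplitudes, constant = config$ami_constant)
    list(records = records,
         hierarchy = hierarchy_regressions(records),
         roi_tests = per_roi_validity_tests(records),
         ami_vs_one = ami_vs_one_test(records),
         lmm_pre = fit_attention_lmm(records, "pre"),
         lmm_post = fit_attention_lmm(records, "post"),
         laterality = lapply(setNames(nm = .attention_types()),
                             function(a) laterality_anova(amplitudes, a)))
  })
  cfg_plain <- unclass(config)
  cfg_plain$noise <- unclass(cfg_plain$noise)
  provenance <- list(config = cfg_plain,
                     config_hash = config_hash(config),
                     package_version = as.character(utils::packageVersion("attnmod")),
                     defaults = list(highpass_hz = config$highpass_hz,
                                     n_discard = config$n_discard,
                                     coherence_min = config$coherence_min,
                                     ami_constant = config$ami_constant))
  out <- structure(list(behavior = behavior,
                        selection_reports = do.call(rbind, sel_reports),
                        amplitudes = amplitudes, ami = stats$records,
                        hierarchy = stats$hierarchy,
                        roi_tests = stats$roi_tests,
                        ami_vs_one = stats$ami_vs_one,
                        lmm_pre = stats$lmm_pre, lmm_post = stats$lmm_post,
                        laterality = stats$laterality,
                        provenance = provenance),
                   class = "attnmod_results")
  if (!is.null(output_dir)) write_results(out, output_dir)
  out
}

#' @export
print.attnmod_results <- function(x, ...) {
  cat("attnmod pipeline results\n")
  cat(sprintf("  %d participants, config hash %s\n",
              x$provenance$config$participants, x$provenance$config_hash))
  cat("\nHierarchy regressions (valid - invalid AMI difference on rank):\n")
  print(x$hierarchy, digits = 3)
  cat(sprintf("\nAMI vs 1: t(%d) = %.2f, p = %.3g, Cohen's d = %.2f\n",
              x$ami_vs_one$df, x$ami_vs_one$t, x$ami_vs_one$p_value,
              x$ami_vs_one$cohens_d))
  invisible(x)
}

#' Write the result bundle to disk
#'
#' Tables as CSV (with a `# config_hash:` provenance comment line readable
#' back via `comment.char = "#"`), plus a provenance JSON.
#'
#' @param results An `attnmod_results` bundle.
#' @param dir Output directory.
#' @export
write_results <- function(results, dir) {
  stopifnot(inherits(results, "attnmod_results"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hdr <- paste0("# config_hash: ", results$provenance$config_hash)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    writeLines(hdr, p)
    suppressWarnings(write.table(df, p, sep = ",", row.names = FALSE,
                                 append = TRUE, quote = FALSE))
    p
  }
  wr(results$behavior$summary$per_participant, "behavior_per_participant.csv")
  wr(results$behavior$anova_dprime, "behavior_anova_dprime.csv")
  wr(results$selection_reports, "selection_report.csv")
  wr(results$amplitudes, "condition_amplitudes.csv")
  wr(results$ami, "ami_records.csv")
  wr(results$hierarchy, "hierarchy_regressions.csv")
  wr(results$roi_tests, "per_roi_tests.csv")
  wr(results$lmm_pre$fixed, "lmm_pre_fixed.csv")
  wr(results$lmm_post$fixed, "lmm_post_fixed.csv")
  jsonlite::write_json(results$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
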