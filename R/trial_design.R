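#' Within-trial event timeline
#'
#' Returns the onsets and offsets (seconds from trial start) of the cue,
#' grating stimulus and response cue for one trial. Cues last 67 ms; the
#' cue-stimulus ISI is 50 ms for exogenous and 250 ms for endogenous
#' attention (SOAs of 117 ms and 317 ms); gratings last 50 ms; the response
#' cue lasts 800 ms and ends the trial. Total trial duration is 1.7 s
#' (exogenous) or 1.9 s (endogenous). Post-cue trials swap the cue and
#' stimulus intervals, keeping every duration identical, so the visual
#' event times coincide across pre- and post-cue trials. Cue-only trials
#' drop the stimulus events; blank trials retain only the response-cue
#' window.
#'
#' @param trial_type One of `"pre_cue"`, `"post_cue"`, `"cue_only"`,
#'   `"blank"`.
#' @param attention_type `"endogenous"` or `"exogenous"`.
#' @return Named numeric vector with elements `cue_on`, `cue_off`,
#'   `stim_on`, `stim_off`, `response_cue_on`, `response_cue_off` (absent
#'   events are `NA`) plus attribute `"total_duration"`.
#' @examples
#' trial_timeline("pre_cue", "exogenous")["stim_on"]  # SOA = 0.117 s
#' @export
trial_timeline <- function(trial_type = c("pre_cue", "post_cue", "cue_only", "blank"),
                           attention_type = c("endogenous", "exogenous")) {
  trial_type <- match.arg(trial_type)
  attention_type <- match.arg(attention_type)
  tm <- timing_constants(attention_type)
  on <- c(cue_on = NA_real_, cue_off = NA_real_, stim_on = NA_real_,
          stim_off = NA_real_, response_cue_on = NA_real_,
          response_cue_off = NA_real_)
  on["response_cue_on"] <- tm$total - tm$resp_dur
  on["response_cue_off"] <- tm$total
  if (trial_type %in% c("pre_cue", "cue_only")) {
    on["cue_on"] <- 0
    on["cue_off"] <- tm$cue_dur
    if (trial_type == "pre_cue") {
      on["stim_on"] <- tm$cue_dur + tm$isi
      on["stim_off"] <- tm$cue_dur + tm$isi + tm$stim_dur
    }
  } else if (trial_type == "post_cue") {
    # stimulus first, cue second: intervals swapped, durations identical
    on["stim_on"] <- 0
    on["stim_off"] <- tm$stim_dur
    on["cue_on"] <- tm$stim_dur + tm$isi
    on["cue_off"] <- tm$stim_dur + tm$isi + tm$cue_dur
  }
  structure(on, total_duration = tm$total)
}

timing_constants <- function(attention_type) {
  list(cue_dur = 0.067,
       isi = if (attention_type == "exogenous") 0.050 else 0.250,
       stim_dur = 0.050,
       resp_dur = 0.800,
       total = if (attention_type == "exogenous") 1.700 else 1.900)
}

#' Generate a randomized, exactly counterbalanced attention session
#'
#' Builds the full trial sequence for one scanning session of one attention
#' condition. The trial-type mixture is exact: 40\% pre-cue, 40\% post-cue,
#' 10\% cue-only and 10\% blank trials. Among stimulus (pre/post-cue)
#' trials, the validity proportion is exact (default 0.75 for endogenous,
#' 0.50 for exogenous sessions) and the response cue points left on exactly
#' half of them. Counterbalancing is enforced at the session level by
#' default (proportions are defined per session); set `per_run_balance` to
#' enforce it within every run.
#'
#' Trials occupy fixed-length slots (`trial_slot_s`, default 7 s = 4 TRs at
#' TR 1.75 s) after a lead-in of `lead_in_s` (default 14 s = the 8 volumes
#' later discarded), so that run duration is an integer number of volumes;
#' the residual slot time after the 1.7/1.9 s trial is fixation (the ITI).
#'
#' @param attention_type `"endogenous"` or `"exogenous"`.
#' @param n_runs Number of runs (default 14).
#' @param trials_per_run Trials per run; must be divisible by 20 so that
#'   every stated proportion is realizable exactly (default 40).
#' @param seed Integer seed controlling the shuffle (required).
#' @param validity_rate Proportion of valid trials among stimulus trials;
#'   `NULL` uses the attention-type default (0.75 endogenous, 0.50
#'   exogenous).
#' @param per_run_balance Counterbalance exactly within each run rather
#'   than only across the session.
#' @param trial_slot_s Fixed trial slot length in seconds.
#' @param lead_in_s Lead-in fixation before the first trial, seconds.
#' @param tr Repetition time in seconds (used only to check that the run
#'   length is a whole number of volumes).
#' @return A `session_design` object: list with `trials` (one row per
#'   trial, event onsets in seconds from run start), `attention_type`,
#'   `n_runs`, `trials_per_run`, `validity_rate`, `seed`, `timing`.
#' @examples
#' s <- generate_session("endogenous", n_runs = 2, trials_per_run = 40, seed = 1)
#' table(s$trials$trial_type)
#' @export
generate_session <- function(attention_type = c("endogenous", "exogenous"),
                             n_runs = 14L, trials_per_run = 40L, seed,
                             validity_rate = NULL, per_run_balance = FALSE,
                             trial_slot_s = 7, lead_in_s = 14, tr = 1.75) {
  attention_type <- match.arg(attention_type)
  if (missing(seed) || is.null(seed))
    stop("'seed' is required for a reproducible session design")
  if (trials_per_run %% 20L != 0L)
    stop("'trials_per_run' must be divisible by 20 so that the 40/40/10/10% ",
         "trial-type mixture and validity proportions are exact")
  if (is.null(validity_rate))
    validity_rate <- if (attention_type == "endogenous") 0.75 else 0.50
  run_dur <- lead_in_s + trials_per_run * trial_slot_s
  if (abs(run_dur / tr - round(run_dur / tr)) > 1e-9)
    stop("run duration (", run_dur, " s) is not an integer number of volumes at TR ", tr)

  set.seed(seed)
  if (per_run_balance) {
    blocks <- lapply(seq_len(n_runs), function(r) {
      blk <- counterbalanced_block(trials_per_run, validity_rate)
      blk[sample.int(nrow(blk)), , drop = FALSE]
    })
    trials <- do.call(rbind, blocks)
  } else {
    trials <- counterbalanced_block(n_runs * trials_per_run, validity_rate)
    trials <- trials[sample.int(nrow(trials)), , drop = FALSE]
  }
  n <- nrow(trials)
  trials$run <- rep(seq_len(n_runs), each = trials_per_run)
  trials$trial_index <- rep(seq_len(trials_per_run), times = n_runs)
  trials$attention_type <- attention_type

  slot_start <- lead_in_s + (trials$trial_index - 1L) * trial_slot_s
  ev <- t(vapply(trials$trial_type,
                 function(tt) as.numeric(trial_timeline(tt, attention_type)),
                 numeric(6)))
  colnames(ev) <- c("cue_on", "cue_off", "stim_on", "stim_off",
                    "response_cue_on", "response_cue_off")
  ev <- ev + slot_start
  trials <- cbind(trials, as.data.frame(ev))
  trials$onset <- slot_start
  trials$duration <- if (attention_type == "exogenous") 1.700 else 1.900
  trials$correct <- NA
  trials$excluded <- FALSE
  rownames(trials) <- NULL
  ord <- c("run", "trial_index", "attention_type", "trial_type", "cue_side",
           "response_cue_side", "validity", "onset", "duration",
           colnames(ev), "correct", "excluded")
  trials <- trials[, ord]

  structure(list(trials = trials, attention_type = attention_type,
                 n_runs = as.integer(n_runs),
                 trials_per_run = as.integer(trials_per_run),
                 validity_rate = validity_rate, seed = as.integer(seed),
                 timing = c(timing_constants(attention_type),
                            list(trial_slot_s = trial_slot_s,
                                 lead_in_s = lead_in_s, tr = tr,
                                 run_duration_s = run_dur))),
            class = "session_design")
}

# one exactly counterbalanced block of n trials (n divisible by 20)
counterbalanced_block <- function(n, validity_rate) {
  n_pre <- (n * 2L) %/% 5L; n_post <- n_pre
  n_cue_only <- n %/% 10L; n_blank <- n %/% 10L
  stim_cell <- function(trial_type, n_epoch) {
    n_valid <- n_epoch * validity_rate
    if (abs(n_valid - round(n_valid)) > 1e-9 ||
        (round(n_valid) %% 2L) != 0L || ((n_epoch - round(n_valid)) %% 2L) != 0L)
      stop("validity_rate ", validity_rate, " is not exactly realizable with ",
           n_epoch, " ", trial_type, " trials")
    n_valid <- as.integer(round(n_valid)); n_invalid <- n_epoch - n_valid
    data.frame(
      trial_type = trial_type,
      validity = rep(c("valid", "invalid"), c(n_valid, n_invalid)),
      response_cue_side = c(rep(c("left", "right"), each = n_valid %/% 2L),
                            rep(c("left", "right"), each = n_invalid %/% 2L)),
      stringsAsFactors = FALSE)
  }
  stim <- rbind(stim_cell("pre_cue", n_pre), stim_cell("post_cue", n_post))
  stim$cue_side <- ifelse(stim$validity == "valid", stim$response_cue_side,
                          ifelse(stim$response_cue_side == "left", "right", "left"))
  cue_only <- data.frame(trial_type = "cue_only", validity = "n/a",
                         cue_side = rep(c("left", "right"), each = n_cue_only %/% 2L),
                         stringsAsFactors = FALSE)
  cue_only$response_cue_side <- cue_only$cue_side
  blank <- data.frame(trial_type = "blank", validity = "n/a", cue_side = "none",
                      response_cue_side = rep(c("left", "right"), each = n_blank %/% 2L),
                      stringsAsFactors = FALSE)
  cols <- c("trial_type", "cue_side", "response_cue_side", "validity")
  rbind(stim[, cols], cue_only[, cols], blank[, cols])
}

#' @export
print.session_design <- function(x, ...) {
  cat("Session design:", x$attention_type, "attention\n")
  cat(sprintf("  %d runs x %d trials (validity rate %.2f, seed %d)\n",
              x$n_runs, x$trials_per_run, x$validity_rate, x$seed))
  print(table(trial_type = x$trials$trial_type,
              validity = x$trials$validity))
  invisible(x)
}

#' Write or read per-run event tables (tab-separated, BIDS-events dialect)
#'
#' One file per run with columns `onset`, `duration`, `trial_type`,
#' `cue_side`, `response_cue_side`, `validity`, `correct`, `excluded` plus
#' the within-run event onsets and `attention_type`/`run` so the table
#' round-trips losslessly. Onsets are in seconds, 0-based from run start.
#'
#' @param session A `session_design` (or its `trials` data frame).
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix; files are `<prefix>_run-<rr>_events.tsv`.
#' @return Invisibly, the paths written.
#' @export
write_events_tsv <- function(session, dir, prefix = "session") {
  trials <- if (inherits(session, "session_design")) session$trials else session
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (r in sort(unique(trials$run))) {
    p <- file.path(dir, sprintf("%s_run-%02d_events.tsv", prefix, r))
    df <- trials[trials$run == r, , drop = FALSE]
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE, na = "n/a")
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname write_events_tsv
#' @param path Path of one events TSV written by [write_events_tsv()].
#' @export
read_events_tsv <- function(path) {
  df <- read.delim(path, na.strings = "n/a", stringsAsFactors = FALSE)
  # validity uses "n/a" as a real level for cue-only/blank trials
  df$validity[is.na(df$validity)] <- "n/a"
  df$cue_side[is.na(df$cue_side)] <- "none"
  df$excluded <- as.logical(df$excluded)
  df$correct <- as.logical(df$correct)
  df
}
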