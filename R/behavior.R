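#' Simulated 2-AFC observer
#'
#' Defines the psychophysical observer used to fill in trial-level
#' responses. Accuracy on the clockwise/counter-clockwise grating
#' discrimination follows a cumulative-Gaussian psychometric function of
#' absolute tilt with a validity-dependent sensitivity and a lapse rate:
#' \deqn{p(\mathrm{correct}) = \lambda/2 + (1-\lambda)\,\Phi(\theta\,s_v/\sigma)}
#' where \eqn{\theta} is tilt in degrees, \eqn{\sigma} the sensitivity
#' scale (tilt at which valid-trial accuracy, lapse-free, reaches
#' \eqn{\Phi(1)\approx 0.84}), and \eqn{s_v = 1} for valid and
#' `validity_effect` (< 1) for invalid trials. Reaction times are drawn
#' from a shifted log-normal per validity level (positive, right-skewed;
#' invalid trials are slower).
#'
#' @param sigma Sensitivity scale in degrees of tilt (> 0).
#' @param validity_effect Multiplicative sensitivity factor for invalid
#'   trials, in (0, 1].
#' @param lapse_rate Lapse probability, between 0 and 0.1.
#' @param rt_shift,rt_meanlog_valid,rt_meanlog_invalid,rt_sdlog Shifted
#'   log-normal RT parameters (seconds; meanlog/sdlog on the log scale).
#' @return An `observer_model` object.
#' @export
observer_model <- function(sigma = 1.5, validity_effect = 0.7,
                           lapse_rate = 0.01, rt_shift = 0.15,
                           rt_meanlog_valid = log(0.35),
                           rt_meanlog_invalid = log(0.42),
                           rt_sdlog = 0.25) {
  stopifnot(sigma > 0, validity_effect > 0, validity_effect <= 1,
            lapse_rate >= 0, lapse_rate <= 0.1, rt_sdlog > 0, rt_shift >= 0)
  structure(list(sigma = sigma, validity_effect = validity_effect,
                 lapse_rate = lapse_rate, rt_shift = rt_shift,
                 rt_meanlog_valid = rt_meanlog_valid,
                 rt_meanlog_invalid = rt_meanlog_invalid,
                 rt_sdlog = rt_sdlog),
            class = "observer_model")
}

#' @export
print.observer_model <- function(x, ...) {
  cat(sprintf("2-AFC observer: sigma = %.3g deg, validity effect = %.2f, lapse = %.3f\n",
              x$sigma, x$validity_effect, x$lapse_rate))
  invisible(x)
}

#' Psychometric function of the simulated observer
#'
#' @param observer An [observer_model()].
#' @param tilt Tilt magnitude in degrees (>= 0), vectorized.
#' @param validity `"valid"` or `"invalid"`, vectorized.
#' @return Probability correct.
#' @export
p_correct <- function(observer, tilt, validity = "valid") {
  stopifnot(inherits(observer, "observer_model"))
  if (any(tilt < 0)) stop("tilt must be non-negative")
  s <- ifelse(validity == "invalid", observer$validity_effect, 1)
  observer$lapse_rate / 2 +
    (1 - observer$lapse_rate) * pnorm(tilt * s / observer$sigma)
}

#' Invert the psychometric function at a target accuracy
#'
#' @inheritParams p_correct
#' @param target Target proportion correct, in (0.5, 1).
#' @return Tilt in degrees at which expected accuracy equals `target`.
#' @export
tilt_for_accuracy <- function(observer, target, validity = "valid") {
  stopifnot(target > 0.5, target < 1)
  ceiling_p <- 1 - observer$lapse_rate / 2
  if (target >= ceiling_p)
    stop("target accuracy ", target, " exceeds the observer ceiling ",
         round(ceiling_p, 4), " set by the lapse rate")
  s <- if (identical(validity, "invalid")) observer$validity_effect else 1
  qnorm((target - observer$lapse_rate / 2) / (1 - observer$lapse_rate)) *
    observer$sigma / s
}

#' Simulate trial-level responses for a session
#'
#' Fills per-trial correctness, response identity and reaction time for all
#' stimulus trials, marks cue-only and blank trials as third-key responses
#' (always correct), and flags fixation-break exclusions at a configurable
#' rate, independently of trial type.
#'
#' @param session A `session_design` from [generate_session()].
#' @param observer An [observer_model()].
#' @param tilt Grating tilt magnitude in degrees (>= 0).
#' @param exclusion_rate Probability a trial is flagged as a fixation
#'   break (default 0.13).
#' @param seed Integer seed (required).
#' @return The session with `trials` gaining columns `target_cw`,
#'   `response_cw`, `correct`, `rt` and filled `excluded`.
#' @export
simulate_responses <- function(session, observer, tilt, exclusion_rate = 0.13,
                               seed) {
  stopifnot(inherits(session, "session_design"),
            inherits(observer, "observer_model"))
  if (tilt < 0) stop("tilt must be non-negative")
  if (missing(seed) || is.null(seed)) stop("'seed' is required")
  set.seed(seed)
  tr <- session$trials
  n <- nrow(tr)
  is_stim <- tr$trial_type %in% c("pre_cue", "post_cue")
  # target orientation counterbalanced within epoch x validity cells (as
  # orientation assignments are in practice), then shuffled
  tr$target_cw <- NA
  for (g in split(which(is_stim),
                  interaction(tr$trial_type[is_stim], tr$validity[is_stim],
                              drop = TRUE))) {
    cw <- rep(c(TRUE, FALSE), length.out = length(g))
    tr$target_cw[g] <- sample(cw)
  }
  p <- rep(1, n)
  p[is_stim] <- p_correct(observer, tilt, tr$validity[is_stim])
  tr$correct <- runif(n) < p           # cue-only/blank: third key, p = 1
  tr$response_cw <- NA
  tr$response_cw[is_stim] <- ifelse(tr$correct[is_stim], tr$target_cw[is_stim],
                                    !tr$target_cw[is_stim])
  meanlog <- ifelse(is_stim & tr$validity == "invalid",
                    observer$rt_meanlog_invalid, observer$rt_meanlog_valid)
  tr$rt <- observer$rt_shift + rlnorm(n, meanlog, observer$rt_sdlog)
  tr$excluded <- runif(n) < exclusion_rate
  session$trials <- tr
  session
}

#' Titrate tilt with a 3-down-1-up staircase
#'
#' Adjusts tilt against the simulated observer with the 3-down-1-up rule
#' (three consecutive correct valid trials decrease tilt, one error
#' increases it), which converges on the 79.4\% point of the valid-trial
#' psychometric function — the procedure used to hold performance near 80\%
#' correct. Step size halves after every 2 reversals down to `min_step`.
#' Non-convergence (trace still moving by more than `tolerance` at the end,
#' or tilt pinned at `max_tilt`, e.g. when the lapse rate caps accuracy
#' below target) is reported in the result and raises a warning.
#'
#' @param observer An [observer_model()].
#' @param target_accuracy Target proportion correct (only used to sanity
#'   check achievability and report; the 3-down-1-up rule itself targets
#'   0.794). In (0.5, 1).
#' @param n_trials Number of staircase trials (>= 100).
#' @param seed Integer seed (required).
#' @param start_tilt Initial tilt (degrees).
#' @param step_init Initial additive step (degrees).
#' @param min_step Smallest step after halving.
#' @param max_tilt Upper bound on tilt.
#' @param tolerance Convergence tolerance on the late-trace drift (degrees).
#' @return A `staircase_fit`: list with `tilt` (converged estimate: the
#'   mean tilt over all trials after the step first reaches `min_step`,
#'   i.e. the stationary stretch of the up-down chain), `trace` data
#'   frame (`trial`, `tilt`, `step`, `correct`, `reversal`), `converged`,
#'   `n_reversals`, `target_accuracy`.
#' @export
run_staircase <- function(observer, target_accuracy = 0.794, n_trials = 400L,
                          seed, start_tilt = 2, step_init = 0.4,
                          min_step = 0.1, max_tilt = 45,
                          tolerance = 0.5) {
  stopifnot(inherits(observer, "observer_model"),
            target_accuracy > 0.5, target_accuracy < 1)
  if (n_trials < 100) stop("n_trials must be >= 100 for a stable estimate")
  if (missing(seed) || is.null(seed)) stop("'seed' is required")
  set.seed(seed)
  tilt <- start_tilt; step <- step_init
  n_correct_streak <- 0L; last_dir <- 0L
  trace <- data.frame(trial = seq_len(n_trials), tilt = NA_real_,
                      step = NA_real_, correct = NA, reversal = FALSE)
  rev_tilts <- numeric(0)
  for (i in seq_len(n_trials)) {
    trace$tilt[i] <- tilt
    trace$step[i] <- step
    corr <- runif(1) < p_correct(observer, tilt, "valid")
    trace$correct[i] <- corr
    dir <- 0L
    if (corr) {
      n_correct_streak <- n_correct_streak + 1L
      if (n_correct_streak == 3L) { dir <- -1L; n_correct_streak <- 0L }
    } else {
      dir <- +1L; n_correct_streak <- 0L
    }
    if (dir != 0L) {
      if (last_dir != 0L && dir != last_dir) {
        trace$reversal[i] <- TRUE
        rev_tilts <- c(rev_tilts, tilt)
        if (length(rev_tilts) %% 2L == 0L) step <- max(step / 2, min_step)
      }
      last_dir <- dir
      tilt <- min(max(tilt + dir * step, 0), max_tilt)
    }
  }
  plateau <- which(trace$step <= min_step + 1e-12)
  est <- if (length(plateau) >= 20) mean(trace$tilt[plateau])
         else mean(trace$tilt[trace$trial > n_trials / 2])
  late <- trace$tilt[trace$trial > 0.75 * n_trials]
  # converged when the stationary stretch has stopped drifting and the
  # tilt is not pinned at the ceiling (e.g. a lapse-limited observer that
  # cannot reach the target accuracy keeps drifting upward)
  drift <- if (length(plateau) >= 20) {
    half <- length(plateau) %/% 2
    abs(mean(trace$tilt[plateau[seq_len(half)]]) -
          mean(trace$tilt[plateau[-seq_len(half)]]))
  } else Inf
  converged <- length(rev_tilts) >= 8 && max(late) < max_tilt &&
    drift <= tolerance
  if (!converged)
    warning("staircase did not converge: stationary-stretch drift ",
            signif(drift, 3), " deg (", length(rev_tilts), " reversals",
            if (max(late) >= max_tilt) ", tilt pinned at the ceiling", ")")
  structure(list(tilt = est, trace = trace, converged = converged,
                 n_reversals = length(rev_tilts),
                 target_accuracy = target_accuracy),
            class = "staircase_fit")
}

#' @export
print.staircase_fit <- function(x, ...) {
  cat(sprintf("3-down-1-up staircase: tilt = %.3f deg (%d reversals, %s)\n",
              x$tilt, x$n_reversals,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Sensitivity (d-prime) for the 2-AFC discrimination
#'
#' Convention: "clockwise" responses to clockwise targets are hits; to
#' counter-clockwise targets, false alarms; d' = z(H) - z(F). Extreme
#' proportions 0 and 1 are replaced by 1/(2N) and 1 - 1/(2N) for the
#' relevant trial count so d' stays finite.
#'
#' @param n_hit,n_target_cw Hits and number of clockwise-target trials.
#' @param n_fa,n_target_ccw False alarms and number of counter-clockwise
#'   target trials.
#' @return d' (unitless).
#' @export
dprime <- function(n_hit, n_target_cw, n_fa, n_target_ccw) {
  stopifnot(n_target_cw > 0, n_target_ccw > 0)
  clamp <- function(k, n) {
    p <- k / n
    pmin(pmax(p, 1 / (2 * n)), 1 - 1 / (2 * n))
  }
  qnorm(clamp(n_hit, n_target_cw)) - qnorm(clamp(n_fa, n_target_ccw))
}

#' Summarize behavior: d-prime and median RT per condition
#'
#' Computes per-participant d' and median reaction time for every
#' attention-type x cue-epoch x validity cell, after removing excluded
#' trials and all cue-only/blank trials.
#'
#' @param sessions A list of simulated `session_design`s (from
#'   [simulate_responses()]); names, if present, are participant ids —
#'   otherwise participants are numbered. Alternatively, a single data
#'   frame of trials with a `participant` column.
#' @return A `behavioral_summary`: list with `per_participant` (one row
#'   per participant x condition cell: `participant`, `attention_type`,
#'   `cue_epoch`, `validity`, `d_prime`, `median_rt_s`, `n_trials`) and
#'   `group` (means and SEMs across participants).
#' @export
summarize_behavior <- function(sessions) {
  trials <- collect_trials(sessions)
  trials <- trials[!trials$excluded &
                     trials$trial_type %in% c("pre_cue", "post_cue"), ,
                   drop = FALSE]
  if (any(is.na(trials$correct)))
    stop("trials have no simulated responses; run simulate_responses() first")
  trials$cue_epoch <- ifelse(trials$trial_type == "pre_cue", "pre", "post")
  key <- c("participant", "attention_type", "cue_epoch", "validity")
  split_idx <- interaction(trials[key], drop = FALSE)
  full <- expand.grid(participant = unique(trials$participant),
                      attention_type = unique(trials$attention_type),
                      cue_epoch = c("pre", "post"),
                      validity = c("valid", "invalid"),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(full)), function(i) {
    cell <- full[i, ]
    m <- trials$participant == cell$participant &
      trials$attention_type == cell$attention_type &
      trials$cue_epoch == cell$cue_epoch & trials$validity == cell$validity
    if (!any(m))
      stop("empty cell after exclusions: ",
           paste(names(cell), unlist(cell), sep = "=", collapse = ", "))
    tt <- trials[m, ]
    cw <- tt$target_cw
    cell$d_prime <- if (any(cw) && any(!cw)) {
      dprime(sum(tt$response_cw[cw]), sum(cw),
             sum(tt$response_cw[!cw]), sum(!cw))
    } else {
      # exclusions left only one target orientation in this cell: fall
      # back to the symmetric-observer identity d' = 2 z(prop. correct)
      nn <- nrow(tt)
      2 * qnorm(min(max(mean(tt$correct), 1 / (2 * nn)), 1 - 1 / (2 * nn)))
    }
    cell$median_rt_s <- median(tt$rt)
    cell$n_trials <- nrow(tt)
    cell
  })
  per_participant <- do.call(rbind, rows)
  agg <- aggregate(cbind(d_prime, median_rt_s) ~ attention_type + cue_epoch + validity,
                   per_participant, mean)
  sem <- aggregate(cbind(d_prime, median_rt_s) ~ attention_type + cue_epoch + validity,
                   per_participant, function(x) sd(x) / sqrt(length(x)))
  names(sem)[4:5] <- c("d_prime_sem", "median_rt_s_sem")
  group <- merge(agg, sem)
  structure(list(per_participant = per_participant, group = group),
            class = "behavioral_summary")
}

collect_trials <- function(sessions) {
  if (is.data.frame(sessions)) {
    stopifnot("participant" %in% names(sessions))
    return(sessions)
  }
  if (inherits(sessions, "session_design")) sessions <- list(sessions)
  ids <- names(sessions)
  if (is.null(ids)) ids <- paste0("P", seq_along(sessions))
  do.call(rbind, lapply(seq_along(sessions), function(i) {
    tr <- if (inherits(sessions[[i]], "session_design")) sessions[[i]]$trials
          else sessions[[i]]
    tr$participant <- ids[i]
    tr
  }))
}

#' @export
print.behavioral_summary <- function(x, ...) {
  cat("Behavioral summary (group means):\n")
  print(x$group, digits = 3)
  invisible(x)
}

#' Three-way repeated-measures ANOVA on behavioral summaries
#'
#' The 2 x 2 x 2 (attention type x validity x cue epoch) within-participant
#' ANOVA on d' (or median RT) used to establish the attentional benefits.
#'
#' @param summary A `behavioral_summary` (or its `per_participant` frame).
#' @param dv `"d_prime"` or `"median_rt_s"`.
#' @return Data frame of effects with F, dfs and p-values (see
#'   [rm_anova()]).
#' @export
behavior_anova <- function(summary, dv = c("d_prime", "median_rt_s")) {
  dv <- match.arg(dv)
  df <- if (inherits(summary, "behavioral_summary")) summary$per_participant
        else summary
  rm_anova(df, dv, within = c("attention_type", "validity", "cue_epoch"))
}
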