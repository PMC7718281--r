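#' Attentional Modulation Index
#'
#' AMI = (N + c) / mean(Vc + c, Ic + c, Vi + c, Ii + c), where Vc/Ic are
#' the contralateral valid/invalid response amplitudes, Vi/Ii the
#' ipsilateral (distractor) ones, c a fixed constant added to every
#' condition value so that all offset values are positive (default 0.2),
#' and N the chosen numerator amplitude (default Vc). A ratio of 1 means
#' no attentional modulation; the larger the AMI, the stronger the
#' modulation on valid trials. Across the four numerator choices the AMIs
#' sum to exactly 4 for any amplitudes and constant.
#'
#' @param Vc,Ic,Vi,Ii Condition amplitudes in percent signal change
#'   (vectorized).
#' @param constant Non-negative offset added to all four amplitudes.
#' @param numerator Which offset amplitude forms the numerator.
#' @return The AMI (unitless).
#' @examples
#' compute_ami(0.3, 0.1, 0.1, 0.1, constant = 0.2)  # 0.5 / 0.35
#' @export
compute_ami <- function(Vc, Ic, Vi, Ii, constant = 0.2,
                        numerator = c("Vc", "Ic", "Vi", "Ii")) {
  numerator <- match.arg(numerator)
  if (constant < 0) stop("'constant' must be non-negative")
  off <- cbind(Vc = Vc + constant, Ic = Ic + constant,
               Vi = Vi + constant, Ii = Ii + constant)
  denom <- rowMeans(off)
  if (any(denom <= 0))
    stop("non-positive offset denominator; raise 'constant' so that all ",
         "offset condition values are positive (the constant exists so the ",
         "ratio is computed on positive values)")
  as.numeric(off[, numerator] / denom)
}

#' Build AMI records from a condition-amplitude table
#'
#' For every participant x ROI x attention type x cue epoch, forms Vc and
#' Ic from the epoch-specific contralateral valid/invalid amplitudes
#' (averaged over the two cue sides) and Vi and Ii from the ipsilateral
#' amplitudes averaged over pre and post cues (the distractor terms pool
#' both epochs; set `ipsi_epoch_specific` for a fully epoch-specific
#' variant), then computes the AMI with numerator Vc ("valid") and Ic
#' ("invalid").
#'
#' @param amp_table Condition-amplitude data frame as returned by
#'   [condition_amplitudes()] (columns `participant`, `attention_type`,
#'   `roi`, `laterality`, `cue_epoch`, `validity`, `beta_psc`).
#' @param constant AMI constant (default 0.2).
#' @param ipsi_epoch_specific Use epoch-specific ipsilateral terms.
#' @param rois Named integer vector of hierarchy ranks.
#' @return An `ami_records` data frame: `participant`, `roi`, `rank`,
#'   `attention_type`, `cue_epoch`, `numerator_condition`
#'   (`valid`/`invalid`), `ami`, `constant_used`.
#' @export
ami_table <- function(amp_table, constant = 0.2, ipsi_epoch_specific = FALSE,
                      rois = roi_hierarchy) {
  need <- c("participant", "attention_type", "roi", "laterality",
            "cue_epoch", "validity", "beta_psc")
  if (!all(need %in% names(amp_table)))
    stop("amplitude table is missing column(s): ",
         paste(setdiff(need, names(amp_table)), collapse = ", "))
  keys <- unique(amp_table[, c("participant", "attention_type", "roi")])
  rows <- list()
  for (i in seq_len(nrow(keys))) {
    k <- keys[i, ]
    sub <- amp_table[amp_table$participant == k$participant &
                       amp_table$attention_type == k$attention_type &
                       amp_table$roi == k$roi, , drop = FALSE]
    amp <- function(lat, val, epoch = NULL) {
      m <- sub$laterality == lat & sub$validity == val
      if (!is.null(epoch)) m <- m & sub$cue_epoch == epoch
      if (!any(m)) stop("missing amplitude cell (", lat, ", ", val,
                        if (!is.null(epoch)) paste0(", ", epoch), ") for ",
                        k$participant, "/", k$roi)
      mean(sub$beta_psc[m])
    }
    for (epoch in c("pre", "post")) {
      Vc <- amp("contralateral", "valid", epoch)
      Ic <- amp("contralateral", "invalid", epoch)
      Vi <- amp("ipsilateral", "valid", if (ipsi_epoch_specific) epoch)
      Ii <- amp("ipsilateral", "invalid", if (ipsi_epoch_specific) epoch)
      for (num in c("valid", "invalid")) {
        rows[[length(rows) + 1L]] <- data.frame(
          participant = k$participant, roi = k$roi,
          rank = unname(rois[[k$roi]]),
          attention_type = k$attention_type, cue_epoch = epoch,
          numerator_condition = num,
          ami = compute_ami(Vc, Ic, Vi, Ii, constant = constant,
                            numerator = if (num == "valid") "Vc" else "Ic"),
          constant_used = constant, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ami_records", "data.frame")
  out
}

# valid - invalid AMI difference per participant x ROI x attention x epoch
ami_differences <- function(records) {
  w <- merge(records[records$numerator_condition == "valid",
                     c("participant", "roi", "rank", "attention_type",
                       "cue_epoch", "ami")],
             records[records$numerator_condition == "invalid",
                     c("participant", "roi", "attention_type", "cue_epoch", "ami")],
             by = c("participant", "roi", "attention_type", "cue_epoch"),
             suffixes = c("_valid", "_invalid"))
  w$diff <- w$ami_valid - w$ami_invalid
  w
}

#' AMI sensitivity to the additive constant
#'
#' Recomputes the AMI and the four hierarchy regressions for each
#' candidate constant and reports whether the qualitative pattern (which
#' condition's regression is significant at `alpha`, and each slope's
#' sign) is invariant to the constant.
#'
#' @param amp_table Condition-amplitude table.
#' @param constants Constants to try (all must yield positive offset
#'   denominators).
#' @param alpha Significance level for the pattern comparison.
#' @inheritParams ami_table
#' @return List with `regressions` (per constant x condition: slope, F,
#'   p, R2) and `pattern_invariant` (logical).
#' @export
ami_sensitivity <- function(amp_table, constants = c(0.1, 0.2, 0.4),
                            alpha = 0.05, rois = roi_hierarchy) {
  res <- list()
  for (const in constants) {
    recs <- ami_table(amp_table, constant = const, rois = rois)
    hr <- hierarchy_regressions(recs)
    hr$constant <- const
    res[[length(res) + 1L]] <- hr
  }
  regs <- do.call(rbind, res)
  pat <- split(paste(regs$p_value < alpha, sign(regs$slope)),
               regs$constant)
  structure(list(regressions = regs,
                 pattern_invariant = length(unique(pat)) == 1L),
            class = "ami_sensitivity")
}

#' @export
print.ami_sensitivity <- function(x, ...) {
  cat("AMI constant sensitivity: qualitative pattern",
      if (x$pattern_invariant) "INVARIANT" else "CHANGES",
      "across constants\n")
  print(x$regressions, digits = 3)
  invisible(x)
}

#' One-sample test of the AMI against 1
#'
#' Averages each participant's (valid-numerator) AMI over all conditions
#' and ROIs and tests the participant means against 1 (two-sided
#' one-sample t-test), with Cohen's d = (mean - 1) / SD.
#'
#' @param records An `ami_records` data frame.
#' @return List with `t`, `df`, `p_value`, `cohens_d`, `mean`, `n`,
#'   `degenerate` (TRUE when the participant means have zero variance, in
#'   which case t and p are NA and only d's sign is meaningful).
#' @export
ami_vs_one_test <- function(records) {
  v <- records[records$numerator_condition == "valid", , drop = FALSE]
  means <- tapply(v$ami, v$participant, mean)
  if (length(means) < 2) stop("at least 2 participants are required")
  s <- sd(means)
  if (s == 0) {
    return(list(t = NA_real_, df = length(means) - 1L, p_value = NA_real_,
                cohens_d = NA_real_, mean = mean(means), n = length(means),
                degenerate = TRUE))
  }
  tt <- t.test(means, mu = 1)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, cohens_d = (mean(means) - 1) / s,
       mean = mean(means), n = length(means), degenerate = FALSE)
}

#' Per-ROI one-tailed valid vs. invalid tests
#'
#' Paired one-tailed t-tests (alternative: valid > invalid AMI) for every
#' ROI x attention type x cue epoch cell, across participants. No
#' multiple-comparison correction by default; `correction = "holm"` is
#' available.
#'
#' @param records An `ami_records` data frame.
#' @param correction `"none"` (default) or a [stats::p.adjust()] method.
#' @return Data frame: `roi`, `rank`, `attention_type`, `cue_epoch`, `t`,
#'   `df`, `p_value` (adjusted if requested), `mean_diff`.
#' @export
per_roi_validity_tests <- function(records, correction = "none") {
  d <- ami_differences(records)
  cells <- unique(d[, c("roi", "rank", "attention_type", "cue_epoch")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    k <- cells[i, ]
    sub <- d[d$roi == k$roi & d$attention_type == k$attention_type &
               d$cue_epoch == k$cue_epoch, , drop = FALSE]
    if (anyDuplicated(sub$participant))
      stop("multiple AMI values per participant in cell ", k$roi, "/",
           k$attention_type, "/", k$cue_epoch, "; data are not paired")
    if (sd(sub$diff) == 0) {
      # degenerate paired data: at zero difference the one-tailed test is
      # exactly at its null midpoint; a constant nonzero difference is a
      # sign-determined limit
      m <- mean(sub$diff)
      tt <- list(statistic = if (m == 0) 0 else sign(m) * Inf,
                 parameter = length(sub$diff) - 1L,
                 p.value = if (m == 0) 0.5 else if (m > 0) 0 else 1)
    } else {
      tt <- t.test(sub$diff, alternative = "greater")
    }
    data.frame(roi = k$roi, rank = k$rank, attention_type = k$attention_type,
               cue_epoch = k$cue_epoch, t = unname(tt$statistic),
               df = unname(tt$parameter), p_value = tt$p.value,
               mean_diff = mean(sub$diff), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (correction != "none")
    out$p_value <- stats::p.adjust(out$p_value, method = correction)
  out[order(out$attention_type, out$cue_epoch, out$rank), ]
}

#' Hierarchy regression of the valid-invalid difference on ROI rank
#'
#' Ordinary least squares of the group-mean valid-invalid AMI difference
#' (one point per ROI) on hierarchy rank, with the slope's F test on
#' (1, n_rois - 2) df and R-squared — F(1, 4) for the six visual areas.
#'
#' @param diff Numeric vector of group-mean differences, one per ROI.
#' @param rank Integer hierarchy ranks (same length, >= 3 ROIs).
#' @return One-row data frame: `slope`, `intercept`, `F`, `df1`, `df2`,
#'   `p_value`, `r_squared`.
#' @export
hierarchy_regression <- function(diff, rank) {
  if (length(diff) != length(rank)) stop("diff and rank lengths differ")
  if (length(diff) < 3) stop("at least 3 ROIs are required")
  fit <- lm(diff ~ rank)
  # exact fits trip lm's "essentially perfect fit" notice; the degenerate
  # branches below handle them explicitly
  sm <- suppressWarnings(summary(fit))
  df2 <- length(diff) - 2L
  if (sm$sigma < 1e-12) {
    # degenerate cases: an exactly linear increase (R2 = 1, F infinite)
    # or exactly constant differences (nothing to explain: R2 = 0, F = 0)
    exact_line <- abs(unname(coef(fit)[2])) > 1e-12
    return(data.frame(slope = unname(coef(fit)[2]),
                      intercept = unname(coef(fit)[1]),
                      F = if (exact_line) Inf else 0, df1 = 1L, df2 = df2,
                      p_value = if (exact_line) 0 else 1,
                      r_squared = if (exact_line) 1 else 0, row.names = NULL))
  }
  Fv <- unname(sm$fstatistic[1])
  data.frame(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
             F = Fv, df1 = 1L, df2 = df2,
             p_value = pf(Fv, 1, df2, lower.tail = FALSE),
             r_squared = sm$r.squared, row.names = NULL)
}

#' @rdname hierarchy_regression
#' @param records An `ami_records` data frame: regressions are run on the
#'   group-mean difference per ROI for each attention type x cue epoch.
#' @export
hierarchy_regressions <- function(records) {
  d <- ami_differences(records)
  g <- aggregate(diff ~ roi + rank + attention_type + cue_epoch, d, mean)
  out <- do.call(rbind, lapply(
    split(g, list(g$attention_type, g$cue_epoch)), function(s) {
      cbind(data.frame(attention_type = s$attention_type[1],
                       cue_epoch = s$cue_epoch[1]),
            hierarchy_regression(s$diff, s$rank))
    }))
  rownames(out) <- NULL
  out
}

#' Repeated-measures laterality ANOVA on condition amplitudes
#'
#' Within-participant ANOVA of response amplitude with laterality
#' (contralateral/ipsilateral), validity and ROI factors, for one
#' attention type (amplitudes averaged over cue epochs and cue sides
#' first). Reports all effects; the laterality main effect and the
#' laterality x validity interaction are the ones of interest
#' (contralateral > ipsilateral activity, larger for valid cues).
#'
#' @param amp_table Condition-amplitude table.
#' @param attention_type Which attention condition to analyse.
#' @return Effects table from [rm_anova()].
#' @export
laterality_anova <- function(amp_table,
                             attention_type = c("endogenous", "exogenous")) {
  attention_type <- match.arg(attention_type)
  sub <- amp_table[amp_table$attention_type == attention_type, , drop = FALSE]
  if (nrow(sub) == 0) stop("no rows for attention type ", attention_type)
  agg <- aggregate(beta_psc ~ participant + roi + laterality + validity,
                   sub, mean)
  rm_anova(agg, "beta_psc", within = c("laterality", "validity", "roi"))
}

#' Linear mixed model of attentional modulation along the hierarchy
#'
#' Fits the valid-invalid AMI difference for one cue epoch against ROI
#' hierarchy rank, attention condition (endogenous/exogenous, +/- 1/2
#' contrast coding so the intercept is the grand mean) and their
#' interaction, with by-participant random intercepts and independent
#' random slopes for rank and attention (no random interaction). Maximum
#' likelihood; p-values by likelihood-ratio tests on nested models; t
#' statistics use the df convention n_obs - n_fixed (56 for 5
#' participants x 6 ROIs x 2 attention conditions). On non-convergence the
#' random-effects structure falls back to intercepts only (logged in the
#' result); singular fits are reported in the diagnostics, not hidden.
#'
#' @param records An `ami_records` data frame.
#' @param cue_epoch `"pre"` or `"post"`.
#' @param correlated_slopes Use a correlated random intercept+slope
#'   structure instead of independent terms.
#' @return An `attention_lmm`: list with `fixed` (estimate, se, t, df,
#'   LRT p per fixed effect), `model` (the lme4 fit), `singular`,
#'   `fallback`, `data`.
#' @export
fit_attention_lmm <- function(records, cue_epoch = c("pre", "post"),
                              correlated_slopes = FALSE) {
  cue_epoch <- match.arg(cue_epoch)
  d <- ami_differences(records)
  d <- d[d$cue_epoch == cue_epoch, , drop = FALSE]
  if (length(unique(d$attention_type)) != 2)
    stop("both attention types are required for the mixed model")
  d$att <- ifelse(d$attention_type == "endogenous", 0.5, -0.5)
  d$rank <- as.numeric(d$rank)

  forms <- if (correlated_slopes) {
    list(full = diff ~ rank * att + (1 + rank + att | participant),
         no_int = diff ~ rank + att + (1 + rank + att | participant),
         no_rank = diff ~ att + (1 + rank + att | participant),
         no_att = diff ~ rank + (1 + rank + att | participant),
         no_intercept = diff ~ 0 + rank + att + rank:att +
           (1 + rank + att | participant))
  } else {
    re <- "(1 | participant) + (0 + rank | participant) + (0 + att | participant)"
    mk <- function(fe) stats::as.formula(paste("diff ~", fe, "+", re))
    list(full = mk("rank * att"), no_int = mk("rank + att"),
         no_rank = mk("att"), no_att = mk("rank"),
         no_intercept = mk("0 + rank + att + rank:att"))
  }
  fit1 <- function(f) {
    suppressWarnings(suppressMessages(
      lme4::lmer(f, data = d, REML = FALSE,
                 control = lme4::lmerControl(check.conv.singular = "ignore",
                                             calc.derivs = FALSE))))
  }
  fallback <- FALSE
  fits <- tryCatch(lapply(forms, fit1), error = function(e) NULL)
  if (is.null(fits)) {
    fallback <- TRUE
    forms <- lapply(list(full = "rank * att", no_int = "rank + att",
                         no_rank = "att", no_att = "rank",
                         no_intercept = "0 + rank + att + rank:att"),
                    function(fe) stats::as.formula(
                      paste("diff ~", fe, "+ (1 | participant)")))
    fits <- lapply(forms, fit1)
  }
  full <- fits$full
  singular <- lme4::isSingular(full, tol = 1e-4)
  est <- lme4::fixef(full)
  se <- sqrt(diag(as.matrix(vcov(full))))
  df_t <- nrow(d) - length(est)
  lrt_p <- function(reduced, term_full = full) {
    stat <- 2 * (as.numeric(logLik(term_full)) - as.numeric(logLik(reduced)))
    pchisq(max(stat, 0), df = 1, lower.tail = FALSE)
  }
  p <- c("(Intercept)" = lrt_p(fits$no_intercept),
         rank = lrt_p(fits$no_rank, fits$no_int),
         att = lrt_p(fits$no_att, fits$no_int),
         "rank:att" = lrt_p(fits$no_int))
  fixed <- data.frame(term = names(est), estimate = unname(est),
                      se = unname(se), t = unname(est / se), df = df_t,
                      p_lrt = unname(p[names(est)]), row.names = NULL)
  structure(list(fixed = fixed, model = full, singular = singular,
                 fallback = fallback, cue_epoch = cue_epoch, data = d),
            class = "attention_lmm")
}

#' @export
print.attention_lmm <- function(x, ...) {
  cat("Linear mixed model (", x$cue_epoch, "-cue): diff ~ rank * attention\n",
      sep = "")
  if (x$fallback) cat("  [random-effects structure fell back to intercepts only]\n")
  if (x$singular) cat("  [fit is singular: some random-effect variances are ~0]\n")
  print(x$fixed, digits = 3)
  invisible(x)
}
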