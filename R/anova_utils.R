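#' Repeated-measures ANOVA via within-subject error strata
#'
#' Thin wrapper around [stats::aov()] with an `Error(subject/(A*B*...))`
#' term, i.e. the standard within-participant sums-of-squares
#' decomposition. The design must be complete and balanced: exactly one
#' observation per subject per factor-level cell (aggregate first if not).
#'
#' @param data Data frame in long format.
#' @param dv Name of the numeric response column.
#' @param within Character vector of within-subject factor columns.
#' @param subject Name of the subject identifier column.
#' @return Data frame with one row per effect: `effect`, `df1`, `df2`,
#'   `statistic` (F), `p_value`.
#' @export
rm_anova <- function(data, dv, within, subject = "participant") {
  stopifnot(all(c(dv, within, subject) %in% names(data)))
  data[[subject]] <- factor(data[[subject]])
  if (nlevels(data[[subject]]) < 2)
    stop("repeated-measures ANOVA requires at least 2 subjects")
  for (w in within) data[[w]] <- factor(data[[w]])

  cells <- do.call(table, c(data[c(subject, within)]))
  if (any(cells != 1L)) {
    bad <- which(cells != 1L, arr.ind = TRUE)[1, ]
    dn <- dimnames(cells)
    lab <- paste(mapply(function(d, i) paste0(names(dn)[d], "=", dn[[d]][i]),
                        seq_along(bad), bad), collapse = ", ")
    stop("design is incomplete/unbalanced at cell: ", lab,
         " (each subject needs exactly one observation per cell)")
  }

  rhs <- paste(within, collapse = " * ")
  f <- stats::as.formula(paste0(dv, " ~ ", rhs, " + Error(", subject,
                                "/(", rhs, "))"))
  fit <- aov(f, data = data)
  out <- do.call(rbind, lapply(summary(fit), function(stratum) {
    tab <- stratum[[1]]
    rows <- rownames(tab)
    keep <- !grepl("Residuals", rows)
    if (!any(keep)) return(NULL)
    err_df <- tab[grepl("Residuals", rows), "Df"]
    data.frame(effect = gsub(" ", "", rows[keep]),
               df1 = tab[keep, "Df"], df2 = err_df,
               statistic = tab[keep, "F value"],
               p_value = tab[keep, "Pr(>F)"],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
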