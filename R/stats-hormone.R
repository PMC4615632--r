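.checkHormonePanel <- function(panel) {
  need <- c("female", "timepoint", "testosterone")
  if (!all(need %in% names(panel)))
    stop("hormone panel needs columns: ", paste(need, collapse = ", "))
  panel <- panel[!is.na(panel$testosterone), , drop = FALSE]
  if (any(panel$testosterone <= 0))
    stop("testosterone concentrations must be positive (ng/mL)")
  if (anyDuplicated(panel[, c("female", "timepoint")]))
    stop("at most one record per (female, timepoint)")
  panel$female <- factor(panel$female)
  tp <- c("pre", "week1", "week4")
  panel$timepoint <- if (all(panel$timepoint %in% tp))
    factor(panel$timepoint, levels = tp) else factor(panel$timepoint)
  panel <- droplevels(panel)
  if (nlevels(panel$timepoint) < 2L)
    stop("need at least 2 timepoints")
  if (any(table(panel$timepoint) < 2L))
    stop("need at least 2 observations per timepoint")
  panel
}

#' Repeated-measures ANOVA of plasma testosterone over timepoints
#'
#' Tests the change in circulating testosterone across sampling timepoints
#' (pre-implant, week 1, week 4) within females. Because females contribute
#' unequal numbers of samples, the model is the female-blocked additive
#' linear model `testosterone ~ female + timepoint`; the timepoint F is the
#' marginal (extra-sum-of-squares) test on the residual error df
#' `N - 1 - (n_females - 1) - (n_timepoints - 1)`. Least-squares timepoint
#' means and standard errors come from emmeans.
#'
#' @param panel data.frame with columns `female`, `timepoint`,
#'   `testosterone` (ng/mL); at most one record per (female, timepoint);
#'   missing cells simply absent.
#' @return Object of class `anovaTime`: list with `F`, `df` (num, den),
#'   `pValue`, `lsmeans` (timepoint, mean, SE), `nRecords`, `nFemales`, and
#'   the underlying `fit`.
#' @examples
#' p <- genHormonePanel(seed = 1)
#' anovaTime(p)
#' @export
anovaTime <- function(panel) {
  panel <- .checkHormonePanel(panel)
  fit <- stats::lm(testosterone ~ female + timepoint, data = panel)
  if (sum(stats::residuals(fit)^2) <= 1e-12 * sum(panel$testosterone^2))
    stop("degenerate input: zero residual variance, the time-effect F is unbounded")
  fit0 <- stats::lm(testosterone ~ female, data = panel)
  aovtab <- stats::anova(fit0, fit)
  dfNum <- aovtab$Df[2]
  dfDen <- fit$df.residual
  Fstat <- aovtab$F[2]
  em <- emmeans::emmeans(fit, "timepoint")
  es <- as.data.frame(em)
  structure(list(
    F = Fstat, df = c(as.integer(dfNum), as.integer(dfDen)),
    pValue = aovtab$`Pr(>F)`[2],
    lsmeans = data.frame(timepoint = as.character(es$timepoint),
                         mean = es$emmean, SE = es$SE),
    nRecords = nrow(panel), nFemales = nlevels(panel$female),
    fit = fit),
    class = "anovaTime")
}

#' @export
print.anovaTime <- function(x, ...) {
  cat(sprintf("Testosterone time course: F(%d, %d) = %.2f, p = %.3g (%d records, %d females)\n",
              x$df[1], x$df[2], x$F, x$pValue, x$nRecords, x$nFemales))
  print(transform(x$lsmeans, mean = round(mean, 2), SE = round(SE, 2)))
  invisible(x)
}

#' Tukey-adjusted pairwise timepoint contrasts
#'
#' Least-squares mean differences between sampling timepoints from the
#' fitted blocked model, with Tukey-Kramer multiplicity adjustment on the
#' model's error df.
#'
#' @param model an `anovaTime` fit (or a raw panel, which is fitted first).
#' @return data.frame with columns `contrast`, `estimate`, `SE`, `df`, `t`,
#'   `pAdjusted`.
#' @export
pairwiseAdjusted <- function(model) {
  if (!inherits(model, "anovaTime")) model <- anovaTime(model)
  pr <- summary(emmeans::contrast(emmeans::emmeans(model$fit, "timepoint"),
                                  method = "pairwise", adjust = "tukey"))
  data.frame(contrast = as.character(pr$contrast),
             estimate = pr$estimate, SE = pr$SE, df = pr$df,
             t = pr$t.ratio, pAdjusted = pr$p.value)
}
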