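# Wald F test of each fixed-effect term (all its coefficients jointly 0),
# with the residual (containment-style) denominator df N - rank(X).
.waldFTable <- function(beta, V, asgn, labels, dfDen) {
  rows <- lapply(seq_along(labels), function(j) {
    idx <- which(asgn == j)
    if (!length(idx)) return(NULL)
    b <- beta[idx]
    Fj <- drop(t(b) %*% solve(V[idx, idx, drop = FALSE], b)) / length(idx)
    data.frame(term = labels[j], F = Fj, dfNum = length(idx), dfDen = dfDen,
               pValue = stats::pf(Fj, length(idx), dfDen, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.checkTimecourse <- function(data, response) {
  need <- c("female", "week", "morph", response)
  if (!all(need %in% names(data)))
    stop("time-course data needs columns: ", paste(need, collapse = ", "))
  data <- data[is.finite(data[[response]]), , drop = FALSE]
  data$female <- factor(data$female)
  data$morph <- .groupFactor(data$morph)
  data
}

#' Quadratic mixed-effects model of a colour variable over time
#'
#' Fits the colour-development model: fixed effects of week, week squared,
#' morph and the morph x week and morph x week-squared interactions, with a
#' random intercept per female to absorb repeated measures, estimated by
#' REML ([lme4::lmer()]). Morph is coded with sum-to-zero contrasts so each
#' term's Wald F (residual-df denominator) is a marginal (type III) test;
#' the morph x week-squared interaction is the test of morph-specific
#' curvature.
#'
#' @param data data.frame with columns `female`, `week`, `morph` and the
#'   response; at least 2 morphs and 3 distinct weeks.
#' @param response name of the response column (e.g. `"prop_red"`).
#' @return Object of class `timecourseFit`: list with `anova` (term, F,
#'   dfNum, dfDen, pValue), `varianceComponents` (femaleIntercept,
#'   residual), `fixef`, `response`, `n`, and the lme4 `fit`.
#' @examples
#' d <- genTimecourse(seed = 1)
#' fitTimecourse(d, "prop_red")$anova
#' @export
fitTimecourse <- function(data, response) {
  data <- .checkTimecourse(data, response)
  if (nlevels(data$morph) < 2L) stop("need at least 2 morphs")
  if (length(unique(data$week)) < 3L) stop("need at least 3 distinct weeks")
  if (any(table(data$female) < 2L))
    stop("every female needs at least 2 observations")
  data$week2 <- data$week^2
  fml <- stats::as.formula(
    paste(response, "~ morph + week + week2 + morph:week + morph:week2 + (1 | female)"))
  fit <- tryCatch(
    lme4::lmer(fml, data = data, REML = TRUE,
               contrasts = list(morph = "contr.sum"),
               control = lme4::lmerControl(check.conv.singular = "ignore")),
    error = function(e) stop("mixed-model fit failed: ", conditionMessage(e)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  vcomp <- c(femaleIntercept = vc$vcov[vc$grp == "female"],
             residual = vc$vcov[vc$grp == "Residual"])
  if (vcomp[["residual"]] <= 1e-12)
    stop("degenerate input: zero residual variance (response is exactly determined)")
  X <- stats::model.matrix(fit)
  asgn <- attr(X, "assign")
  labels <- attr(stats::terms(fit), "term.labels")
  dfDen <- nrow(X) - qr(X)$rank
  tab <- .waldFTable(lme4::fixef(fit), as.matrix(stats::vcov(fit)),
                     asgn, labels, dfDen)
  structure(list(anova = tab, varianceComponents = vcomp,
                 fixef = lme4::fixef(fit), response = response,
                 n = nrow(X), fit = fit),
            class = "timecourseFit")
}

#' @export
print.timecourseFit <- function(x, ...) {
  cat(sprintf("Colour time-course model for '%s' (n = %d):\n", x$response, x$n))
  tab <- x$anova
  tab$F <- round(tab$F, 2)
  tab$pValue <- signif(tab$pValue, 3)
  print(tab, row.names = FALSE)
  cat(sprintf("  variance components: female intercept %.4g, residual %.4g\n",
              x$varianceComponents[["femaleIntercept"]],
              x$varianceComponents[["residual"]]))
  invisible(x)
}

#' Linear and quadratic time trends within one morph
#'
#' The follow-up fit used when the morph x week-squared interaction is
#' significant: the same random-intercept model restricted to one morph,
#' without morph terms, giving F tests for the linear and quadratic week
#' effects.
#'
#' @inheritParams fitTimecourse
#' @param morph morph label to restrict to.
#' @return A `timecourseFit` whose `anova` has `week` and `week2` rows.
#' @export
perMorphTrend <- function(data, response, morph) {
  data <- .checkTimecourse(data, response)
  data <- droplevels(data[data$morph == morph, , drop = FALSE])
  if (nrow(data) == 0L) stop("no rows for morph '", morph, "'")
  if (length(unique(data$week)) < 3L)
    stop("need at least 3 distinct weeks within the morph")
  data$week2 <- data$week^2
  fml <- stats::as.formula(paste(response, "~ week + week2 + (1 | female)"))
  fit <- lme4::lmer(fml, data = data, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  vc <- as.data.frame(lme4::VarCorr(fit))
  vcomp <- c(femaleIntercept = vc$vcov[vc$grp == "female"],
             residual = vc$vcov[vc$grp == "Residual"])
  if (vcomp[["residual"]] <= 1e-12)
    stop("degenerate input: zero residual variance")
  X <- stats::model.matrix(fit)
  tab <- .waldFTable(lme4::fixef(fit), as.matrix(stats::vcov(fit)),
                     attr(X, "assign"), attr(stats::terms(fit), "term.labels"),
                     nrow(X) - qr(X)$rank)
  structure(list(anova = tab, varianceComponents = vcomp,
                 fixef = lme4::fixef(fit), response = response,
                 n = nrow(X), fit = fit),
            class = "timecourseFit")
}
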