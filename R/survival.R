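#' Kaplan-Meier product-limit estimate per group
#'
#' Wraps [survival::survfit()] and returns a tidy step-function table with
#' Greenwood standard errors.
#'
#' @param surv Data frame with columns `time` (> 0) and `event` (0/1).
#' @param by Optional grouping vector (or column name in `surv`); omitted =
#'   one curve.
#' @return Data frame with `group`, `time`, `n_risk`, `n_event`, `surv`,
#'   `std_err`, `lower`, `upper`.
#' @export
km_estimate <- function(surv, by = NULL) {
  surv <- validate_survival(surv)
  groups <- resolve_group(surv, by)
  if (any(table(groups) == 0)) stop("empty group")
  fit <- survival::survfit(survival::Surv(surv$time, surv$event) ~ groups)
  smry <- summary(fit)
  grp <- if (is.null(smry$strata)) rep(unique(as.character(groups)),
                                       length(smry$time))
         else sub("^groups=", "", as.character(smry$strata))
  data.frame(group = grp, time = smry$time, n_risk = smry$n.risk,
             n_event = smry$n.event, surv = smry$surv,
             std_err = smry$std.err, lower = smry$lower,
             upper = smry$upper, stringsAsFactors = FALSE)
}

validate_survival <- function(surv) {
  stopifnot(all(c("time", "event") %in% colnames(surv)))
  surv <- surv[!is.na(surv$time) & !is.na(surv$event), , drop = FALSE]
  if (any(surv$time <= 0)) stop("times must be positive")
  if (!all(surv$event %in% c(0, 1))) stop("event must be 0/1")
  surv
}

resolve_group <- function(surv, by) {
  if (is.null(by)) return(factor(rep("all", nrow(surv))))
  if (length(by) == 1 && is.character(by) && by %in% colnames(surv))
    return(factor(surv[[by]]))
  factor(by)
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic: observed minus expected events with
#' hypergeometric variance summed over event times; `chi2 = (O - E)^2 / V`,
#' p from the chi-square distribution with `k - 1` degrees of freedom.
#'
#' @param surv Data frame with `time`, `event`.
#' @param groups Grouping vector or column name.
#' @return List with `chi2`, `df`, `p.value`.
#' @export
logrank_test <- function(surv, groups = "group") {
  surv <- validate_survival(surv)
  g <- resolve_group(surv, groups)
  if (nlevels(droplevels(g)) < 2) stop("need at least 2 groups")
  if (sum(surv$event) == 0) stop("no events; log-rank undefined")
  sd <- survival::survdiff(survival::Surv(surv$time, surv$event) ~ g)
  df <- length(sd$n) - 1
  list(chi2 = unname(sd$chisq), df = df,
       p.value = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards model
#'
#' Newton-Raphson maximization of the Breslow (default) or Efron partial
#' likelihood via [survival::coxph()]; reports hazard ratios with Wald 95 percent
#' confidence intervals.
#'
#' @param surv Data frame with `time`, `event` and covariate columns.
#' @param covariates Character vector of covariate column names.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return Data frame with `term`, `coef`, `hr`, `lower`, `upper`, `p`.
#' @export
cox_ph <- function(surv, covariates, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  surv <- validate_survival(surv)
  if (sum(surv$event) < length(covariates) + 1)
    stop("too few events for the number of covariates")
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(covariates, collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = surv, ties = ties),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be", conditionMessage(w)))
        stop("Cox model failed to converge (monotone likelihood?): ",
             conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)
  co <- sm$coefficients
  if (any(!is.finite(co[, "coef"]))) stop("non-finite Cox coefficient")
  data.frame(term = rownames(co), coef = co[, "coef"],
             hr = exp(co[, "coef"]),
             lower = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
             upper = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
             p = co[, "Pr(>|z|)"], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Hazard ratio as a smooth function of a continuous score
#'
#' Fits a Cox model on a natural cubic spline basis of the score (knots at
#' quantiles, `df` degrees of freedom) and evaluates the log hazard ratio on
#' a score grid relative to the median score, with pointwise Wald confidence
#' intervals. The curve is exactly 0 at the median by construction.
#'
#' @param surv Data frame with `time`, `event`.
#' @param scores Continuous per-subject score aligned to `surv`.
#' @param df Spline degrees of freedom (must be below the number of distinct
#'   scores).
#' @param grid_n Number of evaluation points (the median is always included).
#' @return Data frame with `score`, `ln_hr`, `lower`, `upper`.
#' @export
hr_score_curve <- function(surv, scores, df = 4, grid_n = 100) {
  surv <- validate_survival(surv)
  stopifnot(length(scores) == nrow(surv))
  if (df >= length(unique(scores)))
    stop("df must be smaller than the number of distinct scores")
  basis <- splines::ns(scores, df = df)
  fit <- survival::coxph(survival::Surv(surv$time, surv$event) ~ basis,
                         ties = "breslow")
  beta <- stats::coef(fit)
  V <- stats::vcov(fit)
  med <- stats::median(scores)
  grid <- sort(unique(c(med, seq(min(scores), max(scores),
                                 length.out = grid_n))))
  Xg <- stats::predict(basis, grid)
  Xm <- stats::predict(basis, med)
  D <- sweep(Xg, 2, as.vector(Xm))
  ln_hr <- as.vector(D %*% beta)
  se <- sqrt(pmax(rowSums((D %*% V) * D), 0))
  data.frame(score = grid, ln_hr = ln_hr,
             lower = ln_hr - 1.96 * se, upper = ln_hr + 1.96 * se)
}
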