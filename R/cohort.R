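# Outcome association under case-cohort, matched case-control,
# repeated-measures and effect-modification designs.

# Prentice risk-set construction as counting-process intervals: subcohort
# members are at risk over (entry, exit]; cases outside the subcohort enter
# only just before their own event.
# eps must stay above coxph's relative tie tolerance on the age scale
prentice_intervals <- function(d, eps = 1e-4) {
  stopifnot(all(c("entry_age", "exit_age", "event", "subcohort") %in% names(d)))
  if (any(d$exit_age <= d$entry_age)) stop("exit_age must exceed entry_age")
  if (any(d$event == 0 & !d$subcohort)) {
    stop("non-subcohort rows must all be cases")
  }
  tstart <- ifelse(d$subcohort, d$entry_age, d$exit_age - eps)
  data.frame(tstart = tstart, tstop = d$exit_age, d, check.names = FALSE)
}

check_model_complete <- function(d, cols) {
  bad <- cols[vapply(cols, function(cn) anyNA(d[[cn]]), logical(1))]
  if (length(bad)) {
    stop(sprintf("missing values in model columns (complete-case contract): %s",
                 paste(bad, collapse = ", ")))
  }
}

#' Prentice-weighted Cox regression for case-cohort data
#'
#' Fits a Cox proportional hazards model with age as the underlying time
#' scale and Prentice pseudo-likelihood risk sets, with robust
#' (grouped-jackknife) variance clustered on subject. With
#' `subcohort = TRUE` for every row the fit reduces to a standard cohort Cox
#' model.
#'
#' @param d data.frame with `id`, `entry_age`, `exit_age`, `event` (0/1),
#'   `subcohort` (logical), the exposure and covariate columns (complete
#'   cases required).
#' @param exposure exposure column name.
#' @param covariates character vector of adjustment column names.
#' @param ties_method `"efron"` (default) or `"breslow"`.
#' @return a `hazard_result`: hazard ratio per exposure unit with robust
#'   95% CI, robust SE, log-HR, p-value and model metadata.
#' @export
fit_prentice_cox <- function(d, exposure, covariates = character(0),
                             ties_method = c("efron", "breslow")) {
  ties_method <- match.arg(ties_method)
  stopifnot(is.data.frame(d), exposure %in% names(d),
            all(covariates %in% names(d)))
  check_model_complete(d, c(exposure, covariates, "entry_age", "exit_age", "event"))
  if (sum(d$event) == 0) stop("no events: the partial likelihood is undefined")
  cp <- prentice_intervals(d)
  rhs <- paste(c(sprintf("`%s`", exposure),
                 sprintf("`%s`", covariates)), collapse = " + ")
  fml <- stats::as.formula(paste("survival::Surv(tstart, tstop, event) ~", rhs))
  fit <- survival::coxph(fml, data = cp, ties = ties_method, robust = TRUE,
                         cluster = id)
  if (anyNA(stats::coef(fit))) {
    stop("Cox model failed to converge / produced undefined coefficients")
  }
  co <- stats::coef(fit)[1]
  rse <- sqrt(diag(fit$var))[1]
  hazard_result(loghr = unname(co), se = unname(rse),
                n = nrow(d), n_events = sum(d$event),
                exposure = exposure, covariates = covariates,
                design = "case-cohort (Prentice)", fit = fit)
}

hazard_result <- function(loghr, se, n, n_events, exposure, covariates,
                          design, fit = NULL) {
  z <- stats::qnorm(0.975)
  structure(list(
    hr = exp(loghr), ci_lower = exp(loghr - z * se), ci_upper = exp(loghr + z * se),
    loghr = loghr, se_robust = se,
    p = 2 * stats::pnorm(abs(loghr / se), lower.tail = FALSE),
    n = n, n_events = n_events, exposure = exposure,
    covariates = covariates, design = design, fit = fit
  ), class = "hazard_result")
}

#' @export
print.hazard_result <- function(x, ...) {
  pr <- percent_risk_reduction(x)
  cat(sprintf("<hazard_result> HR = %.3f (95%% CI %.3f-%.3f); reduction %.1f%% (%.1f%% to %.1f%%); n=%d, events=%d\n",
              x$hr, x$ci_lower, x$ci_upper, pr$reduction, pr$ci_lower,
              pr$ci_upper, x$n, x$n_events))
  invisible(x)
}

#' Percent risk reduction implied by a hazard ratio
#'
#' `(1 - HR) * 100`, with the CI endpoints transformed monotonically (the
#' upper HR limit becomes the lower reduction limit).
#'
#' @param hr `hazard_result` or a positive numeric HR (optionally with
#'   `ci` as a length-2 vector).
#' @param ci optional CI for a numeric `hr`.
#' @return list with `reduction`, `ci_lower`, `ci_upper` (percent).
#' @export
percent_risk_reduction <- function(hr, ci = NULL) {
  if (inherits(hr, "hazard_result")) {
    ci <- c(hr$ci_lower, hr$ci_upper)
    hr <- hr$hr
  }
  if (hr <= 0) stop("hazard ratio must be positive")
  out <- list(reduction = (1 - hr) * 100)
  if (!is.null(ci)) {
    out$ci_lower <- (1 - ci[2]) * 100
    out$ci_upper <- (1 - ci[1]) * 100
  }
  out
}

#' Conditional logistic regression for 1:1 matched case-control data
#'
#' Maximizes the conditional likelihood per matched pair (equivalent, for
#' 1:1 matching, to logistic regression on within-pair differences with no
#' intercept). The exposure is standardized to the control distribution by
#' default, giving odds ratios per control s.d.
#'
#' @param pairs data.frame with `pair_id`, `role` (`"case"`/`"control"`) or a
#'   0/1 `case` column, the exposure and covariates.
#' @param exposure exposure column name.
#' @param covariates adjustment column names.
#' @param standardize divide the exposure by the control-group s.d.
#' @return an `odds_result`: OR per (s.d. of) exposure, 95% CI, SE, p,
#'   number of informative pairs.
#' @export
fit_conditional_logistic <- function(pairs, exposure,
                                     covariates = character(0),
                                     standardize = TRUE) {
  stopifnot(is.data.frame(pairs), "pair_id" %in% names(pairs),
            exposure %in% names(pairs), all(covariates %in% names(pairs)))
  if (!"case" %in% names(pairs)) {
    if (!"role" %in% names(pairs)) stop("pairs need a `case` or `role` column")
    pairs$case <- as.integer(pairs$role == "case")
  }
  check_model_complete(pairs, c(exposure, covariates))
  tab <- table(pairs$pair_id, pairs$case)
  if (any(tab != 1)) {
    stop("every matched stratum must contain exactly one case and one control")
  }
  x <- pairs[[exposure]]
  sdev <- 1
  if (standardize) {
    sdev <- stats::sd(x[pairs$case == 0])
    if (!is.finite(sdev) || sdev == 0) stop("control exposure has zero variance")
  }
  pairs$.ex <- x / sdev
  split_diff <- tapply(pairs$.ex, pairs$pair_id, function(v) diff(range(v)))
  if (all(split_diff == 0)) {
    stop("exposure is identical within every pair: no information")
  }
  # conditional likelihood via the exact-method Cox trick (what clogit does)
  pairs$.one <- 1
  rhs <- paste(c(".ex", sprintf("`%s`", covariates),
                 "survival::strata(pair_id)"), collapse = " + ")
  fml <- stats::as.formula(paste("survival::Surv(.one, case) ~", rhs))
  fit <- survival::coxph(fml, data = pairs, method = "exact")
  co <- stats::coef(fit)[".ex"]
  se <- sqrt(diag(fit$var))[1]
  if (!is.finite(co) || abs(co) > 15) {
    stop("conditional logistic fit separated (|log OR| > 15); check the exposure coding")
  }
  z <- stats::qnorm(0.975)
  structure(list(or = exp(unname(co)), ci_lower = exp(unname(co) - z * se),
                 ci_upper = exp(unname(co) + z * se), logor = unname(co),
                 se = unname(se),
                 p = 2 * stats::pnorm(abs(co / se), lower.tail = FALSE),
                 n_pairs = nrow(pairs) / 2, per_sd = standardize,
                 sd_used = sdev, fit = fit),
            class = "odds_result")
}

#' @export
print.odds_result <- function(x, ...) {
  cat(sprintf("<odds_result> OR%s = %.3f (95%% CI %.3f-%.3f), p = %.3g, pairs = %d\n",
              if (x$per_sd) " per s.d." else "", x$or, x$ci_lower, x$ci_upper,
              x$p, as.integer(x$n_pairs)))
  invisible(x)
}

#' Ten-year change analysis in matched pairs
#'
#' Conditional logistic regression of case status on the standardized
#' exposure change between two timepoints, adjusted for the baseline
#' exposure and further covariates. Both measurements must precede all
#' events (`timepoints_precede_events` flag).
#'
#' @param pairs matched-pairs data.frame with `score_t1` and `score_t2`
#'   columns (plus `pair_id` and case indicator as in
#'   [fit_conditional_logistic()]).
#' @param covariates adjustment column names.
#' @param timepoints_precede_events logical assertion supplied by the caller.
#' @return an `odds_result` for the change term (OR per s.d. of change).
#' @export
change_analysis <- function(pairs, covariates = character(0),
                            timepoints_precede_events = TRUE) {
  stopifnot(all(c("score_t1", "score_t2") %in% names(pairs)))
  if (!isTRUE(timepoints_precede_events)) {
    stop("both measurements must precede all events (timepoint ordering violated)")
  }
  pairs$score_change <- pairs$score_t2 - pairs$score_t1
  if (stats::sd(pairs$score_change) == 0) {
    stop("exposure change is degenerate (identically constant)")
  }
  fit_conditional_logistic(pairs, exposure = "score_change",
                           covariates = c("score_t1", covariates),
                           standardize = TRUE)
}

#' Effect modification of an intervention by pre-intervention score
#'
#' Two stages, on an intervention case-cohort with pre-intervention and
#' in-trial (1-year) score measurements:
#' \enumerate{
#'   \item a Prentice-weighted Cox model with the three-way interaction
#'     `arm x score_pre x score_year1` plus all main effects and two-way
#'     terms, adjusted for age and sex; the Wald p-value of the three-way
#'     term is reported;
#'   \item Prentice-weighted Cox models of the intervention vs control within
#'     pre-intervention-score strata split at the median (ties to the low
#'     stratum), adjusted for age, sex and pre-intervention BMI.
#' }
#' A stratum with zero events in either arm is flagged and not estimated.
#'
#' @param d case-cohort data.frame with `arm` (0/1), `score_pre`,
#'   `score_year1`, `age`, `sex`, `bmi` plus the case-cohort design columns.
#' @return list: `interaction_p`, `median_pre`, `strata` (named list of
#'   `hazard_result` or a flag string), `interaction_fit`.
#' @export
interaction_and_strata <- function(d) {
  need <- c("arm", "score_pre", "score_year1", "age", "sex", "bmi",
            "entry_age", "exit_age", "event", "subcohort", "id")
  stopifnot(all(need %in% names(d)))
  check_model_complete(d, c("arm", "score_pre", "score_year1", "age", "sex"))
  cp <- prentice_intervals(d)
  fit <- survival::coxph(
    survival::Surv(tstart, tstop, event) ~ arm * score_pre * score_year1 +
      age + sex,
    data = cp, robust = TRUE, cluster = id, ties = "efron")
  cf <- stats::coef(fit)
  k <- which(names(cf) == "arm:score_pre:score_year1")
  z <- cf[k] / sqrt(diag(fit$var))[k]
  interaction_p <- unname(2 * stats::pnorm(abs(z), lower.tail = FALSE))

  med <- stats::median(d$score_pre)
  strata_def <- list(low = d$score_pre <= med, high = d$score_pre > med)
  strata <- lapply(strata_def, function(sel) {
    ds <- d[sel, , drop = FALSE]
    ev <- table(factor(ds$arm, levels = c(0, 1)), ds$event)
    if (ncol(ev) < 2 || any(ev[, "1"] == 0)) {
      return("zero events in at least one arm: stratum not estimable")
    }
    fit_prentice_cox(ds, exposure = "arm", covariates = c("age", "sex", "bmi"))
  })
  list(interaction_p = interaction_p, median_pre = med, strata = strata,
       interaction_fit = fit)
}

#' Spearman correlations of a score with covariate or food-group tables
#'
#' @param scores numeric vector (aligned to `table` rows).
#' @param table data.frame of numeric columns.
#' @param method correlation method (default `"spearman"`).
#' @return data.frame: `variable`, `rho`, `n` (pairwise complete); constant
#'   or under-sized columns yield `NA` with a reason.
#' @export
correlate_score <- function(scores, table, method = "spearman") {
  stopifnot(is.numeric(scores), is.data.frame(table),
            length(scores) == nrow(table))
  rows <- lapply(names(table), function(v) {
    x <- table[[v]]
    ok <- !is.na(x) & !is.na(scores)
    n <- sum(ok)
    if (n < 3 || !is.numeric(x) || stats::sd(x[ok]) == 0) {
      return(data.frame(variable = v, rho = NA_real_, n = n,
                        note = if (n < 3) "fewer than 3 paired observations"
                               else "constant or non-numeric column"))
    }
    data.frame(variable = v,
               rho = stats::cor(scores[ok], x[ok], method = method),
               n = n, note = "")
  })
  do.call(rbind, rows)
}
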