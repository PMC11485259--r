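# Per-lipid intervention-effect estimation and score-component selection.

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up q-values: `q_(i) = min_{j >= i} m * p_(j) / j` on the sorted
#' p-values. Rejection at level `level` uses the strict convention
#' `q < level` (equivalent to the classic step-up rule except on the
#' measure-zero boundary `q == level`).
#'
#' @param p_values numeric vector of p-values in \[0, 1\] (no `NA`).
#' @param level FDR level, default 0.05.
#' @return list with `q` (same order as input) and logical `reject`.
#' @export
bh_fdr <- function(p_values, level = 0.05) {
  if (any(is.na(p_values))) stop("p-values must not contain NA/NaN")
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p_values)
  o <- order(p_values)
  q_sorted <- p_values[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  list(q = q, reject = q < level)
}

#' Estimate per-lipid diet-intervention effects
#'
#' For each lipid, ordinary least squares of the post-intervention
#' log concentration on the trial arm indicator (control as reference),
#' adjusting for the lipid's baseline concentration, age, BMI and sex. The
#' arm coefficient is the intervention effect; its model-based standard error
#' and two-sided t-test p-value (residual degrees of freedom) are reported,
#' followed by Benjamini-Hochberg q-values and the selection flag.
#'
#' Lipids with zero variance at either visit are excluded with a log entry;
#' collinear covariates abort with the offending columns named; fits with no
#' residual degrees of freedom are an error.
#'
#' @param trial `trial_dataset` with log-scale matrices.
#' @param fdr_level FDR level for the selection flag (default 0.05).
#' @return an `effect_table` data.frame: `variable`, `beta`, `se`, `p`, `q`,
#'   `selected`; attribute `excluded` lists skipped lipids.
#' @export
estimate_diet_effects <- function(trial, fdr_level = 0.05) {
  stopifnot(inherits(trial, "trial_dataset"))
  require_scale(trial$baseline, "log", "diet-effect estimation")
  require_scale(trial$post, "log", "diet-effect estimation")
  s <- trial$subjects
  arm <- as.integer(s$arm == "intervention")
  covs <- cbind(age = s$age, bmi = s$bmi, sex = s$sex)
  vars <- variable_names(trial$post)
  n <- nrow(trial$post$values)
  if (n - 6 < 1) stop("insufficient residual degrees of freedom for the adjusted model")
  qr_c <- qr(cbind(1, arm, covs))
  if (qr_c$rank < ncol(qr_c$qr)) {
    bad <- colnames(qr_c$qr)[qr_c$pivot[(qr_c$rank + 1):ncol(qr_c$qr)]]
    stop(sprintf("collinear covariates: %s", paste(bad, collapse = ", ")))
  }
  beta <- se <- p <- rep(NA_real_, length(vars))
  excluded <- character(0)
  for (j in seq_along(vars)) {
    y <- trial$post$values[, j]
    b <- trial$baseline$values[, vars[j]]
    if (stats::sd(y) == 0 || stats::sd(b) == 0) {
      excluded <- c(excluded, vars[j])
      next
    }
    X <- cbind(1, arm, b, covs)
    fit <- stats::lm.fit(X, y)
    df <- n - fit$rank
    if (df < 1) stop("insufficient residual degrees of freedom for the adjusted model")
    sigma2 <- sum(fit$residuals^2) / df
    XtXi <- chol2inv(fit$qr$qr[seq_len(fit$rank), seq_len(fit$rank), drop = FALSE])
    # arm is column 2 and is never pivoted out (full-rank check above)
    k <- which(fit$qr$pivot == 2L)
    beta[j] <- fit$coefficients[2]
    se[j] <- sqrt(sigma2 * XtXi[k, k])
    p[j] <- 2 * stats::pt(abs(beta[j] / se[j]), df, lower.tail = FALSE)
  }
  keep <- !(vars %in% excluded)
  fdr <- bh_fdr(p[keep], level = fdr_level)
  out <- data.frame(variable = vars[keep], beta = beta[keep], se = se[keep],
                    p = p[keep], q = fdr$q, selected = fdr$reject,
                    stringsAsFactors = FALSE)
  class(out) <- c("effect_table", "data.frame")
  attr(out, "excluded") <- excluded
  attr(out, "fdr_level") <- fdr_level
  out
}

#' Select score components from an effect table
#'
#' The lipids flagged as significant after FDR control become the score
#' components, with the estimated intervention effects as weights and the
#' scaling constant unset (`s = 1`).
#'
#' @param effects `effect_table`.
#' @param level FDR level (reapplied to the stored q-values).
#' @return a `score_definition` (empty, with a warning, if nothing passes).
#' @export
select_components <- function(effects, level = 0.05) {
  stopifnot(inherits(effects, "effect_table"))
  sel <- effects$q < level
  if (!any(sel)) {
    warning("no lipid passed the FDR threshold; returning an empty score definition")
    return(score_definition(character(0), numeric(0), variant = "MLS"))
  }
  score_definition(effects$variable[sel], effects$beta[sel], variant = "MLS",
                   provenance = list(fdr_level = level,
                                     n_tested = nrow(effects)))
}

# same adjusted model as estimate_diet_effects, applied to a single outcome
# column (a score or a biomarker); returns the arm effect and its SE
arm_effect_on <- function(post_value, baseline_value, subjects) {
  arm <- as.integer(subjects$arm == "intervention")
  X <- cbind(1, arm, baseline_value, age = subjects$age, bmi = subjects$bmi,
             sex = subjects$sex)
  fit <- stats::lm.fit(X, post_value)
  df <- length(post_value) - fit$rank
  if (df < 1) stop("insufficient residual degrees of freedom")
  sigma2 <- sum(fit$residuals^2) / df
  XtXi <- chol2inv(fit$qr$qr[seq_len(fit$rank), seq_len(fit$rank), drop = FALSE])
  k <- which(fit$qr$pivot == 2L)
  list(effect = unname(fit$coefficients[2]),
       se = sqrt(sigma2 * XtXi[k, k]), df = df)
}
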