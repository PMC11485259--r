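# Weighted lipid scores: construction, standardization, cross-platform
# reduction and sub-scores.

#' Create a score definition
#'
#' A `score_definition` holds the ordered lipid variables, one weight per
#' variable, an optional intercept (used by reduced scores), a positive
#' scaling constant `s` and a variant tag. Per-sample scores are
#' `(sum_j w_j x_ij + intercept) / s` on log-scale data.
#'
#' @param variables character vector of canonical lipid names (unique).
#' @param weights numeric weights, finite, same length.
#' @param s scaling constant (> 0); 1 means unscaled.
#' @param intercept additive constant (score units before scaling).
#' @param variant one of `"MLS"`, `"rMLS"`, `"sphingolipid_subscore"`,
#'   `"clinical_score"`, `"cluster_score"`.
#' @param provenance free-form list (trial id, model spec, FDR level, ...).
#' @return a `score_definition`.
#' @export
score_definition <- function(variables, weights, s = 1, intercept = 0,
                             variant = c("MLS", "rMLS", "sphingolipid_subscore",
                                         "clinical_score", "cluster_score"),
                             provenance = list()) {
  variant <- match.arg(variant)
  stopifnot(length(variables) == length(weights))
  if (anyDuplicated(variables)) stop("score variables must be unique")
  if (length(weights) && any(!is.finite(weights))) stop("weights must be finite")
  assert_scalar_number(s)
  if (s <= 0) stop("scaling constant `s` must be positive")
  structure(list(variables = as.character(variables),
                 weights = as.numeric(weights), s = s,
                 intercept = intercept, variant = variant,
                 provenance = provenance),
            class = "score_definition")
}

#' @export
print.score_definition <- function(x, ...) {
  cat(sprintf("<score_definition:%s> %d variables, s = %.6g\n",
              x$variant, length(x$variables), x$s))
  invisible(x)
}

#' Compute per-sample scores
#'
#' @param m log-scale `lipid_matrix` containing every score variable.
#' @param def `score_definition`.
#' @return named numeric vector of per-sample scores.
#' @export
compute_score <- function(m, def) {
  stopifnot(inherits(def, "score_definition"))
  require_scale(m, "log", "score computation")
  missing_vars <- setdiff(def$variables, variable_names(m))
  if (length(missing_vars)) {
    stop(sprintf("score variables missing from the matrix: %s",
                 paste(missing_vars, collapse = ", ")))
  }
  if (length(def$variables) == 0L) {
    return(stats::setNames(rep(0, nrow(m$values)), rownames(m$values)))
  }
  x <- m$values[, def$variables, drop = FALSE]
  drop((x %*% def$weights + def$intercept) / def$s)
}

#' Standardize a score to the trial intervention contrast
#'
#' Estimates the trial-arm effect on the unscaled score with the same
#' baseline-adjusted linear model used per lipid (post score ~ arm +
#' baseline score + age + BMI + sex) and sets the scaling constant to that
#' effect, so that one score unit equals the diet intervention contrast.
#' After scaling, the re-estimated arm effect on the score is 1 by
#' construction.
#'
#' @param def `score_definition`.
#' @param trial `trial_dataset`.
#' @param tolerance minimal |arm effect| regarded as a usable contrast.
#' @return `score_definition` with `s` set (provenance records the contrast).
#' @export
standardize_to_contrast <- function(def, trial, tolerance = 1e-10) {
  stopifnot(inherits(def, "score_definition"), inherits(trial, "trial_dataset"))
  def0 <- def
  def0$s <- 1
  u_post <- compute_score(trial$post, def0)
  u_base <- compute_score(trial$baseline, def0)
  eff <- arm_effect_on(u_post, u_base, trial$subjects)
  if (abs(eff$effect) < tolerance) {
    stop("arm effect on the unscaled score is ~0; the intervention contrast is undefined")
  }
  if (eff$effect < 0) {
    warning("arm effect on the unscaled score is negative; scaling flips the score sign")
  }
  out <- def
  out$s <- abs(eff$effect)
  out$provenance$contrast <- list(arm_effect = eff$effect, se = eff$se)
  out
}

#' Standardize a score to a reference-population standard deviation
#'
#' Per-s.d. reporting convention: the scaling constant becomes the standard
#' deviation of the unscaled score in the reference sample (e.g. the
#' subcohort).
#'
#' @param def `score_definition`.
#' @param reference log-scale `lipid_matrix` of the reference population.
#' @return `score_definition` with `s` = reference s.d.
#' @export
variance_standardize <- function(def, reference) {
  def0 <- def
  def0$s <- 1
  s <- stats::sd(compute_score(reference, def0))
  if (!is.finite(s) || s == 0) stop("reference score has zero variance")
  out <- def
  out$s <- s
  out$provenance$sd_reference <- s
  out
}

#' Restrict a score to a variable subset
#'
#' @param def `score_definition`.
#' @param variable_subset non-empty subset of `def$variables`.
#' @param variant tag for the restricted score.
#' @return `score_definition` over the subset (same weights, same `s`).
#' @export
subscore <- function(def, variable_subset, variant = "sphingolipid_subscore") {
  stopifnot(inherits(def, "score_definition"))
  if (length(variable_subset) == 0L) stop("variable subset must be non-empty")
  bad <- setdiff(variable_subset, def$variables)
  if (length(bad)) {
    stop(sprintf("subset variables not in the score: %s", paste(bad, collapse = ", ")))
  }
  idx <- match(variable_subset, def$variables)
  score_definition(def$variables[idx], def$weights[idx], s = def$s,
                   intercept = 0, variant = variant,
                   provenance = c(def$provenance, list(parent = def$variant)))
}

# candidate predictors for an unavailable class-FA sum: isobaric species of
# the same class whose totals could contain the target fatty acid
reduction_candidates <- function(target, available_vars) {
  tgt <- parse_lipid_name(target)
  if (tgt$resolution != "class_fatty_acid_sum") return(character(0))
  cd <- parse_cd(tgt$fatty_acid)
  keep <- vapply(available_vars, function(nm) {
    v <- tryCatch(parse_lipid_name(nm), error = function(e) NULL)
    !is.null(v) && v$resolution == "isobaric_species" &&
      v$lipid_class == tgt$lipid_class &&
      v$total_carbons >= cd[["carbons"]] &&
      v$total_double_bonds >= cd[["double_bonds"]]
  }, logical(1))
  available_vars[keep]
}

#' Reduce a score to a lower-resolution lipidomics platform
#'
#' For each score variable: kept if directly available on the target
#' platform; otherwise imputed by regressing the variable on candidate
#' isobaric species of the same class in the reference dataset (which carries
#' both resolutions, log scale) and folding the regression weights into the
#' reduced score; otherwise skipped. The reduced score keeps the original
#' scaling constant.
#'
#' @param def `score_definition` (class-FA-sum resolution variables).
#' @param available character vector of variable names measured on the
#'   target platform.
#' @param reference log-scale `lipid_matrix` containing both the score
#'   variables and the available species variables.
#' @param ridge optional nonnegative ridge penalty for p > n reference panels.
#' @return list with `definition` (a `score_definition` over available
#'   variables, variant `"rMLS"`) and `map` (per-variable status + predictor
#'   weights; the `ReducedScoreMap`).
#' @export
reduce_score <- function(def, available, reference, ridge = 0) {
  stopifnot(inherits(def, "score_definition"))
  require_scale(reference, "log", "score reduction")
  ref_vars <- variable_names(reference)
  miss <- setdiff(def$variables, ref_vars)
  if (length(miss)) {
    stop(sprintf("reference matrix lacks score variables: %s",
                 paste(miss, collapse = ", ")))
  }
  w_out <- stats::setNames(numeric(0), character(0))
  intercept <- 0
  map <- list()
  for (i in seq_along(def$variables)) {
    v <- def$variables[i]
    w <- def$weights[i]
    if (v %in% available) {
      map[[v]] <- list(status = "kept")
      w_out[v] <- (if (v %in% names(w_out)) w_out[v] else 0) + w
      next
    }
    cand <- reduction_candidates(v, intersect(available, ref_vars))
    if (length(cand) == 0L) {
      map[[v]] <- list(status = "skipped")
      next
    }
    X <- cbind(1, reference$values[, cand, drop = FALSE])
    y <- reference$values[, v]
    if (ridge > 0) {
      XtX <- crossprod(X) + diag(c(0, rep(ridge, length(cand))))
      beta <- solve(XtX, crossprod(X, y))
    } else {
      fit <- stats::lm.fit(X, y)
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0
    }
    map[[v]] <- list(status = "imputed", predictors = cand,
                     intercept = unname(beta[1]),
                     coefficients = stats::setNames(as.numeric(beta[-1]), cand))
    intercept <- intercept + w * beta[1]
    for (k in seq_along(cand)) {
      nm <- cand[k]
      w_out[nm] <- (if (nm %in% names(w_out)) w_out[nm] else 0) + w * beta[1 + k]
    }
  }
  statuses <- vapply(map, `[[`, "", "status")
  if (!any(statuses %in% c("kept", "imputed"))) {
    stop("no score variable could be kept or imputed on the target platform")
  }
  rdef <- score_definition(names(w_out), as.numeric(w_out), s = def$s,
                           intercept = unname(intercept), variant = "rMLS",
                           provenance = c(def$provenance,
                                          list(reduced_from = def$variant)))
  structure(list(definition = rdef, map = map), class = "reduced_score_map")
}

#' Serialize / deserialize a score definition as JSON
#'
#' Round trips are lossless for variables, weights, scaling constant,
#' intercept, variant and provenance.
#'
#' @param def `score_definition`.
#' @param path JSON file path.
#' @return `read_score_definition` returns the `score_definition`.
#' @export
write_score_definition <- function(def, path) {
  stopifnot(inherits(def, "score_definition"))
  jsonlite::write_json(unclass(def), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_score_definition
#' @export
read_score_definition <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  score_definition(x$variables %||% character(0),
                   x$weights %||% numeric(0),
                   s = x$s, intercept = x$intercept %||% 0,
                   variant = x$variant,
                   provenance = as.list(x$provenance %||% list()))
}
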