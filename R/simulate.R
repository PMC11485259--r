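# Synthetic-data generator: trial, cohort, matched, repeated-measures and
# second-platform datasets with known ground truth. Defaults state the
# simulated world once (see the methods vignette); they are not tuning knobs.

# deterministic, parseable names for p synthetic class-FA-sum lipid variables
synthetic_lipid_names <- function(p) {
  cl <- lipid_classes()$code
  fas <- c(sprintf("%d:%d", rep(seq(12, 26, 2), each = 4), rep(0:3, times = 8)))
  grid <- expand.grid(fa = fas, class = cl, stringsAsFactors = FALSE)
  if (p > nrow(grid)) stop("p exceeds the synthetic lipid name space")
  sprintf("%s(FA %s)", grid$class[seq_len(p)], grid$fa[seq_len(p)])
}

#' Generate ground truth for the synthetic world
#'
#' Builds a sparse conditional-dependence structure over `p` lipid variables
#' (random spanning tree plus extra random edges, guaranteeing connectivity),
#' converts it to a positive-definite precision matrix via diagonal loading,
#' rescales so marginal variances are 1, and draws an intervention effect
#' vector `delta` that is nonzero (negative) on exactly `n_affected`
#' variables.
#'
#' @param p number of lipid variables.
#' @param n_affected number of intervention-affected variables
#'   (`0 <= n_affected <= p`).
#' @param graph_density target edge density in (0, 1); `0` yields a diagonal
#'   precision (mutually independent lipids).
#' @param effect_scale typical |effect| in log-concentration units; per-lipid
#'   magnitudes are jittered by U(0.75, 1.25) and all effects are negative
#'   (the intervention reduces the affected concentrations).
#' @param seed integer seed (required).
#' @param gamma log-hazard per standard deviation of the true score
#'   (default `log(0.68)`).
#' @param lambda0 baseline hazard, events per person-year.
#' @param rho_time autocorrelation of repeated lipidome measures.
#' @param censor_quantile per-lipid left-censoring quantile used by
#'   [censor_lipid_matrix()].
#' @return an `mls_ground_truth` object.
#' @export
generate_ground_truth <- function(p, n_affected, graph_density = 0.05,
                                  effect_scale = 0.5, seed,
                                  gamma = log(0.68), lambda0 = 0.006,
                                  rho_time = 0.6, censor_quantile = 0.05) {
  assert_seed(seed)
  stopifnot(p >= 1, n_affected >= 0, n_affected <= p)
  if (graph_density < 0 || graph_density >= 1) {
    stop("graph_density must lie in [0, 1)")
  }
  set.seed(seed)

  adj <- matrix(FALSE, p, p)
  if (graph_density > 0 && p > 1) {
    for (i in 2:p) {                       # random spanning tree: connectivity
      j <- sample.int(i - 1L, 1L)
      adj[i, j] <- adj[j, i] <- TRUE
    }
    target <- round(graph_density * p * (p - 1) / 2)
    extra <- target - (p - 1L)
    if (extra > 0) {
      free <- which(upper.tri(adj) & !adj)
      pick <- sample(free, min(extra, length(free)))
      adj[pick] <- TRUE
      adj <- adj | t(adj)
    }
  }

  omega <- diag(p)
  if (any(adj)) {
    w <- matrix(0, p, p)
    ut <- which(upper.tri(adj) & adj)
    w[ut] <- stats::runif(length(ut), 0.2, 0.4) *
      sample(c(-1, 1), length(ut), replace = TRUE)
    w <- w + t(w)
    omega <- omega + w
    ev_min <- min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values)
    if (ev_min < 0.05) omega <- omega + (0.05 - ev_min) * diag(p)
    ev_min <- min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values)
    if (ev_min <= 0) stop("precision construction failed to reach positive definiteness")
  }
  sigma <- solve(omega)
  d <- sqrt(diag(sigma))
  sigma <- sigma / tcrossprod(d)           # unit marginal variances
  omega <- diag(d) %*% omega %*% diag(d)   # zero pattern preserved

  affected <- if (n_affected > 0) sort(sample.int(p, n_affected)) else integer(0)
  delta <- numeric(p)
  if (n_affected > 0) {
    delta[affected] <- -abs(effect_scale) * stats::runif(n_affected, 0.75, 1.25)
  }

  vars <- synthetic_lipid_names(p)
  structure(list(
    p = p, variables = vars,
    graph = adj, precision = omega, sigma = sigma, sigma_chol = chol(sigma),
    mu = stats::rnorm(p, 2, 0.5),          # baseline mean log concentrations
    affected_set = affected, delta = delta,
    gamma = gamma, lambda0 = lambda0, rho_time = rho_time,
    censor_quantile = censor_quantile, seed = seed
  ), class = "mls_ground_truth")
}

#' @export
print.mls_ground_truth <- function(x, ...) {
  cat(sprintf("<mls_ground_truth> p=%d, %d affected, %d edges\n",
              x$p, length(x$affected_set), sum(x$graph) / 2))
  invisible(x)
}

draw_covariates <- function(n, id_prefix = "P") {
  data.frame(
    id = sprintf("%s%05d", id_prefix, seq_len(n)),
    age = stats::runif(n, 35, 65),
    sex = stats::rbinom(n, 1, 0.5),
    bmi = stats::rnorm(n, 26, 4),
    stringsAsFactors = FALSE
  )
}

#' Simulate a two-arm dietary intervention trial
#'
#' Baseline log concentrations are multivariate normal with covariance equal
#' to the inverse ground-truth precision (shifted by per-lipid means); the
#' post-intervention visit is an autocorrelated redraw
#' (`rho_time` within-subject correlation) plus `delta` for the intervention
#' arm only. Arm sizes default to the 65 control / 130 pooled-intervention
#' layout.
#'
#' @param gt `mls_ground_truth`.
#' @param n_per_arm integer vector `c(control, intervention)`, each >= 2.
#' @param seed integer seed (required).
#' @return a `trial_dataset`: `subjects` data.frame (id, arm, age, bmi, sex)
#'   and log-scale `baseline` / `post` lipid matrices.
#' @export
simulate_trial <- function(gt, n_per_arm = c(65, 130), seed) {
  assert_seed(seed)
  stopifnot(inherits(gt, "mls_ground_truth"), length(n_per_arm) == 2,
            all(n_per_arm >= 2))
  set.seed(seed)
  n <- sum(n_per_arm)
  subjects <- draw_covariates(n, "T")
  subjects$arm <- factor(rep(c("control", "intervention"), n_per_arm),
                         levels = c("control", "intervention"))
  rho <- gt$rho_time
  base_dev <- rmvn(n, chol_sigma = gt$sigma_chol)
  post_dev <- rho * base_dev + sqrt(1 - rho^2) * rmvn(n, chol_sigma = gt$sigma_chol)
  baseline <- sweep(base_dev, 2, gt$mu, "+")
  post <- sweep(post_dev, 2, gt$mu, "+")
  arm_i <- subjects$arm == "intervention"
  post[arm_i, ] <- sweep(post[arm_i, , drop = FALSE], 2, gt$delta, "+")
  dimnames(baseline) <- dimnames(post) <- list(subjects$id, gt$variables)
  structure(list(subjects = subjects,
                 baseline = lipid_matrix(baseline, scale = "log"),
                 post = lipid_matrix(post, scale = "log"),
                 covariate_log = "age ~ U(35,65); sex ~ Bern(0.5); bmi ~ N(26,16)"),
            class = "trial_dataset")
}

#' Simulate a prospective cohort with score-driven hazards
#'
#' Event times are exponential with hazard
#' `lambda0 * exp(gamma * true_score)`, where the true score is the
#' (population-standardized) score computed from the simulated baseline
#' lipidome under `score_def`; censoring is administrative at
#' `followup_years`. Age is the entry time scale. When `repeated = TRUE` a
#' second lipidome `years_apart` later is generated with autocorrelation
#' `gt$rho_time` plus an optional per-subject score drift.
#'
#' @param gt `mls_ground_truth`.
#' @param n cohort size.
#' @param followup_years administrative follow-up span (> 0).
#' @param score_def `score_definition` used as the hazard-driving true score;
#'   default: weights `gt$delta` on the affected lipids.
#' @param seed integer seed (required).
#' @param repeated also simulate a second lipidome measurement.
#' @param years_apart gap between repeated measures.
#' @param drift_sd s.d. of per-subject drift added along the score direction
#'   at the second timepoint.
#' @return a `cohort_dataset` with fields `subjects` (id, entry_age,
#'   exit_age, event, covariates, true_score), `lipids` (log-scale baseline
#'   matrix) and optionally `lipids_t2`.
#' @export
simulate_cohort <- function(gt, n, followup_years = 10, score_def = NULL,
                            seed, repeated = FALSE, years_apart = 10,
                            drift_sd = 0.3) {
  assert_seed(seed)
  stopifnot(inherits(gt, "mls_ground_truth"))
  if (followup_years <= 0) stop("followup_years must be positive")
  if (!is.finite(gt$gamma)) stop("hazard coefficient gamma must be finite")
  if (gt$lambda0 <= 0) stop("baseline hazard lambda0 must be positive")
  set.seed(seed)
  subjects <- draw_covariates(n, "C")
  dev <- rmvn(n, chol_sigma = gt$sigma_chol)
  lip <- sweep(dev, 2, gt$mu, "+")
  dimnames(lip) <- list(subjects$id, gt$variables)
  m <- lipid_matrix(lip, scale = "log")
  if (is.null(score_def)) {
    keep <- if (length(gt$affected_set)) gt$affected_set else seq_len(gt$p)
    score_def <- score_definition(gt$variables[keep], gt$delta[keep],
                                  variant = "MLS")
  }
  raw_score <- compute_score(m, score_def)
  sd_raw <- stats::sd(raw_score)
  true_score <- if (is.finite(sd_raw) && sd_raw > 0) {
    as.numeric(raw_score - mean(raw_score)) / sd_raw
  } else {
    rep(0, n)   # degenerate (e.g. null-effect) score: no hazard gradient
  }
  rate <- gt$lambda0 * exp(gt$gamma * true_score)
  t_event <- stats::rexp(n, rate)
  subjects$entry_age <- subjects$age
  subjects$event <- as.integer(t_event <= followup_years)
  subjects$exit_age <- subjects$entry_age + pmin(t_event, followup_years)
  subjects$true_score <- true_score
  out <- list(subjects = subjects, lipids = m, score_def = score_def,
              followup_years = followup_years)
  if (repeated) {
    rho <- gt$rho_time
    dev2 <- rho * dev + sqrt(1 - rho^2) * rmvn(n, chol_sigma = gt$sigma_chol)
    w <- numeric(gt$p)
    idx <- match(score_def$variables, gt$variables)
    w[idx] <- score_def$weights
    wn <- w / sqrt(sum(w^2))
    drift <- stats::rnorm(n, 0, drift_sd)
    dev2 <- dev2 + outer(drift, wn)
    lip2 <- sweep(dev2, 2, gt$mu, "+")
    dimnames(lip2) <- list(subjects$id, gt$variables)
    out$lipids_t2 <- lipid_matrix(lip2, scale = "log")
    out$years_apart <- years_apart
  }
  structure(out, class = "cohort_dataset")
}

#' Emulate left-censoring at the lower limit of quantification
#'
#' Deletes, per lipid, values below the `censor_quantile` empirical quantile
#' (they become `NA`, to be refilled by [impute_left_censored()]).
#'
#' @param m `lipid_matrix` (raw or log scale).
#' @param censor_quantile per-variable quantile below which values go missing.
#' @return `lipid_matrix` with `NA`s.
#' @export
censor_lipid_matrix <- function(m, censor_quantile = 0.05) {
  stopifnot(inherits(m, "lipid_matrix"))
  vals <- m$values
  for (j in seq_len(ncol(vals))) {
    thr <- stats::quantile(vals[, j], censor_quantile, na.rm = TRUE, names = FALSE)
    vals[vals[, j] < thr, j] <- NA
  }
  out <- m
  out$values <- vals
  out$meta$censor_quantile <- censor_quantile
  out
}

#' Draw a case-cohort sample
#'
#' A random subcohort of `round(fraction * n)` subjects is drawn uniformly
#' without replacement; all cases outside the subcohort are appended with
#' `subcohort = FALSE`. Every case of the endpoint appears exactly once.
#'
#' @param cohort `cohort_dataset` (or its `subjects` data.frame).
#' @param subcohort_fraction sampling fraction in (0, 1].
#' @param endpoint name of the 0/1 event column (default `"event"`).
#' @param seed integer seed (required).
#' @return data.frame: the cohort rows retained, plus a logical `subcohort`
#'   column; attribute `n_subcohort_cases` counts the case overlap.
#' @export
draw_case_cohort <- function(cohort, subcohort_fraction, endpoint = "event",
                             seed) {
  assert_seed(seed)
  d <- if (inherits(cohort, "cohort_dataset")) cohort$subjects else cohort
  stopifnot(is.data.frame(d), endpoint %in% names(d))
  if (subcohort_fraction <= 0 || subcohort_fraction > 1) {
    stop("subcohort_fraction must lie in (0, 1]")
  }
  set.seed(seed)
  n <- nrow(d)
  m <- round(subcohort_fraction * n)
  idx <- sort(sample.int(n, m))
  sub <- logical(n)
  sub[idx] <- TRUE
  is_case <- d[[endpoint]] == 1
  if (!any(is_case)) warning("no cases of the requested endpoint in the cohort")
  keep <- sub | is_case
  out <- d[keep, , drop = FALSE]
  out$subcohort <- sub[keep]
  rownames(out) <- NULL
  attr(out, "n_subcohort_cases") <- sum(sub & is_case)
  attr(out, "subcohort_fraction") <- subcohort_fraction
  out
}

#' Draw 1:1 matched case-control pairs
#'
#' Exact matching on categorical factors; continuous factors match within the
#' supplied calipers. Each case receives one unique control (sampling without
#' replacement); unmatched cases are dropped and counted. Given a fixed seed
#' the pairing is invariant to input row order (subjects are processed in id
#' order internally).
#'
#' @param cohort `cohort_dataset` or subjects data.frame.
#' @param endpoint 0/1 event column name.
#' @param matching_vars character vector of matching columns.
#' @param caliper named numeric vector of maximal absolute differences for
#'   continuous matching variables; unlisted variables are matched exactly.
#' @param seed integer seed (required).
#' @return data.frame with columns `pair_id`, `role` (case/control) bound to
#'   the matched subject rows; attribute `n_unmatched` counts dropped cases.
#' @export
draw_matched_pairs <- function(cohort, endpoint = "event", matching_vars,
                               caliper = c(age = 5), seed) {
  assert_seed(seed)
  d <- if (inherits(cohort, "cohort_dataset")) cohort$subjects else cohort
  stopifnot(all(matching_vars %in% names(d)), endpoint %in% names(d))
  d <- d[order(d$id), , drop = FALSE]
  set.seed(seed)
  cases <- d[d[[endpoint]] == 1, , drop = FALSE]
  controls <- d[d[[endpoint]] == 0, , drop = FALSE]
  used <- logical(nrow(controls))
  pairs <- list()
  unmatched <- 0L
  for (k in seq_len(nrow(cases))) {
    ok <- !used
    for (v in matching_vars) {
      if (v %in% names(caliper)) {
        ok <- ok & abs(controls[[v]] - cases[[v]][k]) <= caliper[[v]]
      } else {
        ok <- ok & controls[[v]] == cases[[v]][k]
      }
    }
    cand <- which(ok)
    if (length(cand) == 0L) {
      unmatched <- unmatched + 1L
      next
    }
    pick <- cand[sample.int(length(cand), 1L)]
    used[pick] <- TRUE
    pid <- length(pairs) + 1L
    pairs[[pid]] <- rbind(
      cbind(pair_id = pid, role = "case", cases[k, , drop = FALSE]),
      cbind(pair_id = pid, role = "control", controls[pick, , drop = FALSE])
    )
  }
  out <- if (length(pairs)) do.call(rbind, pairs) else
    cbind(pair_id = integer(0), role = character(0), d[0, , drop = FALSE])
  rownames(out) <- NULL
  if (unmatched > 0) {
    message(sprintf("draw_matched_pairs: %d case(s) had no eligible control and were dropped",
                    unmatched))
  }
  attr(out, "n_unmatched") <- unmatched
  out
}

#' Simulate macronutrient intakes coupled to the true score
#'
#' Draws percent-energy intakes (SFA, MUFA, PUFA, protein, alcohol; carbohydrate
#' closes the budget to 100) with realistic ranges, plus total energy and
#' food-group intakes for diet-quality indices. `coupling` is the effect of
#' replacing 8% of energy from SFA with UFA on the true score, in score
#' units per 8%E: the true score is shifted by `coupling * UFA/8` (SFA
#' neutral), so the leave-one-out substitution coefficient for UFA equals
#' `coupling` exactly in the noiseless limit. Rows whose named components sum
#' above 100%E are rejected and logged.
#'
#' @param cohort `cohort_dataset`.
#' @param coupling substitution effect per 8%E (score s.d. units).
#' @param seed integer seed (required).
#' @return the cohort with `$macros` (and food groups) attached and
#'   `$subjects$true_score` shifted by the diet coupling.
#' @export
simulate_macronutrients <- function(cohort, coupling = 0, seed) {
  assert_seed(seed)
  stopifnot(inherits(cohort, "cohort_dataset"))
  set.seed(seed)
  n <- nrow(cohort$subjects)
  draw <- function(n) {
    data.frame(
      sfa = stats::rnorm(n, 13, 3),
      mufa = stats::rnorm(n, 12, 2.5),
      pufa = stats::rnorm(n, 6, 1.5),
      protein = stats::rnorm(n, 16, 3),
      animal_protein = NA_real_, vegetable_protein = NA_real_,
      alcohol_g = pmax(stats::rnorm(n, 8, 8), 0)
    )
  }
  mac <- draw(n)
  mac$sfa <- pmax(mac$sfa, 2); mac$mufa <- pmax(mac$mufa, 2)
  mac$pufa <- pmax(mac$pufa, 1); mac$protein <- pmax(mac$protein, 8)
  mac$alcohol_pct <- mac$alcohol_g * 7 / 20   # ~7 kcal/g at ~2000 kcal/day
  named_sum <- mac$sfa + mac$mufa + mac$pufa + mac$protein + mac$alcohol_pct
  bad <- named_sum > 100
  n_bad <- sum(bad)
  if (n_bad > 0) {
    # redraw rejected rows from the bulk of the distribution
    repl <- draw(n_bad)
    repl$alcohol_g <- pmin(repl$alcohol_g, 10)
    for (cn in c("sfa", "mufa", "pufa", "protein", "alcohol_g")) {
      mac[[cn]][bad] <- pmin(pmax(repl[[cn]], 1), 25)
    }
    mac$alcohol_pct <- mac$alcohol_g * 7 / 20
  }
  mac$ufa <- mac$mufa + mac$pufa
  mac$carbohydrate <- 100 - (mac$sfa + mac$ufa + mac$protein + mac$alcohol_pct)
  prot_split <- stats::runif(n, 0.4, 0.8)
  mac$animal_protein <- mac$protein * prot_split
  mac$vegetable_protein <- mac$protein * (1 - prot_split)
  fat_split <- stats::runif(n, 0.3, 0.8)
  mac$fat <- mac$sfa + mac$ufa
  mac$animal_fat <- mac$fat * fat_split
  mac$vegetable_fat <- mac$fat * (1 - fat_split)
  mac$energy_kcal <- stats::rnorm(n, 2000, 350)
  rln <- function(ml, sl) stats::rlnorm(n, ml, sl)
  foods <- data.frame(
    vegetables = rln(0.9, 0.5), fruits = rln(0.7, 0.6), nuts = rln(-1.2, 0.9),
    whole_grains = rln(3.2, 0.6), legumes = rln(-1.5, 0.8),
    fish = rln(-1.0, 0.8), red_processed_meat = rln(-0.3, 0.7),
    ssb = rln(-1.0, 1.0), long_chain_n3 = rln(4.7, 0.6),
    trans_pct = pmax(stats::rnorm(n, 1.5, 0.7), 0.1),
    sodium_mg = rln(7.8, 0.3)
  )
  cohort$macros <- cbind(mac, foods)
  cohort$subjects$true_score <- cohort$subjects$true_score +
    coupling * mac$ufa / 8
  cohort$macro_rejected <- n_bad
  cohort
}
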