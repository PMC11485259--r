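test_that("Prentice fit with a full-cohort subcohort equals standard Cox", {
  cc <- make_cc_table(n = 1200, loghr = log(0.7), seed = 101)
  h <- fit_prentice_cox(cc, "score", c("age", "sex"))
  oracle <- survival::coxph(
    survival::Surv(entry_age, exit_age, event) ~ score + age + sex,
    data = cc, ties = "efron")
  expect_lt(abs(h$loghr - coef(oracle)[["score"]]), 1e-6)
  # breslow ties route too
  hb <- fit_prentice_cox(cc, "score", c("age", "sex"), ties_method = "breslow")
  ob <- survival::coxph(
    survival::Surv(entry_age, exit_age, event) ~ score + age + sex,
    data = cc, ties = "breslow")
  expect_lt(abs(hb$loghr - coef(ob)[["score"]]), 1e-6)
})

test_that("Prentice-weighted fits recover the simulated hazard ratio", {
  cc <- make_cc_table(n = 8000, loghr = log(0.68), seed = 102,
                      subcohort_fraction = 0.15)
  h <- fit_prentice_cox(cc, "score", c("age", "sex"))
  expect_gt(h$ci_upper, 0.68)
  expect_lt(h$ci_lower, 0.68)
})

test_that("design-contract violations raise errors", {
  cc <- make_cc_table(n = 200, loghr = 0, seed = 103)
  cc$event <- 0
  expect_error(fit_prentice_cox(cc, "score"), "no events")
  cc2 <- make_cc_table(n = 200, loghr = 0, seed = 104)
  cc2$score[3] <- NA
  expect_error(fit_prentice_cox(cc2, "score"), "complete-case")
  cc3 <- make_cc_table(n = 200, loghr = 0, seed = 105)
  cc3$subcohort <- FALSE
  expect_error(fit_prentice_cox(cc3, "score"), "non-subcohort")
})

test_that("percent risk reduction transforms HR and CI monotonically", {
  expect_equal(percent_risk_reduction(0.68)$reduction, 32)
  expect_equal(percent_risk_reduction(1)$reduction, 0)
  pr <- percent_risk_reduction(0.5, ci = c(0.4, 0.625))
  expect_equal(pr$reduction, 50)
  expect_equal(pr$ci_lower, 37.5)
  expect_equal(pr$ci_upper, 60)
  expect_error(percent_risk_reduction(-1), "positive")
})

test_that("1:1 conditional logistic equals the discordant-pair closed form", {
  pr <- make_binary_pairs(b = 20, cc = 10, conc = 5)
  r <- fit_conditional_logistic(pr, "exposure", standardize = FALSE)
  expect_equal(r$or, 2, tolerance = 1e-9)
  # a second layout, to make sure it is not an accident of b/cc choice
  r2 <- fit_conditional_logistic(make_binary_pairs(b = 9, cc = 27, conc = 4),
                                 "exposure", standardize = FALSE)
  expect_equal(r2$or, 1 / 3, tolerance = 1e-9)
})

test_that("matched strata and exposure degeneracies are rejected", {
  pr <- make_binary_pairs(b = 5, cc = 5, conc = 0)
  bad <- pr
  bad$role[2] <- "case"                      # two cases in one stratum
  expect_error(fit_conditional_logistic(bad, "exposure"),
               "exactly one case")
  conc_only <- make_binary_pairs(b = 0, cc = 0, conc = 8)
  expect_error(fit_conditional_logistic(conc_only, "exposure",
                                        standardize = FALSE),
               "identical within every pair")
})

test_that("conditional logistic recovers a simulated continuous log-OR", {
  pr <- make_logit_pairs(n_pairs = 900, beta = log(0.72), seed = 111)
  r <- fit_conditional_logistic(pr, "exposure", standardize = FALSE)
  expect_gt(r$ci_upper, 0.72)
  expect_lt(r$ci_lower, 0.72)
  # per-s.d. standardization rescales the coefficient by the control s.d.
  rs <- fit_conditional_logistic(pr, "exposure", standardize = TRUE)
  sd_ctl <- sd(pr$exposure[pr$role == "control"])
  expect_equal(rs$logor, r$logor * sd_ctl, tolerance = 1e-6)
})

test_that("change analysis is translation invariant and guards its inputs", {
  pr <- make_logit_pairs(n_pairs = 400, beta = log(0.76), seed = 112)
  pr$score_t2 <- pr$exposure
  set.seed(113)
  pr$score_t1 <- pr$exposure - rnorm(nrow(pr))   # change carries the signal
  r1 <- change_analysis(pr)
  pr_shift <- pr
  pr_shift$score_t1 <- pr$score_t1 + 5
  pr_shift$score_t2 <- pr$score_t2 + 5
  r2 <- change_analysis(pr_shift)
  expect_equal(r1$logor, r2$logor, tolerance = 1e-8)
  expect_error(change_analysis(pr, timepoints_precede_events = FALSE),
               "precede")
  pr0 <- pr
  pr0$score_t2 <- pr0$score_t1
  expect_error(change_analysis(pr0), "degenerate")
})

test_that("a protective change effect is recovered within its CI", {
  # the exact conditional model: case status driven by the within-pair
  # difference of the change variable
  set.seed(114)
  n_pairs <- 800
  d1 <- rnorm(n_pairs); d2 <- rnorm(n_pairs)     # changes of member 1 and 2
  beta <- log(0.7)
  first_case <- rbinom(n_pairs, 1, plogis(beta * (d1 - d2)))
  pr <- data.frame(
    pair_id = rep(seq_len(n_pairs), each = 2),
    role = as.vector(rbind(ifelse(first_case == 1, "case", "control"),
                           ifelse(first_case == 1, "control", "case"))),
    score_t1 = rnorm(2 * n_pairs))
  pr$score_t2 <- pr$score_t1 + as.vector(rbind(d1, d2))
  r <- change_analysis(pr)
  expect_gt(r$ci_upper, 0.7)
  expect_lt(r$ci_lower, 0.7)
})

test_that("permuted exposure gives a null hazard ratio", {
  cc <- make_cc_table(n = 3000, loghr = log(0.7), seed = 115,
                      subcohort_fraction = 0.3)
  set.seed(116)
  cc$score <- sample(cc$score)
  h <- fit_prentice_cox(cc, "score", c("age", "sex"))
  expect_gt(h$ci_upper, 1)
  expect_lt(h$ci_lower, 1)
})

test_that("mutual adjustment attenuates the noisy proxy, not the driver", {
  set.seed(117)
  n <- 6000
  s <- rnorm(n)                      # the score truly drives the hazard
  proxy <- s + rnorm(n, 0, 1.2)      # a correlated surrogate biomarker
  d <- data.frame(id = seq_len(n), score = s, proxy = proxy,
                  entry_age = runif(n, 40, 60), subcohort = TRUE)
  tev <- rexp(n, 0.02 * exp(log(0.7) * s))
  d$event <- as.integer(tev <= 10)
  d$exit_age <- d$entry_age + pmin(tev, 10)
  h_score <- fit_prentice_cox(d, "score", "proxy")
  h_proxy <- fit_prentice_cox(d, "proxy", "score")
  expect_lt(h_score$p, 0.05)
  expect_gt(abs(h_score$loghr), abs(h_proxy$loghr))
})

test_that("stratified effect modification separates as designed", {
  set.seed(118)
  n <- 4000
  pre <- rnorm(n)
  year1 <- 0.6 * pre + 0.8 * rnorm(n)
  arm <- rbinom(n, 1, 0.5)
  med <- median(pre)
  lhr <- -0.8 * arm * (pre <= med)     # intervention helps only low-score half
  d <- data.frame(id = seq_len(n), arm = arm, score_pre = pre,
                  score_year1 = year1, age = runif(n, 55, 75),
                  sex = rbinom(n, 1, 0.5), bmi = rnorm(n, 28, 4),
                  entry_age = runif(n, 55, 75), subcohort = TRUE)
  tev <- rexp(n, 0.05 * exp(lhr))
  d$event <- as.integer(tev <= 5)
  d$exit_age <- d$entry_age + pmin(tev, 5)
  res <- interaction_and_strata(d)
  expect_s3_class(res$strata$low, "hazard_result")
  expect_s3_class(res$strata$high, "hazard_result")
  expect_lt(res$strata$low$ci_upper, 1)       # clear benefit in low stratum
  expect_gt(res$strata$high$ci_upper, 1)      # null in high stratum
  expect_lt(res$strata$low$hr, res$strata$high$hr)
  # strata split at the median: sizes differ by at most one
  expect_lte(abs(sum(d$score_pre <= res$median_pre) -
                 sum(d$score_pre > res$median_pre)), 1)
})

test_that("correlate_score handles monotone, constant and short columns", {
  x <- c(1, 2, 3, 4, 5)
  tab <- data.frame(up = x^3, down = -x, flat = rep(1, 5),
                    short = c(1, NA, NA, NA, 2))
  r <- correlate_score(x, tab)
  expect_equal(r$rho[r$variable == "up"], 1)
  expect_equal(r$rho[r$variable == "down"], -1)
  expect_true(is.na(r$rho[r$variable == "flat"]))
  expect_true(is.na(r$rho[r$variable == "short"]))
  expect_equal(r$n[r$variable == "short"], 2)
})
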