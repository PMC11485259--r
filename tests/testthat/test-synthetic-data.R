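test_that("ground truth satisfies its structural invariants", {
  gt <- generate_ground_truth(p = 111, n_affected = 45, graph_density = 0.05,
                              effect_scale = 0.3, seed = 1)
  expect_length(gt$affected_set, 45)
  expect_true(all(gt$delta[gt$affected_set] < 0))
  expect_true(all(gt$delta[-gt$affected_set] == 0))
  ev <- eigen(gt$precision, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  # zero pattern of the precision matches the generated graph
  off <- abs(gt$precision) > 1e-10 & !diag(111)
  expect_equal(unname(off), unname(gt$graph))
  # unit marginal variances
  expect_equal(unname(diag(gt$sigma)), rep(1, 111), tolerance = 1e-8)
})

test_that("degenerate ground-truth cases behave as specified", {
  gt0 <- generate_ground_truth(p = 5, n_affected = 0, graph_density = 0.2,
                               seed = 2)
  expect_equal(gt0$delta, rep(0, 5))
  gtd <- generate_ground_truth(p = 10, n_affected = 2, graph_density = 0,
                               seed = 3)
  expect_equal(unname(gtd$precision), diag(10))
  expect_equal(unname(gtd$sigma), diag(10))
  expect_error(generate_ground_truth(p = 5, n_affected = 2,
                                     graph_density = 0.2, seed = NULL),
               "seed")
})

test_that("trial simulation matches the requested design", {
  gt <- tiny_gt()
  tr <- simulate_trial(gt, n_per_arm = c(65, 130), seed = 7)
  expect_equal(nrow(tr$subjects), 195)
  expect_equal(as.vector(table(tr$subjects$arm)), c(65, 130))
  expect_identical(colnames(tr$baseline$values), colnames(tr$post$values))
  expect_true(all(tr$subjects$id == rownames(tr$post$values)))
  # smallest legal input
  expect_s3_class(simulate_trial(gt, n_per_arm = c(2, 2), seed = 1),
                  "trial_dataset")
  expect_error(simulate_trial(gt, n_per_arm = c(65, 130), seed = NULL), "seed")
  # bit-identical under identical seeds
  tr2 <- simulate_trial(gt, n_per_arm = c(65, 130), seed = 7)
  expect_identical(tr$post$values, tr2$post$values)
})

test_that("under a null effect, arm differences stay within Monte-Carlo error", {
  gt <- generate_ground_truth(p = 30, n_affected = 0, graph_density = 0.1,
                              seed = 11)
  tr <- simulate_trial(gt, n_per_arm = c(1000, 1000), seed = 12)
  arm <- tr$subjects$arm == "intervention"
  dif <- colMeans(tr$post$values[arm, ]) - colMeans(tr$post$values[!arm, ])
  se <- sqrt(apply(tr$post$values[arm, ], 2, var) / sum(arm) +
             apply(tr$post$values[!arm, ], 2, var) / sum(!arm))
  expect_gte(mean(abs(dif) < 3 * se), 0.9)
})

test_that("sample covariance converges to the inverse ground-truth precision", {
  gt <- generate_ground_truth(p = 15, n_affected = 5, graph_density = 0.15,
                              seed = 21)
  frob <- sapply(c(500, 5000), function(n) {
    tr <- simulate_trial(gt, n_per_arm = c(n / 2, n / 2), seed = 22)
    norm(cov(tr$baseline$values) - gt$sigma, type = "F")
  })
  expect_lt(frob[2], frob[1])
})

test_that("cohort simulation respects hazard and follow-up contracts", {
  gt <- tiny_gt()
  expect_error(simulate_cohort(gt, n = 100, followup_years = 0, seed = 1),
               "followup_years")
  ch <- simulate_cohort(gt, n = 500, seed = 4)
  s <- ch$subjects
  expect_true(all(s$exit_age > s$entry_age))
  expect_true(all(s$exit_age <= s$entry_age + ch$followup_years + 1e-12))
  # events end follow-up at the event age
  expect_true(all(s$exit_age[s$event == 1] < s$entry_age[s$event == 1] + 10))
})

test_that("a null hazard coefficient yields HR about 1 on the full cohort", {
  gt <- generate_ground_truth(p = 6, n_affected = 2, graph_density = 0.2,
                              seed = 31, gamma = 0, lambda0 = 0.02)
  ch <- simulate_cohort(gt, n = 5000, seed = 32)
  fit <- survival::coxph(survival::Surv(entry_age, exit_age, event) ~ true_score,
                         data = ch$subjects)
  ci <- exp(confint(fit))
  expect_gt(ci[2], 1)
  expect_lt(ci[1], 1)
})

test_that("case-cohort sampling is exact and keeps every case once", {
  gt <- tiny_gt()
  ch <- simulate_cohort(gt, n = 300, seed = 5)
  cc <- draw_case_cohort(ch, 1.0, seed = 6)
  expect_equal(nrow(cc), 300)
  expect_true(all(cc$subcohort))
  # exact subcohort size at the reference sampling fraction
  big <- data.frame(id = 1:26437, event = rbinom(26437, 1, 0.02))
  cc2 <- draw_case_cohort(big, 1262 / 26437, seed = 8)
  expect_equal(sum(cc2$subcohort), 1262)
  expect_equal(sum(cc2$event), sum(big$event))
  expect_equal(anyDuplicated(cc2$id), 0L)
  expect_true(all(cc2$event[!cc2$subcohort] == 1))
  expect_warning(draw_case_cohort(data.frame(id = 1:5, event = rep(0, 5)),
                                  0.5, seed = 1), "no cases")
})

test_that("subcohort inclusion probability equals the sampling fraction", {
  d <- data.frame(id = 1:6, event = c(1, 0, 0, 0, 0, 0))
  hits <- numeric(6)
  reps <- 3000
  for (r in seq_len(reps)) {
    cc <- draw_case_cohort(d, 0.5, seed = r)
    hits[cc$id[cc$subcohort]] <- hits[cc$id[cc$subcohort]] + 1
  }
  # each subject lands in the subcohort with probability 3/6
  expect_true(all(abs(hits / reps - 0.5) < 0.03))
})

test_that("matched-pair drawing is exact, unique and order invariant", {
  d <- data.frame(id = sprintf("x%02d", 1:6),
                  event = c(1, 1, 1, 0, 0, 0),
                  stratum = c("a", "b", "c", "a", "b", "c"))
  pr <- draw_matched_pairs(d, matching_vars = "stratum", caliper = NULL,
                           seed = 3)
  expect_equal(nrow(pr), 6)
  expect_equal(anyDuplicated(pr$id), 0L)
  expect_equal(attr(pr, "n_unmatched"), 0L)
  # unmatched case dropped with a log entry
  d2 <- data.frame(id = c("a", "b"), event = c(1, 0),
                   stratum = c("x", "y"))
  expect_message(pr2 <- draw_matched_pairs(d2, matching_vars = "stratum",
                                           caliper = NULL, seed = 1),
                 "no eligible control")
  expect_equal(nrow(pr2), 0)
  expect_equal(attr(pr2, "n_unmatched"), 1L)
  # permutation of input rows does not change the pairing under a fixed seed
  set.seed(9)
  d3 <- data.frame(id = sprintf("s%03d", 1:60),
                   event = rep(c(1, 0, 0), 20),
                   g = sample(c("m", "f"), 60, TRUE),
                   age = runif(60, 40, 60))
  p1 <- draw_matched_pairs(d3, matching_vars = c("g", "age"),
                           caliper = c(age = 5), seed = 77)
  p2 <- draw_matched_pairs(d3[sample.int(60), ], matching_vars = c("g", "age"),
                           caliper = c(age = 5), seed = 77)
  expect_identical(p1, p2)
})

test_that("macronutrient tables respect the energy budget and log rejections", {
  gt <- tiny_gt()
  ch <- simulate_cohort(gt, n = 2000, seed = 41)
  ch <- simulate_macronutrients(ch, coupling = 0, seed = 42)
  m <- ch$macros
  expect_true(all(m$sfa + m$ufa + m$protein + m$alcohol_pct <= 100))
  expect_true(all(m$carbohydrate >= 0))
  expect_gte(ch$macro_rejected, 0)
  # null coupling: substitution estimate consistent with zero
  f <- fit_substitution(ch$subjects$true_score, m)
  ufa <- f[f$term == "ufa", ]
  expect_lt(abs(ufa$estimate / ufa$se), 3)
})
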