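log_mat <- function(vals) lipid_matrix(vals, scale = "log")

test_that("compute_score is the documented weighted sum", {
  vals <- matrix(c(2, 0, 1, 0), 2, 2,
                 dimnames = list(c("a", "b"), c("CE(FA 16:0)", "CE(FA 18:1)")))
  def <- score_definition(colnames(vals), c(-0.5, -0.3))
  sc <- compute_score(log_mat(vals), def)
  expect_equal(unname(sc), c(-1.3, 0))
  # missing variable and raw-scale input are hard errors
  expect_error(compute_score(log_mat(vals[, 1, drop = FALSE]), def),
               "CE\\(FA 18:1\\)")
  expect_error(compute_score(lipid_matrix(exp(vals), scale = "raw"), def),
               "log")
})

test_that("global concentration doubling shifts all scores uniformly", {
  m <- make_species_world(n = 40, seed = 5)
  fa <- log_transform(within_class_fatty_acid_sums(m))
  def <- score_definition(colnames(fa$values)[1:4], c(-0.4, -0.2, -0.1, -0.3),
                          s = 2)
  s1 <- compute_score(fa, def)
  m2 <- fa
  m2$values <- fa$values + log(2)
  s2 <- compute_score(m2, def)
  shift <- sum(def$weights) * log(2) / def$s
  expect_equal(s2 - s1, rep(shift, 40), ignore_attr = TRUE)
  expect_equal(order(s1), order(s2))
})

test_that("score linearity and weight-scaling invariance hold", {
  m <- make_species_world(n = 30, seed = 6)
  fa <- log_transform(within_class_fatty_acid_sums(m))
  v <- colnames(fa$values)[1:3]
  d1 <- score_definition(v, c(-1, 0.5, 2))
  d2 <- score_definition(v, c(0.3, -0.2, 1))
  dsum <- score_definition(v, d1$weights + d2$weights)
  expect_equal(compute_score(fa, dsum),
               compute_score(fa, d1) + compute_score(fa, d2))
  dscaled <- score_definition(v, 3 * d1$weights, s = 3 * d1$s)
  expect_equal(compute_score(fa, dscaled), compute_score(fa, d1))
})

test_that("standardizing to the trial contrast makes the arm effect exactly 1", {
  gt <- tiny_gt(p = 12, n_affected = 6, seed = 81)
  tr <- simulate_trial(gt, n_per_arm = c(65, 130), seed = 82)
  eff <- estimate_diet_effects(tr)
  def <- select_components(eff)
  sdef <- standardize_to_contrast(def, tr)
  post <- compute_score(tr$post, sdef)
  base <- compute_score(tr$baseline, sdef)
  re <- lipidscore:::arm_effect_on(post, base, tr$subjects)
  expect_equal(re$effect, 1, tolerance = 1e-8)
  expect_gt(sdef$s, 0)
})

test_that("a vanishing contrast is rejected", {
  gt <- tiny_gt(p = 6, n_affected = 0, seed = 83)
  tr <- simulate_trial(gt, n_per_arm = c(20, 20), seed = 84)
  tr$post <- tr$baseline   # no change between visits: arm effect exactly 0
  def <- score_definition(gt$variables[1:3], c(-1, -1, -1))
  expect_error(standardize_to_contrast(def, tr), "contrast is undefined")
})

test_that("variance standardization gives unit-s.d. scores in the reference", {
  gt <- tiny_gt(p = 10, n_affected = 4, seed = 85)
  tr <- simulate_trial(gt, n_per_arm = c(200, 200), seed = 86)
  def <- score_definition(gt$variables[1:5], rep(-0.5, 5))
  vdef <- variance_standardize(def, tr$baseline)
  expect_equal(sd(compute_score(tr$baseline, vdef)), 1, tolerance = 1e-12)
  # single-biomarker analogue: a one-variable score scales the same way
  # (the raw arm effect is negative, so the flip warning is expected)
  one <- score_definition(gt$variables[1], 1)
  expect_warning(sone <- standardize_to_contrast(one, tr), "flips")
  expect_equal(sone$s, abs(lipidscore:::arm_effect_on(
    tr$post$values[, 1], tr$baseline$values[, 1], tr$subjects)$effect))
})

test_that("subscores restrict weights and reject bad subsets", {
  def <- score_definition(c("CE(FA 16:0)", "CE(FA 18:1)", "SM(FA 16:0)"),
                          c(-1, -2, -3), s = 4)
  full <- subscore(def, def$variables)
  expect_equal(full$weights, def$weights)
  single <- subscore(def, "SM(FA 16:0)")
  expect_equal(single$weights, -3)
  expect_equal(single$s, 4)
  expect_error(subscore(def, character(0)), "non-empty")
  expect_error(subscore(def, "PI 38:4"), "not in the score")
})

test_that("a sphingolipid-style subscore tracks the full score under shared structure", {
  set.seed(87)
  n <- 500
  f <- rnorm(n)   # latent diet-quality factor drives all component lipids
  nm <- c(sprintf("Cer(FA %d:0)", c(16, 18, 20, 22, 24)),
          sprintf("SM(FA %d:1)", c(16, 18)),
          sprintf("CE(FA %d:0)", c(14, 16, 18)))
  vals <- sapply(seq_along(nm), function(j) 0.8 * f + 0.6 * rnorm(n))
  colnames(vals) <- nm
  m <- log_mat(vals)
  def <- score_definition(nm, rep(-0.4, 10))
  sph <- subscore(def, nm[1:7])
  rho <- cor(compute_score(m, def), compute_score(m, sph), method = "spearman")
  expect_gt(rho, 0.5)
})

test_that("lossless aggregation reduces to an equivalent score", {
  # one molecular species per (class, FA): each class-FA sum equals exactly
  # one isobaric species, so the reference regressions are exact
  set.seed(88)
  n <- 300
  sp <- c("DAG(16:0/18:1)", "PC(16:0/18:2)", "TAG(16:0/18:1/18:2)")
  mm <- lipid_matrix(matrix(rlnorm(n * 3, 1, 0.4), n, 3,
                            dimnames = list(NULL, sp)), scale = "raw")
  fa <- within_class_fatty_acid_sums(mm)
  iso <- isobaric_species_sums(mm)
  ref <- log_mat(cbind(log(fa$values), log(iso$values)))
  def <- score_definition(colnames(fa$values),
                          -seq(0.2, 0.9, length.out = ncol(fa$values)), s = 2)
  red <- reduce_score(def, available = colnames(iso$values), reference = ref)
  s_full <- compute_score(ref, def)
  s_red <- compute_score(ref, red$definition)
  expect_gt(cor(s_full, s_red, method = "spearman"), 0.99)
  expect_lt(max(abs(s_full - s_red)), 1e-8)
  expect_true(all(vapply(red$map, `[[`, "", "status") == "imputed"))
  expect_equal(red$definition$s, def$s)
})

test_that("identity reduction keeps the score unchanged and total loss errors", {
  m <- make_species_world(n = 100, seed = 9)
  fa <- log_transform(within_class_fatty_acid_sums(m))
  def <- score_definition(colnames(fa$values), rep(-0.3, ncol(fa$values)))
  red <- reduce_score(def, available = def$variables, reference = fa)
  expect_equal(compute_score(fa, red$definition), compute_score(fa, def))
  expect_true(all(vapply(red$map, `[[`, "", "status") == "kept"))
  expect_error(reduce_score(def, available = character(0), reference = fa),
               "kept or imputed")
})

test_that("lossy reduction still correlates strongly on held-out samples", {
  ref_raw <- make_species_world(n = 500, seed = 10, noise_sd = 0.3)
  new_raw <- make_species_world(n = 300, seed = 11, noise_sd = 0.3)
  build <- function(raw) {
    fa <- within_class_fatty_acid_sums(raw)
    iso <- isobaric_species_sums(raw)
    log_mat(cbind(log(fa$values), log(iso$values)))
  }
  ref <- build(ref_raw)
  new <- build(new_raw)
  fa_names <- colnames(within_class_fatty_acid_sums(ref_raw)$values)
  iso_names <- colnames(isobaric_species_sums(ref_raw)$values)
  def <- score_definition(fa_names, -seq(0.1, 0.6, length.out = length(fa_names)))
  # target platform only offers a subset of the species variables
  red <- reduce_score(def, available = iso_names[1:2], reference = ref)
  rho <- cor(compute_score(new, def), compute_score(new, red$definition),
             method = "spearman")
  expect_gt(rho, 0.9)
})

test_that("score definitions round trip through JSON losslessly", {
  def <- score_definition(c("CE(FA 16:0)", "DAG(FA 18:1)"),
                          c(-0.123456789012345, -0.3), s = 2.5,
                          intercept = 0.25, variant = "rMLS",
                          provenance = list(fdr_level = 0.05, trial = "synthetic"))
  path <- tempfile(fileext = ".json")
  write_score_definition(def, path)
  back <- read_score_definition(path)
  expect_equal(back$variables, def$variables)
  expect_equal(back$weights, def$weights)
  expect_equal(back$s, def$s)
  expect_equal(back$intercept, def$intercept)
  expect_equal(back$variant, def$variant)
})
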