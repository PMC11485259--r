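# fixtures are built in code; nothing is read from disk

# independent step-up oracle: reject the first k sorted p-values where
# k = max{ i : p_(i) <= i * level / m }
bh_stepup_oracle <- function(p, level = 0.05) {
  m <- length(p)
  o <- order(p)
  ok <- which(p[o] <= seq_len(m) * level / m)
  rej <- logical(m)
  if (length(ok)) rej[o[seq_len(max(ok))]] <- TRUE
  rej
}

# small ground truth reused across tests (cheap to build, deterministic)
tiny_gt <- function(p = 8, n_affected = 3, density = 0.2, seed = 42, ...) {
  generate_ground_truth(p = p, n_affected = n_affected, graph_density = density,
                        seed = seed, ...)
}

# molecular-species matrix with a shared latent factor per sample, so
# class-FA sums and isobaric sums are strongly correlated across samples
make_species_world <- function(n = 400, seed = 99, noise_sd = 0.3) {
  set.seed(seed)
  species <- c("DAG(16:0/18:1)", "DAG(16:0/18:2)", "DAG(18:1/18:2)",
               "DAG(16:0/16:0)", "PC(16:0/18:1)", "PC(16:0/18:2)",
               "PC(18:0/18:1)", "TAG(16:0/18:1/18:2)", "TAG(16:0/16:0/18:1)")
  f <- rnorm(n)
  vals <- sapply(seq_along(species), function(j) {
    exp(1 + 0.8 * f + noise_sd * rnorm(n))
  })
  colnames(vals) <- species
  rownames(vals) <- paste0("S", seq_len(n))
  lipid_matrix(vals, scale = "raw")
}

# 1:1 matched pairs with binary exposure: `b` pairs case-exposed only,
# `cc` pairs control-exposed only, `conc` concordant pairs
make_binary_pairs <- function(b, cc, conc = 5) {
  np <- b + cc + conc
  d <- data.frame(pair_id = rep(seq_len(np), each = 2),
                  role = rep(c("case", "control"), np))
  ex <- numeric(2 * np)
  if (b > 0) ex[2 * seq_len(b) - 1] <- 1
  if (cc > 0) ex[2 * (b + seq_len(cc))] <- 1
  if (conc > 0) {
    idx <- b + cc + seq_len(conc)
    ex[2 * idx - 1] <- 1
    ex[2 * idx] <- 1
  }
  d$exposure <- ex
  d
}

# 1:1 pairs with continuous exposure from the exact conditional-logistic
# model: P(first member is the case) = plogis(beta * (x1 - x2))
make_logit_pairs <- function(n_pairs, beta, seed, sd_x = 1) {
  set.seed(seed)
  x1 <- rnorm(n_pairs, 0, sd_x)
  x2 <- rnorm(n_pairs, 0, sd_x)
  first_case <- rbinom(n_pairs, 1, plogis(beta * (x1 - x2)))
  data.frame(
    pair_id = rep(seq_len(n_pairs), each = 2),
    role = as.vector(rbind(ifelse(first_case == 1, "case", "control"),
                           ifelse(first_case == 1, "control", "case"))),
    exposure = as.vector(rbind(x1, x2))
  )
}

# plain case-cohort table with exposure-driven exponential event times
make_cc_table <- function(n, loghr, seed, lambda0 = 0.02, followup = 10,
                          subcohort_fraction = 1) {
  set.seed(seed)
  x <- rnorm(n)
  d <- data.frame(id = seq_len(n), score = x,
                  age = runif(n, 40, 60), sex = rbinom(n, 1, 0.5),
                  bmi = rnorm(n, 26, 4))
  d$entry_age <- d$age
  tev <- rexp(n, lambda0 * exp(loghr * x))
  d$event <- as.integer(tev <= followup)
  d$exit_age <- d$entry_age + pmin(tev, followup)
  draw_case_cohort(d, subcohort_fraction, seed = seed + 1)
}

# linear-model fitter with the netcoupler_classify contract, for cheap tests
lm_fitter <- function(outcome_col) {
  function(d, exposure, covariates = character(0)) {
    X <- cbind(1, as.matrix(d[, c(exposure, covariates), drop = FALSE]))
    fit <- stats::lm.fit(X, d[[outcome_col]])
    df <- nrow(X) - fit$rank
    sigma2 <- sum(fit$residuals^2) / df
    XtXi <- chol2inv(fit$qr$qr[seq_len(fit$rank), seq_len(fit$rank), drop = FALSE])
    se <- sqrt(sigma2 * diag(XtXi))[order(fit$qr$pivot)]
    co <- fit$coefficients[2]
    list(loghr = unname(co),
         p = 2 * stats::pt(abs(co / se[2]), df, lower.tail = FALSE))
  }
}
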