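# Isocaloric macronutrient substitution models and diet-quality indices.

#' Isocaloric macronutrient substitution model
#'
#' Leave-one-out linear model: all macronutrient densities (percent total
#' energy) except the left-out component enter jointly, each divided by
#' `scale` so coefficients read "per `scale` %E substituted for the left-out
#' macronutrient at constant total energy". Adjusted for total energy intake
#' excluding alcohol, alcohol (g/day) and any further covariates.
#'
#' @param scores numeric outcome (a variance-standardized score).
#' @param macros data.frame of percent-energy columns plus `alcohol_g` and
#'   `energy_kcal`.
#' @param components macronutrient density columns to model (must include
#'   `leave_out`).
#' @param leave_out the substituted-away component (default `"sfa"`).
#' @param scale substitution contrast in %E (default 8).
#' @param covariates data.frame of additional adjustment columns (optional).
#' @return data.frame: `term`, `estimate`, `se`, `ci_lower`, `ci_upper`, `p`;
#'   rows for the substitution terms carry the per-`scale`%E interpretation.
#' @export
fit_substitution <- function(scores, macros,
                             components = c("sfa", "ufa", "protein", "carbohydrate"),
                             leave_out = "sfa", scale = 8,
                             covariates = NULL) {
  stopifnot(is.numeric(scores), is.data.frame(macros),
            leave_out %in% components,
            all(components %in% names(macros)))
  keep <- setdiff(components, leave_out)
  X <- as.matrix(macros[, keep, drop = FALSE]) / scale
  adj <- cbind(energy_kcal = macros$energy_kcal, alcohol_g = macros$alcohol_g)
  if (!is.null(covariates)) adj <- cbind(adj, as.matrix(covariates))
  M <- cbind(1, X, adj)
  if (qr(M)$rank < ncol(M)) {
    stop(sprintf("design is rank deficient after leaving out '%s'; macronutrient columns are linearly dependent",
                 leave_out))
  }
  fit <- stats::lm.fit(M, scores)
  df <- length(scores) - fit$rank
  sigma2 <- sum(fit$residuals^2) / df
  XtXi <- chol2inv(fit$qr$qr[seq_len(fit$rank), seq_len(fit$rank), drop = FALSE])
  se_piv <- sqrt(sigma2 * diag(XtXi))
  se <- se_piv[order(fit$qr$pivot)]
  est <- fit$coefficients
  z <- stats::qt(0.975, df)
  out <- data.frame(term = c("(intercept)", keep, colnames(adj)),
                    estimate = unname(est), se = unname(se),
                    ci_lower = unname(est - z * se),
                    ci_upper = unname(est + z * se),
                    p = unname(2 * stats::pt(abs(est / se), df, lower.tail = FALSE)),
                    stringsAsFactors = FALSE)
  attr(out, "leave_out") <- leave_out
  attr(out, "scale") <- scale
  out
}

# rank-based equal-count strata; ties share a stratum (ties.method = "min"),
# so identical intakes always score identically
lcd_strata <- function(x, n_strata = 11L) {
  r <- rank(x, ties.method = "min")
  pmin(floor((r - 1) * n_strata / length(x)), n_strata - 1L)
}

#' Low-carbohydrate-diet (LCD) scores
#'
#' Subjects are divided into 11 equal-count strata per component. Fat and
#' protein score 0 (lowest stratum) to 10 (highest); carbohydrate scoring is
#' reversed. Variants: `total` (total fat / total protein / carbohydrate),
#' `animal` (animal fat / animal protein / carbohydrate) and `vegetable`
#' (vegetable fat / vegetable protein / carbohydrate). Range 0-30.
#'
#' @param macros data.frame with `fat`, `protein`, `carbohydrate` and the
#'   `animal_`/`vegetable_` variants as percent energy.
#' @param variant `"total"`, `"animal"` or `"vegetable"`.
#' @return integer vector of scores in \[0, 30\].
#' @export
lcd_score <- function(macros, variant = c("total", "animal", "vegetable")) {
  variant <- match.arg(variant)
  cols <- switch(variant,
    total = c(fat = "fat", protein = "protein"),
    animal = c(fat = "animal_fat", protein = "animal_protein"),
    vegetable = c(fat = "vegetable_fat", protein = "vegetable_protein"))
  need <- c(unname(cols), "carbohydrate")
  miss <- setdiff(need, names(macros))
  if (length(miss)) stop(sprintf("missing macronutrient columns: %s",
                                 paste(miss, collapse = ", ")))
  fat_pts <- lcd_strata(macros[[cols["fat"]]])
  pro_pts <- lcd_strata(macros[[cols["protein"]]])
  carb_pts <- 10L - lcd_strata(macros$carbohydrate)
  as.integer(fat_pts + pro_pts + carb_pts)
}

#' Alternate Mediterranean diet score (aMed)
#'
#' Nine components: vegetables (excluding potatoes), fruits, nuts, whole
#' grains, legumes, fish and the MUFA:SFA ratio score 1 point above the
#' sample median; red and processed meat scores 1 point below the median;
#' alcohol scores 1 point for daily intake between 5 and 15 g. Range 0-9.
#' Medians are pooled across the analysis sample (not sex-specific).
#'
#' @param foods data.frame with `vegetables`, `fruits`, `nuts`,
#'   `whole_grains`, `legumes`, `fish`, `red_processed_meat`, `alcohol_g`.
#' @param macros data.frame with `mufa` and `sfa` (percent energy) for the
#'   fat-ratio component.
#' @return integer vector of scores in \[0, 9\].
#' @export
amed_score <- function(foods, macros) {
  need <- c("vegetables", "fruits", "nuts", "whole_grains", "legumes", "fish",
            "red_processed_meat", "alcohol_g")
  miss <- setdiff(need, names(foods))
  if (length(miss)) stop(sprintf("missing aMed component column(s): %s",
                                 paste(miss, collapse = ", ")))
  if (!all(c("mufa", "sfa") %in% names(macros))) {
    stop("missing aMed component column(s): mufa, sfa")
  }
  above <- function(x) as.integer(x > stats::median(x))
  ratio <- macros$mufa / macros$sfa
  pts <- above(foods$vegetables) + above(foods$fruits) + above(foods$nuts) +
    above(foods$whole_grains) + above(foods$legumes) + above(foods$fish) +
    above(ratio) +
    as.integer(foods$red_processed_meat < stats::median(foods$red_processed_meat)) +
    as.integer(foods$alcohol_g >= 5 & foods$alcohol_g <= 15)
  as.integer(pts)
}

#' Default AHEI-2010 component cut-offs
#'
#' Published AHEI-2010 scoring cut-offs (external to any single study),
#' shipped as a config preset. Each entry gives the intake earning 0 points
#' (`worst`) and 10 points (`best`); component scores interpolate linearly
#' and clamp to \[0, 10\]. Adverse components simply have `worst > best`.
#' Alcohol is special-cased: 10 points inside the moderate window,
#' `abstainer` points at zero intake, 0 points at or above `heavy`.
#'
#' @return named list of cut-off definitions usable by [ahei_score()].
#' @export
ahei_cutoffs <- function() {
  list(
    vegetables = list(worst = 0, best = 5),          # servings/day
    fruits = list(worst = 0, best = 4),              # servings/day
    whole_grains = list(worst = 0, best = 75),       # g/day
    nuts = list(worst = 0, best = 1),                # servings/day (nuts+legumes)
    long_chain_n3 = list(worst = 0, best = 250),     # mg/day EPA+DHA
    pufa = list(worst = 2, best = 10),               # % energy
    ssb = list(worst = 1, best = 0),                 # servings/day (adverse)
    red_processed_meat = list(worst = 1.5, best = 0),# servings/day (adverse)
    trans_pct = list(worst = 4, best = 0.5),         # % energy (adverse)
    sodium_mg = list(worst = 4500, best = 1100),     # mg/day (adverse)
    alcohol = list(low = 5, high = 15, heavy = 30, abstainer = 2.5) # g/day
  )
}

ahei_component <- function(x, worst, best) {
  sc <- 10 * (x - worst) / (best - worst)
  pmin(pmax(sc, 0), 10)
}

#' Alternate Healthy Eating Index (AHEI)
#'
#' Eleven components, each scored 0 (worst) to 10 (best) by linear
#' interpolation between supplied cut-offs (reversed for adverse
#' components); total range 0-110. The `include_alcohol = FALSE` variant
#' ("AHEI without alcohol points") sums the other ten components (0-100).
#'
#' @param foods data.frame with component intake columns: `vegetables`,
#'   `fruits`, `whole_grains`, `nuts`, `long_chain_n3`, `pufa`, `ssb`,
#'   `red_processed_meat`, `trans_pct`, `sodium_mg`, `alcohol_g`.
#' @param cutoffs cut-off config, see [ahei_cutoffs()] (required).
#' @param include_alcohol include the moderate-alcohol component.
#' @return numeric vector of scores.
#' @export
ahei_score <- function(foods, cutoffs = ahei_cutoffs(), include_alcohol = TRUE) {
  if (is.null(cutoffs)) stop("AHEI cut-offs must be supplied")
  comps <- setdiff(names(cutoffs), "alcohol")
  miss <- setdiff(comps, names(foods))
  if (length(miss)) stop(sprintf("missing AHEI component column(s): %s",
                                 paste(miss, collapse = ", ")))
  total <- rep(0, nrow(foods))
  for (cc in comps) {
    co <- cutoffs[[cc]]
    total <- total + ahei_component(foods[[cc]], co$worst, co$best)
  }
  if (include_alcohol) {
    if (!"alcohol_g" %in% names(foods)) stop("missing AHEI component column(s): alcohol_g")
    a <- foods$alcohol_g
    co <- cutoffs$alcohol
    pts <- ifelse(a == 0, co$abstainer,
           ifelse(a >= co$low & a <= co$high, 10,
           ifelse(a < co$low, co$abstainer + (10 - co$abstainer) * a / co$low,
                  pmax(10 * (co$heavy - a) / (co$heavy - co$high), 0))))
    total <- total + pts
  }
  total
}

#' Average the two diet assessments closest to blood collection
#'
#' Documented pre-step for repeated food-frequency data: element-wise mean of
#' two intake tables with identical columns. Averaging commutes with
#' percent-energy computation when total energy is averaged alongside.
#'
#' @param ffq1,ffq2 data.frames with identical numeric columns.
#' @return data.frame of element-wise means.
#' @export
average_ffq <- function(ffq1, ffq2) {
  stopifnot(identical(names(ffq1), names(ffq2)), nrow(ffq1) == nrow(ffq2))
  out <- ffq1
  for (cn in names(out)) out[[cn]] <- (ffq1[[cn]] + ffq2[[cn]]) / 2
  out
}
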