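#' Construct a lipid matrix
#'
#' A `lipid_matrix` is the package's container for samples-by-lipids
#' measurement grids: a numeric matrix (missing values as `NA`) plus the
#' parsed lipid variables, a scale flag and a processing log. Raw values must
#' be strictly positive where observed; the natural-log transform may be
#' applied at most once.
#'
#' @param values numeric matrix, samples in rows, lipid variables in columns
#'   (column names must parse under [parse_lipid_name()]).
#' @param scale `"raw"` (concentrations / relative abundances) or `"log"`
#'   (natural-log transformed).
#' @param meta list of provenance entries (dilution factor, filter log, ...).
#' @return a `lipid_matrix`.
#' @export
lipid_matrix <- function(values, scale = c("raw", "log"), meta = list()) {
  scale <- match.arg(scale)
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(colnames(values))) stop("`values` must have lipid-name column names")
  if (is.null(rownames(values))) rownames(values) <- paste0("S", seq_len(nrow(values)))
  if (scale == "raw" && any(values <= 0, na.rm = TRUE)) {
    stop("raw-scale lipid values must be strictly positive where observed")
  }
  vars <- lapply(colnames(values), parse_lipid_name)
  names(vars) <- colnames(values)
  structure(list(values = values, variables = vars, scale = scale, meta = meta),
            class = "lipid_matrix")
}

#' @export
print.lipid_matrix <- function(x, ...) {
  res <- unique(vapply(x$variables, `[[`, "", "resolution"))
  cat(sprintf("<lipid_matrix> %d samples x %d variables [%s scale; %s]\n",
              nrow(x$values), ncol(x$values), x$scale,
              paste(res, collapse = ", ")))
  invisible(x)
}

#' @export
dim.lipid_matrix <- function(x) dim(x$values)

variable_names <- function(m) colnames(m$values)

resolution_of <- function(m) {
  unique(vapply(m$variables, `[[`, "", "resolution"))
}

require_scale <- function(m, scale, op) {
  if (!inherits(m, "lipid_matrix")) stop("expected a `lipid_matrix`", call. = FALSE)
  if (m$scale != scale) {
    stop(sprintf("%s requires a %s-scale matrix (got %s scale)", op, scale, m$scale),
         call. = FALSE)
  }
  invisible(m)
}

#' Natural-log transform a raw lipid matrix
#'
#' Applied at most once; aggregation operations must run before this (sums of
#' concentrations, never sums of logs).
#'
#' @param m raw-scale `lipid_matrix` with no missing values.
#' @return log-scale `lipid_matrix`.
#' @export
log_transform <- function(m) {
  require_scale(m, "raw", "log_transform")
  out <- m
  out$values <- log(m$values)
  out$scale <- "log"
  out$meta$log_transformed <- TRUE
  out
}

#' Within-class fatty-acid sums
#'
#' Aggregates molecular species to one variable per (lipid class, fatty acid):
#' the total concentration of all species in the class containing that fatty
#' acid. A species carrying the same fatty acid on k chains contributes k
#' times its concentration (documented convention; preserves class-total
#' additivity). For one-fatty-acid classes the output values equal the input
#' species values. Sphingoid backbones are not counted as fatty acids.
#' Fatty acids outside 12-26 carbons / 0-6 double bonds are skipped with a
#' log entry.
#'
#' @param m raw-scale `lipid_matrix` at molecular-species resolution.
#' @return raw-scale `lipid_matrix` at class fatty-acid-sum resolution.
#' @export
within_class_fatty_acid_sums <- function(m) {
  require_scale(m, "raw", "within-class fatty-acid summation")
  if (!all(vapply(m$variables, `[[`, "", "resolution") == "molecular_species")) {
    stop("input must be at molecular_species resolution")
  }
  acc <- list()
  skipped <- character(0)
  for (v in m$variables) {
    conc <- m$values[, format(v)]
    for (ch in species_fa_chains(v)) {
      cd <- parse_cd(ch)
      if (!chain_valid(cd["carbons"], cd["double_bonds"])) {
        skipped <- c(skipped, sprintf("%s[%s]", format(v), ch))
        next
      }
      key <- sprintf("%s(FA %s)", v$lipid_class, ch)
      acc[[key]] <- if (is.null(acc[[key]])) conc else acc[[key]] + conc
    }
  }
  if (length(acc) == 0L) stop("no in-range fatty-acid chains to aggregate")
  out <- do.call(cbind, acc)
  rownames(out) <- rownames(m$values)
  lipid_matrix(out, scale = "raw",
               meta = c(m$meta, list(fa_sum_skipped = unique(skipped))))
}

#' Isobaric species sums
#'
#' For classes with more than one fatty acid per molecule (DAG, TAG, PC, PE,
#' PE O-, PE P-, PI) this sums all molecular species sharing the class, total
#' acyl carbon count and total double-bond count into one isobaric variable.
#'
#' @param m raw-scale `lipid_matrix` at molecular-species resolution.
#' @param classes multi-fatty-acid classes to aggregate (default all present).
#' @return raw-scale `lipid_matrix` at isobaric-species resolution.
#' @export
isobaric_species_sums <- function(m, classes = NULL) {
  require_scale(m, "raw", "isobaric species summation")
  eligible <- multi_fa_classes()
  present <- unique(vapply(m$variables, `[[`, "", "lipid_class"))
  classes <- classes %||% intersect(present, eligible)
  bad <- setdiff(classes, eligible)
  if (length(bad)) {
    stop(sprintf("isobaric aggregation is undefined for one-fatty-acid class(es): %s",
                 paste(bad, collapse = ", ")))
  }
  acc <- list()
  for (v in m$variables) {
    if (!(v$lipid_class %in% classes)) next
    if (v$resolution != "molecular_species") {
      stop("input must be at molecular_species resolution")
    }
    tot <- species_totals(v)
    key <- sprintf("%s %d:%d", v$lipid_class, tot["carbons"], tot["double_bonds"])
    conc <- m$values[, format(v)]
    acc[[key]] <- if (is.null(acc[[key]])) conc else acc[[key]] + conc
  }
  if (length(acc) == 0L) {
    out <- matrix(numeric(0), nrow = nrow(m$values), ncol = 0)
    rownames(out) <- rownames(m$values)
    return(structure(list(values = out, variables = list(), scale = "raw",
                          meta = m$meta), class = "lipid_matrix"))
  }
  out <- do.call(cbind, acc)
  rownames(out) <- rownames(m$values)
  lipid_matrix(out, scale = "raw", meta = m$meta)
}

#' Drop lipid variables with excessive missingness
#'
#' Variables with missing fraction strictly greater than
#' `max_missing_fraction` are removed (a variable missing in exactly 70% of
#' samples is retained at the default threshold). The drop list is recorded in
#' the matrix meta log.
#'
#' @param m `lipid_matrix`.
#' @param max_missing_fraction numeric in \[0, 1\], default 0.70.
#' @return filtered `lipid_matrix`.
#' @export
filter_missing <- function(m, max_missing_fraction = 0.70) {
  stopifnot(inherits(m, "lipid_matrix"))
  frac <- colMeans(is.na(m$values))
  drop <- frac > max_missing_fraction
  out <- m
  out$values <- m$values[, !drop, drop = FALSE]
  out$variables <- m$variables[!drop]
  out$meta$missingness_filter <- list(threshold = max_missing_fraction,
                                      dropped = names(frac)[drop],
                                      missing_fraction = frac)
  out
}

# truncated-normal draw below upper bound `ub` for N(mu, sd)
rtnorm_below <- function(n, mu, sd, ub) {
  pu <- stats::pnorm((ub - mu) / sd)
  pu <- max(pu, 1e-12)
  u <- stats::runif(n, 0, pu)
  mu + sd * stats::qnorm(u)
}

#' Impute left-censored missing lipid values
#'
#' Missingness is assumed to arise from values below the lower limit of
#' quantification. Two methods:
#' \describe{
#'   \item{`qrilc_like`}{per variable, the observed log-values' order
#'     statistics are regressed on standard-normal quantiles (shifted for the
#'     censored mass) to recover the uncensored mean and s.d.; imputations are
#'     drawn from the left tail of that normal, truncated at the observed
#'     minimum. This is a simplified reimplementation of the
#'     quantile-regression imputation idea, not a port of any package.}
#'   \item{`half_min`}{deterministic half of the observed per-variable
#'     minimum.}
#' }
#' Imputed values never exceed the observed per-variable minimum. Variables
#' with fewer than 4 observed values fall back to `half_min` with a warning.
#'
#' @param m raw-scale `lipid_matrix`.
#' @param method `"qrilc_like"` or `"half_min"`.
#' @param seed integer seed (required for `qrilc_like`).
#' @return completed `lipid_matrix` (no missing values).
#' @export
impute_left_censored <- function(m, method = c("qrilc_like", "half_min"),
                                 seed = NULL) {
  method <- match.arg(method)
  require_scale(m, "raw", "left-censored imputation")
  vals <- m$values
  n <- nrow(vals)
  if (method == "qrilc_like") {
    assert_seed(seed)
    set.seed(seed)
  }
  fallbacks <- character(0)
  for (j in seq_len(ncol(vals))) {
    mis <- is.na(vals[, j])
    if (!any(mis)) next
    obs <- vals[!mis, j]
    if (length(obs) == 0L) stop(sprintf("variable %s has no observed values",
                                        colnames(vals)[j]))
    use_half_min <- method == "half_min"
    if (!use_half_min && length(obs) < 4L) {
      fallbacks <- c(fallbacks, colnames(vals)[j])
      use_half_min <- TRUE
    }
    if (use_half_min) {
      vals[mis, j] <- min(obs) / 2
    } else {
      lobs <- sort(log(obs))
      n_mis <- sum(mis)
      q <- stats::qnorm((n_mis + seq_along(lobs)) / (n + 1))
      fit <- stats::lm.fit(cbind(1, q), lobs)
      mu <- fit$coefficients[1]
      sigma <- max(fit$coefficients[2], 1e-8)
      draws <- rtnorm_below(n_mis, mu, sigma, min(lobs))
      vals[mis, j] <- pmin(exp(draws), min(obs))
    }
  }
  if (length(fallbacks)) {
    warning(sprintf("qrilc_like fell back to half_min for %d variable(s) with < 4 observed values",
                    length(fallbacks)))
  }
  out <- m
  out$values <- vals
  out$meta$imputation <- list(method = method, seed = seed,
                              half_min_fallback = fallbacks)
  out
}

#' Correct for a scalar dilution factor
#'
#' Multiplies all raw concentrations by `factor`. The default `1/0.9`
#' corrects for plasma collected with 10% citrate volume.
#'
#' @param m raw-scale `lipid_matrix`.
#' @param factor positive scalar.
#' @return corrected `lipid_matrix`.
#' @export
dilution_correct <- function(m, factor = 1 / 0.9) {
  require_scale(m, "raw", "dilution correction")
  assert_scalar_number(factor)
  if (factor <= 0) stop("dilution `factor` must be positive")
  out <- m
  out$values <- m$values * factor
  out$meta$dilution_factor <- factor
  out
}

#' Read / write a lipid matrix as TSV with a JSON sidecar
#'
#' The TSV carries one `sample` column plus one column per canonical lipid
#' name; the sidecar (`<path>.json`) records the scale flag and processing
#' log so round trips are lossless.
#'
#' @param m `lipid_matrix`.
#' @param path TSV file path.
#' @return `write_lipid_matrix` returns `path` invisibly;
#'   `read_lipid_matrix` returns a `lipid_matrix`.
#' @export
write_lipid_matrix <- function(m, path) {
  stopifnot(inherits(m, "lipid_matrix"))
  df <- data.frame(sample = rownames(m$values), m$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(scale = m$scale, meta = m$meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_lipid_matrix
#' @export
read_lipid_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df$sample
  scale <- "raw"
  meta <- list()
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    scale <- side$scale %||% "raw"
    meta <- as.list(side$meta %||% list())
  }
  lipid_matrix(vals, scale = scale, meta = meta)
}
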