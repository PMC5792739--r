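# Gene-wise Cox proportional-hazards screening of a patient cohort, with
# Benjamini-Hochberg control, dual-cohort intersection and Kaplan-Meier
# median-split summaries. Fitting is delegated to the survival package's
# workhorse (coxph.fit); the screening logic, bookkeeping and direction
# semantics live here.

#' Screen configuration
#'
#' @param fdr_threshold Benjamini-Hochberg threshold used downstream when a
#'   gene is called significant (default 0.1).
#' @param adjust_covariates Character subset of `c("age", "sex")` to adjust
#'   each per-gene model for. The motivating analysis adjusted one cohort for
#'   age and sex; pass `character(0)` for an unadjusted screen.
#' @param ties_method Partial-likelihood ties handling, `"breslow"` (default)
#'   or `"efron"`.
#' @param ci_level Confidence level for the hazard-ratio interval.
#' @return A `screen_config` list.
#' @export
screen_config <- function(fdr_threshold = 0.1,
                          adjust_covariates = c("age", "sex"),
                          ties_method = c("breslow", "efron"),
                          ci_level = 0.95) {
  if (fdr_threshold <= 0 || fdr_threshold >= 1)
    stopf("`fdr_threshold` must be in (0, 1)")
  if (!all(adjust_covariates %in% c("age", "sex")))
    stopf("`adjust_covariates` may only contain 'age' and 'sex'")
  structure(list(fdr_threshold = fdr_threshold,
                 adjust_covariates = adjust_covariates,
                 ties_method = match.arg(ties_method),
                 ci_level = ci_level),
            class = "screen_config")
}

# One Cox fit via the survival package's fitting routine. Returns a list with
# beta, se, and a flag; non-estimable fits (constant expression, monotone
# likelihood / separation) are flagged rather than errored so a screen can
# drop them from the multiple-testing family.
cox_fit_one <- function(X, y, ties_method) {
  storage.mode(X) <- "double"
  fit <- tryCatch(
    suppressWarnings(
      survival::coxph.fit(X, y, strata = NULL, offset = NULL, init = NULL,
                          control = survival::coxph.control(),
                          weights = NULL, method = ties_method,
                          rownames = NULL)),
    error = function(e) NULL)
  if (is.null(fit)) return(list(beta = NA_real_, se = NA_real_, ok = FALSE))
  beta <- fit$coefficients[1]
  se <- sqrt(diag(fit$var))[1]
  ok <- is.finite(beta) && is.finite(se) && se < 50 && abs(beta) < 50
  list(beta = unname(beta), se = unname(se), ok = ok)
}

#' Fit a single-gene Cox proportional-hazards model
#'
#' Models the hazard as `h0(t) exp(beta x + covariates)` where `x` is the
#' gene's per-sample log2 expression, so `exp(beta)` is the hazard ratio per
#' additional unit of log2 expression. The confidence interval is
#' `exp(beta +/- z se)` with the standard error from the observed
#' information, and the p-value is the two-sided Wald test.
#'
#' @param expr Per-sample log2 expression values.
#' @param time,event Follow-up time and 0/1 event indicator.
#' @param age,sex Optional covariates (used when named in
#'   `config$adjust_covariates` and supplied).
#' @param config A [screen_config()].
#' @return One-row tibble with `beta`, `se`, `hr`, `ci_low`, `ci_high`, `p`,
#'   `direction` (`"protective"` for HR < 1, `"adverse"` otherwise) and
#'   `estimable`. Constant expression gives `estimable = FALSE` with `NA`
#'   statistics.
#' @export
fit_cox_single_gene <- function(expr, time, event, age = NULL, sex = NULL,
                                config = screen_config()) {
  if (length(time) != length(expr) || length(event) != length(expr))
    stopf("`expr`, `time` and `event` must have equal length")
  if (any(time <= 0)) stopf("all follow-up times must be > 0")
  if (!all(event %in% c(0, 1))) stopf("`event` must be 0/1")
  if (sum(event) < 1) stopf("degenerate input: no events in the cohort")

  X <- cbind(expr = expr)
  if ("age" %in% config$adjust_covariates && !is.null(age)) X <- cbind(X, age = age)
  if ("sex" %in% config$adjust_covariates && !is.null(sex)) X <- cbind(X, sex = sex)

  if (var(expr) == 0) {
    return(tibble(beta = NA_real_, se = NA_real_, hr = NA_real_,
                  ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
                  direction = NA_character_, estimable = FALSE))
  }
  y <- survival::Surv(time, event)
  f <- cox_fit_one(X, y, config$ties_method)
  if (!f$ok) {
    return(tibble(beta = f$beta, se = f$se, hr = NA_real_, ci_low = NA_real_,
                  ci_high = NA_real_, p = NA_real_,
                  direction = NA_character_, estimable = FALSE))
  }
  z <- qnorm((1 + config$ci_level) / 2)
  tibble(beta = f$beta, se = f$se, hr = exp(f$beta),
         ci_low = exp(f$beta - z * f$se), ci_high = exp(f$beta + z * f$se),
         p = 2 * pnorm(-abs(f$beta / f$se)),
         direction = ifelse(exp(f$beta) < 1, "protective", "adverse"),
         estimable = TRUE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment,
#' `q_(i) = min_{j >= i} m p_(j) / j` capped at 1; the per-element result is
#' invariant to permutation of the input.
#'
#' @param p Vector of p-values in \[0, 1\] (no missing values).
#' @return Adjusted values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stopf("p-values must lie in [0, 1] with no missing values")
  p.adjust(p, method = "BH")
}

#' Run the gene-wise Cox screen over a cohort
#'
#' Fits [fit_cox_single_gene()] for every gene in the cohort's expression
#' matrix and applies [bh_adjust()] across all estimable genes (the
#' multiple-testing family is the cohort's screened panel; non-estimable
#' genes contribute no p-value and are excluded).
#'
#' @param cohort A `cohort_dataset` (see [simulate_cohort()]), or any list
#'   with an `expression` matrix and a `samples` table holding `time`,
#'   `event` and optionally `age`, `sex`.
#' @param config A [screen_config()].
#' @return Tibble with one row per estimable gene: `gene`, `beta`, `se`,
#'   `hr`, `ci_low`, `ci_high`, `p`, `fdr`, `direction`. Attributes
#'   `n_genes_input` and `n_nonestimable` record the bookkeeping.
#' @export
run_cohort_screen <- function(cohort, config = screen_config()) {
  expr <- cohort$expression
  s <- cohort$samples
  if (is.null(expr) || nrow(expr) < 2) stopf("need a cohort with >= 2 genes")
  if (sum(s$event) < 1) stopf("degenerate cohort: no events")
  if (ncol(expr) != nrow(s)) stopf("expression and survival tables do not align")

  y <- survival::Surv(s$time, s$event)
  covars <- NULL
  if ("age" %in% config$adjust_covariates && !is.null(s$age))
    covars <- cbind(covars, age = s$age)
  if ("sex" %in% config$adjust_covariates && !is.null(s$sex))
    covars <- cbind(covars, sex = s$sex)
  z <- qnorm((1 + config$ci_level) / 2)

  fits <- map(seq_len(nrow(expr)), function(g) {
    x <- expr[g, ]
    if (var(x) == 0) return(list(beta = NA_real_, se = NA_real_, ok = FALSE))
    cox_fit_one(cbind(cbind(expr = x), covars), y, config$ties_method)
  })
  beta <- map_dbl(fits, "beta")
  se <- map_dbl(fits, "se")
  ok <- vapply(fits, `[[`, logical(1), "ok")

  res <- tibble(gene = rownames(expr), beta = beta, se = se)[ok, ]
  res <- res |>
    mutate(hr = exp(.data$beta),
           ci_low = exp(.data$beta - z * .data$se),
           ci_high = exp(.data$beta + z * .data$se),
           p = 2 * pnorm(-abs(.data$beta / .data$se)),
           direction = ifelse(.data$hr < 1, "protective", "adverse"))
  res$fdr <- bh_adjust(res$p)
  res <- res |> select("gene", "hr", "ci_low", "ci_high", "p", "fdr",
                       "direction", "beta", "se")
  attr(res, "n_genes_input") <- nrow(expr)
  attr(res, "n_nonestimable") <- sum(!ok)
  attr(res, "cohort_label") <- cohort$label %||% "cohort"
  res
}

#' Intersect two cohort screens at a shared FDR threshold
#'
#' Returns the genes significant (FDR below threshold) in *both* cohorts,
#' flagging whether the hazard-ratio direction agrees
#' (`(hr_a < 1) == (hr_b < 1)`). The concordant fraction is attached as an
#' attribute.
#'
#' @param res_a,res_b Screen tibbles from [run_cohort_screen()], keyed by
#'   shared gene identifiers.
#' @param fdr_threshold Significance threshold applied to both cohorts.
#' @return Tibble of dual-significant genes with `_a` / `_b` suffixed
#'   statistics and a `same_direction` flag; attribute `fraction_concordant`.
#' @export
intersect_cohorts <- function(res_a, res_b, fdr_threshold = 0.1) {
  shared <- inner_join(res_a, res_b, by = "gene", suffix = c("_a", "_b"))
  if (nrow(shared) == 0) stopf("the two screens share no genes")
  out <- shared |>
    filter(.data$fdr_a < fdr_threshold, .data$fdr_b < fdr_threshold) |>
    mutate(same_direction = (.data$hr_a < 1) == (.data$hr_b < 1))
  attr(out, "fraction_concordant") <-
    if (nrow(out)) mean(out$same_direction) else NA_real_
  attr(out, "n_shared") <- nrow(shared)
  out
}

#' Kaplan-Meier median split for one gene
#'
#' Splits samples at the median expression (values strictly greater than the
#' median form the "high" stratum; ties at the median go to "low"), computes
#' the product-limit survival estimate per stratum and a single-covariate Cox
#' hazard ratio for low vs high expression.
#'
#' @param expr Per-sample expression values.
#' @param time,event Follow-up time and 0/1 event indicator.
#' @return A `km_split` object: list with `curves` (tibble `stratum`, `time`,
#'   `n_risk`, `n_event`, `estimate`), `hr` (one-row tibble, low vs high) and
#'   `split_value`.
#' @export
km_median_split <- function(expr, time, event) {
  med <- median(expr)
  grp <- ifelse(expr > med, "high", "low")
  if (min(table(factor(grp, levels = c("low", "high")))) < 2)
    stopf("each stratum needs >= 2 samples; expression is too tied")
  y <- survival::Surv(time, event)
  sf <- survival::survfit(y ~ grp)
  lab <- sub("^grp=", "", rep(names(sf$strata), sf$strata))
  curves <- tibble(stratum = lab, time = sf$time, n_risk = sf$n.risk,
                   n_event = sf$n.event, estimate = sf$surv)
  low <- as.integer(grp == "low")
  f <- cox_fit_one(cbind(low = low), y, "breslow")
  z <- qnorm(0.975)
  hr <- tibble(hr = exp(f$beta), ci_low = exp(f$beta - z * f$se),
               ci_high = exp(f$beta + z * f$se),
               p = 2 * pnorm(-abs(f$beta / f$se)))
  structure(list(curves = curves, hr = hr, split_value = med),
            class = "km_split")
}

#' @export
print.km_split <- function(x, ...) {
  cat(sprintf("<km_split at median %.4g; HR (low vs high) = %.4g [%.4g, %.4g], p = %.3g>\n",
              x$split_value, x$hr$hr, x$hr$ci_low, x$hr$ci_high, x$hr$p))
  invisible(x)
}

#' Reconstruct a Wald p-value from a printed hazard ratio and interval
#'
#' Given a hazard ratio with its two-sided confidence interval at `level`,
#' recovers `SE = (ln ci_high - ln ci_low) / (2 z)` and the two-sided Wald
#' p-value `2 Phi(-|ln hr| / SE)`. Useful for checking published survival
#' tables that print HR, CI and p side by side.
#'
#' @param hr,ci_low,ci_high Hazard ratio and confidence bounds (vectorised;
#'   all must be positive with `ci_low <= hr <= ci_high`).
#' @param level Confidence level of the interval (default 0.95).
#' @return Vector of p-values.
#' @export
#' @examples
#' wald_p_from_hr_ci(0.60248, 0.45858, 0.79153)
wald_p_from_hr_ci <- function(hr, ci_low, ci_high, level = 0.95) {
  if (any(ci_low <= 0) || any(hr <= 0) || any(ci_high <= 0))
    stopf("hazard ratios and bounds must be positive")
  if (any(ci_low > hr) || any(hr > ci_high))
    stopf("need ci_low <= hr <= ci_high")
  z <- qnorm((1 + level) / 2)
  se <- (log(ci_high) - log(ci_low)) / (2 * z)
  ifelse(se == 0, as.numeric(log(hr) == 0),
         2 * pnorm(-abs(log(hr)) / se))
}

#' Published candidate-gene survival statistics
#'
#' The 28-gene candidate table from a two-cohort melanoma survival analysis
#' (per-gene hazard ratio per unit of log2 expression, 95% confidence
#' interval, Wald p and Benjamini-Hochberg FDR for melanoma-specific survival
#' in the Leeds cohort and overall survival in the Lund cohort), shipped as a
#' plain-text fixture for round-trip checks such as
#' [wald_p_from_hr_ci()] reconstruction and direction censuses.
#'
#' @return Tibble with one row per gene.
#' @export
candidate_gene_table <- function() {
  path <- system.file("extdata", "candidate_genes.tsv", package = "crossconcord")
  as_tibble(read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE))
}
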