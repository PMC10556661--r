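#' Welch two-sample t-test from group summaries
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a 95% confidence interval for the mean difference (group A minus
#' group B), computed from group means, standard deviations and sizes. For
#' raw data use [welch_t_vectors()].
#'
#' @param mean_a,sd_a,n_a Summary statistics of group A.
#' @param mean_b,sd_b,n_b Summary statistics of group B.
#' @param conf_level Confidence level, default 0.95.
#' @return One-row tibble: `test_name`, `statistic`, `df`, `p_value`,
#'   `estimate` (mean difference), `ci_low`, `ci_high`.
#' @export
#' @examples
#' welch_t(57.4, 9.5, 658, 59.7, 8.6, 78)
welch_t <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                    conf_level = 0.95) {
  stopifnot(n_a >= 2, n_b >= 2, sd_a >= 0, sd_b >= 0)
  va <- sd_a^2 / n_a
  vb <- sd_b^2 / n_b
  se <- sqrt(va + vb)
  diff <- mean_a - mean_b
  if (se == 0) {
    warning("both groups degenerate (zero variance); t set to 0")
    stat <- 0
    df <- n_a + n_b - 2
  } else {
    stat <- diff / se
    df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  }
  alpha <- 1 - conf_level
  half <- if (se == 0) 0 else stats::qt(1 - alpha / 2, df) * se
  tibble::tibble(
    test_name = "welch_t",
    statistic = stat,
    df = df,
    p_value = 2 * stats::pt(-abs(stat), df),
    estimate = diff,
    ci_low = diff - half,
    ci_high = diff + half
  )
}

#' Welch two-sample t-test from raw vectors
#'
#' Thin wrapper around [stats::t.test()] with `var.equal = FALSE`, returned
#' in the same tidy shape as [welch_t()]. Missing values are dropped.
#'
#' @param a,b Numeric vectors for the two groups.
#' @param conf_level Confidence level, default 0.95.
#' @return One-row tibble as in [welch_t()].
#' @export
welch_t_vectors <- function(a, b, conf_level = 0.95) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  stopifnot(length(a) >= 2, length(b) >= 2)
  ht <- stats::t.test(a, b, var.equal = FALSE, conf.level = conf_level)
  tibble::tibble(
    test_name = "welch_t",
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    estimate = unname(diff(rev(ht$estimate))),
    ci_low = ht$conf.int[1],
    ci_high = ht$conf.int[2]
  )
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson chi-square with expected counts from the row/column margins; for
#' 2x2 tables the Yates continuity correction (|O - E| - 0.5, floored at 0)
#' is applied by default, matching the convention of R's base test.
#'
#' @param table An r x c matrix (or data frame) of non-negative counts, at
#'   least 2x2.
#' @param yates Apply the continuity correction (2x2 tables only; ignored
#'   otherwise). Default `TRUE`.
#' @return One-row tibble: `test_name`, `statistic`, `df`, `p_value`, `n`
#'   (total count).
#' @export
#' @examples
#' chi_square(matrix(c(125, 533, 6, 72), nrow = 2))
chi_square <- function(table, yates = TRUE) {
  m <- as.matrix(table)
  stopifnot(is.numeric(m), all(m >= 0), nrow(m) >= 2, ncol(m) >= 2)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("contingency table has a zero margin", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(m, correct = yates))
  tibble::tibble(
    test_name = if (grepl("continuity", ht$method)) "chi_square_yates" else "chi_square",
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    n = sum(m)
  )
}

#' Covariate-adjusted linear regression for a binary exposure
#'
#' Fits `outcome ~ exposure + covariates` by least squares and reports the
#' exposure coefficient with its 95% confidence interval from t quantiles on
#' the residual degrees of freedom. Education (when present among the
#' covariates) is entered as a factor with levels low < medium < high, i.e.
#' two indicator contrasts against low. Rows with missing values in any
#' model variable are dropped (listwise deletion).
#'
#' @param data Data frame holding outcome, exposure and covariates.
#' @param outcome Name of the numeric outcome column (string).
#' @param exposure Name of the binary (logical or 0/1) exposure column.
#' @param covariates Character vector of adjustment covariate columns;
#'   default `c("age", "sex_gender", "education")`.
#' @param conf_level Confidence level, default 0.95.
#' @return An object of class `fluency_ols`: the underlying [stats::lm] fit
#'   plus the tidied exposure row. Use [tidy()] / [glance()] for full
#'   summaries, or read `$result` for the one-row exposure tibble
#'   (`term`, `B`, `ci_low`, `ci_high`, `p_value`, `n`).
#' @export
ols_adjusted <- function(data, outcome, exposure,
                         covariates = c("age", "sex_gender", "education"),
                         conf_level = 0.95) {
  vars <- c(outcome, exposure, covariates)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols) > 0L) {
    stop("columns not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  d <- data[stats::complete.cases(data[vars]), vars, drop = FALSE]
  if ("education" %in% covariates) {
    d$education <- factor(d$education, levels = c("low", "medium", "high"))
  }
  d[[exposure]] <- as.numeric(d[[exposure]])
  fml <- stats::reformulate(c(exposure, covariates), response = outcome)
  mm <- stats::model.matrix(fml, data = d)
  if (nrow(d) <= ncol(mm)) {
    stop("fewer observations than parameters after listwise deletion",
         call. = FALSE)
  }
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    bad <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1L):ncol(mm)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm(fml, data = d)
  ci <- stats::confint(fit, level = conf_level)
  coefs <- summary(fit)$coefficients
  result <- tibble::tibble(
    term = exposure,
    B = unname(coefs[exposure, "Estimate"]),
    ci_low = ci[exposure, 1],
    ci_high = ci[exposure, 2],
    p_value = unname(coefs[exposure, "Pr(>|t|)"]),
    n = nrow(d)
  )
  structure(list(fit = fit, result = result, outcome = outcome,
                 exposure = exposure, covariates = covariates),
            class = "fluency_ols")
}

#' @export
print.fluency_ols <- function(x, ...) {
  cat("<fluency_ols> ", x$outcome, " ~ ", x$exposure,
      if (length(x$covariates)) paste0(" + ", paste(x$covariates, collapse = " + ")),
      "\n", sep = "")
  r <- x$result
  cat(sprintf("  B = %.2f; 95%% CI = [%.2f; %.2f], p = %.3g, n = %d\n",
              r$B, r$ci_low, r$ci_high, r$p_value, r$n))
  invisible(x)
}

#' Tidy a fluency_ols fit
#'
#' @param x A `fluency_ols` object.
#' @param conf_level Confidence level for the intervals.
#' @param ... Unused.
#' @return Tibble with one row per model term: `term`, `estimate`,
#'   `std_error`, `statistic`, `p_value`, `ci_low`, `ci_high`.
#' @export
tidy.fluency_ols <- function(x, conf_level = 0.95, ...) {
  coefs <- summary(x$fit)$coefficients
  ci <- stats::confint(x$fit, level = conf_level)
  tibble::tibble(
    term = rownames(coefs),
    estimate = coefs[, "Estimate"],
    std_error = coefs[, "Std. Error"],
    statistic = coefs[, "t value"],
    p_value = coefs[, "Pr(>|t|)"],
    ci_low = ci[, 1],
    ci_high = ci[, 2]
  )
}

#' Glance at a fluency_ols fit
#'
#' @param x A `fluency_ols` object.
#' @param ... Unused.
#' @return One-row tibble: `r_squared`, `adj_r_squared`, `sigma`,
#'   `df_residual`, `n`.
#' @export
glance.fluency_ols <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(
    r_squared = s$r.squared,
    adj_r_squared = s$adj.r.squared,
    sigma = s$sigma,
    df_residual = x$fit$df.residual,
    n = x$result$n
  )
}

#' Benjamini-Hochberg false discovery rate control with a fixed family size
#'
#' Orders the p-values from smallest to largest with ranks i = 1..k,
#' computes the critical value (i/m)Q per rank, and rejects every p-value up
#' to and including the largest p(i) that is *smaller than* its critical
#' value. The family size `m` may exceed the number of p-values supplied
#' (e.g. a family of 6 tests evaluated one inference set at a time).
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @param q False discovery rate, default 0.10.
#' @param m Family size; defaults to `length(p_values)`.
#' @param labels Optional test labels carried through to the output.
#' @return Tibble ordered by p-value: `label`, `p_value`, `rank`,
#'   `critical_value`, `rejected`. The rejected set is always a prefix of
#'   the rank ordering.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.04, 0.2, 0.5, 0.9), q = 0.10)
bh_fdr <- function(p_values, q = 0.10, m = length(p_values), labels = NULL) {
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1) {
    stop("q must lie strictly between 0 and 1", call. = FALSE)
  }
  stopifnot(all(p_values >= 0 & p_values <= 1), m >= length(p_values))
  if (is.null(labels)) labels <- paste0("test_", seq_along(p_values))
  ord <- order(p_values)
  p <- p_values[ord]
  k <- length(p)
  rank <- seq_len(k)
  crit <- rank / m * q
  below <- which(p < crit)
  cut <- if (length(below) == 0L) 0L else max(below)
  tibble::tibble(
    label = labels[ord],
    p_value = p,
    rank = rank,
    critical_value = crit,
    rejected = rank <= cut
  )
}
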