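#' Recode the eight Dutch education levels into three categories
#'
#' The Dutch school system codes range from no primary school (1) through an
#' academic degree (8); analyses use three bands: low (less than high
#' school, codes 1-2), medium (at least some high school, codes 3-6), and
#' high (college or university, codes 7-8).
#'
#' @param level Integer vector of education codes 1-8, or a character vector
#'   already holding `"low"`/`"medium"`/`"high"` (returned as-is).
#' @return Character vector with values `"low"`, `"medium"`, `"high"`.
#' @export
recode_education <- function(level) {
  if (is.character(level) || is.factor(level)) {
    lv <- as.character(level)
    stopifnot(all(lv %in% c("low", "medium", "high") | is.na(lv)))
    return(lv)
  }
  stopifnot(all(level %in% 1:8 | is.na(level)))
  dplyr::case_when(
    level <= 2 ~ "low",
    level <= 6 ~ "medium",
    level >= 7 ~ "high"
  )
}

#' Join abundance labels onto a covariate table
#'
#' @param covariates Data frame with one row per participant
#'   (`participant_id`, demographics, cognitive scores).
#' @param results Tibble from [longest_series()].
#' @param cutoff Abundance cutoff applied via [classify_abundant()].
#' @return Covariate tibble with `longest_length`, `longest_class` and
#'   logical `abundant` columns; participants missing from `results` get
#'   `abundant = NA`.
#' @export
build_cohort <- function(covariates, results, cutoff) {
  labelled <- classify_abundant(results, cutoff)
  dplyr::left_join(
    tibble::as_tibble(covariates),
    dplyr::select(labelled, "participant_id", "longest_class",
                  "longest_length", "abundant"),
    by = "participant_id"
  )
}

profession_exclusions_always <- function() {
  c("Military profession", "Multiple professions", "Other")
}

#' Baseline characteristics split by abundance group
#'
#' Descriptive table in the shape of a cohort baseline table: continuous
#' variables as mean, SD and range; categorical variables as counts and
#' within-group percentages. Descriptives are not subject to the category
#' exclusions that the inferential tests apply.
#'
#' @param cohort Tibble from [build_cohort()] with an `abundant` column.
#' @param continuous Character vector of continuous variable names present
#'   in `cohort`.
#' @param categorical Character vector of categorical variable names.
#' @return Tidy tibble: `variable`, `level` (`NA` for continuous), `group`
#'   (`"abundant"` / `"non_abundant"`), `n`, `mean`, `sd`, `min`, `max`
#'   (continuous) or `count`, `percent` (categorical).
#' @export
group_summary <- function(cohort,
                          continuous = intersect(
                            c("age", "animal_fluency_total", "letter_fluency",
                              "mmse", "wlt_total", "wlt_delayed",
                              "rey_delayed", "dart"), names(cohort)),
                          categorical = intersect(
                            c("sex_gender", "education", "profession",
                              "working_status"), names(cohort))) {
  stopifnot("abundant" %in% names(cohort))
  d <- dplyr::filter(cohort, !is.na(.data$abundant)) |>
    dplyr::mutate(group = ifelse(.data$abundant, "abundant", "non_abundant"))
  cont <- purrr::map_dfr(continuous, function(v) {
    d |>
      dplyr::filter(!is.na(.data[[v]])) |>
      dplyr::summarise(
        n = dplyr::n(),
        mean = mean(.data[[v]]),
        sd = stats::sd(.data[[v]]),
        min = min(.data[[v]]),
        max = max(.data[[v]]),
        .by = "group"
      ) |>
      dplyr::mutate(variable = v, level = NA_character_, .before = 1L)
  })
  cat_ <- purrr::map_dfr(categorical, function(v) {
    d |>
      dplyr::filter(!is.na(.data[[v]])) |>
      dplyr::count(.data$group, level = as.character(.data[[v]]),
                   name = "count") |>
      dplyr::mutate(percent = round(100 * .data$count / sum(.data$count), 1),
                    .by = "group") |>
      dplyr::mutate(variable = v, .before = 1L)
  })
  dplyr::bind_rows(cont, cat_)
}

#' Group-comparison tests for personal background factors
#'
#' Runs the background-factor inference set comparing abundant versus
#' non-abundant participants: Welch t-test for age; Yates-corrected
#' chi-square for sex/gender and for working status (restricted to the two
#' interpretable categories, working "Yes" versus retired); chi-square for
#' education (three levels) and profession; chi-square for MMSE dichotomized
#' at > 26. Professions with very low counts (military, multiple, other) are
#' always excluded from the profession test; uneducated staff is
#' additionally excluded in the main (>= 10) analysis but kept in the
#' sensitivity (>= 7) analysis. Benjamini-Hochberg columns are appended with
#' a fixed family size.
#'
#' @param cohort Tibble from [build_cohort()].
#' @param analysis `"main"` (cutoff 10 conventions) or `"sensitivity"`
#'   (cutoff 7 conventions); controls only the uneducated-staff exclusion.
#' @param q False discovery rate for the BH columns (default 0.10).
#' @param m BH family size (default 6, the number of tests in the set).
#' @return Tibble with one row per test: `test`, `test_name`, `statistic`,
#'   `df`, `p_value`, `n`, plus BH `rank`, `critical_value`, `rejected`.
#' @export
compare_groups <- function(cohort, analysis = c("main", "sensitivity"),
                           q = 0.10, m = 6) {
  analysis <- match.arg(analysis)
  d <- dplyr::filter(cohort, !is.na(.data$abundant))
  rows <- list()

  age_t <- welch_t_vectors(d$age[!d$abundant], d$age[d$abundant])
  rows$age <- dplyr::mutate(age_t, test = "age",
                            n = sum(!is.na(d$age)), .before = 1L) |>
    dplyr::select("test", "test_name", "statistic", "df", "p_value", "n")

  cat_test <- function(name, values, yates) {
    keep <- !is.na(values)
    tab <- table(values[keep], d$abundant[keep])
    res <- chi_square(as.matrix(tab), yates = yates)
    dplyr::mutate(res, test = name, .before = 1L) |>
      dplyr::select("test", "test_name", "statistic", "df", "p_value", "n")
  }

  rows$sex <- cat_test("sex_gender", d$sex_gender, yates = TRUE)
  rows$education <- cat_test(
    "education", factor(d$education, levels = c("low", "medium", "high")),
    yates = FALSE
  )

  if ("profession" %in% names(d)) {
    excl <- profession_exclusions_always()
    if (analysis == "main") excl <- c(excl, "Uneducated staff")
    prof <- ifelse(d$profession %in% excl, NA, d$profession)
    rows$profession <- cat_test("profession", prof, yates = FALSE)
  }

  if ("working_status" %in% names(d)) {
    ws <- ifelse(d$working_status %in% c("Yes", "No, I'm retired"),
                 d$working_status, NA)
    rows$working <- cat_test("working_status", ws, yates = TRUE)
  }

  if ("mmse" %in% names(d)) {
    mmse_cat <- ifelse(is.na(d$mmse), NA,
                       ifelse(d$mmse > 26, ">26", "<=26"))
    rows$mmse <- cat_test("mmse_gt26", mmse_cat, yates = TRUE)
  }

  out <- dplyr::bind_rows(rows)
  fdr <- bh_fdr(out$p_value, q = q, m = max(m, nrow(out)), labels = out$test)
  dplyr::left_join(
    out,
    dplyr::select(fdr, test = "label", "rank", "critical_value", "rejected"),
    by = "test"
  )
}

#' Covariate-adjusted regressions of cognitive scores on abundance
#'
#' Fits, per cognitive outcome, a linear regression of the score on the
#' abundance label adjusted for age, sex/gender and education, and appends
#' Benjamini-Hochberg columns over the outcome family.
#'
#' @param cohort Tibble from [build_cohort()].
#' @param outcomes Character vector of outcome columns; defaults to the six
#'   cognitive scores (animal fluency total, letter fluency, word-list
#'   total and delayed recall, figure delayed recall, vocabulary).
#' @param covariates Adjustment set, default age + sex/gender + education.
#' @param q,m BH false discovery rate and family size (defaults 0.10 and 6).
#' @return Tibble with one row per outcome: `outcome`, `B`, `ci_low`,
#'   `ci_high`, `p_value`, `n`, plus BH `rank`, `critical_value`,
#'   `rejected`.
#' @export
cognitive_regressions <- function(cohort,
                                  outcomes = intersect(
                                    c("animal_fluency_total", "letter_fluency",
                                      "wlt_total", "wlt_delayed",
                                      "rey_delayed", "dart"), names(cohort)),
                                  covariates = c("age", "sex_gender",
                                                 "education"),
                                  q = 0.10, m = 6) {
  res <- purrr::map_dfr(outcomes, function(v) {
    fit <- ols_adjusted(cohort, v, "abundant", covariates)
    dplyr::mutate(fit$result, outcome = v, .before = 1L) |>
      dplyr::select("outcome", "B", "ci_low", "ci_high", "p_value", "n")
  })
  fdr <- bh_fdr(res$p_value, q = q, m = max(m, nrow(res)),
                labels = res$outcome)
  dplyr::left_join(
    res,
    dplyr::select(fdr, outcome = "label", "rank", "critical_value",
                  "rejected"),
    by = "outcome"
  )
}
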