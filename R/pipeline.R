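#' Pipeline configuration
#'
#' Bundles file paths and analysis settings for [run_pipeline()].
#'
#' @param transcripts,scheme,covariates Input file paths (long-format
#'   transcript CSV/TSV, item/class scheme, covariate CSV).
#' @param out_dir Output directory for report files.
#' @param cutoff_main Main abundance cutoff (default 10, ~90th percentile).
#' @param cutoff_sensitivity Sensitivity cutoff (default 7, ~67th
#'   percentile); must not exceed `cutoff_main`.
#' @param cutoff_range Cutoffs for the prevalence table (default 5:15).
#' @param include_incorrect Incorrect-token policy for series detection
#'   (see [maximal_series()]).
#' @param strict_lexicon Scoring policy for unknown tokens (see
#'   [score_tokens()]).
#' @param singular_map,proper_names Optional paths: plural/singular CSV and
#'   one-name-per-line proper-name list.
#' @param q,m Benjamini-Hochberg rate and family size (defaults 0.10, 6).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(transcripts, scheme, covariates, out_dir,
                            cutoff_main = 10, cutoff_sensitivity = 7,
                            cutoff_range = 5:15,
                            include_incorrect = FALSE,
                            strict_lexicon = TRUE,
                            singular_map = NULL, proper_names = NULL,
                            q = 0.10, m = 6) {
  stopifnot(cutoff_main >= 1, cutoff_sensitivity >= 1,
            cutoff_main >= cutoff_sensitivity, all(cutoff_range >= 1))
  structure(
    list(transcripts = transcripts, scheme = scheme,
         covariates = covariates, out_dir = out_dir,
         cutoff_main = as.integer(cutoff_main),
         cutoff_sensitivity = as.integer(cutoff_sensitivity),
         cutoff_range = as.integer(cutoff_range),
         include_incorrect = include_incorrect,
         strict_lexicon = strict_lexicon,
         singular_map = singular_map, proper_names = proper_names,
         q = q, m = m),
    class = "pipeline_config"
  )
}

#' Run the full item-level fluency analysis pipeline
#'
#' Reads transcripts, scheme and covariates; scores tokens and imputes
#' placeholders; detects the longest within-class series per participant;
#' and writes the report bundle: prevalence across cutoffs, class
#' distributions by series length, baseline tables and group-comparison
#' statistics (with Benjamini-Hochberg columns) at the main and sensitivity
#' cutoffs, and the covariate-adjusted cognitive regressions. Progress and
#' row counts are logged via [message()]; data go to files only.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, a named list of the result tibbles that were written
#'   (`series`, `prevalence`, `class_distribution`, `placeholder_summary`,
#'   and per cutoff: `baseline`, `comparisons`, `regressions`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- function(...) message("[pipeline] ", ...)

  scheme <- load_scheme(config$scheme)
  log("scheme: ", dplyr::n_distinct(scheme$entries$item), " items")
  transcripts <- read_transcripts(config$transcripts)
  log("transcripts: ", dplyr::n_distinct(transcripts$participant_id),
      " participants, ", nrow(transcripts), " tokens")
  covariates <- readr::read_csv(config$covariates, show_col_types = FALSE)
  covariates$education <- recode_education(covariates$education)

  sing <- if (!is.null(config$singular_map)) {
    readr::read_csv(config$singular_map, show_col_types = FALSE)
  }
  propers <- if (!is.null(config$proper_names)) {
    readr::read_lines(config$proper_names)
  } else character(0)

  scored <- score_tokens(transcripts, scheme, singular_map = sing,
                         proper_names = propers,
                         strict_lexicon = config$strict_lexicon) |>
    impute_placeholders()
  log("scored: ", sum(!scored$correct), " incorrect tokens, ",
      sum(scored$is_placeholder), " placeholders")

  series <- longest_series(scored, scheme,
                           include_incorrect = config$include_incorrect)
  prevalence <- prevalence_table(series, cutoffs = config$cutoff_range)
  distribution <- class_distribution(series)
  plus_summary <- placeholder_stats(scored)

  out <- list(series = series, prevalence = prevalence,
              class_distribution = distribution,
              placeholder_summary = plus_summary)

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, name) {
    readr::write_csv(x, file.path(config$out_dir, paste0(name, ".csv")))
  }
  w(series, "series")
  w(prevalence, "prevalence")
  w(distribution, "class_distribution")
  w(plus_summary, "placeholder_summary")

  for (which in c("main", "sensitivity")) {
    cutoff <- if (which == "main") config$cutoff_main else config$cutoff_sensitivity
    cohort <- build_cohort(covariates, series, cutoff)
    log(which, " analysis (cutoff ", cutoff, "): ",
        sum(cohort$abundant, na.rm = TRUE), " abundant of ",
        sum(!is.na(cohort$abundant)))
    baseline <- group_summary(cohort)
    comparisons <- compare_groups(cohort, analysis = which,
                                  q = config$q, m = config$m)
    regressions <- cognitive_regressions(cohort, q = config$q, m = config$m)
    w(baseline, paste0("baseline_", which))
    w(comparisons, paste0("comparisons_", which))
    w(regressions, paste0("regressions_", which))
    out[[paste0("baseline_", which)]] <- baseline
    out[[paste0("comparisons_", which)]] <- comparisons
    out[[paste0("regressions_", which)]] <- regressions
  }
  log("done; reports in ", config$out_dir)
  invisible(out)
}
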