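#' Maximal class series in a membership sequence
#'
#' The core detector. Given a logical vector marking which tokens of a
#' recall sequence belong to a target animal class, finds every *maximal
#' series*: a contiguous span that starts and ends on a class member and
#' contains at most one internal non-member token (the single tolerated
#' interruption), such that no extension of the span is itself a valid
#' series. Series length counts class members only; the interrupting token
#' does not add to length.
#'
#' The scan is linear: member runs are located with run-length encoding; a
#' pair of runs separated by exactly one non-member token fuses into an
#' interrupted series, and a lone run is maximal only when neither flanking
#' gap has width one.
#'
#' @param member Logical vector; `member[i]` is `TRUE` when token `i`
#'   belongs to the target class.
#' @return Tibble with one row per maximal series: `span_start`, `span_end`
#'   (0-based, half-open positions into `member`), `length` (member count),
#'   `n_interruptions` (0 or 1), `interruption_position` (0-based, `NA` when
#'   uninterrupted), ordered by `span_start`.
#' @export
#' @examples
#' maximal_runs(c(TRUE, TRUE, FALSE, TRUE, TRUE))   # one series, length 4
#' maximal_runs(c(TRUE, TRUE, FALSE, FALSE, TRUE))  # two series, lengths 2, 1
maximal_runs <- function(member) {
  m <- runs_matrix(as.logical(member))
  tibble::tibble(
    span_start = m[, 1L] - 1L,          # to 0-based
    span_end = m[, 2L],                 # half-open: 1-based end == 0-based bound
    length = m[, 3L],
    n_interruptions = m[, 4L],
    interruption_position = m[, 5L] - 1L
  )
}

# algorithm core, 1-based inclusive coordinates; one row per maximal series:
# (start, end, length, n_interruptions, interruption_position)
runs_matrix <- function(member) {
  if (length(member) == 0L || !any(member)) {
    return(matrix(integer(0), ncol = 5L))
  }
  r <- rle(member)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  mem_runs <- which(r$values)
  k <- length(mem_runs)
  gap_after <- function(j) {
    # width of the non-member gap between member run j and member run j + 1
    starts[mem_runs[j + 1L]] - ends[mem_runs[j]] - 1L
  }
  rows <- list()
  for (j in seq_len(k)) {
    left_fused <- j > 1L && gap_after(j - 1L) == 1L
    right_fused <- j < k && gap_after(j) == 1L
    if (!left_fused && !right_fused) {
      rows[[length(rows) + 1L]] <- c(
        starts[mem_runs[j]], ends[mem_runs[j]],
        r$lengths[mem_runs[j]], 0L, NA_integer_
      )
    }
    if (right_fused) {
      rows[[length(rows) + 1L]] <- c(
        starts[mem_runs[j]], ends[mem_runs[j + 1L]],
        r$lengths[mem_runs[j]] + r$lengths[mem_runs[j + 1L]], 1L,
        ends[mem_runs[j]] + 1L
      )
    }
  }
  do.call(rbind, rows)
}

# Detection sequence for one participant: under the default policy incorrect
# tokens are removed first (they are not valid recalls); under
# `include_incorrect = TRUE` they stay and act as interruption candidates.
# Returns the retained rows; span coordinates downstream index this sequence.
detection_sequence <- function(tokens, include_incorrect = FALSE) {
  if (include_incorrect) tokens else tokens[tokens$correct, , drop = FALSE]
}

# A token is a member of the target class only when it is a valid recall
# (correct; placeholders are always "correct") whose scheme or imputed
# classes include the class. Incorrect tokens kept under the alternative
# policy are therefore interruption candidates, never members.
member_flags <- function(tokens, target_class) {
  has_imp <- "imputed_classes" %in% names(tokens)
  vapply(seq_len(nrow(tokens)), function(i) {
    tokens$correct[i] &&
      (target_class %in% tokens$classes[[i]] ||
         (has_imp && target_class %in% tokens$imputed_classes[[i]]))
  }, logical(1))
}

#' Maximal series of one class in one participant's transcript
#'
#' A token counts as a member of the target class when the class is among
#' its scheme classes or its imputed classes (for placeholders); correct
#' non-members and unimputable placeholders are interruption candidates.
#'
#' @param tokens Scored and imputed transcript rows for a single
#'   participant.
#' @param target_class A taxonomic class label of `scheme`.
#' @param scheme The `class_scheme` in use (validates that `target_class` is
#'   taxonomic).
#' @param include_incorrect If `FALSE` (default) incorrect tokens are
#'   removed before detection; if `TRUE` they are kept as interruption
#'   candidates. Span positions index the detection sequence (the cleaned
#'   sequence under the default policy).
#' @return Tibble of maximal series as in [maximal_runs()], with a
#'   `class_label` column.
#' @export
maximal_series <- function(tokens, target_class, scheme,
                           include_incorrect = FALSE) {
  stopifnot(inherits(scheme, "class_scheme"))
  tax <- taxonomic_labels(scheme)
  if (!target_class %in% tax) {
    stop("'", target_class, "' is not a taxonomic class of this scheme",
         call. = FALSE)
  }
  seq_tokens <- detection_sequence(tokens, include_incorrect)
  out <- maximal_runs(member_flags(seq_tokens, target_class))
  dplyr::mutate(out, class_label = target_class, .before = 1L)
}

longest_one <- function(tokens, tax, include_incorrect = FALSE) {
  seq_tokens <- detection_sequence(tokens, include_incorrect)
  best_class <- NA_character_
  best <- c(NA_integer_, NA_integer_, 0L, NA_integer_, NA_integer_)
  if (nrow(seq_tokens) > 0L) {
    for (cl in tax) {
      m <- runs_matrix(member_flags(seq_tokens, cl))
      if (nrow(m) == 0L) next
      top <- m[order(-m[, 3L], m[, 1L]), , drop = FALSE][1L, ]
      better <- top[3L] > best[3L] ||
        (top[3L] == best[3L] &&
           (is.na(best[1L]) || top[1L] < best[1L] ||
              (top[1L] == best[1L] && cl < best_class)))
      if (better) {
        best_class <- cl
        best <- top
      }
    }
  }
  tibble::tibble(
    longest_class = best_class,
    longest_length = best[3L],
    span_start = best[1L] - 1L,
    span_end = best[2L],
    n_interruptions = best[4L]
  )
}

#' Longest within-class series per participant
#'
#' Runs the series detector over every taxonomic class of the scheme and
#' keeps, per participant, the longest series found. A participant showing
#' long series in more than one class (say eight Insects and nine Birds) is
#' characterized by the longest one; ties break by earliest span start, then
#' alphabetical class label.
#'
#' @param transcripts Scored and imputed transcript tibble (whole cohort).
#' @param scheme A `class_scheme`.
#' @param include_incorrect Incorrect-token policy, see [maximal_series()].
#' @return Tibble with one row per participant: `participant_id`,
#'   `longest_class` (`NA` if no series), `longest_length` (0 if none),
#'   `span_start`, `span_end`, `n_interruptions`.
#' @export
longest_series <- function(transcripts, scheme, include_incorrect = FALSE) {
  stopifnot(inherits(scheme, "class_scheme"))
  tax <- taxonomic_labels(scheme)
  if (length(tax) == 0L) {
    stop("scheme has no taxonomic classes; series detection needs at least one",
         call. = FALSE)
  }
  transcripts |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_modify(~ longest_one(.x, tax, include_incorrect)) |>
    dplyr::ungroup()
}

#' Per-class best series lengths per participant
#'
#' @inheritParams longest_series
#' @return Tibble with one row per participant and taxonomic class that has
#'   at least one series: `participant_id`, `class_label`, `length`,
#'   `span_start`, `span_end`, `n_interruptions` (the best series of that
#'   class).
#' @export
best_series_by_class <- function(transcripts, scheme,
                                 include_incorrect = FALSE) {
  stopifnot(inherits(scheme, "class_scheme"))
  tax <- taxonomic_labels(scheme)
  transcripts |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_modify(function(d, key) {
      seq_tokens <- detection_sequence(d, include_incorrect)
      purrr::map_dfr(tax, function(cl) {
        runs <- maximal_runs(member_flags(seq_tokens, cl))
        if (nrow(runs) == 0L) return(NULL)
        top <- runs[order(-runs$length, runs$span_start), ][1L, ]
        tibble::tibble(
          class_label = cl, length = top$length, span_start = top$span_start,
          span_end = top$span_end, n_interruptions = top$n_interruptions
        )
      })
    }) |>
    dplyr::ungroup()
}

#' Label participants with abundant animal class knowledge
#'
#' @param results Tibble from [longest_series()].
#' @param cutoff Minimum longest-series length (>= 1) for the abundant
#'   label; the headline analysis uses 10 (about the 90th percentile), the
#'   sensitivity analysis 7 (about the 67th).
#' @return `results` with an added logical `abundant` column.
#' @export
classify_abundant <- function(results, cutoff) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, cutoff >= 1)
  dplyr::mutate(results, abundant = .data$longest_length >= cutoff)
}

#' Prevalence of abundant class knowledge across cutoffs
#'
#' @param results Tibble from [longest_series()].
#' @param cutoffs Ascending integer cutoffs to tabulate (default 5 to 15).
#' @param n_total Cohort size for the percentage denominator; defaults to
#'   the number of rows in `results`.
#' @return Tibble with columns `cutoff`, `n` (participants whose longest
#'   series reaches the cutoff), `percent` (of `n_total`, one decimal).
#' @export
prevalence_table <- function(results, cutoffs = 5:15,
                             n_total = nrow(results)) {
  stopifnot(!is.unsorted(cutoffs))
  if (n_total == 0L) stop("n_total must be positive", call. = FALSE)
  tibble::tibble(
    cutoff = as.integer(cutoffs),
    n = vapply(cutoffs, function(x) sum(results$longest_length >= x),
               integer(1)),
    percent = round(100 * vapply(cutoffs, function(x) {
      sum(results$longest_length >= x)
    }, integer(1)) / n_total, 1)
  )
}

#' Class distribution among participants reaching a series length
#'
#' For each length bin X, tabulates which classes the longest series belong
#' to among participants whose longest series reaches X — the view in which
#' bird and fish series come to dominate as series grow longer.
#'
#' @param results Tibble from [longest_series()].
#' @param length_bins Integer vector of length bins (default 7 to 13).
#' @return Tibble with columns `bin`, `longest_class`, `n`, `percent`
#'   (within bin, one decimal).
#' @export
class_distribution <- function(results, length_bins = 7:13) {
  purrr::map_dfr(length_bins, function(x) {
    sub <- dplyr::filter(results, .data$longest_length >= x)
    if (nrow(sub) == 0L) return(NULL)
    sub |>
      dplyr::count(.data$longest_class, name = "n") |>
      dplyr::mutate(bin = as.integer(x),
                    percent = round(100 * .data$n / sum(.data$n), 1),
                    .before = 1L) |>
      dplyr::arrange(dplyr::desc(.data$n))
  })
}
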