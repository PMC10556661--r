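#' Read fluency transcripts from a long-format file
#'
#' Expects a CSV/TSV with columns `participant_id`, `position`, `token`:
#' one row per recalled item, in recall order, positions 0-based and
#' consecutive within each participant. A literal `"+"` token is the
#' placeholder an interviewer writes when they cannot keep up with the
#' participant.
#'
#' @param path Path to the transcript file.
#' @return A tibble with columns `participant_id` (character), `position`
#'   (integer), `token` (character), `is_placeholder` (logical), ordered by
#'   participant and position.
#' @export
read_transcripts <- function(path) {
  if (!file.exists(path)) stop("transcript file not found: ", path, call. = FALSE)
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    participant_id = readr::col_character(),
    position = readr::col_integer(),
    token = readr::col_character()
  ), progress = FALSE)
  as_transcripts(df)
}

#' Coerce a data frame to a validated transcript tibble
#'
#' @param df Data frame with `participant_id`, `position`, `token` columns.
#' @return Validated transcript tibble (see [read_transcripts()]).
#' @export
as_transcripts <- function(df) {
  stopifnot(all(c("participant_id", "position", "token") %in% names(df)))
  out <- tibble::tibble(
    participant_id = as.character(df$participant_id),
    position = as.integer(df$position),
    token = as.character(df$token)
  ) |>
    dplyr::arrange(.data$participant_id, .data$position)
  if (any(is.na(out$participant_id) | out$participant_id == "")) {
    stop("empty participant_id in transcripts", call. = FALSE)
  }
  dup <- out |>
    dplyr::count(.data$participant_id, .data$position) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    stop("duplicate (participant, position) row for participant '",
         dup$participant_id[1L], "' at position ", dup$position[1L],
         call. = FALSE)
  }
  gaps <- out |>
    dplyr::summarise(
      ok = identical(.data$position, seq(0L, length.out = dplyr::n())),
      .by = "participant_id"
    ) |>
    dplyr::filter(!.data$ok)
  if (nrow(gaps) > 0L) {
    stop("positions of participant '", gaps$participant_id[1L],
         "' are not consecutive from 0", call. = FALSE)
  }
  out$is_placeholder <- out$token == "+"
  out
}

#' Score transcript tokens for correctness
#'
#' Applies the scoring rules used for item-level animal fluency: a token is
#' incorrect when it is a repetition of an earlier token, a plural form of a
#' singular already named, a proper (pet/character) name, or outside the
#' target-language lexicon. Rules are applied in that precedence order; the
#' first occurrence of an item is always eligible to be correct, and
#' placeholders are never marked incorrect.
#'
#' @param transcripts Transcript tibble from [read_transcripts()] /
#'   [as_transcripts()].
#' @param scheme A `class_scheme` used as the target-language lexicon and to
#'   attach each token's animal classes.
#' @param singular_map Optional data frame with columns `plural`, `singular`
#'   mapping plural surface forms to their singular.
#' @param proper_names Optional character vector of proper names (popular
#'   animal names, pet names) scored incorrect.
#' @param strict_lexicon If `TRUE` (default) a token absent from both the
#'   scheme and the singular map is scored incorrect as non-target-language;
#'   if `FALSE` unknown tokens are treated as correct but classless.
#' @return The transcript tibble with added columns `item` (normalized,
#'   singularized form), `correct` (logical), `incorrect_reason` (one of
#'   `"none"`, `"repetition"`, `"plural_after_singular"`, `"proper_name"`,
#'   `"non_target_language"`), and `classes` (list column of class labels).
#' @export
score_tokens <- function(transcripts, scheme, singular_map = NULL,
                         proper_names = character(), strict_lexicon = TRUE) {
  stopifnot(inherits(scheme, "class_scheme"))
  sing <- character(0)
  if (!is.null(singular_map)) {
    stopifnot(all(c("plural", "singular") %in% names(singular_map)))
    sing <- stats::setNames(normalize_item(singular_map$singular),
                            normalize_item(singular_map$plural))
  }
  propers <- normalize_item(proper_names)

  score_one <- function(tokens, placeholder) {
    n <- length(tokens)
    item <- character(n)
    reason <- character(n)
    classes <- vector("list", n)
    seen <- character(0)
    for (i in seq_len(n)) {
      if (placeholder[i]) {
        item[i] <- "+"
        reason[i] <- "none"
        classes[[i]] <- character(0)
        next
      }
      norm <- normalize_item(tokens[i])
      mapped <- unname(sing[norm])
      in_scheme <- !is.null(scheme$lookup[[norm]])
      resolved <- if (!in_scheme && !is.na(mapped)) mapped else norm
      item[i] <- resolved
      classes[[i]] <- classes_of(scheme, resolved)
      reason[i] <-
        if (norm %in% seen) "repetition"
        else if (!is.na(mapped) && mapped %in% seen) "plural_after_singular"
        else if (norm %in% propers) "proper_name"
        else if (strict_lexicon && !in_scheme && is.na(mapped)) "non_target_language"
        else "none"
      seen <- c(seen, norm)
    }
    list(item = item, incorrect_reason = reason, classes = classes)
  }

  transcripts |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_modify(function(d, key) {
      s <- score_one(d$token, d$is_placeholder)
      d$item <- s$item
      d$incorrect_reason <- s$incorrect_reason
      d$classes <- s$classes
      d
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(correct = .data$incorrect_reason == "none")
}

#' Impute classes for plus-sign placeholders
#'
#' For every maximal run of consecutive placeholders whose nearest correct
#' non-placeholder neighbours on both sides share at least one animal class,
#' each placeholder in the run is imputed with that shared class set: when an
#' interviewer misses items in the middle of, say, a bird series, the missed
#' items were most plausibly birds too. Runs without a shared flanking class
#' are left unimputed and act as ordinary interrupting material downstream.
#'
#' @param transcripts Scored transcript tibble from [score_tokens()].
#' @return The tibble with an added `imputed_classes` list column (empty
#'   character vector except for imputed placeholders). Non-placeholder
#'   tokens are never altered.
#' @export
impute_placeholders <- function(transcripts) {
  stopifnot(all(c("classes", "correct") %in% names(transcripts)))
  impute_one <- function(placeholder, correct, classes) {
    n <- length(placeholder)
    imp <- replicate(n, character(0), simplify = FALSE)
    if (!any(placeholder)) return(imp)
    r <- rle(placeholder)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      lo <- starts[k]; hi <- ends[k]
      li <- lo - 1L; ri <- hi + 1L
      if (li < 1L || ri > n) next
      if (!correct[li] || !correct[ri]) next
      shared <- intersect(classes[[li]], classes[[ri]])
      if (length(shared) > 0L) for (i in lo:hi) imp[[i]] <- shared
    }
    imp
  }
  transcripts |>
    dplyr::mutate(
      imputed_classes = impute_one(.data$is_placeholder, .data$correct,
                                   .data$classes),
      .by = "participant_id"
    )
}

#' Summarize placeholder occurrence across a cohort
#'
#' @param transcripts Scored and imputed transcript tibble
#'   ([impute_placeholders()]).
#' @return A one-row tibble: total participants; counts and percentages of
#'   participants with at least one placeholder, with more than one
#'   placeholder, and with more than one consecutive placeholder inside a
#'   same-class (imputable) context. Percentages are of the total cohort,
#'   rounded to one decimal.
#' @export
placeholder_stats <- function(transcripts) {
  stopifnot("imputed_classes" %in% names(transcripts))
  per <- transcripts |>
    dplyr::summarise(
      n_plus = sum(.data$is_placeholder),
      consec_same_class = {
        r <- rle(.data$is_placeholder)
        ends <- cumsum(r$lengths)
        runs <- which(r$values & r$lengths > 1L)
        any(vapply(runs, function(k) {
          length(.data$imputed_classes[[ends[k]]]) > 0L
        }, logical(1)))
      },
      .by = "participant_id"
    )
  n <- nrow(per)
  pct <- function(k) round(100 * k / n, 1)
  tibble::tibble(
    n_participants = n,
    n_with_placeholder = sum(per$n_plus >= 1L),
    pct_with_placeholder = pct(sum(per$n_plus >= 1L)),
    n_with_multiple = sum(per$n_plus > 1L),
    pct_with_multiple = pct(sum(per$n_plus > 1L)),
    n_with_consecutive_same_class = sum(per$consec_same_class),
    pct_with_consecutive_same_class = pct(sum(per$consec_same_class))
  )
}
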