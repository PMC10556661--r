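#' Simulation parameters for a synthetic animal-fluency cohort
#'
#' Constructs and validates the parameter set of the synthetic-cohort
#' generator. Defaults emulate a Dutch middle-aged-to-older vascular cohort
#' doing two-minute animal fluency: 736 participants, age 57.6 +/- 9.4,
#' 18% women, about 25 +/- 9 recalled items, with bird/fish-weighted
#' clustered class runs.
#'
#' @param n_participants Cohort size (default 736).
#' @param age_mean,age_sd Age distribution in years (defaults 57.6, 9.4).
#' @param frac_female Proportion of women among non-planted participants
#'   (default 0.18; the cohort marginal is close to this because the
#'   planted fraction is small).
#' @param total_mean,total_sd Mean and SD of the number of recalled items
#'   per two-minute transcript (defaults 25.2, 8.7; floored at 5).
#' @param class_weights Named numeric vector of selection weights over the
#'   twelve taxonomic classes for background recall; bird/fish-heavy by
#'   default.
#' @param planted_class_weights Class weights for the planted long run;
#'   defaults to a distribution concentrated on Bird and Fish, reflecting
#'   that long series are dominated by those classes.
#' @param pool_size Items per class in the generated scheme (default 40).
#' @param p_stay Probability of continuing the current class run at each
#'   background step; run lengths are truncated-geometric (default 0.55).
#' @param max_background_run Cap on background run lengths; defaults to
#'   `cutoff - 1` so that, with the no-early-revisit rule, no unplanted
#'   participant can reach the planted cutoff.
#' @param planted_abundant Fraction of participants given a planted long
#'   run (default 0.106, the observed prevalence at the >= 10 cutoff).
#' @param cutoff Planted-run cutoff (default 10, the 90th-percentile
#'   definition of abundant class knowledge).
#' @param planted_run_geom Geometric tail parameter of the planted run
#'   length beyond the cutoff (default 0.37, matching the observed decay of
#'   prevalence from >= 10 to >= 15).
#' @param age_offset Mean age shift of planted participants in years
#'   (default 2.3).
#' @param male_odds Odds multiplier for being male among planted
#'   participants (default 2.8).
#' @param retired_odds Odds multiplier for being retired among planted
#'   participants (default 1.8).
#' @param fluency_offset Extra mean recalled items for planted participants
#'   (default 5.6).
#' @param placeholder_rate Per-token probability that the interviewer wrote
#'   a plus sign instead of the item (default 0.004, reproducing roughly
#'   one participant in ten having any placeholder).
#' @param repetition_rate Per-token probability of inserting a repetition
#'   of an earlier item after it (default 0.02).
#' @param seed Integer seed; the seed fully determines all output.
#' @return A validated `sim_params` list.
#' @export
sim_params <- function(n_participants = 736,
                       age_mean = 57.6, age_sd = 9.4,
                       frac_female = 0.18,
                       total_mean = 25.2, total_sd = 8.7,
                       class_weights = NULL,
                       planted_class_weights = NULL,
                       pool_size = 40,
                       p_stay = 0.55,
                       max_background_run = NULL,
                       planted_abundant = 0.106,
                       cutoff = 10,
                       planted_run_geom = 0.37,
                       age_offset = 2.3,
                       male_odds = 2.8,
                       retired_odds = 1.8,
                       fluency_offset = 5.6,
                       placeholder_rate = 0.004,
                       repetition_rate = 0.02,
                       seed = 1L) {
  if (is.null(class_weights)) {
    class_weights <- c(
      Bird = 0.20, Fish = 0.16, Insects = 0.11, Feline = 0.09,
      Canine = 0.08, Bovine = 0.08, Rodents = 0.07, Primates = 0.06,
      `Reptile/Amphibian` = 0.06, Deers = 0.04, Weasels = 0.03, Worms = 0.02
    )
  }
  if (is.null(planted_class_weights)) {
    planted_class_weights <- c(
      Bird = 0.45, Fish = 0.28, Insects = 0.08, Feline = 0.03,
      Canine = 0.03, Bovine = 0.03, Rodents = 0.03, Primates = 0.02,
      `Reptile/Amphibian` = 0.02, Deers = 0.01, Weasels = 0.01, Worms = 0.01
    )
  }
  if (is.null(max_background_run)) max_background_run <- cutoff - 1L
  p <- list(
    n_participants = as.integer(n_participants), age_mean = age_mean,
    age_sd = age_sd, frac_female = frac_female, total_mean = total_mean,
    total_sd = total_sd, class_weights = class_weights,
    planted_class_weights = planted_class_weights,
    pool_size = as.integer(pool_size), p_stay = p_stay,
    max_background_run = as.integer(max_background_run),
    planted_abundant = planted_abundant, cutoff = as.integer(cutoff),
    planted_run_geom = planted_run_geom, age_offset = age_offset,
    male_odds = male_odds, retired_odds = retired_odds,
    fluency_offset = fluency_offset, placeholder_rate = placeholder_rate,
    repetition_rate = repetition_rate, seed = as.integer(seed)
  )
  probs <- c(p$frac_female, p$p_stay, p$planted_abundant,
             p$planted_run_geom, p$placeholder_rate, p$repetition_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(p$n_participants >= 0, p$age_sd > 0, p$total_sd > 0,
            all(p$class_weights > 0), all(p$planted_class_weights > 0),
            setequal(names(p$class_weights), taxonomic_classes()),
            setequal(names(p$planted_class_weights), taxonomic_classes()),
            p$cutoff >= 1, p$max_background_run >= 1)
  if (p$cutoff > p$pool_size) {
    stop("infeasible parameters: planted run length (cutoff ", p$cutoff,
         ") exceeds the per-class item pool (", p$pool_size, ")",
         call. = FALSE)
  }
  class(p) <- "sim_params"
  p
}

#' Default SMART-MR-like simulation preset
#'
#' The preset used throughout the package's examples and tests: N = 736,
#' age 57.6 +/- 9.4, 18% women, 25.2 +/- 8.7 items per transcript, planted
#' abundance fraction 0.106 at cutoff 10 with bird/fish-weighted long runs.
#'
#' @param ... Overrides passed to [sim_params()].
#' @return A `sim_params` object.
#' @export
default_params <- function(...) {
  sim_params(...)
}

#' Synthetic class scheme matching a parameter set
#'
#' Builds the deterministic item-pool scheme the generator draws from:
#' `pool_size` synthetic items per taxonomic class, named
#' `<class>_01 ... <class>_NN`.
#'
#' @param params A `sim_params` object.
#' @return A `class_scheme`.
#' @export
sim_scheme <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  classes <- names(params$class_weights)
  stub <- gsub("[^a-z]+", "", tolower(classes))
  entries <- purrr::map2_dfr(classes, stub, function(cl, s) {
    tibble::tibble(
      item = sprintf("%s_%02d", s, seq_len(params$pool_size)),
      class = cl
    )
  })
  class_scheme(entries, taxonomic = classes, language = "synthetic")
}

# one participant's token sequence: background patch process plus an
# optional planted run. The no-early-revisit rule (a class may not recur
# until at least two tokens of other classes have intervened) guarantees
# that background material can never form a series longer than
# max_background_run, so abundance at `cutoff` is exactly the planted flag
# when noise is off.
simulate_sequence <- function(n_tokens, planted, planted_class, planted_len,
                              params, pools) {
  classes <- names(params$class_weights)
  w <- params$class_weights
  used <- stats::setNames(integer(length(classes)), classes)

  draw_items <- function(cl, k) {
    start <- used[[cl]]
    if (start + k > params$pool_size) return(NULL)
    used[[cl]] <<- start + k
    pools[[cl]][(start + 1L):(start + k)]
  }

  planted_tokens <- character(0)
  if (planted) {
    planted_len <- min(planted_len, params$pool_size)
    planted_tokens <- draw_items(planted_class, planted_len)
    n_tokens <- max(n_tokens, planted_len)
  }
  n_background <- n_tokens - length(planted_tokens)

  patches <- list()
  prev_class <- NA_character_
  prev_prev_class <- NA_character_
  prev_len <- NA_integer_
  remaining <- n_background
  while (remaining > 0L) {
    banned <- prev_class
    if (!is.na(prev_len) && prev_len == 1L) banned <- c(banned, prev_prev_class)
    avail <- classes[!classes %in% banned &
                       used[classes] < params$pool_size]
    if (length(avail) == 0L) break
    cl <- sample(avail, 1L, prob = w[avail])
    len <- 1L + min(stats::rgeom(1L, 1 - params$p_stay),
                    params$max_background_run - 1L)
    len <- min(len, remaining, params$pool_size - used[[cl]])
    items <- draw_items(cl, len)
    patches[[length(patches) + 1L]] <- items
    prev_prev_class <- prev_class
    prev_class <- cl
    prev_len <- len
    remaining <- remaining - len
  }

  if (planted) {
    at <- sample.int(length(patches) + 1L, 1L) - 1L
    patches <- append(patches, list(planted_tokens), after = at)
  }
  unlist(patches, use.names = FALSE)
}

logit_shift <- function(p, odds_mult) {
  stats::plogis(stats::qlogis(p) + log(odds_mult))
}

working_status_levels <- function() {
  c("Yes", "No, I'm looking for a job", "No, I'm houseman/wife",
    "No, I'm retired", "No, I'm incapacitated", "Other")
}

#' Simulate covariates for a set of planted abundance flags
#'
#' The covariate half of the generator, usable on its own for calibration
#' and power studies that do not need transcripts. Planted participants get
#' the configured age offset and male/retired odds multipliers; cognitive
#' scores get the configured mean shifts.
#'
#' @param planted Logical vector of planted-abundance flags (one per
#'   participant).
#' @param params A `sim_params` object.
#' @param n_tokens Optional integer vector of recalled-item counts used as
#'   the animal fluency total; simulated from the configured total-score
#'   distribution when missing.
#' @return Covariate tibble: `participant_id`, `age`, `sex_gender`,
#'   `education`, `profession`, `working_status`, `animal_fluency_total`,
#'   `letter_fluency`, `mmse`, `wlt_total`, `wlt_delayed`, `rey_delayed`,
#'   `dart`.
#' @export
simulate_covariates <- function(planted, params, n_tokens = NULL) {
  n <- length(planted)
  if (is.null(n_tokens)) {
    n_tokens <- pmax(5L, round(stats::rnorm(
      n, params$total_mean + planted * params$fluency_offset,
      params$total_sd
    )))
  }
  p_fem <- ifelse(planted, logit_shift(params$frac_female, 1 / params$male_odds),
                  params$frac_female)
  edu_p <- c(low = 0.090, medium = 0.648, high = 0.254)
  edu_p <- edu_p / sum(edu_p)
  prof_levels <- c("Executive profession", "Senior administrative",
                   "Technical and related professions",
                   "Administrative and sales professions",
                   "Craft professions", "Uneducated staff", "Self-employed",
                   "Military profession", "Multiple professions", "Other")
  prof_p <- c(46, 123, 101, 93, 120, 48, 72, 11, 20, 5)
  prof_p <- prof_p / sum(prof_p)
  ws_levels <- working_status_levels()
  ws_base <- c(269, 15, 42, 330, 64, 11)
  ws_base <- ws_base / sum(ws_base)
  draw_ws <- function(is_planted) {
    p <- ws_base
    if (is_planted) {
      pr <- logit_shift(p[4L], params$retired_odds)
      p[-4L] <- p[-4L] * (1 - pr) / (1 - p[4L])
      p[4L] <- pr
    }
    sample(ws_levels, 1L, prob = p)
  }
  tibble::tibble(
    participant_id = sprintf("p%04d", seq_len(n)),
    age = round(stats::rnorm(n, params$age_mean + planted * params$age_offset,
                             params$age_sd), 1),
    sex_gender = ifelse(stats::runif(n) < p_fem, "female", "male"),
    education = sample(names(edu_p), n, replace = TRUE, prob = edu_p),
    profession = sample(prof_levels, n, replace = TRUE, prob = prof_p),
    working_status = vapply(planted, draw_ws, character(1)),
    animal_fluency_total = as.integer(n_tokens),
    letter_fluency = round(stats::rnorm(n, 11.4 + planted * 1.1, 4.6), 0),
    mmse = pmin(30, round(stats::rnorm(n, 28.6, 1.7))),
    wlt_total = round(stats::rnorm(n, 28.5 + planted * 1.8, 10.4), 0),
    wlt_delayed = round(stats::rnorm(n, 8.7 + planted * 0.6, 3.3), 0),
    rey_delayed = round(stats::rnorm(n, 19.4 + planted * 0.6, 6.4), 1),
    dart = round(stats::rnorm(n, 48.7 - planted * 0.2, 14.8), 0)
  )
}

#' Replace token surfaces with plus-sign placeholders
#'
#' Emulates the interviewer falling behind: each token is independently
#' replaced by a literal `"+"` at the given rate, preserving positions.
#'
#' @param transcripts Transcript tibble.
#' @param rate Per-token replacement probability in \[0, 1\].
#' @param seed Optional integer seed (set when called standalone; inside
#'   [generate_cohort()] randomness flows from the cohort seed).
#' @return List with `transcripts` (corrupted tibble) and `placeholders`
#'   (tibble of `participant_id`, `position`, `original_token` logging every
#'   replacement).
#' @export
corrupt_with_placeholders <- function(transcripts, rate, seed = NULL) {
  stopifnot(rate >= 0, rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  hit <- stats::runif(nrow(transcripts)) < rate
  log <- tibble::tibble(
    participant_id = transcripts$participant_id[hit],
    position = transcripts$position[hit],
    original_token = transcripts$token[hit]
  )
  transcripts$token[hit] <- "+"
  if ("is_placeholder" %in% names(transcripts)) {
    transcripts$is_placeholder <- transcripts$token == "+"
  }
  list(transcripts = transcripts, placeholders = log)
}

#' Generate a synthetic animal-fluency cohort
#'
#' Produces transcripts, covariates and a ground-truth log with the
#' statistical structure the analysis pipeline assumes: clustered class
#' runs from a two-state patch process, planted long runs in a configurable
#' fraction of participants with attached covariate shifts, plus-sign
#' dropout and repetition noise. Output is fully determined by
#' `params$seed`.
#'
#' @param params A `sim_params` object, e.g. [default_params()].
#' @return List of class `fluency_cohort`: `transcripts` (long tibble),
#'   `covariates`, `ground_truth` (per participant: `planted`,
#'   `planted_class`, `planted_length`, `n_placeholders`), `placeholder_log`
#'   (exact corrupted positions), `scheme` (the generating `class_scheme`),
#'   and `params`.
#' @export
generate_cohort <- function(params = default_params()) {
  stopifnot(inherits(params, "sim_params"))
  scheme <- sim_scheme(params)
  classes <- names(params$class_weights)
  pools <- split(scheme$entries$item, scheme$entries$class)[classes]
  n <- params$n_participants
  empty <- list(
    transcripts = tibble::tibble(participant_id = character(0),
                                 position = integer(0), token = character(0),
                                 is_placeholder = logical(0)),
    covariates = simulate_covariates(logical(0), params),
    ground_truth = tibble::tibble(participant_id = character(0),
                                  planted = logical(0),
                                  planted_class = character(0),
                                  planted_length = integer(0),
                                  n_placeholders = integer(0)),
    placeholder_log = tibble::tibble(participant_id = character(0),
                                     position = integer(0),
                                     original_token = character(0)),
    scheme = scheme, params = params
  )
  if (n == 0L) return(structure(empty, class = "fluency_cohort"))

  old <- globalenv()$.Random.seed
  set.seed(params$seed)

  planted <- stats::runif(n) < params$planted_abundant
  planted_class <- sample(classes, n, replace = TRUE,
                          prob = params$planted_class_weights[classes])
  planted_len <- params$cutoff + stats::rgeom(n, params$planted_run_geom)
  planted_len <- pmin(planted_len, params$pool_size)
  n_tokens <- pmax(5L, round(stats::rnorm(
    n, params$total_mean + planted * params$fluency_offset, params$total_sd
  )))

  ids <- sprintf("p%04d", seq_len(n))
  seqs <- vector("list", n)
  for (i in seq_len(n)) {
    tokens <- simulate_sequence(n_tokens[i], planted[i], planted_class[i],
                                planted_len[i], params, pools)
    if (params$repetition_rate > 0 && length(tokens) > 1L) {
      ins <- which(stats::runif(length(tokens)) < params$repetition_rate)
      ins <- ins[ins > 1L]
      for (j in rev(ins)) {
        rep_tok <- tokens[sample.int(j - 1L, 1L)]
        tokens <- append(tokens, rep_tok, after = j)
      }
    }
    seqs[[i]] <- tokens
  }

  transcripts <- tibble::tibble(
    participant_id = rep(ids, lengths(seqs)),
    position = unlist(lapply(lengths(seqs), function(k) seq_len(k) - 1L)),
    token = unlist(seqs, use.names = FALSE)
  )
  corrupted <- corrupt_with_placeholders(transcripts,
                                         params$placeholder_rate)
  transcripts <- corrupted$transcripts
  transcripts$is_placeholder <- transcripts$token == "+"

  covariates <- simulate_covariates(planted, params, n_tokens = n_tokens)
  plus_counts <- table(factor(corrupted$placeholders$participant_id,
                              levels = ids))
  ground_truth <- tibble::tibble(
    participant_id = ids,
    planted = planted,
    planted_class = ifelse(planted, planted_class, NA_character_),
    planted_length = ifelse(planted, planted_len, NA_integer_),
    n_placeholders = as.integer(plus_counts)
  )

  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  structure(
    list(transcripts = transcripts, covariates = covariates,
         ground_truth = ground_truth,
         placeholder_log = corrupted$placeholders,
         scheme = scheme, params = params),
    class = "fluency_cohort"
  )
}

#' @export
print.fluency_cohort <- function(x, ...) {
  cat("<fluency_cohort> ", nrow(x$ground_truth), " participants, ",
      nrow(x$transcripts), " tokens, ",
      sum(x$ground_truth$planted), " planted abundant (cutoff ",
      x$params$cutoff, ")\n", sep = "")
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits the same plain-text schemas the readers consume: `transcripts.csv`
#' (long format), `covariates.csv`, `scheme.csv`, `ground_truth.csv`, and
#' `params.json`.
#'
#' @param cohort A `fluency_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "fluency_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(cohort$transcripts[c("participant_id", "position", "token")],
                   file.path(dir, "transcripts.csv"))
  readr::write_csv(cohort$covariates, file.path(dir, "covariates.csv"))
  write_scheme(cohort$scheme, file.path(dir, "scheme.csv"))
  readr::write_csv(cohort$ground_truth, file.path(dir, "ground_truth.csv"))
  jsonlite::write_json(unclass(cohort$params)[
    !names(unclass(cohort$params)) %in%
      c("class_weights", "planted_class_weights")
  ], file.path(dir, "params.json"), auto_unbox = TRUE)
  invisible(dir)
}
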