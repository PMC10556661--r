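test_that("maximal_runs handles the canonical bridge and block cases", {
  expect_equal(nrow(maximal_runs(logical(0))), 0L)
  expect_equal(nrow(maximal_runs(c(FALSE, FALSE))), 0L)

  # B B x B B -> one series spanning everything, one interruption
  r <- maximal_runs(c(TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_equal(nrow(r), 1L)
  expect_equal(r$span_start, 0L)
  expect_equal(r$span_end, 5L)
  expect_equal(r$length, 4L)
  expect_equal(r$n_interruptions, 1L)
  expect_equal(r$interruption_position, 2L)

  # B B x x B -> two consecutive non-members cannot be bridged
  r2 <- maximal_runs(c(TRUE, TRUE, FALSE, FALSE, TRUE))
  expect_equal(max(r2$length), 2L)
  expect_equal(nrow(r2), 2L)

  # B x B x B -> two overlapping interrupted series, the middle run in both
  r3 <- maximal_runs(c(TRUE, FALSE, TRUE, FALSE, TRUE))
  expect_equal(nrow(r3), 2L)
  expect_equal(r3$length, c(2L, 2L))
  expect_equal(r3$span_start, c(0L, 2L))
})

test_that("detector agrees with the brute-force window oracle", {
  withr::with_seed(101, {
    for (i in 1:2000) {
      member <- random_membership()
      r <- maximal_runs(member)
      best <- if (nrow(r) == 0L) 0L else max(r$length)
      expect_identical(best, oracle_best_length(member))
    }
  })
})

test_that("reported series match the oracle's maximal windows structurally", {
  withr::with_seed(202, {
    for (i in 1:300) {
      member <- random_membership(max_len = 20L, n_classes = 3L)
      r <- maximal_runs(member)
      wins <- oracle_maximal_windows(member)
      expect_equal(nrow(r), nrow(wins))
      if (nrow(r) > 0L) {
        expect_equal(r$span_start, unname(wins[, "start"]) - 1L)
        expect_equal(r$span_end, unname(wins[, "end"]))
        expect_equal(r$length, unname(wins[, "members"]))
        # TYPE invariants
        expect_true(all(r$length >= 1L))
        expect_true(all(r$span_end - r$span_start >= r$length))
        expect_true(all(r$span_end - r$span_start <= r$length + 1L))
        expect_true(all(member[r$span_start + 1L]))
        expect_true(all(member[r$span_end]))
        with_int <- r$n_interruptions == 1L
        expect_true(all(is.na(r$interruption_position[!with_int])))
        expect_true(all(r$interruption_position[with_int] > r$span_start[with_int]))
        expect_true(all(r$interruption_position[with_int] < r$span_end[with_int] - 1L))
      }
    }
  })
})

test_that("removing a member never increases the best length; appending one never decreases it", {
  withr::with_seed(303, {
    for (i in 1:200) {
      member <- random_membership(max_len = 15L)
      if (!any(member)) next
      best <- oracle_best_length(member)
      r <- maximal_runs(member)
      expect_equal(if (nrow(r)) max(r$length) else 0L, best)
      drop_at <- sample(which(member), 1L)
      r_drop <- maximal_runs(member[-drop_at])
      expect_lte(if (nrow(r_drop)) max(r_drop$length) else 0L, best)
      r_app <- maximal_runs(c(member, TRUE))
      expect_gte(if (nrow(r_app)) max(r_app$length) else 0L, best)
    }
  })
})

test_that("maximal_series rejects non-taxonomic targets and counts imputed members", {
  scheme <- demo_scheme()
  sc <- impute_placeholders(score_tokens(
    make_transcripts(c("robin", "+", "sparrow", "salmon")), scheme))
  expect_error(maximal_series(sc, "pets", scheme), "not a taxonomic class")
  r <- maximal_series(sc, "Bird", scheme)
  expect_equal(max(r$length), 3L)  # the imputed plus counts as a Bird
  expect_equal(r$class_label[1], "Bird")
})

test_that("incorrect tokens are deleted by default but can interrupt under the alternative policy", {
  scheme <- demo_scheme()
  # robin, sparrow, repeated robin, eagle, owl: cleaned -> 4 consecutive birds
  sc <- impute_placeholders(score_tokens(
    make_transcripts(c("robin", "sparrow", "robin", "eagle", "owl")), scheme))
  r_default <- maximal_series(sc, "Bird", scheme)
  expect_equal(max(r_default$length), 4L)
  expect_equal(r_default$n_interruptions[which.max(r_default$length)], 0L)
  r_keep <- maximal_series(sc, "Bird", scheme, include_incorrect = TRUE)
  expect_equal(max(r_keep$length), 4L)
  expect_equal(r_keep$n_interruptions[which.max(r_keep$length)], 1L)
})

test_that("longest_series selects the longest class with deterministic tie-breaks", {
  scheme <- demo_scheme()
  insects <- c("ant", "bee", "wasp", "beetle", "butterfly", "fly",
               "mosquito", "grasshopper")
  birds <- c("robin", "sparrow", "eagle", "pigeon", "seagull", "owl",
             "blackbird", "magpie", "heron")
  sc <- impute_placeholders(score_tokens(
    make_transcripts(c(insects, "cow", birds)), scheme))
  res <- longest_series(sc, scheme)
  expect_equal(res$longest_class, "Bird")
  expect_equal(res$longest_length, 9L)

  # equal lengths: earlier span start wins
  sc2 <- impute_placeholders(score_tokens(make_transcripts(
    c("robin", "sparrow", "eagle", "cow", "bull", "salmon", "cod", "eel")),
    scheme))
  res2 <- longest_series(sc2, scheme)
  expect_equal(res2$longest_class, "Bird")
  expect_equal(res2$span_start, 0L)

  # same span and length under two classes: alphabetical label wins
  sc3 <- impute_placeholders(score_tokens(
    make_transcripts(c("caterpillar", "cow")), scheme))
  res3 <- longest_series(sc3, scheme)
  expect_equal(res3$longest_length, 1L)
  expect_equal(res3$longest_class, "Insects")  # Insects < Worms
})

test_that("all-one-class transcripts yield an uninterrupted full-length series", {
  scheme <- demo_scheme()
  fish <- c("salmon", "herring", "cod", "eel", "pike", "carp")
  res <- longest_series(
    impute_placeholders(score_tokens(make_transcripts(fish), scheme)), scheme)
  expect_equal(res$longest_class, "Fish")
  expect_equal(res$longest_length, 6L)
  expect_equal(res$n_interruptions, 0L)
})

test_that("imputation can only lengthen the longest series", {
  params <- default_params(n_participants = 80, placeholder_rate = 0.08,
                           repetition_rate = 0, seed = 77)
  co <- generate_cohort(params)
  scored <- score_tokens(co$transcripts, co$scheme)
  before <- longest_series(scored, co$scheme)
  after <- longest_series(impute_placeholders(scored), co$scheme)
  expect_true(all(after$longest_length >= before$longest_length))
})

test_that("prevalence_table counts and rounds like a cohort prevalence table", {
  res <- tibble::tibble(participant_id = paste0("p", 1:4),
                        longest_length = c(5L, 7L, 10L, 15L))
  tab <- prevalence_table(res, cutoffs = c(5, 7, 10, 15))
  expect_equal(tab$n, c(4L, 3L, 2L, 1L))
  expect_equal(tab$percent, c(100, 75, 50, 25))
  expect_error(prevalence_table(res[0, ], cutoffs = 5), "positive")

  # published-count arithmetic: 78 of 736 at the >= 10 cutoff is 10.6%
  ref <- tibble::tibble(participant_id = 1:78, longest_length = 10L)
  expect_equal(prevalence_table(ref, cutoffs = 10, n_total = 736)$percent, 10.6)
})

test_that("prevalence is monotone non-increasing in the cutoff", {
  withr::with_seed(55, {
    res <- tibble::tibble(participant_id = paste0("p", 1:300),
                          longest_length = sample(0:16, 300, replace = TRUE))
    tab <- prevalence_table(res, cutoffs = 1:16)
    expect_true(all(diff(tab$n) <= 0L))
    expect_true(all(diff(tab$percent) <= 0))
  })
})

test_that("class_distribution tabulates longest classes per length bin", {
  res <- tibble::tibble(participant_id = c("a", "b"),
                        longest_class = c("Bird", "Fish"),
                        longest_length = c(7L, 10L))
  d <- class_distribution(res, length_bins = c(7, 10))
  expect_equal(sort(d$longest_class[d$bin == 7]), c("Bird", "Fish"))
  expect_equal(d$longest_class[d$bin == 10], "Fish")
  expect_equal(d$percent[d$bin == 10], 100)

  all_birds <- tibble::tibble(participant_id = paste0("p", 1:5),
                              longest_class = "Bird",
                              longest_length = c(7L, 8L, 9L, 10L, 11L))
  d2 <- class_distribution(all_birds, length_bins = 7:9)
  expect_true(all(d2$percent == 100))
  expect_true(all(d2$longest_class == "Bird"))
})

test_that("a class planted in long runs dominates the upper length bins", {
  params <- default_params(
    n_participants = 400, seed = 13, placeholder_rate = 0,
    repetition_rate = 0, planted_abundant = 0.15,
    class_weights = c(Bird = 0.60, Fish = 0.05, Insects = 0.05,
                      Feline = 0.04, Canine = 0.04, Bovine = 0.04,
                      Rodents = 0.04, Primates = 0.04,
                      `Reptile/Amphibian` = 0.04, Deers = 0.02,
                      Weasels = 0.02, Worms = 0.02)
  )
  co <- generate_cohort(params)
  res <- longest_series(impute_placeholders(score_tokens(co$transcripts,
                                                         co$scheme)),
                        co$scheme)
  d <- class_distribution(res, length_bins = c(5, 10))
  share <- function(bin) {
    sub <- d[d$bin == bin, ]
    sub$percent[sub$longest_class == "Bird"] / 100
  }
  expect_gt(share(10), share(5))
})

test_that("abundance labels are boundary-correct and monotone across cutoffs", {
  res <- tibble::tibble(participant_id = c("a", "b"),
                        longest_length = c(10L, 9L))
  expect_equal(classify_abundant(res, 10)$abundant, c(TRUE, FALSE))
  withr::with_seed(7, {
    res2 <- tibble::tibble(participant_id = paste0("p", 1:100),
                           longest_length = sample(0:15, 100, replace = TRUE))
    lab7 <- classify_abundant(res2, 7)$abundant
    lab10 <- classify_abundant(res2, 10)$abundant
    expect_true(all(lab7[lab10]))
  })
})

test_that("best_series_by_class reports one best series per class present", {
  scheme <- demo_scheme()
  sc <- impute_placeholders(score_tokens(
    make_transcripts(c("robin", "sparrow", "cow", "eagle", "salmon")), scheme))
  per <- best_series_by_class(sc, scheme)
  expect_setequal(per$class_label, c("Bird", "Bovine", "Fish"))
  # robin sparrow [cow] eagle: interrupted bird series of length 3
  expect_equal(per$length[per$class_label == "Bird"], 3L)
  expect_equal(per$n_interruptions[per$class_label == "Bird"], 1L)
  expect_equal(per$length[per$class_label == "Fish"], 1L)
  # the participant-level longest agrees with the per-class maximum
  res <- longest_series(sc, scheme)
  expect_equal(res$longest_length, max(per$length))
  expect_equal(res$longest_class, per$class_label[which.max(per$length)])
})
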