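# animalfluency

Item-level analysis of semantic (animal) verbal fluency transcripts:
detection of **abundant animal class knowledge** and the cohort statistics
that go with it.

## The problem

In a semantic fluency task, participants name as many animals as they can
in a fixed time window. Beyond the usual total count, the *sequence* of
items is informative: some people produce long consecutive runs from one
taxonomic class — fifteen birds, a dozen fish — plausibly reflecting
personal background (birdwatching, angling, farm work). For item-level
fluency metrics this is a validity concern: does such class-specific
knowledge disproportionally inflate fluency scores relative to other
cognitive measures?

This package implements the analysis pipeline that question requires, for
epidemiologists and neuropsychologists working with item-level fluency
data:

* **Series detection.** A *series* for class *C* is a contiguous span of
  the recall sequence starting and ending on a member of *C* with at most
  one internal interruption by another animal; its length counts members
  only. Per participant the longest series across the twelve taxonomic
  animal classes defines their *abundant class knowledge* label at a cutoff
  *X* (main analysis *X* = 10 ≈ 90th percentile; sensitivity *X* = 7 ≈ 67th
  percentile).
* **Transcript scoring.** Correctness rules (repetitions, plural-after-
  singular, proper names, non-target language), and class imputation for
  plus-sign placeholders flanked by same-class recalls.
* **Cohort statistics.** Welch t-tests (also from published group
  summaries), Yates-corrected chi-square, linear regressions adjusted for
  age, sex/gender and education, and Benjamini–Hochberg FDR control with
  critical values (i/m)·Q (Q = 0.10, m = 6).
* **Synthetic cohorts.** A seeded generator producing transcripts,
  covariates and ground truth with clustered class runs, planted long-run
  participants with covariate shifts, plus-sign dropout and repetition
  noise — so the whole pipeline is testable without restricted cohort
  data (defaults emulate a Dutch cohort: N = 736, age 57.6 ± 9.4, 18%
  women, 25.2 ± 8.7 items per 2-minute transcript).

## Worked example

```r
library(animalfluency)

co <- generate_cohort(default_params(seed = 1))          # synthetic N = 736
scored <- score_tokens(co$transcripts, co$scheme) |>
  impute_placeholders()
series <- longest_series(scored, co$scheme)

prevalence_table(series)
#> # A tibble: 11 × 3
#>    cutoff     n percent
#>     <int> <int>   <dbl>
#>  1      5   502    68.2
#>  2      6   330    44.8
#>  3      7   227    30.8
#>  ...
#>  6     10    65     8.8
#>  ...
#> 11     15    10     1.4
```

8.8% of this synthetic cohort reaches the main cutoff (the generator plants
long runs in 10.6% of participants; placeholder and repetition noise plus
sampling variation move a given seed around that rate). Group comparisons
and adjusted regressions come in tidy form with BH columns:

```r
cohort <- build_cohort(co$covariates, series, cutoff = 10)
compare_groups(cohort, analysis = "main")
#> # A tibble: 6 × 9
#>   test           test_name        statistic    df p_value     n  rank critical_value rejected
#>   <chr>          <chr>                <dbl> <dbl>   <dbl> <int> <int>          <dbl> <lgl>
#> 1 age            welch_t            -1.30    79.3   0.198   736     1         0.0167 FALSE
#> 2 sex_gender     chi_square_yates    1.44     1     0.230   736     3         0.05   FALSE
#> ...

cognitive_regressions(cohort)
#> # A tibble: 6 × 9
#>   outcome                   B ci_low ci_high      p_value     n  rank critical_value rejected
#> 1 animal_fluency_total  6.60   4.35     8.85 0.0000000120   736     1         0.0167 TRUE
#> 2 letter_fluency        1.67   0.525    2.82 0.00433        736     3         0.05   TRUE
#> ...
```

Here the planted participants recall about six items more (B = 6.60,
95% CI [4.35; 8.85]) and also score higher on letter fluency and word-list
learning — the pattern the covariate coupling builds in. `run_pipeline()`
does all of the above from CSV inputs and writes the report bundle;
`plot_prevalence()` and `plot_class_distribution()` draw the two standard
figures.

Real data come in as plain text: long-format transcripts
(`participant_id,position,token`, with `+` as the placeholder), a
two-column `item,class` scheme (a small demonstration scheme ships in
`inst/extdata/`), and a covariate CSV.

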