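#' Published summary tables from the SMART-MR abundant-class-knowledge study
#'
#' The raw SMART-MR cohort data are not public, but the study's published
#' baseline tables contain the contingency counts and group summaries its
#' headline statistics were computed from. This function returns those
#' printed numbers so the package's statistical routines can be checked
#' against the published results at desk scale.
#'
#' @return A named list:
#' \describe{
#'   \item{prevalence}{Participants reaching each cutoff 5..15 of N = 736.}
#'   \item{sex_main, sex_sensitivity}{2x2 matrices of sex/gender (rows:
#'     female, male) by abundance at the >= 10 and >= 7 cutoffs.}
#'   \item{working_main, working_sensitivity}{2x2 matrices of working
#'     status (rows: working, retired) by abundance.}
#'   \item{age_main}{Group age summaries at the >= 10 cutoff: mean, sd, n
#'     for the non-abundant and abundant groups.}
#' }
#' @export
reference_tables <- function() {
  list(
    prevalence = tibble::tibble(
      cutoff = 5:15,
      n = c(416L, 331L, 245L, 169L, 114L, 78L, 49L, 27L, 15L, 11L, 8L),
      percent = c(56.2, 45.0, 33.3, 23.0, 15.5, 10.6, 6.7, 3.7, 2.0, 1.5, 1.1)
    ),
    sex_main = matrix(c(125, 533, 6, 72), nrow = 2,
                      dimnames = list(c("female", "male"),
                                      c("non_abundant", "abundant"))),
    working_main = matrix(c(248, 285, 21, 45), nrow = 2,
                          dimnames = list(c("working", "retired"),
                                          c("non_abundant", "abundant"))),
    sex_sensitivity = matrix(c(106, 385, 25, 220), nrow = 2,
                             dimnames = list(c("female", "male"),
                                             c("non_abundant", "abundant"))),
    working_sensitivity = matrix(c(196, 195, 73, 135), nrow = 2,
                                 dimnames = list(c("working", "retired"),
                                                 c("non_abundant", "abundant"))),
    age_main = tibble::tibble(
      group = c("non_abundant", "abundant"),
      mean = c(57.4, 59.7),
      sd = c(9.5, 8.6),
      n = c(658L, 78L)
    )
  )
}
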