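#' Reference cohort characteristic counts
#'
#' Published summary counts of the 85-patient reference cohort (gender,
#' delivery technique, RP grade, smoking, COPD, fractionation, chemotherapy
#' and regimen). These printed counts are the only part of the clinical
#' cohort that is available; the package uses them for worked-example
#' arithmetic and to set the phantom generator's fractionation mix and
#' incidence target.
#'
#' @return data.frame with columns `characteristic`, `level`, `n`.
#' @export
reference_cohort_counts <- function() {
  path <- system.file("extdata", "reference_cohort_counts.csv",
                      package = "rpvent", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Within-characteristic percentages
#'
#' Converts level counts into percentages of their characteristic's total,
#' rounded to one decimal as summary tables print them (so 21 of 85 is
#' 24.7).
#'
#' @param counts data.frame as returned by [reference_cohort_counts()].
#' @return the input with a `percent` column appended.
#' @export
characteristic_percentages <- function(counts) {
  stopifnot(all(c("characteristic", "level", "n") %in% names(counts)))
  totals <- tapply(counts$n, counts$characteristic, sum)
  counts$percent <- round(100 * counts$n / totals[counts$characteristic], 1)
  counts
}
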