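#' Age-standardise an age-specific rate against a standard population
#'
#' Returns the population-weighted mean `sum(w_a * rate_a)` with weights
#' `w_a = pop_a / sum(pop)`.
#'
#' @param rates A data.frame with columns `age` and one of `prevalence`,
#'   `rate`, `value` (first found is used), covering ages 0-100.
#' @param standard A `population_table` on the same age support.
#' @return A single proportion/rate.
#' @export
age_standardise <- function(rates, standard) {
  col <- intersect(c("prevalence", "rate", "value", "hazard"), names(rates))[1]
  if (is.na(col)) stop_input("'rates' has no recognised value column")
  check_age_table(rates, col, "rates")
  check_age_table(standard, "count", "standard")
  check_aligned(rates, standard, "rates", "standard")
  w <- standard$count / sum(standard$count)
  sum(w * rates[[col]])
}

#' Prevalent cases by age
#'
#' Multiplies an age-specific prevalence curve by the population at each
#' age: `cases_a = p_a * pop_a`.
#'
#' @param curve A `prevalence_curve`.
#' @param population A `population_table` on the same ages.
#' @return A `case_counts`: data.frame with columns `age`, `cases` and a
#'   `group` attribute taken from the curve's disorder label.
#' @export
prevalent_cases <- function(curve, population) {
  check_age_table(curve, "prevalence", "curve")
  check_age_table(population, "count", "population")
  check_aligned(curve, population, "curve", "population")
  case_counts(curve$prevalence * population$count,
              group = attr(curve, "disorder") %||% "cases")
}

case_counts <- function(cases, group) {
  structure(data.frame(age = AGES, cases = as.numeric(cases)),
            class = c("case_counts", "data.frame"), group = group)
}

#' @export
print.case_counts <- function(x, ...) {
  cat(sprintf("Prevalent cases [%s]: total %s\n", attr(x, "group"),
              format(round(sum(x$cases)), big.mark = ",")))
  invisible(x)
}

#' Total cases
#' @param x A `case_counts`.
#' @export
total_cases <- function(x) sum(x$cases)

#' Partition PTSD and depression cases by comorbidity
#'
#' Comorbid cases are `rho * ptsd` at each age (the proportion of PTSD
#' cases comorbid with depression; default 50%), clamped at the
#' depression case count with a warning where the clamp binds. The
#' combined count is `ptsd + depression - comorbid`, so
#' `ptsd_only + dep_only + comorbid = combined` at every age.
#'
#' @param ptsd,dep `case_counts` for PTSD and depression on shared ages.
#' @param rho Proportion of PTSD cases comorbid with depression, in \[0, 1\].
#' @return List of `case_counts`: `ptsd_only`, `dep_only`, `comorbid`,
#'   `combined`.
#' @examples
#' # with the printed Syria-scale totals, combined stays at the PTSD total
#' @export
comorbidity_partition <- function(ptsd, dep, rho = 0.5) {
  check_age_table(ptsd, "cases", "ptsd")
  check_age_table(dep, "cases", "dep")
  check_aligned(ptsd, dep, "ptsd", "dep")
  check_proportion(rho, "rho")
  com <- rho * ptsd$cases
  if (any(com > dep$cases + 1e-9)) {
    warning("comorbid cases exceed depression cases at some ages; clamped",
            call. = FALSE)
    com <- pmin(com, dep$cases)
  }
  list(ptsd_only = case_counts(ptsd$cases - com, "ptsd_only"),
       dep_only  = case_counts(dep$cases - com, "dep_only"),
       comorbid  = case_counts(com, "comorbid"),
       combined  = case_counts(ptsd$cases + dep$cases - com, "combined"))
}
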