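#' Construct a severity model (severity splits + disability weights)
#'
#' A severity model partitions prevalent cases of a disorder into
#' severity classes (asymptomatic cases carry disability weight 0) and
#' attaches a GBD-style disability weight, with 95% uncertainty interval,
#' to each class.
#'
#' @param disorder Disorder label.
#' @param classes data.frame with columns `class`, `proportion`, `dw`,
#'   `dw_lower`, `dw_upper`.
#' @return A `severity_model`.
#' @seealso [default_severity_models()]
#' @export
severity_model <- function(disorder, classes) {
  need <- c("class", "proportion", "dw", "dw_lower", "dw_upper")
  if (!is.data.frame(classes) || !all(need %in% names(classes)))
    stop_input("'classes' needs columns %s", paste(need, collapse = ", "))
  if (abs(sum(classes$proportion) - 1) > 1e-9)
    stop_input("severity-class proportions must sum to 1 (got %.6f)",
               sum(classes$proportion))
  if (any(classes$dw < 0 | classes$dw > 1))
    stop_input("disability weights must lie in [0, 1]")
  if (any(classes$dw_lower > classes$dw | classes$dw > classes$dw_upper))
    stop_input("need dw_lower <= dw <= dw_upper for every class")
  ms <- classes$class %in% c("moderate", "severe")
  structure(list(disorder = disorder, classes = classes,
                 moderate_severe_prop = sum(classes$proportion[ms])),
            class = "severity_model")
}

#' @export
print.severity_model <- function(x, ...) {
  cat(sprintf("Severity model [%s]: expected DW %.4f, moderate+severe %.1f%%\n",
              x$disorder, expected_dw(x), 100 * x$moderate_severe_prop))
  print(x$classes, row.names = FALSE)
  invisible(x)
}

#' Case-weighted expected disability weight of a severity model
#'
#' `sum(proportion_k * dw_k)` over severity classes; the asymptomatic
#' class contributes 0 through its zero disability weight.
#'
#' @param model A `severity_model`.
#' @param moderate_severe_only If `TRUE`, return the conditional expected
#'   disability weight among moderate and severe cases only (used by the
#'   health-benefit model, which follows the moderate-severe caseload).
#' @return Scalar disability weight in \[0, 1\].
#' @export
expected_dw <- function(model, moderate_severe_only = FALSE) {
  stopifnot(inherits(model, "severity_model"))
  cl <- model$classes
  if (moderate_severe_only) {
    ms <- cl$class %in% c("moderate", "severe")
    sum(cl$proportion[ms] * cl$dw[ms]) / sum(cl$proportion[ms])
  } else {
    sum(cl$proportion * cl$dw)
  }
}

#' Years lived with disability from prevalent cases
#'
#' `ylds_a = cases_a * expected_dw(model)` by age. PTSD case counts are
#' conventionally paired with the anxiety-disorders severity model as a
#' proxy, since GBD 2010 does not carry PTSD-specific weights.
#'
#' @param cases A `case_counts`.
#' @param model A `severity_model`.
#' @return A `burden_result`: list with the by-age data.frame (`age`,
#'   `ylds`), the total, and the model used.
#' @export
compute_ylds <- function(cases, model) {
  check_age_table(cases, "cases", "cases")
  stopifnot(inherits(model, "severity_model"))
  if (any(cases$cases < 0)) stop_input("case counts must be non-negative")
  dw <- expected_dw(model)
  by_age <- data.frame(age = cases$age, ylds = cases$cases * dw)
  structure(list(disorder = attr(cases, "group"), by_age = by_age,
                 total = sum(by_age$ylds), expected_dw = dw,
                 lower95 = NA_real_, upper95 = NA_real_, model = model),
            class = "burden_result")
}

#' @export
print.burden_result <- function(x, ...) {
  ui <- if (is.finite(x$lower95))
    sprintf(" (95%% UI %s-%s)", format(round(x$lower95), big.mark = ","),
            format(round(x$upper95), big.mark = ",")) else ""
  cat(sprintf("YLD burden [%s]: %s%s (expected DW %.4f)\n", x$disorder,
              format(round(x$total), big.mark = ","), ui, x$expected_dw))
  invisible(x)
}

#' YLD rate per 1000 population
#'
#' Age-specific rates `1000 * ylds_a / pop_a` plus the age-standardised
#' rate against the same population.
#'
#' @param result A `burden_result`.
#' @param standard A `population_table`.
#' @return List with `by_age` (data.frame `age`, `rate`) and
#'   `standardised` (per 1000).
#' @export
yld_rate <- function(result, standard) {
  stopifnot(inherits(result, "burden_result"))
  check_age_table(standard, "count", "standard")
  check_aligned(result$by_age, standard, "result", "standard")
  bad <- standard$count == 0 & result$by_age$ylds > 0
  if (any(bad))
    stop_input("zero population at age(s) %s with nonzero YLDs",
               paste(standard$age[bad], collapse = ", "))
  rate <- ifelse(standard$count > 0, 1000 * result$by_age$ylds / standard$count, 0)
  w <- standard$count / sum(standard$count)
  list(by_age = data.frame(age = standard$age, rate = rate),
       standardised = sum(w * rate))
}

#' Propagate parameter uncertainty to a YLD total
#'
#' Combines per-draw case totals and per-draw expected disability weights
#' multiplicatively and summarises the draw distribution: the point
#' estimate is the Monte-Carlo mean, the 95% UI the empirical 2.5th/97.5th
#' percentiles (the deterministic product is also returned).
#'
#' @param case_draws Numeric vector of case-total draws (or a scalar).
#' @param dw_draws Numeric vector of expected-DW draws (or a scalar);
#'   recycled against `case_draws`.
#' @return List: `point` (mean of draws), `lower95`, `upper95`,
#'   `deterministic` (product of the means), `draws`.
#' @export
propagate_uncertainty <- function(case_draws, dw_draws) {
  n <- max(length(case_draws), length(dw_draws))
  if (n < 1) stop_input("need at least one draw")
  ylds <- rep_len(case_draws, n) * rep_len(dw_draws, n)
  q <- unname(stats::quantile(ylds, c(0.025, 0.975), type = 7))
  list(point = mean(ylds), lower95 = q[1], upper95 = q[2],
       deterministic = mean(case_draws) * mean(dw_draws), draws = ylds)
}

#' Full uncertainty analysis for one disorder's YLD burden
#'
#' Draws the age-standardised prevalence (beta, matching its 95% UI) and
#' each severity class's disability weight (beta), rebuilds the expected
#' DW per draw with fixed severity splits, and propagates both to the YLD
#' total and the standardised YLD rate per 1000.
#'
#' @param target_prev,prev_lower,prev_upper Prevalence point and 95% UI.
#' @param model A `severity_model`.
#' @param population A `population_table` (the case multiplier and
#'   standardisation weights).
#' @param curve Optional `prevalence_curve` shape; defaults to the
#'   package's peaked curve rescaled per draw.
#' @param n_draws Number of Monte-Carlo draws (>= 100).
#' @param seed Integer seed.
#' @return A `burden_result` with `lower95`/`upper95` filled in and an
#'   extra `rate_per_1000` element (point and UI).
#' @export
yld_uncertainty <- function(target_prev, prev_lower, prev_upper, model,
                            population, curve = NULL,
                            n_draws = 2000, seed = 20150101L) {
  if (n_draws < 100) stop_input("'n_draws' must be at least 100")
  if (is.null(curve))
    curve <- make_prevalence_curve(model$disorder, target_prev, population)
  cases0 <- total_cases(prevalent_cases(curve, population))
  pop_total <- sum(population$count)

  prev_draws <- draw_parameters(target_prev, prev_lower, prev_upper,
                                n_draws, "proportion", seed = seed)
  cl <- model$classes
  dw_draws <- rep(0, n_draws)
  for (k in seq_len(nrow(cl))) {
    if (cl$dw[k] == 0) next
    dk <- draw_parameters(cl$dw[k], cl$dw_lower[k], cl$dw_upper[k],
                          n_draws, "proportion", seed = seed + k)
    dw_draws <- dw_draws + cl$proportion[k] * dk
  }
  # cases scale linearly in the standardised prevalence
  case_draws <- cases0 * prev_draws / target_prev
  pu <- propagate_uncertainty(case_draws, dw_draws)

  res <- compute_ylds(prevalent_cases(curve, population), model)
  res$total <- pu$point
  res$lower95 <- pu$lower95
  res$upper95 <- pu$upper95
  res$deterministic <- pu$deterministic
  res$rate_per_1000 <- list(point = 1000 * pu$point / pop_total,
                            lower95 = 1000 * pu$lower95 / pop_total,
                            upper95 = 1000 * pu$upper95 / pop_total)
  res
}

#' GBD 2010 global age-standardised YLD rate references (per 1000)
#'
#' Comparator constants: major depression 9.2 (7.0-11.8) and anxiety
#' disorders 3.9 (2.7-5.4) YLDs per 1000 population.
#' @return Named list of reference rates.
#' @export
gbd_global_yld_rates <- function() {
  list(depression = list(point = 9.2, lower95 = 7.0, upper95 = 11.8),
       anxiety = list(point = 3.9, lower95 = 2.7, upper95 = 5.4))
}
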