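#' Construct an intervention package for the health-benefit model
#'
#' @param name Package name.
#' @param coverage_target Target population coverage `c_k` in \[0, 1\];
#'   total coverage in a scenario year is `c_k` times the scenario's
#'   scale-up coverage.
#' @param d_remission Proportional increase in remission at full
#'   effective coverage, in \[0, 1\].
#' @param d_dw Proportional reduction in disability weight at full
#'   effective coverage, in \[0, 1\].
#' @return An `intervention_package`.
#' @export
intervention_package <- function(name, coverage_target, d_remission, d_dw) {
  check_proportion(coverage_target, "coverage_target")
  check_proportion(d_remission, "d_remission")
  check_proportion(d_dw, "d_dw")
  structure(list(name = name, coverage_target = coverage_target,
                 d_remission = d_remission, d_dw = d_dw),
            class = "intervention_package")
}

#' Combined effectiveness of a set of intervention packages
#'
#' WHO-CHOICE combination: each package contributes an effective fraction
#' `e_k = efficacy_k x c_k x s` (efficacy times target coverage times the
#' scenario's scale-up coverage `s`), and the combined effect is
#' `1 - prod(1 - e_k)`.
#'
#' @param packages List of `intervention_package`s.
#' @param scaleup Scale-up coverage `s` in \[0, 1\] (scalar or vector over
#'   years).
#' @param channel `"remission"` or `"dw"`: which efficacy to combine.
#' @return Combined effectiveness, same length as `scaleup`.
#' @export
combined_effectiveness <- function(packages, scaleup,
                                   channel = c("remission", "dw")) {
  channel <- match.arg(channel)
  if (any(scaleup < 0 | scaleup > 1))
    stop_input("scale-up coverage must lie in [0, 1]")
  eff <- vapply(packages, function(p)
    if (channel == "remission") p$d_remission else p$d_dw, numeric(1))
  cov <- vapply(packages, `[[`, numeric(1), "coverage_target")
  out <- rep(1, length(scaleup))
  for (k in seq_along(packages)) {
    e_k <- eff[k] * cov[k] * scaleup
    if (any(e_k > 1)) stop_input("effective fraction exceeds 1 for package '%s'",
                                 packages[[k]]$name)
    out <- out * (1 - e_k)
  }
  1 - out
}

#' Apply a combined effectiveness to disease parameters
#'
#' Treatment raises remission and lowers the disability weight:
#' `r' = r (1 + d_remission x eff)` and `dw' = dw (1 - d_dw x eff)`.
#' With `eff = 0` the parameters are unchanged.
#'
#' @param remission Untreated remission rate, per person-year.
#' @param dw Untreated disability weight.
#' @param eff Combined effectiveness in \[0, 1\].
#' @param d_remission,d_dw Proportional changes at `eff = 1` (default 1,
#'   i.e. `eff` already folds in the effect size).
#' @return List with adjusted `remission` and `dw`.
#' @export
apply_effectiveness <- function(remission, dw, eff, d_remission = 1, d_dw = 1) {
  if (any(eff < 0 | eff > 1)) stop_input("'eff' must lie in [0, 1]")
  dw2 <- dw * (1 - d_dw * eff)
  if (any(dw2 < 0)) stop_input("adjusted disability weight is negative")
  list(remission = remission * (1 + d_remission * eff), dw = dw2)
}

#' Scenario scale-up coverage series
#'
#' Per-year scale-up coverage `s(t)`, `t = 0..years-1`: 0 for the
#' partial-null (no treatment) scenario, constant 0.01 for current
#' coverage, and an interpolation from 0.01 to 0.30 (`target30`) or 1.0
#' (`target100`) for the scale-up scenarios.
#'
#' @param scenario One of `"partial_null"`, `"current"`, `"target30"`,
#'   `"target100"`.
#' @param mode `"linear"` or `"exponential"` (ignored for the constant
#'   scenarios).
#' @param years Horizon (default 15).
#' @param baseline Baseline coverage (default 0.01).
#' @return Numeric vector of length `years`.
#' @export
scenario_scaleup <- function(scenario = c("partial_null", "current",
                                          "target30", "target100"),
                             mode = c("linear", "exponential"),
                             years = 15, baseline = 0.01) {
  scenario <- match.arg(scenario)
  mode <- match.arg(mode)
  switch(scenario,
    partial_null = rep(0, years),
    current = rep(baseline, years),
    target30 = coverage_trajectory(baseline, 0.30, years, mode)$coverage,
    target100 = coverage_trajectory(baseline, 1.00, years, mode)$coverage)
}

#' The six mhGAP adult age cohorts
#'
#' Age bands 15-29, 30-44, 45-59, 60-69, 70-79 and 80+ with mid-ages 22,
#' 37, 52, 64.5, 74.5 and 85; each cohort is modelled from its mid-age
#' over the 15-year horizon.
#'
#' @return data.frame with columns `band`, `age_lo`, `age_hi`, `mid_age`.
#' @export
benefit_cohorts <- function() {
  data.frame(band = c("15-29", "30-44", "45-59", "60-69", "70-79", "80+"),
             age_lo = c(15, 30, 45, 60, 70, 80),
             age_hi = c(29, 44, 59, 69, 79, 100),
             mid_age = c(22, 37, 52, 64.5, 74.5, 85))
}

# Interpolate an age-indexed vector (ages 0-100) at possibly non-integer
# ages; ages above 100 are truncated to the terminal value.
age_lookup <- function(values, at) {
  stats::approx(AGES, values, xout = pmin(at, 100), rule = 2)$y
}

#' Build the inputs for the avertable-burden analysis
#'
#' Assembles the per-disorder-stream ingredients of the multi-cohort
#' Markov model: a PTSD stream (PTSD-only cases; remission 0.17/year, no
#' excess mortality; anxiety-model disability weight) and a depression
#' stream (comorbid depression/PTSD, optionally plus depression-only
#' cases; remission 1.40/year, mortality RR 1.9; depression-model
#' disability weight). The model follows moderate-severe cases only, so
#' each stream's prevalence is its case prevalence times the
#' moderate-severe share, with the conditional moderate-severe disability
#' weight. Incidence is back-calculated with [fit_incidence()] so each
#' stream's epidemiology is internally consistent.
#'
#' @param fixture Output of [syria_fixture()] (or a list with the same
#'   elements).
#' @param rho Comorbid proportion of PTSD cases (default 0.5).
#' @param severity Named severity models (see
#'   [default_severity_models()]).
#' @param epi Epidemiological parameters (see [default_epi_params()]).
#' @param packages Intervention packages (see
#'   [default_intervention_packages()]).
#' @param include_dep_only Fold depression-only cases into the
#'   depression-parameter stream (default TRUE).
#' @return A `benefit_setup` list.
#' @export
benefit_setup <- function(fixture = syria_fixture(), rho = 0.5,
                          severity = default_severity_models(),
                          epi = default_epi_params(),
                          packages = default_intervention_packages(),
                          include_dep_only = TRUE) {
  pop <- fixture$population
  part <- comorbidity_partition(prevalent_cases(fixture$ptsd, pop),
                                prevalent_cases(fixture$depression, pop), rho)
  m <- fixture$mortality$hazard

  stream <- function(cases_vec, sev_model, pars) {
    q <- sev_model$moderate_severe_prop
    prev_ms <- q * cases_vec / pop$count
    target <- data.frame(age = AGES, prevalence = prev_ms)
    f <- m * (pars$rr_mortality - 1)
    fit <- fit_incidence(target, remission = pars$remission,
                         excess = f, background = m)
    list(prev_ms = prev_ms, dw = expected_dw(sev_model, moderate_severe_only = TRUE),
         remission = rep_len(pars$remission, 101), excess = f, background = m,
         incidence = fit$incidence$incidence, fit = fit)
  }

  dep_cases <- part$comorbid$cases +
    if (include_dep_only) part$dep_only$cases else 0
  streams <- list(
    ptsd = stream(part$ptsd_only$cases, severity$anxiety, epi$ptsd),
    depression = stream(dep_cases, severity$depression, epi$depression))

  structure(list(population = pop, partition = part, streams = streams,
                 packages = packages, cohorts = benefit_cohorts(),
                 include_dep_only = include_dep_only),
            class = "benefit_setup")
}

#' Propagate one age cohort under a scenario's effectiveness series
#'
#' Runs the illness-death model from the cohort's mid-age over the
#' horizon, with year-specific treated remission and disability weight.
#' YLDs accrue as the within-year average diseased population times the
#' treated disability weight.
#'
#' @param size Cohort persons.
#' @param mid_age Starting (mid-band) age.
#' @param stream One stream element of a [benefit_setup()].
#' @param eff_r,eff_dw Per-year combined effectiveness on remission and
#'   disability weight (vectors, length `years`).
#' @param years Horizon (default 15).
#' @return List: `ylds`, `C`, `alive` per year (plus the final state).
#' @export
run_cohort <- function(size, mid_age, stream, eff_r, eff_dw, years = 15) {
  stopifnot(length(eff_r) == years, length(eff_dw) == years)
  if (mid_age + years > 100 + 1)
    warning("cohort ages past 100 are truncated to the terminal rates",
            call. = FALSE)
  p0 <- age_lookup(stream$prev_ms, mid_age)
  S <- size * (1 - p0); C <- size * p0; D <- 0
  ylds <- Cs <- alive <- numeric(years)
  for (t in seq_len(years) - 1) {
    a <- mid_age + t
    adj <- apply_effectiveness(age_lookup(stream$remission, a) , stream$dw,
                               eff = 1, d_remission = eff_r[t + 1],
                               d_dw = eff_dw[t + 1])
    st <- step_year(c(S, C, D),
                    i = age_lookup(stream$incidence, a),
                    r = adj$remission,
                    f = age_lookup(stream$excess, a),
                    m = age_lookup(stream$background, a))
    ylds[t + 1] <- adj$dw * st$person_years[["C"]]
    S <- st$state[[1]]; C <- st$state[[2]]; D <- st$state[[3]]
    Cs[t + 1] <- C; alive[t + 1] <- S + C
  }
  list(ylds = ylds, C = Cs, alive = alive, final_state = c(S = S, C = C, D = D))
}

#' Run one avertable-burden scenario
#'
#' Sums YLDs over the six age cohorts, both disorder streams and the
#' 15-year horizon under the scenario's scale-up coverage. The DALY
#' burden equals the YLD burden (case fatality is negligible for these
#' disorders, so no YLL component is modelled).
#'
#' @param setup A `benefit_setup`.
#' @param scenario Scenario name (see [scenario_scaleup()]).
#' @param mode `"linear"` or `"exponential"`.
#' @param discount_rate Annual discount rate applied to the YLD series
#'   (default 0; the reference year is undiscounted).
#' @param years Horizon (default 15).
#' @return A `scenario_result`: list with `total` DALYs, `by_year`,
#'   `by_stream`, and the scenario descriptors.
#' @export
run_scenario <- function(setup, scenario = "partial_null",
                         mode = c("linear", "exponential"),
                         discount_rate = 0, years = 15) {
  stopifnot(inherits(setup, "benefit_setup"))
  mode <- match.arg(mode)
  s <- scenario_scaleup(scenario, mode, years)
  eff_r <- combined_effectiveness(setup$packages, s, "remission")
  eff_dw <- combined_effectiveness(setup$packages, s, "dw")

  pop <- setup$population
  coh <- setup$cohorts
  by_year <- numeric(years)
  by_stream <- stats::setNames(numeric(length(setup$streams)),
                               names(setup$streams))
  for (sn in names(setup$streams)) {
    stream <- setup$streams[[sn]]
    for (j in seq_len(nrow(coh))) {
      size <- sum(pop$count[pop$age >= coh$age_lo[j] & pop$age <= coh$age_hi[j]])
      res <- run_cohort(size, coh$mid_age[j], stream, eff_r, eff_dw, years)
      by_year <- by_year + res$ylds
      by_stream[sn] <- by_stream[sn] + discount(res$ylds, discount_rate)
    }
  }
  structure(list(scenario = scenario, mode = mode,
                 discount_rate = discount_rate,
                 total = discount(by_year, discount_rate),
                 by_year = by_year, by_stream = by_stream),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("Scenario '%s' (%s scale-up%s): %s DALYs over %d years\n",
              x$scenario, x$mode,
              if (x$discount_rate > 0)
                sprintf(", %g%% discount", 100 * x$discount_rate) else "",
              format(round(x$total), big.mark = ","), length(x$by_year)))
  invisible(x)
}

#' Burden averted by a scenario relative to a comparator
#'
#' `averted = comparator total - scenario total`;
#' `percent = 100 x averted / comparator total`.
#'
#' @param scenario,comparator `scenario_result`s over the same cohorts
#'   and horizon.
#' @return List: `averted` (DALYs) and `percent`.
#' @export
averted_burden <- function(scenario, comparator) {
  stopifnot(inherits(scenario, "scenario_result"),
            inherits(comparator, "scenario_result"))
  if (length(scenario$by_year) != length(comparator$by_year))
    stop_input("scenario and comparator horizons differ")
  averted <- comparator$total - scenario$total
  list(averted = averted, percent = 100 * averted / comparator$total)
}

#' Discounted total of a per-year series
#'
#' `sum(value_t / (1 + rate)^t)` for `t = 0..n-1` (year 0 undiscounted).
#'
#' @param series Per-year values.
#' @param rate Annual discount rate (>= 0; 0 returns the plain sum).
#' @return Discounted total.
#' @export
discount <- function(series, rate = 0.03) {
  if (rate < 0) stop_input("discount rate must be non-negative")
  t <- seq_along(series) - 1
  sum(series / (1 + rate)^t)
}

#' Avertable-burden summary across scenarios
#'
#' Runs the partial-null comparator plus the requested scenarios and
#' tabulates DALYs and percent averted.
#'
#' @param setup A `benefit_setup`.
#' @param scenarios Scenario names (default current/target30/target100).
#' @param modes Scale-up modes to run.
#' @param discount_rate Annual discount rate.
#' @return data.frame with columns `scenario`, `mode`, `dalys`,
#'   `averted`, `percent_averted`.
#' @export
avertable_analysis <- function(setup,
                               scenarios = c("current", "target30", "target100"),
                               modes = c("linear", "exponential"),
                               discount_rate = 0) {
  rows <- list()
  for (mode in modes) {
    comp <- run_scenario(setup, "partial_null", mode, discount_rate)
    for (sc in scenarios) {
      res <- run_scenario(setup, sc, mode, discount_rate)
      av <- averted_burden(res, comp)
      rows[[length(rows) + 1]] <- data.frame(
        scenario = sc, mode = mode, dalys = res$total,
        averted = av$averted, percent_averted = av$percent)
    }
  }
  do.call(rbind, rows)
}
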