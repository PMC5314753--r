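#' Generate a synthetic single-year-of-age population table
#'
#' Builds an all-ages (0-100) population pyramid with a requested total.
#' The `"young"` shape is an exponentially declining pyramid typical of
#' high-fertility, conflict-affected populations; `"uniform"` spreads the
#' total evenly; `"custom"` accepts explicit non-negative weights.
#'
#' @param total Total persons (> 0).
#' @param shape One of `"young"`, `"uniform"`, `"custom"`.
#' @param decline Exponential decline rate per year of age for the
#'   `"young"` shape (default 0.028, giving a median age in the low 20s).
#' @param weights Numeric vector of 101 non-negative weights, used when
#'   `shape = "custom"`.
#' @param female_share Proportion of the population that is female,
#'   recorded as an attribute and used by the perinatal eligibility rule.
#' @param reference_year Calendar year the table refers to.
#' @param seed Integer recorded with the table. The generator itself is
#'   deterministic; the seed is stored so downstream draws that pair with
#'   this table have a single provenance record.
#' @return A `population_table`: data.frame with columns `age`, `count`,
#'   attributes `reference_year`, `female_share`, `seed`.
#' @examples
#' pop <- make_population(1e6)
#' sum(pop$count)
#' @export
make_population <- function(total,
                            shape = c("young", "uniform", "custom"),
                            decline = 0.028,
                            weights = NULL,
                            female_share = 0.493,
                            reference_year = 2015,
                            seed = 20150101L) {
  check_number(total, "total")
  if (total <= 0) stop_input("'total' must be positive, got %g", total)
  shape <- match.arg(shape)
  check_proportion(female_share, "female_share")

  w <- switch(shape,
    uniform = rep(1, 101),
    young   = exp(-decline * AGES),
    custom  = {
      if (is.null(weights) || length(weights) != 101L || any(weights < 0))
        stop_input("'weights' must be 101 non-negative values for shape = 'custom'")
      weights
    })
  count <- total * w / sum(w)
  out <- data.frame(age = AGES, count = count)
  structure(out,
            class = c("population_table", "data.frame"),
            reference_year = reference_year,
            female_share = female_share,
            seed = seed)
}

#' @export
print.population_table <- function(x, ...) {
  cat(sprintf("Population table, reference year %s\n", attr(x, "reference_year")))
  cat(sprintf("  total: %s persons over ages 0-100 (female share %.3f)\n",
              format(round(sum(x$count)), big.mark = ","), attr(x, "female_share")))
  invisible(x)
}

#' Gompertz-Makeham all-cause mortality schedule
#'
#' `hazard(a) = A + B * exp(theta * a)` for single ages 0-100, per
#' person-year. The default parameters are calibrated so the implied
#' period life expectancy at birth falls in the 65-75 year range typical
#' of the modelled setting (see [life_expectancy()]).
#'
#' @param makeham_A Age-independent hazard component (>= 0), per person-year.
#' @param gompertz_B Senescent hazard at age 0 (> 0), per person-year.
#' @param gompertz_theta Exponential rate of senescence (> 0), per year.
#' @return A `mortality_schedule`: data.frame with columns `age`, `hazard`.
#' @examples
#' m <- make_mortality()
#' life_expectancy(m)
#' @export
make_mortality <- function(makeham_A = 0.0035,
                           gompertz_B = 3.2e-05,
                           gompertz_theta = 0.095) {
  check_number(makeham_A, "makeham_A", lower = 0)
  check_number(gompertz_B, "gompertz_B")
  check_number(gompertz_theta, "gompertz_theta")
  if (gompertz_B <= 0 || gompertz_theta <= 0)
    stop_input("'gompertz_B' and 'gompertz_theta' must be positive")
  hazard <- makeham_A + gompertz_B * exp(gompertz_theta * AGES)
  if (any(hazard > 2))
    warning("mortality hazard exceeds 2/year before age 100; life table implausible",
            call. = FALSE)
  structure(data.frame(age = AGES, hazard = hazard),
            class = c("mortality_schedule", "data.frame"))
}

#' Period life expectancy at birth implied by a mortality schedule
#'
#' Survivorship is accumulated with constant hazards within single-year
#' ages (`l(a+1) = l(a) exp(-h(a))`); person-years per age use the exact
#' within-interval integral of exponential survival.
#'
#' @param schedule A `mortality_schedule`.
#' @return Life expectancy at birth, years.
#' @export
life_expectancy <- function(schedule) {
  check_age_table(schedule, "hazard", "schedule")
  h <- schedule$hazard
  l <- cumprod(c(1, exp(-h)))[seq_along(h)]
  # person-years lived between a and a+1 under constant hazard h
  py <- ifelse(h > 0, l * (1 - exp(-h)) / h, l)
  sum(py)
}

#' Age-specific prevalence curve calibrated to an age-standardised target
#'
#' Produces a unimodal (log-normal in age) prevalence curve peaking in
#' young adulthood, rescaled so that its age-standardised value against
#' the paired population equals `target_std_prev` exactly. A `"flat"`
#' shape returns the target at every age (the standardisation identity).
#'
#' @param disorder Label, e.g. `"ptsd"` or `"depression"`.
#' @param target_std_prev Age-standardised prevalence target in (0, 1).
#' @param population A `population_table` providing the standard weights.
#' @param peak_age Modal age of the curve, years.
#' @param spread Log-scale spread of the curve (larger = flatter).
#' @param shape `"peaked"` (default) or `"flat"`.
#' @return A `prevalence_curve`: data.frame with columns `age`,
#'   `prevalence`; attributes `disorder`, `target`.
#' @examples
#' pop <- make_population(1e6)
#' cv <- make_prevalence_curve("ptsd", 0.129, pop)
#' age_standardise(cv, pop)  # 0.129
#' @export
make_prevalence_curve <- function(disorder, target_std_prev, population,
                                  peak_age = 25, spread = 0.75,
                                  shape = c("peaked", "flat")) {
  check_number(target_std_prev, "target_std_prev")
  if (target_std_prev <= 0 || target_std_prev >= 1)
    stop_input("'target_std_prev' must be strictly between 0 and 1")
  check_age_table(population, "count", "population")
  shape <- match.arg(shape)

  if (shape == "flat") {
    p <- rep(target_std_prev, 101)
  } else {
    # log-normal density in age with mode at peak_age
    mu <- log(peak_age) + spread^2
    raw <- stats::dlnorm(AGES + 0.5, meanlog = mu, sdlog = spread)
    w <- population$count / sum(population$count)
    p <- raw * target_std_prev / sum(w * raw)
    if (any(p > 1))
      stop_input("rescaling to the target pushes prevalence above 1 at some age; %s",
                 "increase 'spread' or lower the target")
  }
  structure(data.frame(age = AGES, prevalence = p),
            class = c("prevalence_curve", "data.frame"),
            disorder = disorder, target = target_std_prev)
}

#' Monte-Carlo draws matching a point estimate and 95% uncertainty interval
#'
#' Rates use a log-normal fitted so its 2.5th/97.5th percentiles equal the
#' stated interval; proportions use a beta whose two shape parameters are
#' solved numerically to match both percentiles. A degenerate interval
#' (`lower == upper == point`) returns constant draws.
#'
#' @param point Point estimate.
#' @param lower,upper 95% uncertainty interval bounds (`lower <= point <= upper`).
#' @param n Number of draws.
#' @param type `"proportion"` (beta) or `"rate"` (log-normal).
#' @param seed Integer seed; draws are reproducible.
#' @return Numeric vector of `n` non-negative draws.
#' @examples
#' d <- draw_parameters(0.129, 0.069, 0.229, n = 1e4, seed = 1)
#' stats::quantile(d, c(0.025, 0.975))
#' @export
draw_parameters <- function(point, lower, upper, n,
                            type = c("proportion", "rate"),
                            seed = 20150101L) {
  type <- match.arg(type)
  check_number(point, "point", lower = 0)
  check_number(lower, "lower", lower = 0)
  check_number(upper, "upper", lower = 0)
  if (!(lower <= point && point <= upper))
    stop_input("need lower <= point <= upper, got [%g, %g, %g]", lower, point, upper)
  if (type == "proportion" && upper > 1)
    stop_input("proportion upper bound %g exceeds 1", upper)
  if (n < 1) stop_input("'n' must be at least 1")

  if (lower == upper) return(rep(point, n))

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  z <- stats::qnorm(0.975)
  if (type == "rate") {
    if (lower <= 0) stop_input("rate lower bound must be positive for a log-normal fit")
    meanlog <- (log(lower) + log(upper)) / 2
    sdlog <- (log(upper) - log(lower)) / (2 * z)
    stats::rlnorm(n, meanlog, sdlog)
  } else {
    par <- fit_beta_quantiles(lower, upper)
    stats::rbeta(n, par[1], par[2])
  }
}

# Solve beta shape parameters so the 2.5/97.5 percentiles match the bounds.
fit_beta_quantiles <- function(lower, upper) {
  mid <- (lower + upper) / 2
  sd0 <- (upper - lower) / (2 * stats::qnorm(0.975))
  v <- min(sd0^2, mid * (1 - mid) * 0.99)
  k0 <- mid * (1 - mid) / v - 1
  start <- log(c(mid * k0, (1 - mid) * k0))
  obj <- function(lp) {
    a <- exp(lp[1]); b <- exp(lp[2])
    q <- stats::qbeta(c(0.025, 0.975), a, b)
    sum((log(q) - log(c(lower, upper)))^2)
  }
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  if (fit$value > 1e-6)
    warning("beta quantile fit imperfect (objective ", signif(fit$value, 3), ")",
            call. = FALSE)
  exp(fit$par)
}

#' Syria-like synthetic fixture
#'
#' Bundles the default synthetic inputs used throughout the package: a
#' young population pyramid whose total is anchored so that a 12.9%
#' age-standardised PTSD prevalence yields 2.2 million prevalent cases, a
#' calibrated Gompertz-Makeham mortality schedule, and PTSD / depression
#' prevalence curves age-standardising to 12.9% and 7.6%.
#'
#' @param total Population total; default `2.2e6 / 0.129`.
#' @param seed Seed recorded with the fixture.
#' @return List with elements `population`, `mortality`, `ptsd`,
#'   `depression` (prevalence curves).
#' @export
syria_fixture <- function(total = 2.2e6 / 0.129, seed = 20150101L) {
  pop <- make_population(total, shape = "young", seed = seed)
  list(population = pop,
       mortality = make_mortality(),
       ptsd = make_prevalence_curve("ptsd", 0.129, pop),
       depression = make_prevalence_curve("depression", 0.076, pop))
}
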