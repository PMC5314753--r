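# Shared fixtures, built once per test run.

fx <- syria_fixture()

fixture_partition <- function() {
  comorbidity_partition(prevalent_cases(fx$ptsd, fx$population),
                        prevalent_cases(fx$depression, fx$population))
}

fixture_eligibles <- function() {
  c(eligible_population(fixture_partition(), default_severity_models()),
    perinatal = eligible_perinatal(fx$population))
}

# Cache the benefit setup (two incidence back-calculations) across tests.
fixture_benefit_setup <- local({
  setup <- NULL
  function() {
    if (is.null(setup)) setup <<- benefit_setup(fx)
    setup
  }
})

# all cases at one adult age, for scalar-total arithmetic through the
# age-indexed interfaces
cases_at_age <- function(total, age = 30, group = "cases") {
  v <- numeric(101)
  v[age + 1] <- total
  structure(data.frame(age = 0:100, cases = v),
            class = c("case_counts", "data.frame"), group = group)
}

# classical RK4 integration of the three-state system, used as the
# fine-grid ODE oracle for the closed-form one-year step
ode_oracle_step <- function(state, i, r, f, m, substeps = 1000) {
  deriv <- function(x) c(-(i + m) * x[1] + r * x[2],
                         i * x[1] - (r + m + f) * x[2],
                         m * x[1] + (m + f) * x[2])
  h <- 1 / substeps
  x <- state
  for (k in seq_len(substeps)) {
    k1 <- deriv(x); k2 <- deriv(x + h / 2 * k1)
    k3 <- deriv(x + h / 2 * k2); k4 <- deriv(x + h * k3)
    x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  x
}
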