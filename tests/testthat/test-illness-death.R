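test_that("the one-year step matches closed forms and conserves mass", {
  # no hazards: nothing moves
  st <- step_year(c(100, 50, 5), 0, 0, 0, 0)
  expect_equal(st$state, c(S = 100, C = 50, D = 5))

  # pure incidence: exponential decay into the diseased state
  st2 <- step_year(c(1000, 0, 0), i = 0.1, r = 0, f = 0, m = 0)
  expect_equal(unname(st2$state["C"]), 1000 * (1 - exp(-0.1)), tolerance = 1e-12)

  # total case mortality hazard is RR times background
  m <- make_mortality()
  f <- excess_mortality_from_rr(m, 1.9)
  expect_equal(f$hazard + m$hazard, 1.9 * m$hazard)
  expect_equal(excess_mortality_from_rr(m, 1)$hazard, rep(0, 101))
  expect_error(excess_mortality_from_rr(m, 0.8), ">= 1")
  expect_error(step_year(c(1, 0, 0), -0.1, 0, 0, 0), "non-negative")
})

test_that("the closed-form step agrees with a 1000-substep ODE oracle", {
  set.seed(20150101)
  for (k in 1:20) {
    h <- runif(4, 0, 2)
    x0 <- c(runif(1, 100, 1000), runif(1, 0, 500), 0)
    got <- step_year(x0, h[1], h[2], h[3], h[4])$state
    want <- ode_oracle_step(x0, h[1], h[2], h[3], h[4])
    expect_equal(unname(got), want, tolerance = 1e-6)
  }
})

test_that("cohort mass is conserved along trajectories to 1e-10 relative", {
  set.seed(99)
  for (k in 1:10) {
    h <- runif(4, 0, 2)
    x0 <- c(800, 200, 0)
    x <- x0
    for (t in 1:30) x <- step_year(x, h[1], h[2], h[3], h[4])$state
    expect_lt(abs(sum(x) - sum(x0)) / sum(x0), 1e-10)
  }
})

test_that("forward solutions reproduce analytic prevalence limits", {
  # no transitions: prevalence stays at its initial value
  tr <- solve_forward(list(incidence = 0, remission = 0, excess = 0,
                           background = 0.01), c(900, 100, 0), 20, 60)
  expect_equal(tr$prevalence, rep(0.1, 41))

  # constant incidence, equal mortality in both states: p = 1 - exp(-i a)
  tr2 <- solve_forward(list(incidence = 0.02, remission = 0, excess = 0,
                            background = 0.015), c(1000, 0, 0), 0, 100)
  expect_equal(tr2$prevalence, 1 - exp(-0.02 * (0:100)), tolerance = 1e-9)

  # bounds always hold
  tr3 <- solve_forward(list(incidence = 0.5, remission = 1.2, excess = 0.05,
                            background = 0.01), c(500, 500, 0), 0, 100)
  expect_true(all(tr3$prevalence >= 0 & tr3$prevalence <= 1))
  expect_error(solve_forward(list(incidence = 0, remission = 0, excess = 0,
                                  background = 0), c(1, 0, 0), 50, 20),
               "age_from < age_to")
})

test_that("incidence back-calculation is self-consistent and recovers known rates", {
  m <- fx$mortality$hazard
  # zero target prevalence from a disease-free start needs no incidence
  z <- data.frame(age = 0:100, prevalence = rep(0, 101))
  fit0 <- fit_incidence(z, remission = 0.2, excess = 0, background = m)
  expect_equal(fit0$incidence$incidence, rep(0, 101))

  # round-trip: forward solution of the fit reproduces the target
  cv <- make_prevalence_curve("x", 0.05, fx$population)
  fit <- fit_incidence(cv, remission = 0.17, excess = 0, background = m)
  expect_lt(max(abs(fit$fitted - cv$prevalence)), 1e-6)
  pred <- predict(fit)
  expect_lt(max(abs(pred$prevalence - cv$prevalence)), 1e-6)

  # parameter recovery from forward-simulated prevalence
  tr <- solve_forward(list(incidence = 0.02, remission = 0.17, excess = 0,
                           background = m), c(1, 0, 0), 0, 100)
  fit2 <- fit_incidence(data.frame(age = 0:100, prevalence = tr$prevalence),
                        remission = 0.17, excess = 0, background = m)
  expect_lt(max(abs(fit2$incidence$incidence[1:100] - 0.02) / 0.02), 0.01)
})

test_that("declining prevalence clamps incidence at zero with a diagnostic", {
  p <- c(seq(0, 0.3, length.out = 31), seq(0.3, 0.05, length.out = 70))
  tgt <- data.frame(age = 0:100, prevalence = p)
  expect_message(fit <- fit_incidence(tgt, remission = 0.01, excess = 0,
                                      background = 0.005), "clamped")
  expect_gt(length(fit$clamped), 0)
  expect_true(all(fit$incidence$incidence >= 0))
})

test_that("dismod_fit behaves like a fitted model object", {
  cv <- make_prevalence_curve("x", 0.05, fx$population)
  fit <- fit_incidence(cv, remission = 0.17, excess = 0,
                       background = fx$mortality$hazard)
  expect_s3_class(fit, "dismod_fit")
  expect_length(coef(fit), 101)
  expect_equal(unname(residuals(fit)), unname(fitted(fit) - cv$prevalence))
  expect_output(print(fit), "Illness-death")
  s <- summary(fit)
  expect_lt(s$max_abs_residual, 1e-6)
  expect_error(fit_incidence(data.frame(age = 0:100, prevalence = rep(1, 101)),
                             0.1, 0, 0.01), "\\[0, 1\\)")
})
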