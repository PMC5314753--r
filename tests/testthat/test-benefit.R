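test_that("combined effectiveness follows the WHO-CHOICE combination", {
  one <- list(intervention_package("a", coverage_target = 1,
                                   d_remission = 0.5, d_dw = 0.5))
  expect_equal(combined_effectiveness(one, 1, "remission"), 0.5)
  two <- list(intervention_package("a", 1, 0.5, 0.5),
              intervention_package("b", 1, 0.5, 0.5))
  expect_equal(combined_effectiveness(two, 1, "remission"), 0.75)
  zero <- list(intervention_package("a", 1, 0, 0))
  expect_equal(combined_effectiveness(zero, 1, "dw"), 0)
  # scales with the scale-up coverage
  expect_equal(combined_effectiveness(one, 0.5, "remission"), 0.25)
  expect_error(combined_effectiveness(one, 1.2, "remission"), "\\[0, 1\\]")
})

test_that("effectiveness adjusts remission up and disability weight down", {
  id <- apply_effectiveness(1.4, 0.3, eff = 0)
  expect_equal(id$remission, 1.4)
  expect_equal(id$dw, 0.3)
  expect_equal(apply_effectiveness(1.4, 0.3, eff = 0.4, d_remission = 0.5,
                                   d_dw = 0)$remission, 1.68)
  expect_equal(apply_effectiveness(1, 0.3, eff = 1, d_remission = 0,
                                   d_dw = 1)$dw, 0)
  expect_error(apply_effectiveness(1, 0.3, eff = 1.5), "\\[0, 1\\]")
})

test_that("scenario scale-up series match their definitions", {
  expect_equal(scenario_scaleup("partial_null"), rep(0, 15))
  expect_equal(scenario_scaleup("current"), rep(0.01, 15))
  lin <- scenario_scaleup("target30", "linear")
  expect_equal(lin[1], 0.01)
  expect_equal(lin[15], 0.30)
  expect_equal(scenario_scaleup("target100", "exponential")[15], 1)
})

test_that("cohorts conserve people and produce no YLDs without disease", {
  setup <- fixture_benefit_setup()
  stream <- setup$streams$ptsd
  res <- run_cohort(1000, 22, stream, rep(0, 15), rep(0, 15))
  mass <- res$alive[15] + res$final_state[["D"]]
  expect_equal(mass, 1000, tolerance = 1e-10)

  empty <- stream
  empty$prev_ms <- rep(0, 101)
  empty$incidence <- rep(0, 101)
  res0 <- run_cohort(1000, 22, empty, rep(0, 15), rep(0, 15))
  expect_equal(res0$ylds, rep(0, 15))
})

test_that("scenario engine is deterministic and null-consistent", {
  setup <- fixture_benefit_setup()
  null1 <- run_scenario(setup, "partial_null", "linear")
  null2 <- run_scenario(setup, "partial_null", "linear")
  expect_identical(null1$total, null2$total)
  expect_equal(averted_burden(null1, null2)$averted, 0)
  expect_equal(averted_burden(null1, null2)$percent, 0)

  # zero-efficacy packages avert exactly zero
  setup0 <- setup
  setup0$packages <- list(intervention_package("null", 0.3, 0, 0))
  s100 <- run_scenario(setup0, "target100", "linear")
  expect_equal(averted_burden(s100, run_scenario(setup0, "partial_null",
                                                 "linear"))$averted, 0)

  # current coverage averts a small positive burden
  cur <- run_scenario(setup, "current", "linear")
  av <- averted_burden(cur, null1)
  expect_gt(av$averted, 0)
  expect_lt(av$percent, 2)
})

test_that("averted burden is monotone in coverage and efficacy", {
  setup <- fixture_benefit_setup()
  null <- run_scenario(setup, "partial_null", "linear")
  pct <- function(sc) averted_burden(run_scenario(setup, sc, "linear"), null)$percent
  p_cur <- pct("current"); p_30 <- pct("target30"); p_100 <- pct("target100")
  expect_true(p_cur < p_30 && p_30 < p_100)

  # halved efficacies avert less
  weak <- setup
  weak$packages <- lapply(setup$packages, function(p) {
    p$d_remission <- p$d_remission / 2; p$d_dw <- p$d_dw / 2; p
  })
  null_w <- run_scenario(weak, "partial_null", "linear")
  p_30w <- averted_burden(run_scenario(weak, "target30", "linear"), null_w)$percent
  expect_lt(p_30w, p_30)
})

test_that("linear scale-up dominates exponential scale-up in cumulative averted burden", {
  setup <- fixture_benefit_setup()
  for (sc in c("target30", "target100")) {
    av_lin <- averted_burden(run_scenario(setup, sc, "linear"),
                             run_scenario(setup, "partial_null", "linear"))
    av_exp <- averted_burden(run_scenario(setup, sc, "exponential"),
                             run_scenario(setup, "partial_null", "exponential"))
    expect_gt(av_lin$averted, av_exp$averted)
  }
})

test_that("discounting matches the closed-form annuity and lowers totals", {
  expect_equal(discount(rep(1, 15), 0), 15)
  expect_equal(discount(rep(1, 15), 0.03), sum(1.03^-(0:14)), tolerance = 1e-12)
  expect_equal(discount(rep(1, 15), 0.03), 12.296, tolerance = 1e-4)
  s <- runif(15, 0, 10)
  expect_lte(discount(s, 0.05), sum(s))
  expect_error(discount(1:3, -0.01), "non-negative")
})

test_that("3% discounting shifts percent averted by only a few points", {
  setup <- fixture_benefit_setup()
  for (sc in c("target30", "target100")) {
    p0 <- averted_burden(run_scenario(setup, sc, "linear"),
                         run_scenario(setup, "partial_null", "linear"))$percent
    p3 <- averted_burden(run_scenario(setup, sc, "linear", discount_rate = 0.03),
                         run_scenario(setup, "partial_null", "linear",
                                      discount_rate = 0.03))$percent
    expect_lt(abs(p0 - p3), 5)
  }
})
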