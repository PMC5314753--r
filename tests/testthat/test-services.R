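toy_staffing <- function() {
  providers <- "clinician"
  staffing_parameters(
    days_per_year = c(clinician = 240),
    consults_per_day = matrix(10, 3, 1,
      dimnames = list(c("primary_care", "ancillary", "outpatient"), providers)),
    shares = matrix(1, 3, 1,
      dimnames = list(c("primary_care", "ancillary", "outpatient"), providers)),
    staff_per_ward = c(clinician = 4))
}

test_that("coverage trajectories interpolate between the stated endpoints", {
  lin <- coverage_trajectory(0.01, 0.30, mode = "linear")
  exp_ <- coverage_trajectory(0.01, 0.30, mode = "exponential")
  expect_equal(coverage_at(lin, 0), 0.01)
  expect_equal(coverage_at(exp_, 0), 0.01)
  expect_equal(coverage_at(lin, 14), 0.30)
  expect_equal(coverage_at(exp_, 14), 0.30)
  # geometric midpoint
  expect_equal(coverage_at(exp_, 7), sqrt(0.01 * 0.30))
  # monotone, and linear dominates exponential strictly inside the horizon
  expect_true(all(diff(lin$coverage) > 0) && all(diff(exp_$coverage) > 0))
  expect_true(all(lin$coverage[2:14] >= exp_$coverage[2:14]))
  expect_error(coverage_trajectory(0, 0.3, mode = "exponential"), "undefined")
  expect_error(coverage_at(lin, 15), "out of range")
})

test_that("eligible populations apply the moderate-severe 15+ rule", {
  sev <- default_severity_models()
  # 1000 depression cases aged 15+ at 28% -> 280 eligible
  part <- list(ptsd_only = cases_at_age(0), dep_only = cases_at_age(1000, 30),
               comorbid = cases_at_age(0))
  e <- eligible_population(part, sev)
  expect_equal(unname(e["dep_only"]), 280)
  expect_equal(unname(e["ptsd_only"]), 0)
  # all cases under 15 -> none eligible
  part2 <- list(ptsd_only = cases_at_age(500, age = 10),
                dep_only = cases_at_age(0), comorbid = cases_at_age(0))
  expect_equal(unname(eligible_population(part2, sev)["ptsd_only"]), 0)
  # PTSD-only uses the 30% anxiety share
  part3 <- list(ptsd_only = cases_at_age(1000, 40), dep_only = cases_at_age(0),
                comorbid = cases_at_age(0))
  expect_equal(unname(eligible_population(part3, sev)["ptsd_only"]), 300)
})

test_that("perinatal eligibility is the stated product of proportions", {
  w <- numeric(101); w[31] <- 1  # all persons aged 30
  pop <- make_population(100000 / 0.493, shape = "custom", weights = w)
  # 100,000 women aged 15-44: x 0.11 x 0.15 x 0.28 = 462
  expect_equal(eligible_perinatal(pop), 462)
  expect_equal(eligible_perinatal(pop, fertility = 0.22), 924)  # linear
  pop0 <- make_population(1000, shape = "custom",
                          weights = c(rep(1, 10), rep(0, 91)))
  expect_equal(eligible_perinatal(pop0), 0)
})

test_that("visit and bed-day arithmetic follows the product rules", {
  pkg <- care_package("p", groups = "dep_only", coverage_target = 0.5,
                      rows = data.frame(type = "primary_care", proportion = 1,
                                        visits = 4, minutes = 20,
                                        pct_use = NA, bed_days = NA))
  expect_equal(unname(visits_required(1000, 0.5, pkg)["primary_care"]), 2000)
  expect_equal(sum(visits_required(1000, 0, pkg)), 0)

  ip <- care_package("ip", groups = c("dep_only"), coverage_target = 0.3,
                     rows = data.frame(type = "inpatient", proportion = NA,
                                       visits = NA, minutes = NA,
                                       pct_use = 0.05, bed_days = 14))
  expect_equal(bed_days_required(1000, 0.01, ip, "dep_only"), 7)
  expect_error(bed_days_required(1000, 0.01, ip, "ptsd_only"), "PTSD-only")
  expect_error(bed_days_required(1000, 0.01, pkg), "no inpatient")
  # packages cannot assign inpatient care to PTSD-only cases at all
  expect_error(care_package("bad", groups = "ptsd_only", coverage_target = 0.3,
                            inpatient_groups = "ptsd_only",
                            rows = data.frame(type = "inpatient", proportion = NA,
                                              visits = NA, minutes = NA,
                                              pct_use = 0.05, bed_days = 14)),
               "ptsd_only")
})

test_that("bed conversion divides by 365 and inflates for 86% occupancy", {
  expect_equal(beds_required(0), 0)
  expect_equal(beds_required(365), 1.15)
  expect_equal(round(beds_required(44000)), 139)
})

test_that("FTE arithmetic follows the consultation and ward formulas", {
  st <- toy_staffing()
  expect_equal(sum(fte_outpatient(c(primary_care = 0, ancillary = 0,
                                    outpatient = 0), st)), 0)
  # 2400 visits, share 1, 10 consults/day, 240 days -> 1 FTE
  expect_equal(unname(fte_outpatient(c(primary_care = 2400, ancillary = 0,
                                       outpatient = 0), st)["clinician"]), 1)
  expect_equal(unname(fte_inpatient(25, st)["clinician"]), 4)
  expect_equal(unname(fte_inpatient(0, st)["clinician"]), 0)
  bad <- st; bad$consults_per_day["primary_care", ] <- 0
  expect_error(fte_outpatient(c(primary_care = 10, ancillary = 0,
                                outpatient = 0), bad), "zero consultations")
})

test_that("scale-up plans are monotone, additive and agree across modes at the endpoints", {
  elig <- fixture_eligibles()
  st <- default_staffing()
  total <- sum(fx$population$count)
  lin <- run_scaleup(elig, default_care_packages(), st, total, mode = "linear")
  exp_ <- run_scaleup(elig, default_care_packages(), st, total,
                      mode = "exponential")
  for (col in c("primary_care", "ancillary", "outpatient", "bed_days",
                "beds", "fte_total"))
    expect_true(all(diff(lin[[col]]) >= 0), info = col)
  # endpoint agreement between modes
  expect_equal(lin[c(1, 15), ], exp_[c(1, 15), ], tolerance = 1e-12,
               ignore_attr = TRUE)
  # dominance strictly inside the horizon
  expect_true(all(lin$fte_total[2:14] >= exp_$fte_total[2:14]))
  # additivity: provider FTEs sum to the total
  providers <- default_staffing()$providers
  expect_equal(unname(rowSums(as.data.frame(lin)[, providers])), lin$fte_total)
  # per-100k definition
  expect_equal(lin$fte_per_100k, lin$fte_total / total * 1e5)
})

test_that("a zero-coverage trajectory produces an all-zero plan", {
  elig <- fixture_eligibles()
  pk <- lapply(default_care_packages(), function(p) { p$coverage_target <- 0; p })
  plan <- run_scaleup(elig, pk, default_staffing(), sum(fx$population$count),
                      baseline = 0, mode = "linear")
  expect_equal(sum(plan$fte_total), 0)
  expect_equal(sum(plan$primary_care), 0)
})

test_that("PTSD-only cases generate no inpatient demand in the default configuration", {
  elig <- fixture_eligibles()
  elig["dep_only"] <- 0; elig["comorbid"] <- 0; elig["perinatal"] <- 0
  plan <- run_scaleup(elig, default_care_packages(), default_staffing(),
                      sum(fx$population$count))
  expect_equal(sum(plan$bed_days), 0)
  expect_gt(sum(plan$primary_care), 0)
})

test_that("incomplete configurations are rejected with the missing pieces named", {
  elig <- fixture_eligibles()[c("ptsd_only", "dep_only")]
  expect_error(run_scaleup(elig, default_care_packages(), default_staffing(),
                           1e6), "comorbid")
})
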