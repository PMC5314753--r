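TREATMENT_TYPES <- c("primary_care", "ancillary", "outpatient", "inpatient")

#' Construct a care package
#'
#' A care package names the case groups it applies to, its 2030 coverage
#' target, and one row per treatment type giving the proportion of
#' package recipients who receive that type, visits (or bed-days) per
#' person, minutes per visit and, for inpatient care, the percentage use.
#' PTSD-only cases never receive inpatient care: `inpatient_groups`
#' restricts the inpatient row (default: applicable groups minus
#' `"ptsd_only"`).
#'
#' @param name Package name.
#' @param groups Case groups the package applies to (subset of
#'   `ptsd_only`, `dep_only`, `comorbid`, `perinatal`).
#' @param coverage_target Target coverage in 2030, in \[0, 1\].
#' @param rows data.frame with columns `type`, `proportion`, `visits`,
#'   `minutes`, `pct_use`, `bed_days`.
#' @param inpatient_groups Groups eligible for the inpatient row.
#' @return A `care_package`.
#' @export
care_package <- function(name, groups, coverage_target, rows,
                         inpatient_groups = setdiff(groups, "ptsd_only")) {
  check_proportion(coverage_target, "coverage_target")
  if (!all(rows$type %in% TREATMENT_TYPES))
    stop_input("unknown treatment type(s): %s",
               paste(setdiff(rows$type, TREATMENT_TYPES), collapse = ", "))
  out_rows <- rows[rows$type != "inpatient", , drop = FALSE]
  if (nrow(out_rows) && (any(out_rows$proportion < 0 | out_rows$proportion > 1) ||
                         any(out_rows$visits < 0)))
    stop_input("package '%s': proportions must be in [0,1] and visits >= 0", name)
  if ("inpatient" %in% rows$type) {
    if ("ptsd_only" %in% inpatient_groups)
      stop_input("package '%s': inpatient care cannot be assigned to ptsd_only", name)
    ip <- rows[rows$type == "inpatient", ]
    if (any(ip$pct_use < 0 | ip$pct_use > 1) || any(ip$bed_days < 0))
      stop_input("package '%s': invalid inpatient parameters", name)
  }
  structure(list(name = name, groups = groups,
                 coverage_target = coverage_target, rows = rows,
                 inpatient_allowed = "inpatient" %in% rows$type,
                 inpatient_groups = if ("inpatient" %in% rows$type) inpatient_groups
                                    else character(0)),
            class = "care_package")
}

#' Construct staffing parameters
#'
#' @param days_per_year Named vector of working days per provider type.
#' @param consults_per_day Matrix (outpatient setting x provider) of
#'   consultations per day.
#' @param shares Matrix (outpatient setting x provider) of the share of
#'   each setting's care delivered by each provider; rows must sum to 1.
#' @param staff_per_ward Named vector of FTE staff per 25-bed ward.
#' @param ward_beds Beds per inpatient ward (default 25).
#' @param occupancy_factor Bed inflation factor (default 1.15, 86%
#'   occupancy).
#' @return A `staffing_parameters`.
#' @export
staffing_parameters <- function(days_per_year, consults_per_day, shares,
                                staff_per_ward, ward_beds = 25,
                                occupancy_factor = 1.15) {
  providers <- names(days_per_year)
  stopifnot(identical(colnames(consults_per_day), providers),
            identical(colnames(shares), providers),
            identical(names(staff_per_ward), providers))
  if (any(abs(rowSums(shares) - 1) > 1e-9))
    stop_input("provider shares must sum to 1 within each treatment type")
  if (any(days_per_year <= 0) || any(consults_per_day <= 0) ||
      ward_beds <= 0 || occupancy_factor <= 0)
    stop_input("staffing parameters must be positive")
  structure(list(providers = providers, days_per_year = days_per_year,
                 consults_per_day = consults_per_day, shares = shares,
                 staff_per_ward = staff_per_ward, ward_beds = ward_beds,
                 occupancy_factor = occupancy_factor),
            class = "staffing_parameters")
}

#' Coverage trajectory over the scale-up horizon
#'
#' Linear: `c0 + (cT - c0) * t/(T-1)`. Exponential (geometric):
#' `c0 * (cT/c0)^(t/(T-1))`. Both endpoints agree across modes.
#'
#' @param baseline Baseline coverage `c0` (default 0.01).
#' @param target Target coverage `cT`.
#' @param years Horizon length (default 15, indices `t = 0..14`).
#' @param mode `"linear"` or `"exponential"`.
#' @return A `coverage_trajectory` (list with a per-year `coverage` vector).
#' @export
coverage_trajectory <- function(baseline = 0.01, target, years = 15,
                                mode = c("linear", "exponential")) {
  mode <- match.arg(mode)
  check_proportion(baseline, "baseline")
  check_proportion(target, "target")
  if (mode == "exponential" && baseline <= 0)
    stop_input("exponential scale-up is undefined for baseline coverage 0")
  t <- seq_len(years) - 1
  cov <- if (mode == "linear") {
    baseline + (target - baseline) * t / (years - 1)
  } else {
    baseline * (target / baseline)^(t / (years - 1))
  }
  structure(list(baseline = baseline, target = target, years = years,
                 mode = mode, coverage = cov),
            class = "coverage_trajectory")
}

#' Coverage at a given year index
#' @param traj A `coverage_trajectory`.
#' @param t Year index `0..years-1`.
#' @export
coverage_at <- function(traj, t) {
  stopifnot(inherits(traj, "coverage_trajectory"))
  if (any(t < 0 | t > traj$years - 1)) stop_input("year index out of range")
  traj$coverage[t + 1]
}

#' Eligible population for treatment packages
#'
#' People aged 15+ with a moderate-severe case, per case group: the
#' moderate+severe severity share (30% for PTSD-only through the anxiety
#' model; 28% for depression-only and comorbid cases through the
#' depression model) applied to cases aged 15 and over.
#'
#' @param partition Output of [comorbidity_partition()].
#' @param severity Named list with `depression` and `anxiety`
#'   [severity_model()]s.
#' @param min_age Minimum eligible age (default 15).
#' @return Named vector of eligible persons for `ptsd_only`, `dep_only`,
#'   `comorbid`.
#' @export
eligible_population <- function(partition, severity = default_severity_models(),
                                min_age = 15) {
  props <- c(ptsd_only = severity$anxiety$moderate_severe_prop,
             dep_only = severity$depression$moderate_severe_prop,
             comorbid = severity$depression$moderate_severe_prop)
  if (any(is.na(props))) stop_input("missing moderate-severe severity proportion")
  vapply(names(props), function(g) {
    cc <- partition[[g]]
    sum(cc$cases[cc$age >= min_age]) * props[[g]]
  }, numeric(1))
}

#' Eligible population for the perinatal depression package
#'
#' Women aged 15-44 who gave birth during the year (fertility 11%) and
#' had moderate-severe perinatal depression (15% perinatal depression
#' prevalence, 28% moderate-severe share).
#'
#' @param population A `population_table` (its `female_share` attribute
#'   supplies the female proportion).
#' @param fertility Annual births per woman 15-44 (default 0.11).
#' @param perinatal_prev Perinatal depression prevalence (default 0.15).
#' @param moderate_severe Moderate-severe share (default 0.28).
#' @return Eligible persons.
#' @export
eligible_perinatal <- function(population, fertility = 0.11,
                               perinatal_prev = 0.15, moderate_severe = 0.28) {
  check_age_table(population, "count", "population")
  women <- sum(population$count[population$age >= 15 & population$age <= 44]) *
    (attr(population, "female_share") %||% 0.5)
  women * fertility * perinatal_prev * moderate_severe
}

#' Visits required for the outpatient components of a care package
#'
#' Per treatment type: `eligible x coverage x proportion receiving x
#' visits per person`.
#'
#' @param eligible Eligible persons.
#' @param coverage Treatment coverage, in \[0, 1\].
#' @param pkg A `care_package`.
#' @return Named vector of visits for `primary_care`, `ancillary`,
#'   `outpatient` (zero where the package has no such component).
#' @export
visits_required <- function(eligible, coverage, pkg) {
  check_number(eligible, "eligible", lower = 0)
  check_proportion(coverage, "coverage")
  out <- c(primary_care = 0, ancillary = 0, outpatient = 0)
  rows <- pkg$rows[pkg$rows$type != "inpatient", , drop = FALSE]
  for (i in seq_len(nrow(rows)))
    out[rows$type[i]] <- eligible * coverage * rows$proportion[i] * rows$visits[i]
  out
}

#' Bed-days required for the inpatient component of a care package
#'
#' `eligible x coverage x percentage use x bed-days per person`; errors
#' for groups excluded from inpatient care (PTSD-only).
#'
#' @param eligible Eligible persons.
#' @param coverage Treatment coverage.
#' @param pkg A `care_package` with an inpatient row.
#' @param group Case group receiving care (inpatient demand for
#'   `"ptsd_only"` is an error by design).
#' @return Bed-days per year.
#' @export
bed_days_required <- function(eligible, coverage, pkg, group = "dep_only") {
  if (!pkg$inpatient_allowed)
    stop_input("package '%s' has no inpatient component", pkg$name)
  if (identical(group, "ptsd_only"))
    stop_input("inpatient treatment is excluded for PTSD-only cases")
  check_number(eligible, "eligible", lower = 0)
  check_proportion(coverage, "coverage")
  ip <- pkg$rows[pkg$rows$type == "inpatient", ]
  eligible * coverage * ip$pct_use * ip$bed_days
}

#' Beds required for a bed-day total
#'
#' `bed_days / 365 * occupancy_factor` (1.15, i.e. 86% occupancy).
#' Unrounded; round at report time.
#'
#' @param bed_days Bed-days per year.
#' @param occupancy_factor Default 1.15.
#' @return Beds (real).
#' @export
beds_required <- function(bed_days, occupancy_factor = 1.15) {
  if (any(bed_days < 0)) stop_input("bed_days must be non-negative")
  bed_days / 365 * occupancy_factor
}

#' FTE staff for community/outpatient care
#'
#' For each provider: total visits in each setting, times the share of
#' that setting's care delivered by the provider, divided by annual
#' consultations (consultations per day x days worked per year), summed
#' over settings.
#'
#' @param visits Named vector of visits (`primary_care`, `ancillary`,
#'   `outpatient`).
#' @param staffing A `staffing_parameters`.
#' @return Named vector of FTE by provider type.
#' @export
fte_outpatient <- function(visits, staffing) {
  stopifnot(inherits(staffing, "staffing_parameters"))
  fte <- stats::setNames(numeric(length(staffing$providers)), staffing$providers)
  for (setting in rownames(staffing$shares)) {
    v <- visits[[setting]] %||% 0
    if (is.na(v) || v == 0) next
    sh <- staffing$shares[setting, ]
    cons_yr <- staffing$consults_per_day[setting, ] * staffing$days_per_year
    active <- sh > 0
    if (any(active & cons_yr == 0))
      stop_input("zero consultations/day with a nonzero share in '%s'", setting)
    fte[active] <- fte[active] + v * sh[active] / cons_yr[active]
  }
  fte
}

#' FTE staff for inpatient care
#'
#' `beds / 25 x staff of each provider type per 25-bed ward`.
#'
#' @param beds Beds (real, unrounded).
#' @param staffing A `staffing_parameters`.
#' @return Named vector of FTE by provider type.
#' @export
fte_inpatient <- function(beds, staffing) {
  stopifnot(inherits(staffing, "staffing_parameters"))
  if (beds < 0) stop_input("beds must be non-negative")
  beds / staffing$ward_beds * staffing$staff_per_ward
}

#' Run the full service scale-up model over the 15-year horizon
#'
#' For each year, applies the scale-up coverage to every care package
#' (each package's coverage runs from the baseline rate to its own
#' target), accumulates visits and bed-days over packages and case
#' groups, converts bed-days to beds, and computes FTE staff by provider
#' type plus FTE per 100,000 population.
#'
#' @param eligibles Named vector from [eligible_population()], optionally
#'   with a `perinatal` element (see [eligible_perinatal()]).
#' @param packages List of `care_package`s.
#' @param staffing A `staffing_parameters`.
#' @param population_total Total population (for the per-100k rate).
#' @param baseline Baseline coverage (default 0.01).
#' @param mode `"linear"` or `"exponential"`.
#' @param years Horizon (default 15).
#' @return A `resource_plan`: data.frame with one row per year (columns:
#'   `year`, visit totals by type, `bed_days`, `beds`, FTE per provider,
#'   `fte_total`, `fte_per_100k`).
#' @export
run_scaleup <- function(eligibles, packages, staffing, population_total,
                        baseline = 0.01, mode = c("linear", "exponential"),
                        years = 15) {
  mode <- match.arg(mode)
  if (!all(vapply(packages, inherits, logical(1), "care_package")))
    stop_input("'packages' must be a list of care_package objects")
  missing_groups <- setdiff(unlist(lapply(packages, `[[`, "groups")),
                            names(eligibles))
  if (length(missing_groups))
    stop_input("eligibles missing for group(s): %s",
               paste(missing_groups, collapse = ", "))

  trajs <- lapply(packages, function(p)
    coverage_trajectory(baseline, p$coverage_target, years, mode))
  rows <- vector("list", years)
  for (t in seq_len(years) - 1) {
    visits <- c(primary_care = 0, ancillary = 0, outpatient = 0)
    bed_days <- 0
    for (k in seq_along(packages)) {
      pkg <- packages[[k]]
      cov <- coverage_at(trajs[[k]], t)
      for (g in pkg$groups) {
        visits <- visits + visits_required(eligibles[[g]], cov, pkg)
        if (pkg$inpatient_allowed && g %in% pkg$inpatient_groups)
          bed_days <- bed_days + bed_days_required(eligibles[[g]], cov, pkg, g)
      }
    }
    beds <- beds_required(bed_days, staffing$occupancy_factor)
    fte <- fte_outpatient(visits, staffing) + fte_inpatient(beds, staffing)
    rows[[t + 1]] <- c(year = t, visits, bed_days = bed_days, beds = beds,
                       fte, fte_total = sum(fte),
                       fte_per_100k = sum(fte) / population_total * 1e5)
  }
  out <- as.data.frame(do.call(rbind, rows))
  structure(out, class = c("resource_plan", "data.frame"),
            mode = mode, baseline = baseline)
}

#' @export
print.resource_plan <- function(x, ...) {
  if (!all(c("year", "primary_care", "fte_per_100k") %in% names(x)))
    return(NextMethod())
  cat(sprintf("Service scale-up plan (%s mode), %d years\n",
              attr(x, "mode"), nrow(x)))
  show <- data.frame(year = x$year,
                     primary_care = round(x$primary_care),
                     ancillary = round(x$ancillary),
                     outpatient = round(x$outpatient),
                     bed_days = round(x$bed_days),
                     beds = round(x$beds),
                     fte_total = round(x$fte_total, 1),
                     fte_per_100k = round(x$fte_per_100k, 2))
  print(show, row.names = FALSE)
  invisible(x)
}
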