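# Default numerical configuration.
#
# Severity splits and disability weights follow the GBD 2010 convention:
# four classes (asymptomatic carries DW 0), with moderate+severe shares of
# 28% for major depression and 30% for the anxiety-disorders model used as
# the PTSD proxy. Care-package and staffing values are an mhGAP-costing-tool
# style reconstruction (see the methods vignette for how each block was
# fixed); all of them can be overridden through the YAML config.

#' Default GBD-2010-style severity models
#'
#' @return Named list of two [severity_model()]s: `depression` (major
#'   depression) and `anxiety` (anxiety disorders, used as the PTSD proxy).
#' @export
default_severity_models <- function() {
  dep <- data.frame(
    class      = c("asymptomatic", "mild", "moderate", "severe"),
    proportion = c(0.145, 0.575, 0.197, 0.083),
    dw         = c(0, 0.159, 0.406, 0.655),
    dw_lower   = c(0, 0.107, 0.276, 0.469),
    dw_upper   = c(0, 0.223, 0.551, 0.816))
  anx <- data.frame(
    class      = c("asymptomatic", "mild", "moderate", "severe"),
    proportion = c(0.102, 0.598, 0.148, 0.152),
    dw         = c(0, 0.030, 0.133, 0.523),
    dw_lower   = c(0, 0.018, 0.091, 0.362),
    dw_upper   = c(0, 0.046, 0.186, 0.677))
  list(depression = severity_model("depression", dep),
       anxiety = severity_model("anxiety", anx))
}

#' Default care packages (mhGAP-style)
#'
#' Four packages: basic psychosocial treatment, anti-depressant
#' medication, intensive psychosocial intervention (with a small inpatient
#' component) and perinatal psychosocial care. Depression packages are
#' also assigned to PTSD-only cases, but with inpatient care excluded for
#' that group. `coverage_target` is the 2030 target coverage of each
#' package.
#'
#' @return List of `care_package` objects.
#' @export
default_care_packages <- function() {
  list(
    care_package(
      name = "basic_psychosocial",
      groups = c("ptsd_only", "dep_only", "comorbid"),
      coverage_target = 0.30,
      rows = data.frame(
        type = c("primary_care", "ancillary"),
        proportion = c(1, 1), visits = c(3, 6),
        minutes = c(20, 30), pct_use = c(NA, NA), bed_days = c(NA, NA))),
    care_package(
      name = "antidepressant_medication",
      groups = c("ptsd_only", "dep_only", "comorbid"),
      coverage_target = 0.30,
      rows = data.frame(
        type = c("primary_care", "ancillary"),
        proportion = c(1, 1), visits = c(4, 8),
        minutes = c(15, 15), pct_use = c(NA, NA), bed_days = c(NA, NA))),
    care_package(
      name = "intensive_psychosocial",
      groups = c("ptsd_only", "dep_only", "comorbid"),
      coverage_target = 0.10,
      inpatient_groups = c("dep_only", "comorbid"),
      rows = data.frame(
        type = c("outpatient", "inpatient"),
        proportion = c(0.12, NA), visits = c(8, NA),
        minutes = c(45, NA), pct_use = c(NA, 0.02), bed_days = c(NA, 17))),
    care_package(
      name = "perinatal_psychosocial",
      groups = "perinatal",
      coverage_target = 0.30,
      rows = data.frame(
        type = c("primary_care", "ancillary"),
        proportion = c(1, 1), visits = c(3, 3),
        minutes = c(30, 30), pct_use = c(NA, NA), bed_days = c(NA, NA))))
}

#' Default staffing parameters (mhGAP-style)
#'
#' Provider-level working days, consultations per day by treatment type,
#' the share of each treatment type delivered by each provider (shares sum
#' to 1 within a type), ward staffing per 25-bed inpatient ward, and the
#' occupancy factor (1.15, i.e. 86% occupancy).
#'
#' @return A `staffing_parameters` object.
#' @export
default_staffing <- function() {
  providers <- c("psychiatrist", "other_physician", "nurse",
                 "psychologist", "psychosocial_worker", "other_provider")
  days <- c(psychiatrist = 220, other_physician = 230, nurse = 230,
            psychologist = 220, psychosocial_worker = 230, other_provider = 230)
  consults <- rbind(  # consultations per day, by outpatient-type setting
    primary_care = c(12, 20, 15, 10, 12, 12),
    ancillary    = c(10, 14, 12, 10, 10, 10),
    outpatient   = c(8, 10, 10, 8, 8, 8))
  colnames(consults) <- providers
  shares <- rbind(    # proportion of care in each setting, by provider
    primary_care = c(0.00, 0.30, 0.50, 0.00, 0.00, 0.20),
    ancillary    = c(0.00, 0.00, 0.30, 0.00, 0.50, 0.20),
    outpatient   = c(0.25, 0.20, 0.00, 0.55, 0.00, 0.00))
  colnames(shares) <- providers
  ward <- c(psychiatrist = 0.5, other_physician = 1, nurse = 10,
            psychologist = 0.5, psychosocial_worker = 1, other_provider = 3)
  staffing_parameters(days_per_year = days, consults_per_day = consults,
                      shares = shares, staff_per_ward = ward,
                      ward_beds = 25, occupancy_factor = 1.15)
}

#' Default intervention packages for the health-benefit model
#'
#' Effect sizes (proportional change in remission and in disability
#' weight) are derived calibration values, fixed once so that the
#' synthetic fixture reproduces published avertable-burden magnitudes;
#' they are not published inputs. `coverage_target` is the target
#' population coverage multiplied by the scenario's scale-up coverage to
#' give total coverage.
#'
#' @return List of `intervention_package` objects.
#' @export
default_intervention_packages <- function() {
  list(
    intervention_package("basic_psychosocial", coverage_target = 0.30,
                         d_remission = 0.55, d_dw = 0.40),
    intervention_package("antidepressant_medication", coverage_target = 0.30,
                         d_remission = 0.65, d_dw = 0.50),
    intervention_package("intensive_psychosocial", coverage_target = 0.10,
                         d_remission = 0.80, d_dw = 0.60))
}

#' Default epidemiological parameters for the illness-death model
#'
#' Remission 1.40/year for depression (average episode duration 37.7
#' weeks) and 0.17/year for PTSD; depression all-cause mortality relative
#' risk 1.9; PTSD case fatality zero.
#'
#' @return Named list per disorder stream.
#' @export
default_epi_params <- function() {
  list(ptsd = list(remission = 0.17, rr_mortality = 1.0),
       depression = list(remission = 1.40, rr_mortality = 1.9))
}
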