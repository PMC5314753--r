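#' Read an age-indexed table from CSV
#'
#' Expects a headered CSV with columns `age` and `value` (or a named
#' value column such as `count`, `hazard`, `prevalence`, `cases`),
#' contiguous single-year ages 0-100, no duplicates or gaps.
#'
#' @param path CSV path.
#' @param value One of `"count"`, `"hazard"`, `"prevalence"`, `"cases"`,
#'   `"value"`: the column (and resulting class) to read.
#' @return A classed age table (`population_table`,
#'   `mortality_schedule`, `prevalence_curve`, `case_counts`, or plain
#'   data.frame for `"value"`).
#' @export
read_age_table <- function(path, value = c("value", "count", "hazard",
                                           "prevalence", "cases")) {
  value <- match.arg(value)
  if (!file.exists(path)) stop_input("file not found: %s", path)
  df <- utils::read.csv(path, colClasses = "numeric")
  col <- if (value %in% names(df)) value else setdiff(names(df), "age")[1]
  if (!("age" %in% names(df)) || is.na(col))
    stop_input("%s: need columns 'age' and a value column", path)
  dup <- df$age[duplicated(df$age)]
  if (length(dup))
    stop_input("%s: duplicate age %s", path, paste(unique(dup), collapse = ", "))
  missing <- setdiff(AGES, df$age)
  if (length(missing))
    stop_input("%s: missing age(s) %s", path,
               paste(utils::head(missing, 5), collapse = ", "))
  df <- df[order(df$age), c("age", col)]
  names(df) <- c("age", if (value == "value") "value" else value)
  rownames(df) <- NULL
  cls <- switch(value, count = "population_table", hazard = "mortality_schedule",
                prevalence = "prevalence_curve", cases = "case_counts", NULL)
  if (!is.null(cls)) class(df) <- c(cls, "data.frame")
  if (value == "count") attr(df, "female_share") <- 0.493
  df
}

#' Write an age-indexed table to CSV
#'
#' @param x A data.frame with an `age` column and one value column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_age_table <- function(x, path) {
  utils::write.csv(as.data.frame(x)[, c("age", setdiff(names(x), "age")[1])],
                   path, row.names = FALSE)
  invisible(path)
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML configuration with the blocks the pipeline stages use
#' (`population`, `prevalence`, `severity`, `services`, `benefit`,
#' `seed`) and validates every field, collecting all violations rather
#' than stopping at the first.
#'
#' @param path YAML file path. `NULL` loads the packaged default
#'   configuration (`inst/extdata/default_config.yaml`).
#' @return A validated `run_config` list.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "default_config.yaml", package = "mhplan")
  if (!file.exists(path)) stop_input("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  problems <- character(0)
  need <- function(cond, msg) if (!isTRUE(cond)) problems <<- c(problems, msg)

  need(is.numeric(cfg$population$total) && cfg$population$total > 0,
       "population.total must be a positive number")
  need(is.numeric(cfg$seed), "seed must be numeric")
  for (d in c("ptsd", "depression")) {
    p <- cfg$prevalence[[d]]
    need(!is.null(p), sprintf("prevalence.%s block missing", d))
    if (!is.null(p)) {
      need(is.numeric(p$point) && p$point > 0 && p$point < 1,
           sprintf("prevalence.%s.point must be in (0,1)", d))
      need(is.numeric(p$lower) && is.numeric(p$upper) &&
             p$lower <= p$point && p$point <= p$upper,
           sprintf("prevalence.%s must satisfy lower <= point <= upper", d))
    }
  }
  need(is.numeric(cfg$prevalence$comorbid_rho) &&
         cfg$prevalence$comorbid_rho >= 0 && cfg$prevalence$comorbid_rho <= 1,
       "prevalence.comorbid_rho must be in [0,1]")
  for (d in c("depression", "anxiety")) {
    sv <- cfg$severity[[d]]
    need(!is.null(sv), sprintf("severity.%s block missing", d))
    if (!is.null(sv)) {
      pr <- vapply(sv$classes, function(k) k$proportion, numeric(1))
      dw <- vapply(sv$classes, function(k) k$dw, numeric(1))
      need(abs(sum(pr) - 1) < 1e-9,
           sprintf("severity.%s class proportions must sum to 1", d))
      need(all(dw >= 0 & dw <= 1),
           sprintf("severity.%s disability weights must be in [0,1]", d))
    }
  }
  need(is.numeric(cfg$services$baseline_coverage) &&
         cfg$services$baseline_coverage > 0 && cfg$services$baseline_coverage <= 1,
       "services.baseline_coverage must be in (0,1]")
  need(is.numeric(cfg$benefit$discount_rate) && cfg$benefit$discount_rate >= 0,
       "benefit.discount_rate must be >= 0")

  if (length(problems))
    stop_input("invalid configuration:\n- %s", paste(problems, collapse = "\n- "))
  structure(cfg, class = "run_config", path = path)
}

#' Run the full pipeline
#'
#' Executes the stages in order - synthetic inputs, prevalent cases and
#' comorbidity partition, YLD burden with uncertainty, service scale-up,
#' and avertable burden - writing per-stage CSV/JSON outputs and a run
#' manifest (config hash, seed, package version) to `out_dir`.
#'
#' @param config A `run_config` (see [load_config()]).
#' @param out_dir Output directory (created if needed).
#' @param stages Character subset of
#'   `c("synth", "prevalence", "burden", "services", "benefit")`.
#' @return Invisibly, a list with every stage's in-memory results.
#' @export
run_pipeline <- function(config = load_config(), out_dir = tempfile("mhplan_"),
                         stages = c("synth", "prevalence", "burden",
                                    "services", "benefit")) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  results <- list()

  fixture <- syria_fixture(total = config$population$total, seed = seed)
  fixture$ptsd <- make_prevalence_curve("ptsd", config$prevalence$ptsd$point,
                                        fixture$population)
  fixture$depression <- make_prevalence_curve(
    "depression", config$prevalence$depression$point, fixture$population)
  results$fixture <- fixture
  if ("synth" %in% stages) {
    write_age_table(fixture$population, file.path(out_dir, "population.csv"))
    write_age_table(fixture$mortality, file.path(out_dir, "mortality.csv"))
    write_age_table(fixture$ptsd, file.path(out_dir, "prevalence_ptsd.csv"))
    write_age_table(fixture$depression,
                    file.path(out_dir, "prevalence_depression.csv"))
  }

  severity <- severity_from_config(config)
  part <- comorbidity_partition(
    prevalent_cases(fixture$ptsd, fixture$population),
    prevalent_cases(fixture$depression, fixture$population),
    config$prevalence$comorbid_rho)
  results$partition <- part
  if ("prevalence" %in% stages) {
    for (g in names(part))
      write_age_table(part[[g]], file.path(out_dir, paste0("cases_", g, ".csv")))
    summary <- list(
      totals = lapply(part, total_cases),
      age_standardised = list(
        ptsd = age_standardise(fixture$ptsd, fixture$population),
        depression = age_standardise(fixture$depression, fixture$population)))
    jsonlite::write_json(summary, file.path(out_dir, "prevalence_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  if ("burden" %in% stages) {
    pv <- config$prevalence
    burden <- list(
      ptsd = yld_uncertainty(pv$ptsd$point, pv$ptsd$lower, pv$ptsd$upper,
                             severity$anxiety, fixture$population,
                             curve = fixture$ptsd, seed = seed),
      depression = yld_uncertainty(pv$depression$point, pv$depression$lower,
                                   pv$depression$upper, severity$depression,
                                   fixture$population,
                                   curve = fixture$depression, seed = seed + 100))
    results$burden <- burden
    out <- lapply(burden, function(b)
      list(point = b$total, lower95 = b$lower95, upper95 = b$upper95,
           rate_per_1000 = b$rate_per_1000))
    jsonlite::write_json(out, file.path(out_dir, "burden_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  if ("services" %in% stages) {
    elig <- c(eligible_population(part, severity),
              perinatal = eligible_perinatal(fixture$population))
    plans <- lapply(c(linear = "linear", exponential = "exponential"),
                    function(md) run_scaleup(
                      elig, default_care_packages(), default_staffing(),
                      sum(fixture$population$count),
                      baseline = config$services$baseline_coverage, mode = md))
    results$services <- plans
    for (md in names(plans))
      utils::write.csv(as.data.frame(plans[[md]]),
                       file.path(out_dir, paste0("service_plan_", md, ".csv")),
                       row.names = FALSE)
  }

  if ("benefit" %in% stages) {
    setup <- benefit_setup(fixture, rho = config$prevalence$comorbid_rho,
                           severity = severity)
    av <- avertable_analysis(setup,
                             discount_rate = config$benefit$discount_rate)
    results$benefit <- av
    utils::write.csv(av, file.path(out_dir, "avertable_burden.csv"),
                     row.names = FALSE)
  }

  manifest <- list(package = "mhplan",
                   version = as.character(utils::packageVersion("mhplan")),
                   seed = seed, stages = stages,
                   config_hash = unname(tools::md5sum(
                     attr(config, "path") %||% character(0))),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(results)
}

severity_from_config <- function(config) {
  build <- function(d) {
    cl <- config$severity[[d]]$classes
    severity_model(d, data.frame(
      class = vapply(cl, `[[`, character(1), "class"),
      proportion = vapply(cl, `[[`, numeric(1), "proportion"),
      dw = vapply(cl, `[[`, numeric(1), "dw"),
      dw_lower = vapply(cl, function(k) k$dw_lower %||% k$dw, numeric(1)),
      dw_upper = vapply(cl, function(k) k$dw_upper %||% k$dw, numeric(1))))
  }
  list(depression = build("depression"), anxiety = build("anxiety"))
}
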