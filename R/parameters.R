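#' @keywords internal
"_PACKAGE"

# Schema version written to / expected in configuration files.
FLUCEA_SCHEMA_VERSION <- 1L

# Field lists per block: required fields, and optional fields with defaults.
# Defaults marked NA are resolved contextually in .apply_block_defaults().
.flucea_schema <- list(
  efficacy = list(
    required = c("rve_hd_vs_sd_cases", "rve_hd_vs_sd_hosp",
                 "rve_aqiv_vs_sd_cases"),
    optional = list(
      rve_aqiv_vs_sd_hosp = NA_real_,      # defaults to rve_aqiv_vs_sd_cases
      preventable_fraction_cases = 1,
      preventable_fraction_hosp = 1,
      preventable_fraction_deaths = NA_real_, # defaults to f_cases
      risk_death_scale = 1
    )
  ),
  epi = list(
    required = c("cohort_size", "attack_rate", "p_gp_given_case",
                 "p_er_given_case", "p_hosp_influenza_given_case",
                 "cardioresp_hosp_rate", "excess_mortality_per_100k",
                 "coverage"),
    optional = list()
  ),
  costs = list(
    required = c("price_aqiv", "price_hd", "cost_gp_visit", "cost_er_visit",
                 "cost_hospitalization", "cost_otc_per_case"),
    optional = list(admin_cost = 0)
  ),
  utilities = list(
    required = c("baseline_utility_by_age", "utility_influenza_episode",
                 "utility_hospitalized", "influenza_duration_days",
                 "hospitalization_duration_days"),
    optional = list()
  ),
  life_table = list(
    required = c("ages", "annual_survival_prob"),
    optional = list(discount_rate = 0.03)
  ),
  scenario = list(
    required = character(0),
    optional = list(
      hospitalization_approach = "influenza_coded",
      aqiv_scenario_label = "s1_0pct",
      wtp_per_qaly = 30000
    )
  )
)

.apply_block_defaults <- function(block, name) {
  sch <- .flucea_schema[[name]]
  missing_req <- setdiff(sch$required, names(block))
  if (length(missing_req) > 0) {
    stop("missing required key(s) in '", name, "': ",
         paste(missing_req, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(names(block), c(sch$required, names(sch$optional)))
  if (length(unknown) > 0) {
    stop("unknown key(s) in '", name, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (k in names(sch$optional)) {
    if (is.null(block[[k]])) block[[k]] <- sch$optional[[k]]
  }
  if (name == "efficacy") {
    if (is.na(block$rve_aqiv_vs_sd_hosp))
      block$rve_aqiv_vs_sd_hosp <- block$rve_aqiv_vs_sd_cases
    if (is.na(block$preventable_fraction_deaths))
      block$preventable_fraction_deaths <- block$preventable_fraction_cases
  }
  block
}

#' Assemble a validated model parameter set
#'
#' Bundles the six input blocks of the cost-effectiveness model — efficacy,
#' epidemiology, costs, utilities, life table and scenario settings — together
#' with the cohort age distribution into a single `flucea_params` object.
#' Optional keys take their documented defaults (e.g. `admin_cost = 0`,
#' `rve_aqiv_vs_sd_hosp` mirroring `rve_aqiv_vs_sd_cases`); unknown keys are
#' rejected.
#'
#' @param efficacy named list: `rve_hd_vs_sd_cases`, `rve_hd_vs_sd_hosp`,
#'   `rve_aqiv_vs_sd_cases`, optional `rve_aqiv_vs_sd_hosp`,
#'   `preventable_fraction_cases/hosp/deaths` (attenuation multipliers in
#'   \[0,1\] applied to a relative vaccine efficacy before it scales a
#'   population risk) and `risk_death_scale`.
#' @param epi named list of epidemiology inputs: `cohort_size`, `attack_rate`,
#'   `p_gp_given_case`, `p_er_given_case`, `p_hosp_influenza_given_case`,
#'   `cardioresp_hosp_rate`, `excess_mortality_per_100k`, `coverage`.
#' @param costs named list of unit costs in euros: `price_aqiv`, `price_hd`,
#'   `cost_gp_visit`, `cost_er_visit`, `cost_hospitalization`,
#'   `cost_otc_per_case`, optional `admin_cost`.
#' @param utilities named list: `baseline_utility_by_age` (named numeric
#'   vector, age -> utility), `utility_influenza_episode`,
#'   `utility_hospitalized`, `influenza_duration_days`,
#'   `hospitalization_duration_days`.
#' @param life_table named list: integer `ages` (contiguous grid),
#'   `annual_survival_prob` per age, optional `discount_rate` (default 0.03).
#' @param age_distribution named numeric vector mapping age to the proportion
#'   of the cohort at that age; must sum to 1.
#' @param scenario named list: `hospitalization_approach`
#'   (`"influenza_coded"` or `"cardiorespiratory"`), `aqiv_scenario_label`,
#'   `wtp_per_qaly` (default 30000).
#' @param check if `TRUE` (default), stop on any validation violation.
#'
#' @return An object of class `flucea_params`.
#' @seealso [validate_params()], [load_parameter_set()], [default_italy_like()]
#' @export
parameter_set <- function(efficacy, epi, costs, utilities, life_table,
                          age_distribution, scenario = list(),
                          check = TRUE) {
  utilities$baseline_utility_by_age <-
    .as_age_map(utilities$baseline_utility_by_age, "baseline_utility_by_age")
  age_distribution <- .as_age_map(age_distribution, "age_distribution")
  params <- structure(
    list(
      efficacy = .apply_block_defaults(efficacy, "efficacy"),
      epi = .apply_block_defaults(epi, "epi"),
      costs = .apply_block_defaults(costs, "costs"),
      utilities = .apply_block_defaults(utilities, "utilities"),
      life_table = .apply_block_defaults(life_table, "life_table"),
      scenario = .apply_block_defaults(scenario, "scenario"),
      age_distribution = age_distribution
    ),
    class = "flucea_params"
  )
  if (check) {
    rep <- validate_params(params)
    if (nrow(rep) > 0) {
      stop("invalid parameter set:\n",
           paste(format_validation(rep), collapse = "\n"), call. = FALSE)
    }
  }
  params
}

# Coerce a YAML map or named vector to a named numeric vector keyed by age.
.as_age_map <- function(x, what) {
  if (is.list(x)) x <- unlist(x)
  if (is.null(names(x)) || any(names(x) == "")) {
    stop("'", what, "' must be a named (age -> value) map", call. = FALSE)
  }
  v <- as.numeric(x)
  names(v) <- names(x)
  v[order(as.numeric(names(v)))]
}

.viol <- function(field, value, rule) {
  data.frame(field = field,
             value = paste(signif(as.numeric(value), 8), collapse = ","),
             rule = rule, stringsAsFactors = FALSE)
}

#' Validate a parameter set
#'
#' Checks every type invariant of the model inputs and returns a report of
#' violations instead of stopping: each row names the offending field, its
#' value and the rule it breaks. An empty report means the set is valid.
#' Validation is pure — the same input always yields the same report.
#'
#' @param params a `flucea_params` object (checking is skipped at
#'   construction when `check = FALSE`, so invalid sets can be inspected).
#' @return A data.frame with columns `field`, `value`, `rule`; zero rows iff
#'   the set is valid.
#' @export
validate_params <- function(params) {
  stopifnot(inherits(params, "flucea_params"))
  out <- list()
  add <- function(v) out[[length(out) + 1L]] <<- v

  ef <- params$efficacy
  for (f in c("rve_hd_vs_sd_cases", "rve_hd_vs_sd_hosp", "rve_aqiv_vs_sd_cases",
              "rve_aqiv_vs_sd_hosp", "preventable_fraction_cases",
              "preventable_fraction_hosp", "preventable_fraction_deaths")) {
    if (!is.numeric(ef[[f]]) || is.na(ef[[f]]) || ef[[f]] < 0 || ef[[f]] > 1)
      add(.viol(paste0("efficacy.", f), ef[[f]], "must lie in [0,1]"))
  }
  for (f in c("rve_aqiv_vs_sd_cases", "rve_aqiv_vs_sd_hosp")) {
    if (is.numeric(ef[[f]]) && !is.na(ef[[f]]) && ef[[f]] >= 1)
      add(.viol(paste0("efficacy.", f), ef[[f]],
                "1 - rve must be > 0 (common-comparator division defined)"))
  }
  if (!is.numeric(ef$risk_death_scale) || ef$risk_death_scale < 0)
    add(.viol("efficacy.risk_death_scale", ef$risk_death_scale, "must be >= 0"))

  ep <- params$epi
  for (f in c("attack_rate", "p_gp_given_case", "p_er_given_case",
              "p_hosp_influenza_given_case", "cardioresp_hosp_rate",
              "coverage")) {
    if (!is.numeric(ep[[f]]) || is.na(ep[[f]]) || ep[[f]] < 0 || ep[[f]] > 1)
      add(.viol(paste0("epi.", f), ep[[f]], "probability must lie in [0,1]"))
  }
  if (!is.numeric(ep$cohort_size) || ep$cohort_size <= 0)
    add(.viol("epi.cohort_size", ep$cohort_size, "must be > 0"))
  if (!is.numeric(ep$excess_mortality_per_100k) ||
      ep$excess_mortality_per_100k < 0)
    add(.viol("epi.excess_mortality_per_100k", ep$excess_mortality_per_100k,
              "must be >= 0"))

  co <- params$costs
  for (f in names(co)) {
    if (!is.numeric(co[[f]]) || is.na(co[[f]]) || co[[f]] < 0)
      add(.viol(paste0("costs.", f), co[[f]], "cost must be >= 0"))
  }

  ut <- params$utilities
  bu <- ut$baseline_utility_by_age
  if (any(bu < 0 | bu > 1))
    add(.viol("utilities.baseline_utility_by_age", range(bu),
              "utilities must lie in [0,1]"))
  for (f in c("utility_influenza_episode", "utility_hospitalized")) {
    if (!is.numeric(ut[[f]]) || is.na(ut[[f]]) || ut[[f]] < 0 || ut[[f]] > 1)
      add(.viol(paste0("utilities.", f), ut[[f]], "must lie in [0,1]"))
  }
  if (ut$utility_hospitalized > ut$utility_influenza_episode)
    add(.viol("utilities.utility_hospitalized", ut$utility_hospitalized,
              "must be <= utility_influenza_episode"))
  if (ut$utility_influenza_episode > min(bu))
    add(.viol("utilities.utility_influenza_episode",
              ut$utility_influenza_episode,
              "must be <= minimum baseline utility over ages"))
  for (f in c("influenza_duration_days", "hospitalization_duration_days")) {
    if (!is.numeric(ut[[f]]) || ut[[f]] <= 0)
      add(.viol(paste0("utilities.", f), ut[[f]], "duration must be > 0"))
  }

  lt <- params$life_table
  ages <- lt$ages
  if (length(ages) < 2 || any(diff(ages) != 1))
    add(.viol("life_table.ages", range(ages),
              "age grid must be contiguous (step 1, no gaps)"))
  if (length(lt$annual_survival_prob) != length(ages) ||
      any(lt$annual_survival_prob < 0 | lt$annual_survival_prob > 1))
    add(.viol("life_table.annual_survival_prob",
              range(lt$annual_survival_prob),
              "one survival probability in [0,1] per age"))
  if (!is.numeric(lt$discount_rate) || lt$discount_rate < 0)
    add(.viol("life_table.discount_rate", lt$discount_rate, "must be >= 0"))

  sc <- params$scenario
  if (!sc$hospitalization_approach %in% c("influenza_coded",
                                          "cardiorespiratory"))
    add(.viol("scenario.hospitalization_approach", NA,
              "must be 'influenza_coded' or 'cardiorespiratory'"))
  if (!is.numeric(sc$wtp_per_qaly) || sc$wtp_per_qaly <= 0)
    add(.viol("scenario.wtp_per_qaly", sc$wtp_per_qaly, "must be > 0"))

  ad <- params$age_distribution
  if (abs(sum(ad) - 1) > 1e-9)
    add(.viol("age_distribution", sum(ad), "must sum to 1 (tolerance 1e-9)"))
  if (any(ad < 0))
    add(.viol("age_distribution", min(ad), "proportions must be >= 0"))
  ad_ages <- as.numeric(names(ad))
  if (length(ages) >= 1 && (any(!ad_ages %in% ages)))
    add(.viol("age_distribution", range(ad_ages),
              "ages must lie on the life-table grid"))
  bu_ages <- as.numeric(names(bu))
  if (length(ages) >= 1 && any(!ages %in% bu_ages))
    add(.viol("utilities.baseline_utility_by_age", range(bu_ages),
              "must cover every life-table age"))

  if (length(out) == 0) {
    data.frame(field = character(0), value = character(0),
               rule = character(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, out)
  }
}

#' Format a validation report as printable text
#'
#' @param report a data.frame returned by [validate_params()].
#' @return Character vector, one line per violation ("OK" if empty).
#' @export
format_validation <- function(report) {
  if (nrow(report) == 0) return("OK: all invariants hold")
  sprintf("  %s = %s: %s", report$field, report$value, report$rule)
}

#' @export
print.flucea_params <- function(x, ...) {
  cat("<flucea_params>\n")
  cat(sprintf("  cohort: %s persons (coverage %.1f%%), ages %d-%d\n",
              format(x$epi$cohort_size, big.mark = ","),
              100 * x$epi$coverage,
              min(x$life_table$ages), max(x$life_table$ages)))
  cat(sprintf("  rVE HD vs SD: cases %.1f%%, hosp %.1f%%; aQIV vs SD: cases %.1f%%\n",
              100 * x$efficacy$rve_hd_vs_sd_cases,
              100 * x$efficacy$rve_hd_vs_sd_hosp,
              100 * x$efficacy$rve_aqiv_vs_sd_cases))
  cat(sprintf("  approach: %s, aQIV scenario: %s, WTP: %s EUR/QALY\n",
              x$scenario$hospitalization_approach,
              x$scenario$aqiv_scenario_label,
              format(x$scenario$wtp_per_qaly, big.mark = ",")))
  n <- nrow(validate_params(x))
  cat(if (n == 0) "  valid: yes\n" else sprintf("  valid: NO (%d violations)\n", n))
  invisible(x)
}

#' Read a parameter set from a YAML configuration file
#'
#' The configuration is a YAML document with a `schema: 1` version key and the
#' six blocks accepted by [parameter_set()] plus `age_distribution`. Unknown
#' keys are rejected, missing optional keys take their documented defaults,
#' and the result is validated before being returned.
#'
#' @param path path to a YAML configuration file.
#' @return A validated `flucea_params` object.
#' @export
load_parameter_set <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path,
                               call. = FALSE)
  doc <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("cannot parse configuration '",
                                           path, "': ", conditionMessage(e),
                                           call. = FALSE))
  if (is.null(doc$schema)) stop("missing required key: schema", call. = FALSE)
  if (doc$schema != FLUCEA_SCHEMA_VERSION)
    stop("unsupported schema version: ", doc$schema, call. = FALSE)
  blocks <- c("efficacy", "epi", "costs", "utilities", "life_table",
              "scenario", "age_distribution")
  unknown <- setdiff(names(doc), c("schema", blocks))
  if (length(unknown) > 0)
    stop("unknown top-level key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (b in setdiff(blocks, "scenario")) {
    if (is.null(doc[[b]])) stop("missing required key: ", b, call. = FALSE)
  }
  lt <- doc$life_table
  lt$ages <- as.integer(unlist(lt$ages))
  lt$annual_survival_prob <- as.numeric(unlist(lt$annual_survival_prob))
  parameter_set(
    efficacy = doc$efficacy, epi = doc$epi, costs = doc$costs,
    utilities = doc$utilities, life_table = lt,
    age_distribution = doc$age_distribution,
    scenario = if (is.null(doc$scenario)) list() else doc$scenario
  )
}

#' Write a parameter set to a YAML configuration file
#'
#' Inverse of [load_parameter_set()]: a load-write-load roundtrip is the
#' identity on every field.
#'
#' @param params a `flucea_params` object.
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_parameter_set <- function(params, path) {
  stopifnot(inherits(params, "flucea_params"))
  doc <- list(
    schema = FLUCEA_SCHEMA_VERSION,
    efficacy = params$efficacy,
    epi = params$epi,
    costs = params$costs,
    utilities = list(
      baseline_utility_by_age = as.list(params$utilities$baseline_utility_by_age),
      utility_influenza_episode = params$utilities$utility_influenza_episode,
      utility_hospitalized = params$utilities$utility_hospitalized,
      influenza_duration_days = params$utilities$influenza_duration_days,
      hospitalization_duration_days = params$utilities$hospitalization_duration_days
    ),
    life_table = list(
      ages = as.integer(params$life_table$ages),
      annual_survival_prob = params$life_table$annual_survival_prob,
      discount_rate = params$life_table$discount_rate
    ),
    scenario = params$scenario,
    age_distribution = as.list(params$age_distribution)
  )
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}

#' Get or set a scalar parameter by dotted path
#'
#' Paths address scalar fields inside a parameter set, e.g.
#' `"efficacy.rve_hd_vs_sd_hosp"` or `"costs.cost_hospitalization"`. Used by
#' the sensitivity-analysis machinery to perturb one parameter at a time.
#'
#' @param params a `flucea_params` object.
#' @param path dotted path string `"block.field"`.
#' @param value replacement value (for `param_set`).
#' @return `param_get` returns the scalar value; `param_set` returns the
#'   modified parameter set (unvalidated — call [validate_params()] after a
#'   batch of edits).
#' @export
param_get <- function(params, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (length(parts) != 2 || is.null(params[[parts[1]]]) ||
      is.null(params[[parts[1]]][[parts[2]]]))
    stop("no such parameter: ", path, call. = FALSE)
  params[[parts[1]]][[parts[2]]]
}

#' @rdname param_get
#' @export
param_set <- function(params, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (length(parts) != 2 || is.null(params[[parts[1]]]) ||
      is.null(params[[parts[1]]][[parts[2]]]))
    stop("no such parameter: ", path, call. = FALSE)
  params[[parts[1]]][[parts[2]]] <- value
  params
}
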