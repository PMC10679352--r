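#' Construct an arm-outcomes object
#'
#' Container for the expected events, costs and health totals of one
#' vaccination strategy. Usually produced by [expected_arm_outcomes()], but
#' can be built directly — e.g. to difference externally reported
#' per-strategy columns with [incremental()].
#'
#' @param arm_label strategy identifier (`"HD-QIV"`, `"aQIV"`, `"SD-QIV"`).
#' @param population named list of population totals: `cases`, `gp_visits`,
#'   `er_visits`, `hospitalizations`, `deaths`, `total_cost`, `lys`, `qalys`.
#' @param cohort_size number of vaccinated persons the totals refer to.
#' @param per_person optional named list (`total_cost`, `lys`, `qalys`); when
#'   omitted it is derived as `population / cohort_size`. Supply it explicitly
#'   when reproducing externally reported tables whose per-person and
#'   population figures are rounded independently.
#' @param cost_breakdown optional `flucea_cost_breakdown` attached for
#'   reporting.
#' @return An object of class `flucea_arm_outcomes`.
#' @export
arm_outcomes <- function(arm_label, population, cohort_size,
                         per_person = NULL, cost_breakdown = NULL) {
  needed <- c("cases", "gp_visits", "er_visits", "hospitalizations",
              "deaths", "total_cost", "lys", "qalys")
  missing <- setdiff(needed, names(population))
  if (length(missing) > 0)
    stop("population block missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (is.null(per_person)) {
    per_person <- list(total_cost = population$total_cost / cohort_size,
                       lys = population$lys / cohort_size,
                       qalys = population$qalys / cohort_size)
  }
  structure(list(arm_label = arm_label, population = population,
                 per_person = per_person, cohort_size = cohort_size,
                 cost_breakdown = cost_breakdown),
            class = "flucea_arm_outcomes")
}

#' Expected outcomes of one vaccination strategy
#'
#' Runs the one-season cohort decision tree in expectation. Influenza cases
#' arise at the attack rate scaled by the arm's efficacy against cases;
#' general-practitioner and emergency-room visits are independent,
#' non-mutually-exclusive conditional events among cases. Hospitalizations
#' follow the configured burden definition: conditional on an influenza-coded
#' case (`influenza_coded`), or a cohort-level cardiorespiratory admission
#' rate scaled by the arm's efficacy against hospitalization
#' (`cardiorespiratory`, the "hidden burden" definition). Deaths come from
#' the seasonal excess mortality rate and scale with the case burden averted
#' by the arm. Costs and discounted life-years/QALYs are assembled with
#' [arm_costs()] and [arm_health_totals()].
#'
#' @param params a validated `flucea_params` object.
#' @param arm strategy label: `"HD-QIV"`, `"aQIV"` or `"SD-QIV"` (the
#'   common comparator, i.e. zero relative efficacy).
#' @return A `flucea_arm_outcomes` object.
#' @export
expected_arm_outcomes <- function(params, arm) {
  prof <- .arm_profile(params, arm)
  ep <- params$epi
  cohort <- ep$cohort_size

  cases <- cohort * prof$risk_cases
  gp_visits <- cases * ep$p_gp_given_case
  er_visits <- cases * ep$p_er_given_case
  hospitalizations <- switch(params$scenario$hospitalization_approach,
    influenza_coded = cases * ep$p_hosp_influenza_given_case,
    cardiorespiratory = cohort * prof$risk_hosp
  )
  deaths <- cohort * (ep$excess_mortality_per_100k / 1e5) * prof$death_ratio

  events <- list(cohort_size = cohort, cases = cases, gp_visits = gp_visits,
                 er_visits = er_visits, hospitalizations = hospitalizations,
                 deaths = deaths)
  cb <- arm_costs(events, params$costs, arm = arm)
  health <- arm_health_totals(events, params)

  arm_outcomes(
    arm_label = arm,
    population = list(cases = cases, gp_visits = gp_visits,
                      er_visits = er_visits,
                      hospitalizations = hospitalizations, deaths = deaths,
                      total_cost = cb$total, lys = health$lys,
                      qalys = health$qalys),
    cohort_size = cohort,
    cost_breakdown = cb
  )
}

#' Monte-Carlo simulation of one strategy arm
#'
#' Individual-level Bernoulli simulation through the same decision tree as
#' [expected_arm_outcomes()], used as an independent oracle for the
#' expectation engine: each of `n_individuals` draws a case, conditional
#' GP/ER visits, a hospitalization (per the configured burden definition) and
#' a death, and the empirical event frequencies are scaled to the cohort and
#' valued with the same cost and health machinery.
#'
#' @param params a validated `flucea_params` object.
#' @param arm strategy label.
#' @param n_individuals number of simulated individuals (>= 1).
#' @param seed integer seed; the same seed reproduces the result exactly.
#' @return A `flucea_arm_outcomes` object with empirical (noisy) counts.
#' @export
simulate_arm_outcomes <- function(params, arm, n_individuals, seed) {
  stopifnot(n_individuals >= 1)
  prof <- .arm_profile(params, arm)
  ep <- params$epi
  cohort <- ep$cohort_size
  scale <- cohort / n_individuals

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  n_cases <- stats::rbinom(1, n_individuals, prof$risk_cases)
  n_gp <- stats::rbinom(1, n_cases, ep$p_gp_given_case)
  n_er <- stats::rbinom(1, n_cases, ep$p_er_given_case)
  n_hosp <- switch(params$scenario$hospitalization_approach,
    influenza_coded = stats::rbinom(1, n_cases, ep$p_hosp_influenza_given_case),
    cardiorespiratory = stats::rbinom(1, n_individuals, prof$risk_hosp)
  )
  p_death <- (ep$excess_mortality_per_100k / 1e5) * prof$death_ratio
  n_death <- stats::rbinom(1, n_individuals, min(p_death, 1))

  events <- list(cohort_size = cohort,
                 cases = n_cases * scale, gp_visits = n_gp * scale,
                 er_visits = n_er * scale,
                 hospitalizations = n_hosp * scale,
                 deaths = n_death * scale)
  cb <- arm_costs(events, params$costs, arm = arm)
  health <- arm_health_totals(events, params)

  arm_outcomes(
    arm_label = arm,
    population = list(cases = events$cases, gp_visits = events$gp_visits,
                      er_visits = events$er_visits,
                      hospitalizations = events$hospitalizations,
                      deaths = events$deaths, total_cost = cb$total,
                      lys = health$lys, qalys = health$qalys),
    cohort_size = cohort,
    cost_breakdown = cb
  )
}

#' Total influenza-attributable hospital admissions
#'
#' Combines admissions coded as influenza at discharge with the additional
#' cardiorespiratory admissions statistically attributable to influenza (the
#' "hidden burden"), yielding the total annual influenza-attributable
#' admission count used to motivate the cardiorespiratory hospitalization
#' definition.
#'
#' @param coded admissions per year carrying an influenza diagnosis code.
#' @param attributable_extra additional admissions per year attributable to
#'   influenza-triggered respiratory or circulatory events.
#' @return Their sum.
#' @examples
#' attributable_admissions(4407, 15206)  # 19613
#' @export
attributable_admissions <- function(coded, attributable_extra) {
  stopifnot(coded >= 0, attributable_extra >= 0)
  coded + attributable_extra
}

#' @export
print.flucea_arm_outcomes <- function(x, ...) {
  cat(sprintf("<flucea_arm_outcomes> %s (cohort %s)\n", x$arm_label,
              format(x$cohort_size, big.mark = ",")))
  p <- x$population
  cat(sprintf("  cases %.0f | GP %.0f | ER %.0f | hosp %.0f | deaths %.0f\n",
              p$cases, p$gp_visits, p$er_visits, p$hospitalizations,
              p$deaths))
  cat(sprintf("  per person: cost %.2f EUR | LY %.4f | QALY %.4f\n",
              x$per_person$total_cost, x$per_person$lys, x$per_person$qalys))
  invisible(x)
}

#' Flatten arm outcomes to a one-row data frame
#'
#' @param x a `flucea_arm_outcomes` object.
#' @param row.names,optional,... passed for S3 compatibility; unused.
#' @return A one-row data.frame with documented column names
#'   (`arm`, `cases`, `gp_visits`, `er_visits`, `hospitalizations`, `deaths`,
#'   `total_cost`, `lys`, `qalys`, `cost_per_person`, `lys_per_person`,
#'   `qalys_per_person`).
#' @export
as.data.frame.flucea_arm_outcomes <- function(x, row.names = NULL,
                                              optional = FALSE, ...) {
  p <- x$population
  data.frame(arm = x$arm_label, cases = p$cases, gp_visits = p$gp_visits,
             er_visits = p$er_visits, hospitalizations = p$hospitalizations,
             deaths = p$deaths, total_cost = p$total_cost, lys = p$lys,
             qalys = p$qalys,
             cost_per_person = x$per_person$total_cost,
             lys_per_person = x$per_person$lys,
             qalys_per_person = x$per_person$qalys,
             stringsAsFactors = FALSE)
}
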