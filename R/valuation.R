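#' Discounted life expectancy and quality-adjusted life expectancy at an age
#'
#' Remaining life-years and QALYs from a given age, computed from the life
#' table with annual cycles and end-of-cycle discounting (no half-cycle
#' correction):
#' \deqn{LY(a) = \sum_{t=1}^{T} S(a,t)\,(1+r)^{-t}, \qquad
#'       QALE(a) = \sum_{t=1}^{T} S(a,t)\,u(a+t)\,(1+r)^{-t}}
#' where `S(a,t)` is the cumulative survival probability over `t` years from
#' age `a` (product of the annual survival probabilities) and `u` is the
#' age-specific population utility at the attained age (capped at the
#' terminal age of the table).
#'
#' @param age integer age on the life-table grid.
#' @param life_table list with `ages`, `annual_survival_prob`,
#'   `discount_rate` (as in a `flucea_params` object).
#' @param utilities utilities block with `baseline_utility_by_age`.
#' @return A list with `age`, `life_years` and `qalys` (both discounted).
#' @export
discounted_qale <- function(age, life_table, utilities) {
  ages <- life_table$ages
  if (!age %in% ages)
    stop("age ", age, " outside the life-table grid [", min(ages), ", ",
         max(ages), "]", call. = FALSE)
  r <- life_table$discount_rate
  idx <- which(ages == age):length(ages)
  surv <- life_table$annual_survival_prob[idx]
  s_cum <- cumprod(surv)                       # S(age, t), t = 1..T
  t_vec <- seq_along(s_cum)
  disc <- (1 + r)^(-t_vec)
  bu <- utilities$baseline_utility_by_age
  attained <- pmin(age + t_vec, max(ages))
  u <- unname(bu[as.character(attained)])
  if (anyNA(u))
    stop("baseline_utility_by_age does not cover ages up to ", max(ages),
         call. = FALSE)
  list(age = age,
       life_years = sum(s_cum * disc),
       qalys = sum(s_cum * u * disc))
}

#' QALY loss of a short illness episode
#'
#' The utility decrement of an acute event (influenza episode or
#' hospitalization) applied for its duration, in years:
#' `(u_base - u_event) * duration_days / 365`. Episodes fall within the
#' one-season horizon, so no discounting is applied.
#'
#' @param duration_days duration of the episode in days (> 0).
#' @param u_base baseline utility the person would otherwise have.
#' @param u_event utility during the episode, `0 <= u_event <= u_base <= 1`.
#' @return QALYs lost (non-negative scalar).
#' @examples
#' episode_qaly_loss(6, 0.80, 0.35)  # 0.45 * 6/365
#' @export
episode_qaly_loss <- function(duration_days, u_base, u_event) {
  stopifnot(duration_days > 0, u_event >= 0, u_event <= u_base, u_base <= 1)
  (u_base - u_event) * duration_days / 365
}

# Age-distribution-weighted baseline expectancy per cohort member, and the
# cohort's expected age (used as the age at premature death).
.cohort_baseline <- function(params) {
  ad <- params$age_distribution
  ages <- as.numeric(names(ad))
  per_age <- lapply(ages, discounted_qale,
                    life_table = params$life_table,
                    utilities = params$utilities)
  list(
    ly_pp = sum(ad * vapply(per_age, `[[`, numeric(1), "life_years")),
    qaly_pp = sum(ad * vapply(per_age, `[[`, numeric(1), "qalys")),
    mean_utility = sum(ad * unname(
      params$utilities$baseline_utility_by_age[names(ad)])),
    death_age = round(sum(ad * ages))
  )
}

#' Discounted life-years and QALYs for one strategy arm
#'
#' Assembles population health totals from expected event counts: the cohort's
#' baseline (discounted, age-distribution-weighted) life expectancy minus the
#' short-term QALY decrements of influenza episodes and hospitalizations and
#' minus the lifetime discounted expectancy lost by each premature death.
#' Deaths are valued at the cohort's expected age. Non-fatal events carry a
#' utility loss but no life-year loss.
#'
#' @param events list (or `flucea_arm_outcomes` population block) with
#'   population counts `cases`, `hospitalizations`, `deaths`.
#' @param params a validated `flucea_params` object.
#' @return A list with population `lys` and `qalys` (discounted totals).
#' @export
arm_health_totals <- function(events, params) {
  base <- .cohort_baseline(params)
  cohort <- params$epi$cohort_size
  ut <- params$utilities
  loss_case <- episode_qaly_loss(ut$influenza_duration_days,
                                 base$mean_utility,
                                 ut$utility_influenza_episode)
  loss_hosp <- episode_qaly_loss(ut$hospitalization_duration_days,
                                 base$mean_utility,
                                 ut$utility_hospitalized)
  death_val <- discounted_qale(base$death_age, params$life_table,
                               params$utilities)
  list(
    lys = cohort * base$ly_pp - events$deaths * death_val$life_years,
    qalys = cohort * base$qaly_pp -
      events$cases * loss_case -
      events$hospitalizations * loss_hosp -
      events$deaths * death_val$qalys
  )
}
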