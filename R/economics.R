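#' Cost accumulation for one strategy arm
#'
#' Sums the payer costs of a strategy: vaccine acquisition plus
#' administration for the whole cohort, general-practitioner and
#' emergency-room visit costs, over-the-counter medication applied to every
#' influenza case (not only inpatients), and hospitalization costs at the
#' per-admission tariff.
#'
#' @param events named list with `cohort_size`, `cases`, `gp_visits`,
#'   `er_visits`, `hospitalizations` (expected counts).
#' @param costs the `costs` block of a `flucea_params` object.
#' @param arm strategy label; `"HD-QIV"` is priced at `price_hd`, the other
#'   arms at `price_aqiv`.
#' @return A `flucea_cost_breakdown` list with components `vaccine`, `gp`,
#'   `er`, `otc`, `hospitalization` and their `total` (euros).
#' @export
arm_costs <- function(events, costs, arm = "aQIV") {
  price <- if (identical(arm, "HD-QIV")) costs$price_hd else costs$price_aqiv
  cb <- list(
    vaccine = events$cohort_size * (price + costs$admin_cost),
    gp = events$gp_visits * costs$cost_gp_visit,
    er = events$er_visits * costs$cost_er_visit,
    otc = events$cases * costs$cost_otc_per_case,
    hospitalization = events$hospitalizations * costs$cost_hospitalization
  )
  cb$total <- cb$vaccine + cb$gp + cb$er + cb$otc + cb$hospitalization
  structure(cb, class = "flucea_cost_breakdown")
}

# Quadrant of the cost-effectiveness plane from the signs of
# (delta_cost, delta_qaly). Axis points are folded into the adjacent
# dominance quadrant (weak dominance); the origin gets "none".
.ce_quadrant <- function(delta_cost, delta_qaly) {
  if (delta_qaly == 0 && delta_cost == 0) return("none")
  if (delta_qaly > 0 && delta_cost > 0) return("NE")
  if (delta_qaly < 0 && delta_cost < 0) return("SW")
  if (delta_qaly >= 0 && delta_cost <= 0) return("SE")
  "NW"
}

#' Incremental cost-effectiveness of one strategy versus another
#'
#' Computes per-person incremental costs, life-years and QALYs of the
#' alternative versus the reference arm, the ICERs, the cost-effectiveness
#' plane quadrant (SE = dominant: cheaper and more effective; NW =
#' dominated), and the net monetary benefit `NMB = wtp * dQALY - dCost`.
#' A negative ICER is sign-ambiguous, so the quadrant is always reported
#' alongside it. Population differentials are included whenever both arms
#' carry population blocks.
#'
#' @param ref reference-arm `flucea_arm_outcomes` (the comparator, e.g.
#'   aQIV).
#' @param alt alternative-arm `flucea_arm_outcomes` (e.g. HD-QIV).
#' @param wtp willingness-to-pay threshold in euros per QALY.
#' @return A `flucea_incremental` object with fields `delta_cost`,
#'   `delta_ly`, `delta_qaly` (per person), `icer_per_ly`, `icer_per_qaly`
#'   (NA when the effect delta is zero), `icer_label` (formatted value or
#'   dominance verdict), `quadrant`, `nmb_at_wtp`, `wtp`, and
#'   `population_delta` (named vector of event differentials, alt minus
#'   ref).
#' @export
incremental <- function(ref, alt, wtp = 30000) {
  stopifnot(inherits(ref, "flucea_arm_outcomes"),
            inherits(alt, "flucea_arm_outcomes"))
  delta_cost <- alt$per_person$total_cost - ref$per_person$total_cost
  delta_ly <- alt$per_person$lys - ref$per_person$lys
  delta_qaly <- alt$per_person$qalys - ref$per_person$qalys

  icer_per_qaly <- if (delta_qaly != 0) delta_cost / delta_qaly else NA_real_
  icer_per_ly <- if (delta_ly != 0) delta_cost / delta_ly else NA_real_
  quadrant <- .ce_quadrant(delta_cost, delta_qaly)
  icer_label <- switch(quadrant,
    SE = "Dominant",
    NW = "Dominated",
    none = "indifferent",
    if (is.na(icer_per_qaly)) "undefined (cost-minimization)"
    else sprintf("%.0f", icer_per_qaly)
  )

  fields <- c("cases", "gp_visits", "er_visits", "hospitalizations",
              "deaths", "total_cost", "lys", "qalys")
  pop_delta <- vapply(fields, function(f)
    alt$population[[f]] - ref$population[[f]], numeric(1))

  structure(list(
    ref_label = ref$arm_label, alt_label = alt$arm_label,
    delta_cost = delta_cost, delta_ly = delta_ly, delta_qaly = delta_qaly,
    icer_per_ly = icer_per_ly, icer_per_qaly = icer_per_qaly,
    icer_label = icer_label, quadrant = quadrant,
    nmb_at_wtp = wtp * delta_qaly - delta_cost, wtp = wtp,
    population_delta = pop_delta,
    ref_per_person = ref$per_person, alt_per_person = alt$per_person
  ), class = "flucea_incremental")
}

#' Render an incremental result as a per-person summary table
#'
#' Produces the standard cost-effectiveness summary shape: one row each for
#' total costs, total life-years and total QALYs, with the reference arm,
#' the alternative arm, the increment and the ICER (or dominance verdict).
#'
#' @param x a `flucea_incremental` object.
#' @param digits_cost,digits_effect decimals used for euro and LY/QALY
#'   columns (defaults 2 and 4).
#' @return A data.frame with columns `outcome`, the two arm labels,
#'   `incremental`, `icer`.
#' @export
incremental_table <- function(x, digits_cost = 2, digits_effect = 4) {
  stopifnot(inherits(x, "flucea_incremental"))
  fm <- function(v, d) formatC(v, format = "f", digits = d)
  icer_ly <- if (x$quadrant %in% c("SE", "NW", "none")) x$icer_label
             else if (is.na(x$icer_per_ly)) "undefined"
             else sprintf("%.0f", x$icer_per_ly)
  df <- data.frame(
    outcome = c("Total costs", "Total LYs", "Total QALYs"),
    ref = c(fm(x$ref_per_person$total_cost, digits_cost),
            fm(x$ref_per_person$lys, digits_effect),
            fm(x$ref_per_person$qalys, digits_effect)),
    alt = c(fm(x$alt_per_person$total_cost, digits_cost),
            fm(x$alt_per_person$lys, digits_effect),
            fm(x$alt_per_person$qalys, digits_effect)),
    incremental = c(fm(x$delta_cost, digits_cost),
                    fm(x$delta_ly, 5), fm(x$delta_qaly, 5)),
    icer = c("-", icer_ly, x$icer_label),
    stringsAsFactors = FALSE
  )
  names(df)[2:3] <- c(x$ref_label, x$alt_label)
  df
}

#' @export
print.flucea_incremental <- function(x, ...) {
  cat(sprintf("<flucea_incremental> %s vs %s\n", x$alt_label, x$ref_label))
  cat(sprintf("  dCost %.4f EUR | dLY %.6f | dQALY %.6f (per person)\n",
              x$delta_cost, x$delta_ly, x$delta_qaly))
  cat(sprintf("  ICER %s EUR/QALY | quadrant %s | NMB %.2f EUR at WTP %s\n",
              x$icer_label, x$quadrant, x$nmb_at_wtp,
              format(x$wtp, big.mark = ",")))
  invisible(x)
}
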