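# Parameter class by dotted path: drives clamping rules, default DSA ranges
# and the PSA distribution family convention.
.param_class <- function(path) {
  if (grepl("^efficacy\\.rve_", path)) return("rve")
  if (grepl("^efficacy\\.preventable_fraction", path)) return("probability")
  if (path == "efficacy.risk_death_scale") return("positive")
  if (grepl("^epi\\.(attack_rate|p_|cardioresp_hosp_rate|coverage)", path))
    return("probability")
  if (grepl("^epi\\.", path)) return("positive")
  if (grepl("^costs\\.", path)) return("cost")
  if (grepl("duration", path)) return("positive")
  if (grepl("^utilities\\.utility_", path)) return("probability")
  if (path == "life_table.discount_rate") return("positive")
  "positive"
}

.clamp_param <- function(value, class) {
  switch(class,
    probability = pmin(pmax(value, 0), 1),
    rve = pmin(pmax(value, 0), 1 - 1e-9),
    cost = pmax(value, 0),
    positive = pmax(value, 0),
    value
  )
}

# Scalar paths covered by the default sensitivity analyses.
.default_sa_paths <- function() {
  c("efficacy.rve_hd_vs_sd_cases", "efficacy.rve_hd_vs_sd_hosp",
    "efficacy.rve_aqiv_vs_sd_cases", "efficacy.rve_aqiv_vs_sd_hosp",
    "epi.attack_rate", "epi.p_gp_given_case", "epi.p_er_given_case",
    "epi.p_hosp_influenza_given_case", "epi.cardioresp_hosp_rate",
    "epi.excess_mortality_per_100k",
    "costs.price_aqiv", "costs.price_hd", "costs.admin_cost",
    "costs.cost_gp_visit", "costs.cost_er_visit",
    "costs.cost_hospitalization", "costs.cost_otc_per_case",
    "utilities.utility_influenza_episode", "utilities.utility_hospitalized",
    "utilities.influenza_duration_days",
    "utilities.hospitalization_duration_days")
}

#' One-way range for a sensitivity parameter
#'
#' @param parameter dotted parameter path (see [param_get()]).
#' @param low,high bounds; use 95\% confidence limits when available,
#'   otherwise mean +/- 15\%.
#' @return A `flucea_range` list.
#' @export
param_range <- function(parameter, low, high) {
  if (low > high) stop("low must be <= high for ", parameter, call. = FALSE)
  structure(list(parameter = parameter, low = low, high = high),
            class = "flucea_range")
}

#' Default one-way ranges: mean plus/minus 15 percent
#'
#' Builds the conventional deterministic-sensitivity ranges for every scalar
#' model parameter with no published confidence interval: `mean * (1 - rel)`
#' to `mean * (1 + rel)`, clamped to the parameter's type invariants.
#'
#' @param params a validated `flucea_params` object.
#' @param rel relative half-width (default 0.15).
#' @param paths parameter paths to cover (default: the standard scalar set).
#' @return A list of `flucea_range` objects.
#' @export
default_dsa_ranges <- function(params, rel = 0.15,
                               paths = .default_sa_paths()) {
  lapply(paths, function(p) {
    m <- param_get(params, p)
    cl <- .param_class(p)
    param_range(p, .clamp_param(m * (1 - rel), cl),
                .clamp_param(m * (1 + rel), cl))
  })
}

#' Run both strategy arms and difference them
#'
#' Convenience wrapper: computes expected outcomes for the reference and
#' alternative arms from one parameter set and returns their incremental
#' comparison at the configured willingness-to-pay.
#'
#' @param params a validated `flucea_params` object.
#' @param ref,alt arm labels (defaults `"aQIV"` vs `"HD-QIV"`).
#' @return A `flucea_incremental` object.
#' @export
run_comparison <- function(params, ref = "aQIV", alt = "HD-QIV") {
  incremental(expected_arm_outcomes(params, ref),
              expected_arm_outcomes(params, alt),
              wtp = params$scenario$wtp_per_qaly)
}

#' One-way deterministic sensitivity analysis (tornado table)
#'
#' Re-runs the full two-arm pipeline with each parameter set to its low and
#' high bound (all else at base case) and records the resulting ICERs and
#' net monetary benefits. Because an ICER is sign-ambiguous across
#' cost-effectiveness-plane quadrants, the tornado span is measured on the
#' incremental NMB at the base willingness-to-pay — a single scale on which
#' dominant and non-dominant endpoints are comparable — and the table is
#' sorted by that span, descending. Ranges that still violate a hard
#' invariant after clamping are skipped with a warning.
#'
#' @param params base-case `flucea_params` object.
#' @param ranges list of [param_range()] objects (default: mean +/- 15\%).
#' @param ref,alt arm labels.
#' @return A `flucea_tornado` data.frame with columns `parameter`, `low`,
#'   `high`, `icer_at_low`, `icer_at_high`, `label_low`, `label_high`,
#'   `nmb_at_low`, `nmb_at_high`, `span`.
#' @export
one_way_dsa <- function(params, ranges = default_dsa_ranges(params),
                        ref = "aQIV", alt = "HD-QIV") {
  base_wtp <- params$scenario$wtp_per_qaly
  rows <- lapply(ranges, function(rg) {
    cl <- .param_class(rg$parameter)
    at <- function(v) {
      p2 <- param_set(params, rg$parameter, .clamp_param(v, cl))
      if (nrow(validate_params(p2)) > 0) return(NULL)
      run_comparison(p2, ref, alt)
    }
    lo <- at(rg$low); hi <- at(rg$high)
    if (is.null(lo) || is.null(hi)) {
      warning("skipping '", rg$parameter,
              "': bound violates a hard invariant after clamping",
              call. = FALSE)
      return(NULL)
    }
    data.frame(parameter = rg$parameter, low = rg$low, high = rg$high,
               icer_at_low = lo$icer_per_qaly, icer_at_high = hi$icer_per_qaly,
               label_low = lo$icer_label, label_high = hi$icer_label,
               nmb_at_low = lo$nmb_at_wtp, nmb_at_high = hi$nmb_at_wtp,
               span = abs(hi$nmb_at_wtp - lo$nmb_at_wtp),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows) == 0) {
    data.frame(parameter = character(0), low = numeric(0), high = numeric(0),
               icer_at_low = numeric(0), icer_at_high = numeric(0),
               label_low = character(0), label_high = character(0),
               nmb_at_low = numeric(0), nmb_at_high = numeric(0),
               span = numeric(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  out <- out[order(-out$span), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "wtp") <- base_wtp
  class(out) <- c("flucea_tornado", "data.frame")
  out
}

#' Distribution specification for probabilistic sensitivity analysis
#'
#' Moment-parameterized sampling distribution for one parameter. The
#' package convention follows standard health-economics practice: beta for
#' probabilities and utilities, gamma for costs and other non-negative
#' quantities, normal for relative efficacies; `se = 0` collapses to a point
#' mass.
#'
#' @param parameter dotted parameter path.
#' @param family `"beta"`, `"gamma"`, `"normal"` or `"point"`.
#' @param mean,se target moments; for `beta` the implied variance must
#'   satisfy `se^2 < mean * (1 - mean)`.
#' @return A `flucea_dist` list.
#' @export
distribution_spec <- function(parameter, family, mean, se = 0) {
  family <- match.arg(family, c("beta", "gamma", "normal", "point"))
  if (se < 0) stop("se must be >= 0", call. = FALSE)
  if (se == 0) family <- "point"
  if (family == "beta") {
    if (mean < 0 || mean > 1)
      stop("beta mean must lie in [0,1] for ", parameter, call. = FALSE)
    if (se^2 >= mean * (1 - mean))
      stop("beta se too large for mean ", mean, " (", parameter, ")",
           call. = FALSE)
  }
  if (family == "gamma" && mean <= 0)
    stop("gamma mean must be > 0 for ", parameter, call. = FALSE)
  structure(list(parameter = parameter, family = family, mean = mean,
                 se = se), class = "flucea_dist")
}

#' Default PSA distribution specifications
#'
#' One specification per standard scalar parameter, family chosen by
#' parameter class (beta / gamma / normal) and standard error set so that
#' the central 95\% interval of the distribution spans approximately the
#' mean +/- `rel` deterministic range (`se = rel * mean / 1.96`).
#'
#' @param params a validated `flucea_params` object.
#' @param rel relative spread matched to the one-way range (default 0.15).
#' @param paths parameter paths to cover.
#' @return A list of `flucea_dist` objects.
#' @export
default_distribution_specs <- function(params, rel = 0.15,
                                       paths = .default_sa_paths()) {
  lapply(paths, function(p) {
    m <- param_get(params, p)
    fam <- switch(.param_class(p), probability = "beta", cost = "gamma",
                  rve = "normal", positive = "gamma")
    se <- rel * m / 1.96
    if (m == 0 || se == 0) {
      distribution_spec(p, "point", mean = m, se = 0)
    } else {
      distribution_spec(p, fam, mean = m, se = se)
    }
  })
}

#' Moment-matched parameter draws
#'
#' Samples `n` values for each distribution specification, matching the
#' requested mean and standard error: beta and gamma shapes are derived by
#' moment conversion, normal draws are direct, point masses repeat the mean.
#' Draws are clamped to the parameter's type invariants; the total number of
#' clamped values is attached as attribute `"clamped"`.
#'
#' @param specs list of [distribution_spec()] objects.
#' @param n number of draws (>= 1).
#' @param seed integer seed; the same seed reproduces the table exactly.
#' @return A data.frame with `n` rows, one column per parameter path.
#' @export
draw_parameters <- function(specs, n, seed) {
  stopifnot(n >= 1)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  clamped <- 0L
  cols <- lapply(specs, function(sp) {
    x <- switch(sp$family,
      point = rep(sp$mean, n),
      normal = stats::rnorm(n, sp$mean, sp$se),
      beta = {
        v <- sp$se^2
        k <- sp$mean * (1 - sp$mean) / v - 1
        stats::rbeta(n, sp$mean * k, (1 - sp$mean) * k)
      },
      gamma = {
        v <- sp$se^2
        stats::rgamma(n, shape = sp$mean^2 / v, rate = sp$mean / v)
      }
    )
    xc <- .clamp_param(x, .param_class(sp$parameter))
    clamped <<- clamped + sum(xc != x)
    xc
  })
  names(cols) <- vapply(specs, `[[`, character(1), "parameter")
  out <- as.data.frame(cols, check.names = FALSE)
  attr(out, "clamped") <- clamped
  out
}

#' Probabilistic sensitivity analysis
#'
#' For each of `n` draws from the parameter distributions, substitutes the
#' sampled values into the parameter set, re-runs both strategy arms and
#' records the per-person incremental cost and QALY pair. Draws whose model
#' evaluation fails are recorded as failures (with the error message), not
#' aborted.
#'
#' @param params base-case `flucea_params` object.
#' @param specs list of [distribution_spec()] objects (default:
#'   [default_distribution_specs()]).
#' @param n number of simulations (default 1000).
#' @param seed integer seed.
#' @param ref,alt arm labels.
#' @return A `flucea_psa` object: `n_draws`, `seed`, `draws` (data.frame
#'   with `delta_cost`, `delta_qaly`, per person; NA rows for failures),
#'   `failures` (list of messages), `n_clamped`.
#' @export
run_psa <- function(params, specs = default_distribution_specs(params),
                    n = 1000, seed = 1, ref = "aQIV", alt = "HD-QIV") {
  tab <- draw_parameters(specs, n, seed)
  dc <- dq <- rep(NA_real_, n)
  failures <- list()
  for (i in seq_len(n)) {
    res <- tryCatch({
      p2 <- params
      for (col in names(tab)) p2 <- param_set(p2, col, tab[i, col])
      run_comparison(p2, ref, alt)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        list(draw = i, message = conditionMessage(res))
    } else {
      dc[i] <- res$delta_cost
      dq[i] <- res$delta_qaly
    }
  }
  structure(list(n_draws = n, seed = seed,
                 draws = data.frame(delta_cost = dc, delta_qaly = dq),
                 failures = failures,
                 n_clamped = attr(tab, "clamped")),
            class = "flucea_psa")
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the probability of cost-effectiveness
#' is the fraction of PSA draws with strictly positive net monetary benefit
#' (`wtp * delta_qaly - delta_cost > 0`); ties count as not cost-effective.
#' Failed draws are excluded from the denominator.
#'
#' @param psa a `flucea_psa` object.
#' @param wtp_grid willingness-to-pay grid in euros per QALY (default 0 to
#'   100,000 in steps of 1,000).
#' @return A data.frame with columns `wtp` and `prob_cost_effective`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 100000, by = 1000)) {
  stopifnot(inherits(psa, "flucea_psa"), length(wtp_grid) >= 1)
  ok <- stats::complete.cases(psa$draws)
  dc <- psa$draws$delta_cost[ok]
  dq <- psa$draws$delta_qaly[ok]
  prob <- vapply(wtp_grid, function(w) mean(w * dq - dc > 0), numeric(1))
  data.frame(wtp = wtp_grid, prob_cost_effective = prob)
}

#' @export
print.flucea_psa <- function(x, ...) {
  ok <- stats::complete.cases(x$draws)
  cat(sprintf("<flucea_psa> %d draws (seed %d, %d failed, %d clamped)\n",
              x$n_draws, x$seed, sum(!ok), x$n_clamped))
  if (any(ok)) {
    se_q <- mean(x$draws$delta_cost[ok] < 0 & x$draws$delta_qaly[ok] > 0)
    cat(sprintf("  mean dCost %.4f EUR | mean dQALY %.6f | dominant in %.1f%%\n",
                mean(x$draws$delta_cost[ok]), mean(x$draws$delta_qaly[ok]),
                100 * se_q))
  }
  invisible(x)
}
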