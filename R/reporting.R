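#' Set the aQIV-efficacy scenario of a parameter set
#'
#' The efficacy of the adjuvanted vaccine versus standard dose is explored
#' through scenarios (0\%, 6\%, 12\% in the published analysis). This helper
#' sets `rve_aqiv_vs_sd_cases` — and, unless `override_hosp` is supplied,
#' `rve_aqiv_vs_sd_hosp` to the same value — and stamps the scenario label.
#'
#' @param params a validated `flucea_params` object.
#' @param scenario `"s1_0pct"`, `"s2_6pct"`, `"s3_12pct"` or a numeric
#'   proportion in \[0, 1).
#' @param override_hosp optional distinct value for the hospitalization
#'   outcome.
#' @return The modified, validated `flucea_params` object.
#' @export
set_aqiv_scenario <- function(params, scenario, override_hosp = NULL) {
  if (is.character(scenario)) {
    value <- switch(scenario, s1_0pct = 0, s2_6pct = 0.06, s3_12pct = 0.12,
                    stop("unknown scenario label: ", scenario, call. = FALSE))
    label <- scenario
  } else {
    value <- scenario
    label <- switch(as.character(scenario), "0" = "s1_0pct",
                    "0.06" = "s2_6pct", "0.12" = "s3_12pct", "custom")
  }
  params <- param_set(params, "efficacy.rve_aqiv_vs_sd_cases", value)
  params <- param_set(params, "efficacy.rve_aqiv_vs_sd_hosp",
                      if (is.null(override_hosp)) value else override_hosp)
  params$scenario$aqiv_scenario_label <- label
  rep <- validate_params(params)
  if (nrow(rep) > 0)
    stop("scenario value breaks validation:\n",
         paste(format_validation(rep), collapse = "\n"), call. = FALSE)
  params
}

.scenario_tag <- function(value) sprintf("s%g", 100 * value)

#' Run the full cost-effectiveness pipeline and write report tables
#'
#' Executes the complete analysis for a set of aQIV-efficacy scenarios under
#' one hospitalization-burden definition, and writes figure-ready CSV
#' artifacts to `outdir`: a per-person incremental summary and a population
#' outcomes table per scenario, a tornado table and the probabilistic
#' draws/acceptability curve for the first (base-case) scenario, plus a
#' plain-text run log and a JSON run manifest. Given the same inputs and
#' seed, the CSV outputs are byte-identical across runs.
#'
#' @param config path to a YAML parameter configuration, or `NULL` to use
#'   `params`.
#' @param params a `flucea_params` object used when `config` is `NULL`
#'   (default [default_italy_like()]).
#' @param approach hospitalization definition: `"influenza_coded"` or
#'   `"cardiorespiratory"`.
#' @param scenarios numeric vector of aQIV-vs-SD efficacies to run
#'   (default `c(0, 0.06, 0.12)`).
#' @param psa_n probabilistic draws (default 1000; 0 skips the PSA).
#' @param seed integer seed for the PSA.
#' @param wtp optional willingness-to-pay override (euros per QALY).
#' @param dsa run the one-way deterministic analysis (default `TRUE`).
#' @param outdir output directory, created if absent.
#' @return The run manifest (class `flucea_manifest`): configuration source,
#'   scenario labels, seed, artifact paths, schema version and timestamp.
#' @export
run_analysis <- function(config = NULL, params = NULL,
                         approach = c("influenza_coded", "cardiorespiratory"),
                         scenarios = c(0, 0.06, 0.12), psa_n = 1000,
                         seed = 1, wtp = NULL, dsa = TRUE, outdir) {
  approach <- match.arg(approach)
  if (psa_n < 0) stop("psa_n must be >= 0", call. = FALSE)
  if (length(scenarios) < 1) stop("no scenarios requested", call. = FALSE)
  if (any(scenarios < 0 | scenarios >= 1))
    stop("scenario efficacies must lie in [0, 1)", call. = FALSE)
  if (!is.null(wtp) && wtp <= 0) stop("wtp must be > 0", call. = FALSE)

  base <- if (!is.null(config)) load_parameter_set(config)
          else if (!is.null(params)) params
          else default_italy_like()
  base$scenario$hospitalization_approach <- approach
  if (!is.null(wtp)) base$scenario$wtp_per_qaly <- wtp

  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  log_lines <- c(
    sprintf("config: %s", if (is.null(config)) "<in-memory parameter set>"
            else config),
    sprintf("approach: %s", approach),
    sprintf("scenarios: %s", paste(scenarios, collapse = ", ")),
    sprintf("wtp: %s", base$scenario$wtp_per_qaly),
    sprintf("psa_n: %d", psa_n),
    sprintf("seed: %d", seed)
  )
  artifacts <- character(0)
  emit <- function(df, file) {
    path <- file.path(outdir, file)
    utils::write.csv(df, path, row.names = FALSE)
    artifacts <<- c(artifacts, path)
    path
  }

  labels <- character(0)
  for (sc in scenarios) {
    p_sc <- set_aqiv_scenario(base, sc)
    tag <- .scenario_tag(sc)
    labels <- c(labels, p_sc$scenario$aqiv_scenario_label)
    ref <- expected_arm_outcomes(p_sc, "aQIV")
    alt <- expected_arm_outcomes(p_sc, "HD-QIV")
    inc <- incremental(ref, alt, wtp = p_sc$scenario$wtp_per_qaly)
    emit(incremental_table(inc), sprintf("incremental_%s.csv", tag))
    emit(rbind(as.data.frame(ref), as.data.frame(alt)),
         sprintf("outcomes_%s.csv", tag))
    log_lines <- c(log_lines,
                   sprintf("scenario %s: ICER %s EUR/QALY (quadrant %s)",
                           tag, inc$icer_label, inc$quadrant))
  }

  p_base <- set_aqiv_scenario(base, scenarios[1])
  if (isTRUE(dsa)) {
    emit(as.data.frame(one_way_dsa(p_base)), "dsa_tornado.csv")
    log_lines <- c(log_lines, "dsa: written (base-case scenario)")
  } else {
    log_lines <- c(log_lines, "dsa: skipped")
  }
  if (psa_n > 0) {
    psa <- run_psa(p_base, n = psa_n, seed = seed)
    emit(cbind(draw = seq_len(psa$n_draws), psa$draws), "psa_draws.csv")
    emit(ceac(psa), "ceac.csv")
    log_lines <- c(log_lines,
                   sprintf("psa: %d draws, %d failures", psa$n_draws,
                           length(psa$failures)))
  } else {
    log_lines <- c(log_lines, "psa: skipped (psa_n = 0)")
  }

  log_path <- file.path(outdir, "run.log")
  writeLines(log_lines, log_path)
  artifacts <- c(artifacts, log_path)

  manifest <- structure(list(
    config = if (is.null(config)) NA_character_ else config,
    approach = approach, scenario_labels = labels,
    psa_n = psa_n, psa_skipped = psa_n == 0, seed = seed,
    artifacts = artifacts, schema = FLUCEA_SCHEMA_VERSION,
    package_version = as.character(utils::packageVersion("flucea")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "flucea_manifest")
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(unclass(manifest), manifest_path, auto_unbox = TRUE,
                       digits = NA)
  manifest$artifacts <- c(manifest$artifacts, manifest_path)
  manifest
}

#' @export
print.flucea_manifest <- function(x, ...) {
  cat("<flucea_manifest>\n")
  cat(sprintf("  approach %s | scenarios %s | seed %d\n", x$approach,
              paste(x$scenario_labels, collapse = ", "), x$seed))
  cat(sprintf("  %d artifacts written\n", length(x$artifacts)))
  invisible(x)
}
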