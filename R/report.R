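## Result-file writers tying the modules into a reproducible pipeline.
## Each writer emits canonical CSV/JSON files plus a run manifest recording
## the command, inputs, seed and outputs, so a run can be replayed.

write_manifest <- function(command, outdir, params_path, seed, settings,
                           outputs) {
  manifest <- list(
    command = command,
    parameter_file = if (is.null(params_path)) NA else params_path,
    settings = settings,
    seed = seed,
    package_version = as.character(packageVersion("htnce")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = outputs
  )
  path <- file.path(outdir, paste0(command, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  path
}

#' Write a base-case results report
#'
#' Runs both arms at each requested horizon and writes a results table
#' (outcome rows, per-arm columns, changes column, verdict), as CSV and
#' JSON, plus a run manifest. Monetary values are rounded to cents in the
#' CSV only; JSON keeps full precision.
#'
#' @param params An `htn_params`, or a path to a parameter file.
#' @param outdir Output directory (created if needed).
#' @param horizons Integer vector of time horizons in years.
#' @param method `"cohort"` or `"microsimulation"`.
#' @param config Template [run_config()] for the remaining settings.
#' @return (Invisibly) a named list of written file paths.
#' @export
report_base_case <- function(params, outdir, horizons = c(8L, 15L),
                             method = c("cohort", "microsimulation"),
                             config = run_config()) {
  method <- match.arg(method)
  pp <- resolve_params(params)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  per_h <- purrr::map(horizons, function(h) {
    cfg <- config
    cfg$horizon_years <- as.integer(h)
    bc <- base_case_table(pp$params, cfg, method)
    list(horizon = h, bc = bc)
  })
  tab <- purrr::map_dfr(per_h, function(x) {
    dplyr::mutate(x$bc$table, horizon_years = x$horizon,
                  .before = "outcome")
  })
  verdicts <- purrr::map_dfr(per_h, function(x) {
    cmp <- x$bc$comparison
    tibble::tibble(horizon_years = x$horizon, outcome = "verdict",
                   drug = NA_real_, non_drug = NA_real_, change = NA_real_,
                   label = if (cmp$verdict == "icer") {
                     sprintf("ICER $%.2f/QALY", cmp$icer)
                   } else {
                     cmp$verdict
                   })
  })
  csv_path <- file.path(outdir, "base_case.csv")
  out_tab <- dplyr::mutate(tab, dplyr::across(
    c("drug", "non_drug", "change"),
    ~ ifelse(.data$outcome == "discounted_qalys", .x, round(.x, 2))
  ), label = NA_character_)
  write.csv(dplyr::bind_rows(out_tab, verdicts), csv_path,
            row.names = FALSE)
  json_path <- file.path(outdir, "base_case.json")
  jsonlite::write_json(
    purrr::map(per_h, function(x) {
      list(horizon_years = x$horizon,
           drug = unclass_arm(x$bc$drug),
           non_drug = unclass_arm(x$bc$non_drug),
           comparison = x$bc$comparison[c("delta_cost", "delta_qaly",
                                          "icer", "verdict", "wtp", "nmb",
                                          "cost_effective")])
    }),
    json_path, auto_unbox = TRUE, pretty = TRUE, digits = NA, na = "null"
  )
  manifest <- write_manifest(
    "base_case", outdir, pp$path, config$seed,
    list(horizons = horizons, method = method,
         stage2_effects = config$stage2_effects,
         progression_effect = config$progression_effect,
         n_individuals = if (method == "microsimulation")
           config$n_individuals else NA),
    list(csv = csv_path, json = json_path)
  )
  invisible(list(csv = csv_path, json = json_path, manifest = manifest))
}

unclass_arm <- function(r) {
  list(arm = r$arm, method = r$method, discounted_qalys = r$qalys,
       discounted_cost = r$cost,
       cost_by_category = as.list(r$cost_by_category),
       se_qalys = r$se_qalys, se_cost = r$se_cost)
}

resolve_params <- function(params) {
  if (inherits(params, "htn_params")) {
    list(params = params, path = NULL)
  } else if (is.character(params) && length(params) == 1) {
    list(params = load_parameters(params), path = params)
  } else {
    abort("`params` must be an htn_params object or a file path.")
  }
}

#' Write a probabilistic sensitivity analysis report
#'
#' Runs the PSA and writes the per-draw incremental scatter data
#' (`psa_draws.csv`, the data behind the cost-effectiveness plane), the
#' CEAC table (`ceac.csv`), a summary JSON (per-arm means/SDs, Welch t
#' tests, probability cost-effective at 1x and 3x GDP), and a manifest.
#'
#' @inheritParams report_base_case
#' @param n_draws Number of PSA draws.
#' @param seed Seed for the draw stream (defaults to `config$seed`).
#' @param wtp_grid CEAC grid; defaults to 0 to 3x the GDP anchor.
#' @return (Invisibly) a named list of written file paths.
#' @export
report_psa <- function(params, outdir, n_draws = 10000, seed = NULL,
                       wtp_grid = NULL, config = run_config()) {
  pp <- resolve_params(params)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(seed)) seed <- config$seed
  psa <- run_psa(pp$params, config, n_draws = n_draws, seed = seed)
  cc <- ceac(psa, wtp_grid)
  tt <- psa_t_tests(psa)
  draws_path <- file.path(outdir, "psa_draws.csv")
  write.csv(dplyr::mutate(psa$draws, dplyr::across(
    dplyr::starts_with("cost") | dplyr::all_of("delta_cost"),
    ~ round(.x, 2)
  )), draws_path, row.names = FALSE)
  ceac_path <- file.path(outdir, "ceac.csv")
  write.csv(cc, ceac_path, row.names = FALSE)
  gdp <- pp$params$wtp_per_gdp
  p_at <- function(l) mean(l * psa$draws$delta_qaly -
                             psa$draws$delta_cost > 0)
  summary_path <- file.path(outdir, "psa_summary.json")
  jsonlite::write_json(
    list(n_draws = n_draws, seed = seed,
         horizon_years = config$horizon_years,
         summary = psa$summary, t_tests = tt,
         prob_cost_effective_1gdp = p_at(gdp),
         prob_cost_effective_3gdp = p_at(3 * gdp)),
    summary_path, auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  manifest <- write_manifest(
    "psa", outdir, pp$path, seed,
    list(n_draws = n_draws, horizon_years = config$horizon_years,
         inner = "cohort"),
    list(draws = draws_path, ceac = ceac_path, summary = summary_path)
  )
  invisible(list(draws = draws_path, ceac = ceac_path,
                 summary = summary_path, manifest = manifest))
}

#' Write a one-way (tornado) sensitivity report
#'
#' @inheritParams report_base_case
#' @param wtp WTP for the NMB ranking outcome.
#' @return (Invisibly) a named list of written file paths.
#' @export
report_tornado <- function(params, outdir, wtp = NULL,
                           config = run_config()) {
  pp <- resolve_params(params)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tor <- one_way_tornado(pp$params, config, wtp = wtp)
  path <- file.path(outdir, "tornado.csv")
  write.csv(as.data.frame(tor), path, row.names = FALSE)
  manifest <- write_manifest(
    "tornado", outdir, pp$path, config$seed,
    list(horizon_years = config$horizon_years,
         wtp = attr(tor, "wtp"), base_nmb = attr(tor, "base_nmb")),
    list(tornado = path)
  )
  invisible(list(tornado = path, manifest = manifest))
}

#' Write a scenario-analysis report
#'
#' @inheritParams report_base_case
#' @return (Invisibly) a named list of written file paths.
#' @export
report_scenarios <- function(params, outdir, config = run_config()) {
  pp <- resolve_params(params)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sc <- run_scenarios(pp$params, config = config)
  path <- file.path(outdir, "scenarios.csv")
  write.csv(sc, path, row.names = FALSE)
  manifest <- write_manifest("scenarios", outdir, pp$path, config$seed,
                             list(), list(scenarios = path))
  invisible(list(scenarios = path, manifest = manifest))
}

#' Generate, re-estimate, and write a synthetic-cohort report
#'
#' Generates a synthetic person-time table at the base-case generating
#' rates, re-estimates every rate with its exact Poisson CI, assembles
#' the estimates into a runnable parameter file, and writes the
#' person-time table, the estimate table, the recovered parameter set
#' (JSON, loadable by [load_parameters()]) and a manifest.
#'
#' @param n Persons per stage in the synthetic cohort.
#' @param outdir Output directory.
#' @param seed RNG seed.
#' @param base Base `htn_params` supplying fixed inputs and generating
#'   rates.
#' @return (Invisibly) a named list of written file paths.
#' @export
report_synthetic <- function(n, outdir, seed = 1L,
                             base = default_parameters()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pt <- generate_person_time(
    n, dplyr::select(base$rates, "stage", "event", rate = "mean"),
    seed = seed
  )
  est <- estimate_rates(pt)
  recovered <- assemble_parameter_set(
    dplyr::select(est, "stage", "event", "mean", "ci_low", "ci_high"),
    base
  )
  agg_path <- file.path(outdir, "synthetic_person_time_summary.csv")
  write.csv(est, agg_path, row.names = FALSE)
  params_path <- file.path(outdir, "recovered_parameters.json")
  write_parameters(recovered, params_path)
  manifest <- write_manifest(
    "synth", outdir, NULL, seed, list(n = n),
    list(estimates = agg_path, parameters = params_path)
  )
  invisible(list(estimates = agg_path, parameters = params_path,
                 manifest = manifest))
}

#' Write an `htn_params` object back to a JSON parameter file
#'
#' Round-trips through the same schema as the shipped base-case file, so
#' the output is loadable by [load_parameters()].
#'
#' @param params An `htn_params` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  validate_parameters(params)
  obj <- list(
    description = "Model parameter file written by htnce::write_parameters()",
    discount_rate = list(mean = params$discount_rate,
                         low = params$discount_range[1],
                         high = params$discount_range[2]),
    wtp_per_gdp = params$wtp_per_gdp,
    productivity_window_years = params$productivity_window_years,
    productivity_reduction_drug = params$productivity_reduction_drug,
    rates_per_1000py = params$rates,
    progression_annual_pct = list(mean = 100 * params$progression$mean,
                                  ci_low = 100 * params$progression$ci_low,
                                  ci_high = 100 * params$progression$ci_high),
    relative_risks = params$rrs,
    annual_costs_usd = params$costs,
    utilities = params$utilities
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
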