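## One-way (tornado) analysis, scenario runs, probabilistic sensitivity
## analysis, CEAC construction and PSA summary tests.

#' Default one-way sensitivity grid
#'
#' Builds the list of parameters varied in the tornado analysis: every
#' event rate and relative risk over its 95% CI, the progression
#' probability over its CI, every cost over its +/- fractional range
#' (default 25%), every non-death utility over its range, and the
#' discount rate over its printed range (0-8%).
#'
#' @param params An `htn_params` object.
#' @return Tibble with columns `parameter` (identifier accepted by
#'   [set_model_parameter()]), `low`, `high`.
#' @export
tornado_grid <- function(params) {
  dplyr::bind_rows(
    dplyr::transmute(params$rates,
                     parameter = paste("rate", .data$stage, .data$event,
                                       sep = "."),
                     low = .data$ci_low, high = .data$ci_high),
    tibble::tibble(parameter = "progression",
                   low = params$progression$ci_low,
                   high = params$progression$ci_high),
    dplyr::transmute(params$rrs,
                     parameter = paste("rr", .data$stage, .data$endpoint,
                                       sep = "."),
                     low = .data$ci_low, high = .data$ci_high),
    dplyr::transmute(params$costs,
                     parameter = paste("cost", .data$item, sep = "."),
                     low = .data$mean * (1 - .data$rel_range),
                     high = .data$mean * (1 + .data$rel_range)),
    dplyr::transmute(
      dplyr::filter(params$utilities, .data$state != "death"),
      parameter = paste("utility", .data$state, sep = "."),
      low = .data$ci_low, high = .data$ci_high),
    tibble::tibble(parameter = "discount_rate",
                   low = params$discount_range[1],
                   high = params$discount_range[2])
  )
}

#' One-way (tornado) sensitivity analysis
#'
#' Re-evaluates the drug vs. non-drug comparison with each parameter set
#' to its low and high value in turn, all others at base case. The
#' ranking outcome is the incremental net monetary benefit at `wtp`
#' (well-defined in every quadrant, unlike the ICER, which is also
#' reported per entry).
#'
#' @param params An `htn_params` object.
#' @param config A [run_config()].
#' @param grid Tibble of `parameter`, `low`, `high`; defaults to
#'   [tornado_grid()].
#' @param wtp Willingness-to-pay for the NMB outcome; defaults to the
#'   parameter set's per-capita-GDP anchor.
#' @return A `tornado_result` tibble sorted by descending outcome range:
#'   `parameter`, `low`, `high`, `nmb_low`, `nmb_high`, `icer_low`,
#'   `icer_high`, `width`, with the base-case NMB as attribute
#'   `base_nmb`.
#' @export
one_way_tornado <- function(params, config = run_config(), grid = NULL,
                            wtp = NULL) {
  validate_parameters(params)
  if (is.null(grid)) grid <- tornado_grid(params)
  if (is.null(wtp)) wtp <- params$wtp_per_gdp
  if (any(grid$low > grid$high)) {
    abort("Each varied parameter needs low <= high.")
  }
  eval_at <- function(p) {
    cmp <- base_case_table(p, config)$comparison
    c(nmb = wtp * cmp$delta_qaly - cmp$delta_cost,
      icer = cmp$delta_cost / cmp$delta_qaly)
  }
  base <- eval_at(params)
  res <- purrr::pmap_dfr(grid, function(parameter, low, high) {
    at_low <- eval_at(set_model_parameter(params, parameter, low))
    at_high <- eval_at(set_model_parameter(params, parameter, high))
    tibble::tibble(parameter = parameter, low = low, high = high,
                   nmb_low = at_low[["nmb"]], nmb_high = at_high[["nmb"]],
                   icer_low = at_low[["icer"]], icer_high = at_high[["icer"]],
                   width = abs(at_high[["nmb"]] - at_low[["nmb"]]))
  })
  res <- dplyr::arrange(res, dplyr::desc(.data$width))
  attr(res, "base_nmb") <- base[["nmb"]]
  attr(res, "wtp") <- wtp
  class(res) <- c("tornado_result", class(res))
  res
}

## Distribution specifications for every uncertain parameter, fitted once
## per PSA. Rates and the progression probability get beta distributions
## (on the probability / per-person-year scale), utilities beta, costs
## gamma with CV = rel_range, relative risks lognormal.
psa_dist_specs <- function(params) {
  rate_specs <- purrr::pmap(params$rates, function(stage, event, mean,
                                                   ci_low, ci_high) {
    fit_beta_from_interval(mean / 1000, ci_low / 1000, ci_high / 1000)
  })
  names(rate_specs) <- paste("rate", params$rates$stage, params$rates$event,
                             sep = ".")
  rr_specs <- purrr::pmap(params$rrs, function(stage, endpoint, mean,
                                               ci_low, ci_high) {
    fit_lognormal_from_ci(mean, ci_low, ci_high)
  })
  names(rr_specs) <- paste("rr", params$rrs$stage, params$rrs$endpoint,
                           sep = ".")
  cost_specs <- purrr::pmap(params$costs, function(item, mean, rel_range) {
    if (rel_range == 0 || mean == 0) {
      dist_spec("point", value = mean)
    } else {
      fit_gamma_from_mean_cv(mean, rel_range)
    }
  })
  names(cost_specs) <- paste("cost", params$costs$item, sep = ".")
  util_tbl <- dplyr::filter(params$utilities, .data$state != "death")
  util_specs <- purrr::pmap(util_tbl, function(state, mean, ci_low, ci_high) {
    fit_beta_from_interval(mean, ci_low, ci_high)
  })
  names(util_specs) <- paste("utility", util_tbl$state, sep = ".")
  c(rate_specs, rr_specs, cost_specs, util_specs,
    list(progression = fit_beta_from_interval(params$progression$mean,
                                              params$progression$ci_low,
                                              params$progression$ci_high)))
}

#' Sample parameter draws for probabilistic sensitivity analysis
#'
#' @param params An `htn_params` object.
#' @param n_draws Number of draws.
#' @param seed RNG seed.
#' @return Numeric matrix (`n_draws` rows) whose columns are the uncertain
#'   parameters, in natural units (rates per person-year, probabilities,
#'   dollars, ratios).
#' @export
sample_parameter_draws <- function(params, n_draws, seed = 1L) {
  specs <- psa_dist_specs(params)
  set.seed(seed)
  draws <- vapply(specs, sample_dist, numeric(n_draws), n = n_draws)
  if (n_draws == 1) draws <- matrix(draws, nrow = 1,
                                    dimnames = list(NULL, names(specs)))
  draws
}

## Write one draw (a named row of the draw matrix) into an engine-input
## view. Rates were sampled on the per-person-year scale.
apply_draw_to_inputs <- function(ei, draw) {
  nm <- names(draw)
  for (ev in event_levels()) {
    ei$r1[[ev]] <- draw[[paste0("rate.1.", ev)]]
    ei$r2[[ev]] <- draw[[paste0("rate.2.", ev)]]
  }
  for (ep in rr_endpoint_levels()) {
    key1 <- paste0("rr.1.", ep)
    if (key1 %in% nm) ei$rr1[[ep]] <- draw[[key1]]
    key2 <- paste0("rr.2.", ep)
    if (key2 %in% nm) ei$rr2[[ep]] <- draw[[key2]]
  }
  for (it in cost_item_levels()) {
    ei$costs[[it]] <- draw[[paste0("cost.", it)]]
  }
  for (us in setdiff(utility_state_levels(), "death")) {
    ei$utilities[[us]] <- draw[[paste0("utility.", us)]]
  }
  ei$progression <- draw[["progression"]]
  ei
}

#' Probabilistic sensitivity analysis
#'
#' Samples every uncertain parameter from its fitted distribution (beta
#' for rates, the progression probability and utilities; gamma for costs;
#' lognormal for relative risks), evaluates both strategy arms per draw,
#' and records the paired (cost, QALY) outcomes. The inner evaluation is
#' the deterministic cohort solver by default, so the spread across draws
#' reflects parameter (second-order) uncertainty only; an inner
#' microsimulation of `config$n_individuals` patients per draw can be
#' requested instead.
#'
#' @param params An `htn_params` object.
#' @param config A [run_config()].
#' @param n_draws Number of parameter draws (the published analysis uses
#'   10,000).
#' @param seed RNG seed for the draw stream; defaults to `config$seed`.
#' @param inner `"cohort"` (default) or `"microsimulation"`.
#' @return A `psa_result`: list with `draws` (tibble: `draw`, `cost_drug`,
#'   `qaly_drug`, `cost_non_drug`, `qaly_non_drug`, `delta_cost`,
#'   `delta_qaly`), `summary` (per-arm means and SDs), and the call
#'   settings.
#' @export
run_psa <- function(params, config = run_config(), n_draws = 10000,
                    seed = NULL, inner = c("cohort", "microsimulation")) {
  inner <- match.arg(inner)
  validate_parameters(params)
  if (n_draws < 1) abort("`n_draws` must be >= 1.")
  if (is.null(seed)) seed <- config$seed
  draw_mat <- sample_parameter_draws(params, n_draws, seed)
  ei0 <- engine_inputs(params)
  H <- config$horizon_years
  out <- matrix(NA_real_, n_draws, 4,
                dimnames = list(NULL, c("cost_drug", "qaly_drug",
                                        "cost_non_drug", "qaly_non_drug")))
  inner_seeds <- if (inner == "microsimulation") {
    sample.int(.Machine$integer.max, n_draws)
  }
  for (i in seq_len(n_draws)) {
    ei <- apply_draw_to_inputs(ei0, draw_mat[i, ])
    if (inner == "cohort") {
      rd <- cohort_solve_core(ei, "drug", H, config$discount_rate,
                              config$half_cycle_correction,
                              config$include_productivity,
                              config$stage2_effects,
                              config$progression_effect)
      rn <- cohort_solve_core(ei, "non_drug", H, config$discount_rate,
                              config$half_cycle_correction,
                              config$include_productivity,
                              config$stage2_effects,
                              config$progression_effect)
      out[i, ] <- c(rd$cost, rd$qalys, rn$cost, rn$qalys)
    } else {
      p_i <- params_from_inputs(params, ei)
      cfg_i <- config
      cfg_i$seed <- inner_seeds[i]
      rd <- run_microsimulation(p_i, "drug", cfg_i)
      rn <- run_microsimulation(p_i, "non_drug", cfg_i)
      out[i, ] <- c(rd$cost, rd$qalys, rn$cost, rn$qalys)
    }
  }
  draws <- tibble::as_tibble(out)
  draws$draw <- seq_len(n_draws)
  draws$delta_cost <- draws$cost_drug - draws$cost_non_drug
  draws$delta_qaly <- draws$qaly_drug - draws$qaly_non_drug
  draws <- dplyr::select(draws, "draw", dplyr::everything())
  summary <- tibble::tibble(
    arm = c("drug", "non_drug"),
    mean_cost = c(mean(draws$cost_drug), mean(draws$cost_non_drug)),
    sd_cost = c(stats::sd(draws$cost_drug), stats::sd(draws$cost_non_drug)),
    mean_qaly = c(mean(draws$qaly_drug), mean(draws$qaly_non_drug)),
    sd_qaly = c(stats::sd(draws$qaly_drug), stats::sd(draws$qaly_non_drug))
  )
  structure(
    list(draws = draws, summary = summary, n_draws = n_draws, seed = seed,
         inner = inner, config = config, wtp_per_gdp = params$wtp_per_gdp),
    class = "psa_result"
  )
}

## Rebuild an htn_params with point estimates replaced by an engine-input
## view (used by the inner-microsimulation PSA path).
params_from_inputs <- function(params, ei) {
  for (s in 1:2) {
    r <- if (s == 1) ei$r1 else ei$r2
    for (ev in event_levels()) {
      params <- set_model_parameter(params, paste("rate", s, ev, sep = "."),
                                    r[[ev]] * 1000)
    }
    rrv <- if (s == 1) ei$rr1 else ei$rr2
    for (ep in names(rrv)) {
      params <- set_model_parameter(params, paste("rr", s, ep, sep = "."),
                                    rrv[[ep]])
    }
  }
  for (it in cost_item_levels()) {
    params <- set_model_parameter(params, paste("cost", it, sep = "."),
                                  ei$costs[[it]])
  }
  for (us in setdiff(utility_state_levels(), "death")) {
    params <- set_model_parameter(params, paste("utility", us, sep = "."),
                                  ei$utilities[[us]])
  }
  set_model_parameter(params, "progression", ei$progression)
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d draws, %d-year horizon, inner = %s\n",
              x$n_draws, x$config$horizon_years, x$inner))
  print(x$summary)
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the probability that drug treatment
#' is cost-effective: the fraction of PSA draws with positive incremental
#' net monetary benefit `wtp * delta_qaly - delta_cost`.
#'
#' @param psa A `psa_result` from [run_psa()].
#' @param wtp_grid Non-negative WTP values; defaults to a grid from 0 to
#'   three per-capita GDPs.
#' @return Tibble `wtp`, `prob_cost_effective`.
#' @export
ceac <- function(psa, wtp_grid = NULL) {
  if (is.null(wtp_grid)) {
    wtp_grid <- seq(0, 3 * psa$wtp_per_gdp, length.out = 61)
  }
  if (length(wtp_grid) == 0) abort("`wtp_grid` must be non-empty.")
  if (any(wtp_grid < 0)) abort("`wtp_grid` values must be non-negative.")
  prob <- vapply(wtp_grid, function(l) {
    mean(l * psa$draws$delta_qaly - psa$draws$delta_cost > 0)
  }, numeric(1))
  tibble::tibble(wtp = wtp_grid, prob_cost_effective = prob)
}

#' Welch t tests on PSA outcome samples
#'
#' Two-sample Welch t tests comparing the per-draw cost vectors and QALY
#' vectors of the two arms, as a summary of whether the Monte-Carlo
#' outcome distributions differ.
#'
#' @param psa A `psa_result` with at least 2 draws.
#' @return Tibble with rows `cost` and `effectiveness`: group means,
#'   `statistic`, `df`, `p_value`.
#' @export
psa_t_tests <- function(psa) {
  if (psa$n_draws < 2) abort("Need at least 2 draws per arm.")
  run_test <- function(x, y, outcome) {
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      if (all(x == y)) {
        return(tibble::tibble(outcome = outcome, mean_drug = mean(x),
                              mean_non_drug = mean(y), statistic = 0,
                              df = NA_real_, p_value = 1))
      }
      abort("Zero variance in both samples; t test is degenerate.")
    }
    tt <- t.test(x, y)  # Welch by default
    tibble::tibble(outcome = outcome, mean_drug = mean(x),
                   mean_non_drug = mean(y),
                   statistic = unname(tt$statistic),
                   df = unname(tt$parameter), p_value = tt$p.value)
  }
  dplyr::bind_rows(
    run_test(psa$draws$cost_drug, psa$draws$cost_non_drug, "cost"),
    run_test(psa$draws$qaly_drug, psa$draws$qaly_non_drug, "effectiveness")
  )
}

#' Scenario analyses
#'
#' Evaluates the drug vs. non-drug comparison under alternative run
#' settings: the default set covers the 8- and 15-year base cases, the
#' extended 55-year horizon, and the 15-year run with productivity losses
#' excluded.
#'
#' @param params An `htn_params` object.
#' @param scenarios Tibble with columns `name`, `horizon_years`,
#'   `include_productivity`; `NULL` for the default set.
#' @param config Template [run_config()] supplying the remaining settings.
#' @return Tibble with one row per scenario: per-arm QALYs and costs,
#'   deltas, `icer`, `verdict`, `cost_effective`.
#' @export
run_scenarios <- function(params, scenarios = NULL, config = run_config()) {
  if (is.null(scenarios)) {
    scenarios <- tibble::tibble(
      name = c("base_8y", "base_15y", "horizon_55y", "no_productivity_15y"),
      horizon_years = c(8L, 15L, 55L, 15L),
      include_productivity = c(TRUE, TRUE, TRUE, FALSE)
    )
  }
  purrr::pmap_dfr(scenarios, function(name, horizon_years,
                                      include_productivity, ...) {
    cfg <- config
    cfg$horizon_years <- as.integer(horizon_years)
    cfg$include_productivity <- include_productivity
    bc <- base_case_table(params, cfg)
    cmp <- bc$comparison
    tibble::tibble(
      scenario = name, horizon_years = horizon_years,
      include_productivity = include_productivity,
      qaly_drug = bc$drug$qalys, cost_drug = bc$drug$cost,
      qaly_non_drug = bc$non_drug$qalys, cost_non_drug = bc$non_drug$cost,
      delta_qaly = cmp$delta_qaly, delta_cost = cmp$delta_cost,
      icer = cmp$icer, verdict = cmp$verdict,
      cost_effective = cmp$cost_effective
    )
  })
}
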