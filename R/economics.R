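#' Discount an amount accrued at a given cycle
#'
#' Applies the factor `(1 + rate)^-cycle`; cycle 0 is undiscounted.
#'
#' @param amount Dollar or QALY amount (vectorised).
#' @param cycle Cycle index (integer >= 0, vectorised).
#' @param rate Annual discount rate (>= 0; 0 is the identity).
#' @return Discounted amount.
#' @examples
#' discount(100, 1, 0.05) # 95.2381
#' @export
discount <- function(amount, cycle, rate) {
  if (any(rate < 0)) abort("`rate` must be non-negative.")
  if (any(cycle < 0)) abort("`cycle` must be non-negative.")
  amount * (1 + rate)^(-cycle)
}

#' Per-boundary cost and utility accrual for one state occupancy
#'
#' Returns the undiscounted annual cost ledger entry and utility weight for
#' a patient occupying `state` at cycle boundary `cycle`: stage-1 occupancy
#' accrues screening (plus drug cost in the drug arm), stage-2 accrues
#' screening plus drug cost in both arms, acute stroke/MI accrue the
#' first-year event cost, post-event states the subsequent-year cost, and
#' productivity loss accrues to every living patient while the
#' productivity window (default first 10 years) is open, reduced by 4.8%
#' in the drug arm. Death accrues nothing.
#'
#' @param state A clinical health state (see [health_states()]) or an
#'   engine state label such as `"POST_STROKE_S2"`.
#' @param arm `"drug"` or `"non_drug"`.
#' @param cycle Cycle boundary index (0-based).
#' @param params An `htn_params` object.
#' @param config A [run_config()] (for `include_productivity`).
#' @return Tibble with one row per cost category (`stage1`, `stage2`,
#'   `stroke`, `mi`, `productivity`) holding `amount`, plus the scalar
#'   `utility` as an attribute and column.
#' @examples
#' accrue_cycle("STAGE1_HTN", "drug", 3, default_parameters())
#' @export
accrue_cycle <- function(state, arm = c("drug", "non_drug"), cycle,
                         params, config = run_config()) {
  arm <- match.arg(arm)
  stt <- engine_state_table()
  if (state %in% stt$clinical) {
    engine_state <- stt$state[match(state, stt$clinical)]
  } else if (state %in% stt$state) {
    engine_state <- state
  } else {
    abort(paste0("Unknown health state: ", state))
  }
  ei <- engine_inputs(params)
  vals <- state_value_vectors(ei, arm, config$include_productivity)
  ix <- match(engine_state, stt$state)
  amounts <- setNames(numeric(5), cost_categories())
  cat <- vals$category[ix]
  if (cat != "none") amounts[[cat]] <- vals$cost[[ix]]
  in_window <- cycle < params$productivity_window_years
  if (stt$clinical[ix] != "DEAD" && in_window) {
    amounts[["productivity"]] <- vals$productivity
  }
  tibble::tibble(
    category = names(amounts),
    amount = unname(amounts),
    utility = vals$utility[[ix]],
    state = state, arm = arm, cycle = cycle
  )
}

#' Compare two strategy arms
#'
#' Computes incremental cost and effectiveness of an intervention over a
#' comparator and classifies the result: `dominant` (cheaper and more
#' effective), `dominated` (costlier and less effective), or an ICER.
#' Cost-effectiveness at the willingness-to-pay threshold follows the net
#' monetary benefit rule, which handles every quadrant without division.
#'
#' @param intervention,comparator `arm_result` objects (deltas are
#'   intervention minus comparator).
#' @param wtp Willingness-to-pay threshold in dollars per QALY.
#' @return A `ce_comparison` object with `delta_cost`, `delta_qaly`,
#'   `icer` (NA under dominance or zero effect difference), `verdict`,
#'   `nmb` (net monetary benefit at `wtp`), and `cost_effective`.
#' @examples
#' p <- default_parameters()
#' cfg <- run_config(15)
#' compare_arms(solve_cohort(p, "drug", cfg),
#'              solve_cohort(p, "non_drug", cfg), wtp = p$wtp_per_gdp)
#' @export
compare_arms <- function(intervention, comparator, wtp = 10438.66) {
  dc <- intervention$cost - comparator$cost
  de <- intervention$qalys - comparator$qalys
  if (de == 0 && dc == 0) {
    verdict <- "equivalent"
    icer <- NA_real_
  } else if (de == 0) {
    verdict <- "cost_comparison_only"  # no ICER: equal effectiveness
    icer <- NA_real_
  } else if (dc < 0 && de > 0) {
    verdict <- "dominant"
    icer <- NA_real_
  } else if (dc > 0 && de < 0) {
    verdict <- "dominated"
    icer <- NA_real_
  } else {
    verdict <- "icer"
    icer <- dc / de
  }
  nmb <- wtp * de - dc
  structure(
    list(delta_cost = dc, delta_qaly = de, icer = icer, verdict = verdict,
         wtp = wtp, nmb = nmb, cost_effective = nmb > 0,
         intervention = intervention$arm, comparator = comparator$arm),
    class = "ce_comparison"
  )
}

#' @export
print.ce_comparison <- function(x, ...) {
  cat(sprintf("<ce_comparison> %s vs %s\n", x$intervention, x$comparator))
  cat(sprintf("  delta cost $%.2f, delta QALY %.4f\n",
              x$delta_cost, x$delta_qaly))
  lab <- switch(x$verdict,
    dominant = "dominant (cost-saving)",
    dominated = "dominated",
    icer = sprintf("ICER $%.2f/QALY", x$icer),
    x$verdict)
  cat(sprintf("  verdict: %s; NMB at $%.0f/QALY = $%.2f (%scost-effective)\n",
              lab, x$wtp, x$nmb, if (x$cost_effective) "" else "not "))
  invisible(x)
}

#' Table-2-style comparison of both arms at one horizon
#'
#' Runs both strategy arms (cohort solver by default, or microsimulation)
#' and lays the results out as an outcome-by-arm table with a changes
#' column, matching the structure of the published results table.
#'
#' @param params An `htn_params` object.
#' @param config A [run_config()].
#' @param method `"cohort"` or `"microsimulation"`.
#' @return A list with `table` (tibble: `outcome`, `drug`, `non_drug`,
#'   `change`), the two `arm_result`s, and the `ce_comparison` at the
#'   parameter set's WTP anchor.
#' @export
base_case_table <- function(params, config = run_config(),
                            method = c("cohort", "microsimulation")) {
  method <- match.arg(method)
  runner <- if (method == "cohort") solve_cohort else run_microsimulation
  drug <- runner(params, "drug", config)
  non_drug <- runner(params, "non_drug", config)
  cmp <- compare_arms(drug, non_drug, wtp = params$wtp_per_gdp)
  rows <- c("discounted_qalys", "discounted_cost",
            paste0("cost_", cost_categories()))
  val <- function(r) c(r$qalys, r$cost, unname(r$cost_by_category))
  v_drug <- val(drug)
  v_non <- val(non_drug)
  tab <- tibble::tibble(
    outcome = rows,
    drug = v_drug,
    non_drug = v_non,
    change = v_drug - v_non
  )
  list(table = tab, drug = drug, non_drug = non_drug, comparison = cmp)
}
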