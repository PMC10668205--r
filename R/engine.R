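## Markov engine: expanded state space, transition model, cohort solver and
## individual-level microsimulation.
##
## The seven clinical states are expanded over the persistent hypertension-
## stage attribute (the Table-column a patient's second-event rates come
## from), giving 11 engine states. Acute STROKE/MI are tunnel states: their
## residual transition leads to the matching post-event state, so occupancy
## lasts one cycle unless recurrence, a cross event, or death intervenes.

engine_state_table <- function() {
  tibble::tibble(
    state = c("STAGE1_HTN", "STAGE2_HTN",
              "STROKE_S1", "STROKE_S2", "POST_STROKE_S1", "POST_STROKE_S2",
              "MI_S1", "MI_S2", "POST_MI_S1", "POST_MI_S2", "DEAD"),
    clinical = c("STAGE1_HTN", "STAGE2_HTN",
                 "STROKE", "STROKE", "POST_STROKE", "POST_STROKE",
                 "MI", "MI", "POST_MI", "POST_MI", "DEAD"),
    stage_attr = c(1, 2, 1, 2, 1, 2, 1, 2, 1, 2, NA),
    utility_state = c("hypertension", "hypertension",
                      "stroke", "stroke", "post_stroke", "post_stroke",
                      "mi", "mi", "post_mi", "post_mi", "death"),
    cost_category = c("stage1", "stage2", "stroke", "stroke", "stroke",
                      "stroke", "mi", "mi", "mi", "mi", "none")
  )
}

#' The model's health states
#'
#' @return Character vector of the seven clinical health states. `DEAD` is
#'   absorbing; `STROKE` and `MI` are one-cycle acute (tunnel) states that
#'   feed `POST_STROKE` / `POST_MI`.
#' @export
health_states <- function() {
  c("STAGE1_HTN", "STAGE2_HTN", "STROKE", "POST_STROKE",
    "MI", "POST_MI", "DEAD")
}

#' Run configuration for the Markov evaluation
#'
#' @param horizon_years Integer time horizon in annual cycles (the package's
#'   analyses use 8, 15 and 55).
#' @param n_individuals Number of simulated individuals for the
#'   microsimulation (ignored by the cohort solver).
#' @param seed Integer seed for the microsimulation RNG stream.
#' @param discount_rate Annual discount rate; `NULL` takes the rate from
#'   the parameter set (base case 5%).
#' @param half_cycle_correction Apply the trapezoidal half-cycle correction
#'   (half weight on the entry and terminal boundaries). Default `TRUE`.
#' @param include_productivity Accrue productivity-loss costs during the
#'   productivity window. Default `TRUE`.
#' @param stage2_effects Apply the stage-2 column of treatment-effect
#'   relative risks to drug-arm patients after progression (and to their
#'   post-event states). Default `TRUE`; see the methods vignette.
#' @param progression_effect How the printed progression effect (0.61) acts
#'   on the annual progression probability in the drug arm:
#'   `"risk_reduction"` (default; treated probability
#'   `p * (1 - effect)`) or `"hazard_ratio"` (hazard multiplied by the
#'   effect).
#' @return A `run_config` list.
#' @export
run_config <- function(horizon_years = 15, n_individuals = 1e5, seed = 1L,
                       discount_rate = NULL, half_cycle_correction = TRUE,
                       include_productivity = TRUE, stage2_effects = TRUE,
                       progression_effect = c("risk_reduction",
                                              "hazard_ratio")) {
  if (horizon_years < 1) abort("`horizon_years` must be >= 1.")
  if (n_individuals < 1) abort("`n_individuals` must be >= 1.")
  structure(
    list(horizon_years = as.integer(horizon_years),
         n_individuals = as.integer(n_individuals),
         seed = as.integer(seed),
         discount_rate = discount_rate,
         half_cycle_correction = isTRUE(half_cycle_correction),
         include_productivity = isTRUE(include_productivity),
         stage2_effects = isTRUE(stage2_effects),
         progression_effect = match.arg(progression_effect)),
    class = "run_config"
  )
}

## Flat numeric view of an htn_params object, used on hot paths (cohort
## solves inside PSA/tornado loops) where tibble indexing would dominate.
engine_inputs <- function(params) {
  get_rates <- function(stage) {
    r <- params$rates[params$rates$stage == stage, ]
    setNames(r$mean, r$event)[event_levels()] / 1000
  }
  get_rrs <- function(stage) {
    r <- params$rrs[params$rrs$stage == stage, ]
    out <- setNames(r$mean, r$endpoint)
    out[intersect(rr_endpoint_levels(), names(out))]
  }
  list(
    r1 = get_rates(1), r2 = get_rates(2),
    rr1 = get_rrs(1), rr2 = get_rrs(2),
    progression = params$progression$mean,
    costs = setNames(params$costs$mean, params$costs$item)[cost_item_levels()],
    utilities = setNames(params$utilities$mean,
                         params$utilities$state)[utility_state_levels()],
    discount_rate = params$discount_rate,
    prod_window = params$productivity_window_years,
    prod_reduction = params$productivity_reduction_drug
  )
}

## Allocate competing cause-specific hazards within one cycle: total exit
## probability 1 - exp(-sum(h)), split proportionally to the hazards, so
## the per-destination probabilities are exact under constant competing
## hazards and can never sum beyond 1.
allocate_competing <- function(h) {
  H <- sum(h)
  if (H <= 0) return(h * 0)
  (1 - exp(-H)) * h / H
}

transition_matrix_core <- function(ei, arm, stage2_effects = TRUE,
                                   progression_effect = "risk_reduction") {
  st <- engine_state_table()$state
  drug <- identical(arm, "drug")
  eff <- function(stage, endpoint) {
    if (!drug) return(1)
    if (stage == 2 && !stage2_effects) return(1)
    tab <- if (stage == 1) ei$rr1 else ei$rr2
    tab[[endpoint]]
  }
  P <- matrix(0, 11, 11, dimnames = list(st, st))
  fill_row <- function(from, h, dest, residual) {
    p <- allocate_competing(h)
    P[from, dest] <<- p
    P[from, residual] <<- P[from, residual] + 1 - sum(p)
  }

  h_prog <- if (!drug) {
    -log(1 - ei$progression)
  } else if (progression_effect == "risk_reduction") {
    -log(1 - ei$progression * max(0, 1 - ei$rr1[["progression"]]))
  } else {
    -log(1 - ei$progression) * ei$rr1[["progression"]]
  }
  fill_row("STAGE1_HTN",
           c(ei$r1[["stroke"]] * eff(1, "stroke"),
             ei$r1[["mi"]] * eff(1, "mi"),
             ei$r1[["death"]] * eff(1, "death"),
             h_prog),
           c("STROKE_S1", "MI_S1", "DEAD", "STAGE2_HTN"), "STAGE1_HTN")
  fill_row("STAGE2_HTN",
           c(ei$r2[["stroke"]] * eff(2, "stroke"),
             ei$r2[["mi"]] * eff(2, "mi"),
             ei$r2[["death"]] * eff(2, "death")),
           c("STROKE_S2", "MI_S2", "DEAD"), "STAGE2_HTN")
  for (s in 1:2) {
    r <- if (s == 1) ei$r1 else ei$r2
    h_stroke_side <- c(r[["recurrent_stroke"]] * eff(s, "recurrent_stroke"),
                       r[["mi_after_stroke"]] * eff(s, "mi"),
                       r[["death_after_stroke"]] * eff(s, "death"))
    h_mi_side <- c(r[["recurrent_mi"]] * eff(s, "recurrent_mi"),
                   r[["stroke_after_mi"]] * eff(s, "stroke"),
                   r[["death_after_mi"]] * eff(s, "death"))
    STK <- paste0("STROKE_S", s); PST <- paste0("POST_STROKE_S", s)
    MI <- paste0("MI_S", s); PMI <- paste0("POST_MI_S", s)
    fill_row(STK, h_stroke_side, c(STK, MI, "DEAD"), PST)
    fill_row(PST, h_stroke_side, c(STK, MI, "DEAD"), PST)
    fill_row(MI, h_mi_side, c(MI, STK, "DEAD"), PMI)
    fill_row(PMI, h_mi_side, c(MI, STK, "DEAD"), PMI)
  }
  P["DEAD", "DEAD"] <- 1
  stopifnot(all(abs(rowSums(P) - 1) < 1e-12), all(P >= 0))
  P
}

#' Build the per-arm annual transition model
#'
#' Converts the event rates to per-cycle probabilities under the
#' constant-hazard competing-risks allocation and applies the
#' treatment-effect relative risks for the drug arm (on the hazard scale
#' for event endpoints; see `progression_effect` in [run_config()] for the
#' progression endpoint). The non-drug arm applies a relative risk of 1
#' everywhere.
#'
#' @param params An `htn_params` object.
#' @param arm `"drug"` or `"non_drug"`.
#' @param config A [run_config()]; only the structural switches
#'   (`stage2_effects`, `progression_effect`) are used here.
#' @return An `htn_model` object: the 11-state transition matrix over the
#'   expanded (clinical state x stage attribute) space, the state table,
#'   and a tidy tibble of transitions (`from`, `to`, `probability`).
#' @examples
#' m <- build_transition_model(default_parameters(), "non_drug")
#' dplyr::filter(m$transitions, from == "STAGE1_HTN")
#' @export
build_transition_model <- function(params, arm = c("drug", "non_drug"),
                                   config = run_config()) {
  arm <- match.arg(arm)
  validate_parameters(params)
  ei <- engine_inputs(params)
  P <- transition_matrix_core(ei, arm, config$stage2_effects,
                              config$progression_effect)
  trans <- tibble::as_tibble(as.data.frame.table(P, stringsAsFactors = FALSE))
  names(trans) <- c("from", "to", "probability")
  trans <- dplyr::filter(trans, .data$probability > 0)
  structure(
    list(arm = arm, matrix = P, states = engine_state_table(),
         transitions = trans, config = config, inputs = ei),
    class = "htn_model"
  )
}

#' @export
print.htn_model <- function(x, ...) {
  cat(sprintf("<htn_model> %s arm, %d engine states, %d transitions\n",
              x$arm, nrow(x$matrix), nrow(x$transitions)))
  invisible(x)
}

## Boundary weights for discounted accrual. State membership is valued at
## cycle boundaries t = 0..H; with the half-cycle correction the weights are
## trapezoidal (1/2, 1, ..., 1, 1/2); without it, membership counts at the
## beginning of each cycle (boundaries 0..H-1 at full weight), so the
## zero-event, zero-discount QALY over H cycles is exactly H.
boundary_weights <- function(horizon, half_cycle) {
  w <- rep(1, horizon + 1)
  if (half_cycle) {
    w[1] <- 0.5
    w[horizon + 1] <- 0.5
  } else {
    w[horizon + 1] <- 0
  }
  w
}

## Weights for the productivity-loss stream, active on boundaries
## [0, min(window, horizon)] with its own trapezoid under the half-cycle
## correction.
productivity_weights <- function(horizon, window, half_cycle) {
  w <- rep(0, horizon + 1)
  end <- min(window, horizon)
  if (end <= 0) return(w)
  if (half_cycle) {
    w[seq_len(end + 1)] <- 1
    w[1] <- 0.5
    w[end + 1] <- 0.5
  } else {
    w[seq_len(end)] <- 1  # boundaries 0..end-1, beginning-of-cycle count
  }
  w
}

## Per-state annual cost vectors by category and utility vector, for one arm.
state_value_vectors <- function(ei, arm, include_productivity = TRUE) {
  stt <- engine_state_table()
  cost <- setNames(numeric(11), stt$state)
  screening <- ei$costs[["screening"]]
  drug_cost <- ei$costs[["drug"]]
  cost["STAGE1_HTN"] <- screening + if (arm == "drug") drug_cost else 0
  cost["STAGE2_HTN"] <- screening + drug_cost
  cost[c("STROKE_S1", "STROKE_S2")] <- ei$costs[["stroke_first_year"]]
  cost[c("POST_STROKE_S1", "POST_STROKE_S2")] <- ei$costs[["stroke_subsequent"]]
  cost[c("MI_S1", "MI_S2")] <- ei$costs[["mi_first_year"]]
  cost[c("POST_MI_S1", "POST_MI_S2")] <- ei$costs[["mi_subsequent"]]
  utility <- ei$utilities[stt$utility_state]
  names(utility) <- stt$state
  prod_rate <- if (!include_productivity) {
    0
  } else {
    ei$costs[["productivity"]] *
      (if (arm == "drug") 1 - ei$prod_reduction else 1)
  }
  list(cost = cost, category = stt$cost_category, utility = utility,
       productivity = prod_rate)
}

cost_categories <- function() {
  c("stage1", "stage2", "stroke", "mi", "productivity")
}

## Deterministic cohort solve on the engine-input view; the workhorse behind
## solve_cohort() and every PSA/tornado evaluation.
cohort_solve_core <- function(ei, arm, horizon, discount_rate = NULL,
                              half_cycle = TRUE, include_productivity = TRUE,
                              stage2_effects = TRUE,
                              progression_effect = "risk_reduction",
                              keep_trace = FALSE) {
  d <- if (is.null(discount_rate)) ei$discount_rate else discount_rate
  P <- transition_matrix_core(ei, arm, stage2_effects, progression_effect)
  n_state <- nrow(P)
  occ <- matrix(0, horizon + 1, n_state, dimnames = list(NULL, rownames(P)))
  occ[1, "STAGE1_HTN"] <- 1
  for (t in seq_len(horizon)) occ[t + 1, ] <- occ[t, , drop = FALSE] %*% P
  disc <- (1 + d)^-(0:horizon)
  w <- boundary_weights(horizon, half_cycle)
  vals <- state_value_vectors(ei, arm, include_productivity)
  wdisc <- w * disc
  by_cat <- setNames(numeric(5), cost_categories())
  for (cat in c("stage1", "stage2", "stroke", "mi")) {
    sel <- vals$category == cat
    by_cat[[cat]] <- sum(wdisc * (occ[, sel, drop = FALSE] %*%
                                    vals$cost[sel]))
  }
  alive <- 1 - occ[, "DEAD"]
  wp <- productivity_weights(horizon, ei$prod_window, half_cycle)
  by_cat[["productivity"]] <- sum(wp * disc * alive * vals$productivity)
  qalys <- sum(wdisc * (occ %*% vals$utility))
  out <- list(qalys = qalys, cost = sum(by_cat), cost_by_category = by_cat)
  if (keep_trace) out$trace <- occ
  out
}

arm_result <- function(arm, method, qalys, cost, by_cat, se_qalys = 0,
                       se_cost = 0, config, trace = NULL) {
  stopifnot(abs(cost - sum(by_cat)) < 1e-6)
  structure(
    list(arm = arm, method = method, qalys = qalys, cost = cost,
         cost_by_category = by_cat, se_qalys = se_qalys, se_cost = se_cost,
         config = config, trace = trace),
    class = "arm_result"
  )
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf("<arm_result> %s arm (%s, %d-year horizon)\n", x$arm,
              x$method, x$config$horizon_years))
  cat(sprintf("  discounted QALYs: %.4f", x$qalys))
  if (x$se_qalys > 0) cat(sprintf(" (MC SE %.4f)", x$se_qalys))
  cat(sprintf("\n  discounted cost:  $%.2f", x$cost))
  if (x$se_cost > 0) cat(sprintf(" (MC SE %.2f)", x$se_cost))
  cat("\n  by category: ",
      paste(sprintf("%s $%.2f", names(x$cost_by_category),
                    x$cost_by_category), collapse = ", "), "\n")
  invisible(x)
}

#' Deterministic cohort evaluation of one strategy arm
#'
#' Propagates the full cohort distribution over the expanded state space
#' and accrues discounted QALYs and per-category costs exactly. This is
#' the expected-value limit of [run_microsimulation()] and serves as its
#' internal oracle; results are deterministic (Monte-Carlo standard errors
#' are zero).
#'
#' @param params An `htn_params` object.
#' @param arm `"drug"` or `"non_drug"`.
#' @param config A [run_config()].
#' @param keep_trace Keep the per-cycle state-occupancy matrix (see
#'   [cohort_trace()]).
#' @return An `arm_result` with discounted QALYs, discounted total cost,
#'   and the cost breakdown over categories stage1, stage2, stroke, mi,
#'   productivity.
#' @examples
#' solve_cohort(default_parameters(), "non_drug", run_config(15))
#' @export
solve_cohort <- function(params, arm = c("drug", "non_drug"),
                         config = run_config(), keep_trace = FALSE) {
  arm <- match.arg(arm)
  validate_parameters(params)
  ei <- engine_inputs(params)
  res <- cohort_solve_core(
    ei, arm, config$horizon_years, config$discount_rate,
    config$half_cycle_correction, config$include_productivity,
    config$stage2_effects, config$progression_effect, keep_trace
  )
  arm_result(arm, "cohort", res$qalys, res$cost, res$cost_by_category,
             config = config, trace = res$trace)
}

#' Per-cycle cohort state occupancies
#'
#' @param result An `arm_result` from [solve_cohort()] with
#'   `keep_trace = TRUE`.
#' @return Tibble with columns `cycle`, `state` (engine state), `clinical`,
#'   `occupancy`.
#' @export
cohort_trace <- function(result) {
  if (is.null(result$trace)) {
    abort("No trace stored; call solve_cohort(..., keep_trace = TRUE).")
  }
  occ <- result$trace
  stt <- engine_state_table()
  tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(occ), cycle = 0:(nrow(occ) - 1)),
    -dplyr::all_of("cycle"), names_to = "state", values_to = "occupancy"
  ) |>
    dplyr::left_join(dplyr::select(stt, "state", "clinical"), by = "state") |>
    dplyr::select("cycle", "state", "clinical", "occupancy")
}

## Vectorised state propagation for n individuals over one cycle.
## cum_p: 11 x 11 row-cumulative transition probabilities.
advance_states <- function(state_ix, cum_p, u) {
  nxt <- state_ix
  for (s in unique(state_ix)) {
    idx <- which(state_ix == s)
    cp <- cum_p[s, ]
    nxt[idx] <- 1L + findInterval(u[idx], cp[-length(cp)])
  }
  nxt
}

## Simulate the state matrix (n x horizon+1) of engine-state indices.
simulate_state_matrix <- function(P, n, horizon) {
  cum_p <- t(apply(P, 1, cumsum))
  S <- matrix(1L, n, horizon + 1)
  dead_ix <- which(rownames(P) == "DEAD")
  for (t in seq_len(horizon)) {
    cur <- S[, t]
    alive <- cur != dead_ix
    nxt <- cur
    if (any(alive)) {
      u <- runif(sum(alive))
      nxt[alive] <- advance_states(cur[alive], cum_p, u)
    }
    S[, t + 1] <- nxt
  }
  S
}

#' Simulate a single patient trajectory
#'
#' Draws one individual path through the model, recording the engine state
#' at each cycle boundary and per-cycle event flags.
#'
#' @param model An `htn_model` from [build_transition_model()].
#' @param config A [run_config()]; `horizon_years` and `seed` are used.
#' @param seed Optional seed overriding `config$seed`.
#' @return Tibble with `cycle` (0..horizon), `state`, `clinical`,
#'   `new_stroke`, `new_mi`, `progressed`, `died` flags.
#' @export
simulate_individual <- function(model, config = run_config(), seed = NULL) {
  set.seed(if (is.null(seed)) config$seed else seed)
  S <- simulate_state_matrix(model$matrix, 1L, config$horizon_years)
  stt <- engine_state_table()
  states <- stt$state[S[1, ]]
  clinical <- stt$clinical[S[1, ]]
  prev <- c(NA, clinical[-length(clinical)])
  tibble::tibble(
    cycle = 0:config$horizon_years,
    state = states,
    clinical = clinical,
    new_stroke = !is.na(prev) & clinical == "STROKE",  # acute entry; recurrence re-enters
    new_mi = !is.na(prev) & clinical == "MI",
    progressed = !is.na(prev) & clinical == "STAGE2_HTN" &
      prev == "STAGE1_HTN",
    died = !is.na(prev) & clinical == "DEAD" & prev != "DEAD"
  )
}

#' Individual-level microsimulation of one strategy arm
#'
#' First-order Monte-Carlo evaluation: `n_individuals` independent patient
#' paths are simulated through the per-arm transition model and discounted
#' QALYs and per-category costs are accrued per individual under the same
#' boundary/half-cycle conventions as [solve_cohort()]. Means converge to
#' the cohort solution as `n_individuals` grows; Monte-Carlo standard
#' errors of the means are reported.
#'
#' @inheritParams solve_cohort
#' @return An `arm_result` with `se_qalys`, `se_cost` > 0.
#' @examples
#' run_microsimulation(default_parameters(), "non_drug",
#'                     run_config(15, n_individuals = 2000, seed = 7))
#' @export
run_microsimulation <- function(params, arm = c("drug", "non_drug"),
                                config = run_config()) {
  arm <- match.arg(arm)
  validate_parameters(params)
  if (config$n_individuals < 1) abort("`n_individuals` must be >= 1.")
  ei <- engine_inputs(params)
  P <- transition_matrix_core(ei, arm, config$stage2_effects,
                              config$progression_effect)
  H <- config$horizon_years
  n <- config$n_individuals
  set.seed(config$seed)
  S <- simulate_state_matrix(P, n, H)

  d <- if (is.null(config$discount_rate)) ei$discount_rate else
    config$discount_rate
  disc <- (1 + d)^-(0:H)
  w <- boundary_weights(H, config$half_cycle_correction)
  wdisc <- w * disc
  vals <- state_value_vectors(ei, arm, config$include_productivity)

  util_by_ix <- unname(vals$utility)
  qaly_i <- as.vector(matrix(util_by_ix[S], n, H + 1) %*% wdisc)
  by_cat <- setNames(numeric(5), cost_categories())
  cost_i <- numeric(n)
  for (cat in c("stage1", "stage2", "stroke", "mi")) {
    cvec <- ifelse(vals$category == cat, vals$cost, 0)
    contrib <- as.vector(matrix(unname(cvec)[S], n, H + 1) %*% wdisc)
    by_cat[[cat]] <- mean(contrib)
    cost_i <- cost_i + contrib
  }
  dead_ix <- 11L
  wp <- productivity_weights(H, ei$prod_window,
                             config$half_cycle_correction)
  alive <- matrix(as.numeric(S != dead_ix), n, H + 1)
  prod_i <- as.vector(alive %*% (wp * disc)) * vals$productivity
  by_cat[["productivity"]] <- mean(prod_i)
  cost_i <- cost_i + prod_i

  arm_result(arm, "microsimulation", mean(qaly_i), mean(cost_i), by_cat,
             se_qalys = stats::sd(qaly_i) / sqrt(n),
             se_cost = stats::sd(cost_i) / sqrt(n),
             config = config)
}
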