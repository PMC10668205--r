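#' Convert an event rate to a per-cycle transition probability
#'
#' Converts an event rate expressed per 1000 person-years into a transition
#' probability for a cycle of `cycle_years` under a constant-hazard
#' (exponential) assumption, optionally scaling the hazard by a relative
#' risk. The relative risk multiplies the hazard, not the probability, so
#' the result stays in `[0, 1)` for any positive `rr`.
#'
#' @param rate Event rate per 1000 person-years (non-negative, vectorised).
#' @param rr Relative risk applied on the hazard scale (positive, default 1).
#' @param cycle_years Cycle length in years (positive, default 1).
#'
#' @return Transition probability in `[0, 1)`, same length as the inputs.
#' @examples
#' rate_to_prob(2.9)            # annual stroke probability at 2.9/1000 py
#' rate_to_prob(2.9, rr = 0.85) # under treatment
#' @export
rate_to_prob <- function(rate, rr = 1, cycle_years = 1) {
  if (any(rate < 0)) abort("`rate` must be non-negative.")
  if (any(rr <= 0)) abort("`rr` must be positive.")
  if (any(cycle_years <= 0)) abort("`cycle_years` must be positive.")
  1 - exp(-(rate / 1000) * rr * cycle_years)
}

#' Convert a per-cycle probability back to an annual hazard
#'
#' Inverse of the exponential rate-probability relation, on the hazard
#' (per person-year) scale rather than per 1000 person-years.
#'
#' @param p Probability in `[0, 1)`.
#' @param cycle_years Cycle length in years.
#' @return Hazard per person-year.
#' @export
prob_to_hazard <- function(p, cycle_years = 1) {
  if (any(p < 0 | p >= 1)) abort("`p` must be in [0, 1).")
  -log(1 - p) / cycle_years
}

event_levels <- function() {
  c("stroke", "mi", "death",
    "mi_after_stroke", "recurrent_stroke", "death_after_stroke",
    "stroke_after_mi", "recurrent_mi", "death_after_mi")
}

rr_endpoint_levels <- function() {
  c("stroke", "recurrent_stroke", "mi", "recurrent_mi", "death", "progression")
}

cost_item_levels <- function() {
  c("screening", "drug", "productivity", "stroke_first_year",
    "stroke_subsequent", "mi_first_year", "mi_subsequent")
}

utility_state_levels <- function() {
  c("hypertension", "stroke", "post_stroke", "mi", "post_mi", "death")
}

#' Load a model parameter file
#'
#' Reads and validates a JSON parameter file holding every model input:
#' first- and second-event rates per 1000 person-years with 95% CIs for
#' stage 1 and stage 2 hypertensive patients, the annual probability of
#' progression from stage 1 to stage 2, treatment-effect relative risks
#' with 95% CIs, annual costs (2020 US$) with fractional uncertainty
#' ranges, health-state utilities with ranges, the annual discount rate,
#' and the willingness-to-pay anchor (one per-capita GDP). The package
#' ships a complete base-case file; see [default_parameters()].
#'
#' @param path Path to a JSON parameter file following the schema of the
#'   shipped file `system.file("extdata", "table1_base_case.json",
#'   package = "htnce")`.
#'
#' @return A validated object of class `htn_params`: a list with tibbles
#'   `rates`, `rrs`, `costs`, `utilities`, a `progression` list
#'   (annual probability scale), and scalars `discount_rate`,
#'   `discount_range`, `wtp_per_gdp`, `productivity_window_years`,
#'   `productivity_reduction_drug`.
#' @seealso [default_parameters()], [validate_parameters()]
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Parameter file not found: ", path))
  }
  raw <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = TRUE),
    error = function(e) {
      abort(paste0("Failed to parse parameter file '", path, "': ",
                   conditionMessage(e)))
    }
  )
  required <- c("discount_rate", "wtp_per_gdp", "productivity_window_years",
                "productivity_reduction_drug", "rates_per_1000py",
                "progression_annual_pct", "relative_risks",
                "annual_costs_usd", "utilities")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(paste0("Parameter file is missing required key(s): ",
                 paste(missing, collapse = ", ")))
  }
  params <- structure(
    list(
      rates = tibble::as_tibble(raw$rates_per_1000py),
      progression = list(
        mean = raw$progression_annual_pct$mean / 100,
        ci_low = raw$progression_annual_pct$ci_low / 100,
        ci_high = raw$progression_annual_pct$ci_high / 100
      ),
      rrs = tibble::as_tibble(raw$relative_risks),
      costs = tibble::as_tibble(raw$annual_costs_usd),
      utilities = tibble::as_tibble(raw$utilities),
      discount_rate = raw$discount_rate$mean,
      discount_range = c(raw$discount_rate$low, raw$discount_rate$high),
      wtp_per_gdp = raw$wtp_per_gdp,
      productivity_window_years = raw$productivity_window_years,
      productivity_reduction_drug = raw$productivity_reduction_drug
    ),
    class = "htn_params"
  )
  validate_parameters(params)
}

#' The shipped base-case parameter set
#'
#' Loads the package's base-case parameter file (the full published input
#' table: rates, relative risks, costs, utilities, 5% discount rate, WTP
#' anchor $10,438.66).
#'
#' @return An `htn_params` object.
#' @examples
#' p <- default_parameters()
#' p$rates
#' @export
default_parameters <- function() {
  load_parameters(system.file("extdata", "table1_base_case.json",
                              package = "htnce", mustWork = TRUE))
}

#' Validate a model parameter set
#'
#' Checks completeness (every rate, relative-risk, cost and utility key the
#' transition-model builder needs) and the invariants of each entry:
#' `0 <= ci_low <= mean <= ci_high` for rates, `0 < ci_low` for relative
#' risks, non-negative cost means with fractional ranges in `(0, 1)`,
#' utilities in `[0, 1]`, and a discount rate in `[0, 0.5]`.
#'
#' @param params An `htn_params` object (possibly hand-modified).
#' @return `params`, invisibly classed, if valid; otherwise an error
#'   naming the offending entry.
#' @export
validate_parameters <- function(params) {
  check_interval_tbl <- function(tbl, keys, what, upper = Inf,
                                 lower_open = FALSE) {
    for (nm in c(keys, "mean", "ci_low", "ci_high")) {
      if (!nm %in% names(tbl)) {
        abort(paste0(what, " table is missing column '", nm, "'."))
      }
    }
    bad <- tbl$ci_low > tbl$mean | tbl$mean > tbl$ci_high
    if (any(bad)) {
      lab <- do.call(paste, c(tbl[bad, keys, drop = FALSE], sep = "/"))
      abort(paste0(what, " interval inverted (need ci_low <= mean <= ci_high) for: ",
                   paste(lab, collapse = ", ")))
    }
    low_bad <- if (lower_open) tbl$ci_low <= 0 else tbl$ci_low < 0
    if (any(low_bad)) {
      abort(paste0(what, " lower bound out of range."))
    }
    if (any(tbl$ci_high > upper)) {
      abort(paste0(what, " upper bound exceeds ", upper, "."))
    }
    invisible(TRUE)
  }

  need <- tidyr::expand_grid(stage = 1:2, event = event_levels())
  have <- dplyr::distinct(params$rates, .data$stage, .data$event)
  miss <- dplyr::anti_join(need, have, by = c("stage", "event"))
  if (nrow(miss) > 0) {
    abort(paste0("Missing rate entries: ",
                 paste(paste0("stage ", miss$stage, " ", miss$event),
                       collapse = ", ")))
  }
  check_interval_tbl(params$rates, c("stage", "event"), "Rate")

  need_rr <- dplyr::bind_rows(
    tibble::tibble(stage = 1, endpoint = rr_endpoint_levels()),
    tibble::tibble(stage = 2,
                   endpoint = setdiff(rr_endpoint_levels(), "progression"))
  )
  have_rr <- dplyr::distinct(params$rrs, .data$stage, .data$endpoint)
  miss_rr <- dplyr::anti_join(need_rr, have_rr, by = c("stage", "endpoint"))
  if (nrow(miss_rr) > 0) {
    abort(paste0("Missing relative-risk entries: ",
                 paste(paste0("stage ", miss_rr$stage, " ", miss_rr$endpoint),
                       collapse = ", ")))
  }
  # zero is allowed: under the risk-reduction reading of the progression
  # effect, 0 is the neutral (no-effect) value
  check_interval_tbl(params$rrs, c("stage", "endpoint"), "Relative risk")

  miss_cost <- setdiff(cost_item_levels(), params$costs$item)
  if (length(miss_cost) > 0) {
    abort(paste0("Missing cost entries: ", paste(miss_cost, collapse = ", ")))
  }
  if (any(params$costs$mean < 0)) abort("Cost means must be non-negative.")
  if (any(params$costs$rel_range < 0 | params$costs$rel_range >= 1)) {
    abort("Cost `rel_range` must lie in [0, 1).")
  }

  miss_u <- setdiff(utility_state_levels(), params$utilities$state)
  if (length(miss_u) > 0) {
    abort(paste0("Missing utility entries: ", paste(miss_u, collapse = ", ")))
  }
  check_interval_tbl(params$utilities, "state", "Utility", upper = 1)

  pr <- params$progression
  if (!(pr$ci_low <= pr$mean && pr$mean <= pr$ci_high) ||
      pr$ci_low < 0 || pr$ci_high > 1) {
    abort("Progression probability interval invalid.")
  }
  if (is.null(params$discount_rate) ||
      params$discount_rate < 0 || params$discount_rate > 0.5) {
    abort("discount_rate must lie in [0, 0.5].")
  }
  if (params$wtp_per_gdp <= 0) abort("wtp_per_gdp must be positive.")
  if (params$productivity_window_years < 0) {
    abort("productivity_window_years must be non-negative.")
  }
  if (params$productivity_reduction_drug < 0 ||
      params$productivity_reduction_drug > 1) {
    abort("productivity_reduction_drug must lie in [0, 1].")
  }
  invisible(params)
}

#' @export
print.htn_params <- function(x, ...) {
  cat("<htn_params> stage 1 hypertension cost-effectiveness inputs\n")
  cat(sprintf("  %d event rates (per 1000 py), progression %.2f%%/yr\n",
              nrow(x$rates), 100 * x$progression$mean))
  cat(sprintf("  %d relative risks, %d cost items, %d utilities\n",
              nrow(x$rrs), nrow(x$costs), nrow(x$utilities)))
  cat(sprintf("  discount %.1f%%/yr (range %.0f-%.0f%%), WTP $%.2f/QALY\n",
              100 * x$discount_rate, 100 * x$discount_range[1],
              100 * x$discount_range[2], x$wtp_per_gdp))
  cat(sprintf("  productivity: $%.2f/yr, first %d years, %.1f%% lower on drug\n",
              x$costs$mean[x$costs$item == "productivity"],
              x$productivity_window_years,
              100 * x$productivity_reduction_drug))
  invisible(x)
}

## -- small typed accessors used across the package ---------------------------

param_rate <- function(params, stage, event) {
  row <- params$rates[params$rates$stage == stage & params$rates$event == event, ]
  if (nrow(row) != 1) {
    abort(paste0("Unknown rate: stage ", stage, " ", event))
  }
  row$mean
}

param_rr <- function(params, stage, endpoint) {
  row <- params$rrs[params$rrs$stage == stage & params$rrs$endpoint == endpoint, ]
  if (nrow(row) != 1) {
    abort(paste0("Unknown relative risk: stage ", stage, " ", endpoint))
  }
  row$mean
}

param_cost <- function(params, item) {
  row <- params$costs[params$costs$item == item, ]
  if (nrow(row) != 1) abort(paste0("Unknown cost item: ", item))
  row$mean
}

param_utility <- function(params, state) {
  row <- params$utilities[params$utilities$state == state, ]
  if (nrow(row) != 1) abort(paste0("Unknown utility state: ", state))
  row$mean
}

#' Set a single model input by identifier
#'
#' Addressing scheme used by the one-way sensitivity machinery and by
#' scripted scenario edits. Identifiers are
#' `rate.<stage>.<event>`, `rr.<stage>.<endpoint>`, `cost.<item>`,
#' `utility.<state>`, `progression`, `discount_rate`, and
#' `productivity_reduction_drug`. Only the point estimate is changed;
#' interval bounds are widened if the new value falls outside them so the
#' object still validates.
#'
#' @param params An `htn_params` object.
#' @param id Parameter identifier string.
#' @param value New numeric value (natural units of the parameter; rates
#'   per 1000 person-years, progression as a probability).
#' @return The modified `htn_params` object.
#' @export
set_model_parameter <- function(params, id, value) {
  stopifnot(is.numeric(value), length(value) == 1)
  parts <- strsplit(id, ".", fixed = TRUE)[[1]]
  widen <- function(tbl, i) {
    tbl$mean[i] <- value
    tbl$ci_low[i] <- pmin(tbl$ci_low[i], value)
    tbl$ci_high[i] <- pmax(tbl$ci_high[i], value)
    tbl
  }
  if (parts[1] == "rate" && length(parts) == 3) {
    i <- which(params$rates$stage == as.integer(parts[2]) &
                 params$rates$event == parts[3])
    if (length(i) != 1) abort(paste0("Unknown parameter id: ", id))
    params$rates <- widen(params$rates, i)
  } else if (parts[1] == "rr" && length(parts) == 3) {
    i <- which(params$rrs$stage == as.integer(parts[2]) &
                 params$rrs$endpoint == parts[3])
    if (length(i) != 1) abort(paste0("Unknown parameter id: ", id))
    params$rrs <- widen(params$rrs, i)
  } else if (parts[1] == "cost" && length(parts) == 2) {
    i <- which(params$costs$item == parts[2])
    if (length(i) != 1) abort(paste0("Unknown parameter id: ", id))
    params$costs$mean[i] <- value
  } else if (parts[1] == "utility" && length(parts) == 2) {
    i <- which(params$utilities$state == parts[2])
    if (length(i) != 1) abort(paste0("Unknown parameter id: ", id))
    params$utilities <- widen(params$utilities, i)
  } else if (identical(id, "progression")) {
    params$progression$mean <- value
    params$progression$ci_low <- min(params$progression$ci_low, value)
    params$progression$ci_high <- max(params$progression$ci_high, value)
  } else if (identical(id, "discount_rate")) {
    params$discount_rate <- value
  } else if (identical(id, "productivity_reduction_drug")) {
    params$productivity_reduction_drug <- value
  } else {
    abort(paste0("Unknown parameter id: ", id))
  }
  validate_parameters(params)
}
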