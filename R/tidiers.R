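## broom-style tidiers for the package's result objects.

#' @describeIn solve_cohort Tidy an `arm_result` into one row per cost
#'   category.
#' @param x An `arm_result`.
#' @param ... Unused.
#' @export
tidy.arm_result <- function(x, ...) {
  tibble::tibble(
    arm = x$arm,
    category = names(x$cost_by_category),
    discounted_cost = unname(x$cost_by_category)
  )
}

#' @describeIn solve_cohort One-row summary of an `arm_result`.
#' @export
glance.arm_result <- function(x, ...) {
  tibble::tibble(
    arm = x$arm, method = x$method,
    horizon_years = x$config$horizon_years,
    discounted_qalys = x$qalys, discounted_cost = x$cost,
    se_qalys = x$se_qalys, se_cost = x$se_cost
  )
}

#' @describeIn compare_arms Tidy a `ce_comparison` into a one-row tibble.
#' @param x A `ce_comparison`.
#' @param ... Unused.
#' @export
tidy.ce_comparison <- function(x, ...) {
  tibble::tibble(
    intervention = x$intervention, comparator = x$comparator,
    delta_cost = x$delta_cost, delta_qaly = x$delta_qaly,
    icer = x$icer, verdict = x$verdict, wtp = x$wtp, nmb = x$nmb,
    cost_effective = x$cost_effective
  )
}

#' @describeIn run_psa Tidy a `psa_result` into its per-draw tibble.
#' @param x A `psa_result`.
#' @param ... Unused.
#' @export
tidy.psa_result <- function(x, ...) {
  x$draws
}

#' @describeIn run_psa One-row-per-arm summary (means/SDs across draws).
#' @export
glance.psa_result <- function(x, ...) {
  x$summary
}
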