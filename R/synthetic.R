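## Synthetic upstream data with the statistical structure the model inputs
## assume: person-time event tables at known generating rates (for Poisson
## rate/CI re-estimation) and early-retirement records (for
## productivity-loss computation). Everything here is generated; no real
## cohort data is used or emulated beyond its published summary structure.

#' Generate a synthetic person-time event table
#'
#' For each endpoint, each person's event time is exponential at the
#' generating hazard and censored at an independent uniform follow-up time
#' (interval chosen to give the cohort's mean follow-up of 8.23 years by
#' default). The marginal event counts and person-years are therefore
#' Poisson-consistent with the generating rates, which is the structure
#' the rate estimator assumes.
#'
#' @param n Persons per stage.
#' @param rates Tibble `stage`, `event`, `rate` (per 1000 person-years);
#'   defaults to the point estimates of [default_parameters()].
#' @param followup_range Uniform follow-up interval in years (default
#'   `c(1.90, 14.56)`, mean 8.23).
#' @param seed RNG seed.
#' @return Tibble `id`, `stage`, `event` (endpoint name), `years` (time at
#'   risk), `case` (0/1 event indicator), with the generating rates as
#'   attribute `true_rates`.
#' @export
generate_person_time <- function(n, rates = NULL,
                                 followup_range = c(1.90, 14.56),
                                 seed = 1L) {
  if (n < 1) abort("`n` must be >= 1.")
  if (is.null(rates)) {
    p <- default_parameters()
    rates <- dplyr::select(p$rates, "stage", "event", rate = "mean")
  }
  if (any(rates$rate < 0)) abort("Rates must be non-negative.")
  set.seed(seed)
  stages <- sort(unique(rates$stage))
  per_stage <- purrr::map_dfr(stages, function(s) {
    fu <- runif(n, followup_range[1], followup_range[2])
    rs <- rates[rates$stage == s, ]
    purrr::pmap_dfr(rs, function(stage, event, rate) {
      hazard <- rate / 1000
      t_event <- if (hazard > 0) stats::rexp(n, hazard) else rep(Inf, n)
      tibble::tibble(
        id = paste0("s", stage, "_", seq_len(n)),
        stage = stage,
        event = event,
        years = pmin(t_event, fu),
        case = as.integer(t_event <= fu)
      )
    })
  })
  attr(per_stage, "true_rates") <- rates
  per_stage
}

#' Exact Poisson rate estimate with 95% confidence interval
#'
#' Rate per 1000 person-years with the exact (Garwood) interval from the
#' chi-square/Poisson quantile identity:
#' `lower = qchisq(.025, 2k) / (2 PY)`, `upper = qchisq(.975, 2k + 2) /
#' (2 PY)`; zero events give a zero lower bound.
#'
#' @param events Event count(s), non-negative integers (vectorised).
#' @param person_years Positive person-years at risk (vectorised).
#' @return Tibble `events`, `person_years`, `mean`, `ci_low`, `ci_high`
#'   (per 1000 person-years).
#' @examples
#' estimate_rate_ci(100, 10000)
#' @export
estimate_rate_ci <- function(events, person_years) {
  if (any(person_years <= 0)) abort("`person_years` must be positive.")
  if (any(events < 0)) abort("`events` must be non-negative.")
  lo <- ifelse(events == 0, 0, qchisq(0.025, 2 * events) / 2)
  hi <- qchisq(0.975, 2 * (events + 1)) / 2
  tibble::tibble(
    events = events, person_years = person_years,
    mean = 1000 * events / person_years,
    ci_low = 1000 * lo / person_years,
    ci_high = 1000 * hi / person_years
  )
}

#' Re-estimate event rates from a person-time table
#'
#' Sums events and person-years per (stage, endpoint) and applies
#' [estimate_rate_ci()].
#'
#' @param person_time Output of [generate_person_time()] (or any tibble
#'   with `stage`, `event`, `years`, `case`).
#' @return Tibble `stage`, `event`, `events`, `person_years`, `mean`,
#'   `ci_low`, `ci_high`.
#' @export
estimate_rates <- function(person_time) {
  agg <- dplyr::summarise(
    dplyr::group_by(person_time, .data$stage, .data$event),
    events = sum(.data$case), person_years = sum(.data$years),
    .groups = "drop"
  )
  dplyr::bind_cols(
    dplyr::select(agg, "stage", "event"),
    estimate_rate_ci(agg$events, agg$person_years)
  )
}

#' Generate synthetic early-retirement records
#'
#' Emulates the administrative structure productivity losses are computed
#' from: sex, actual and legal retirement age (60 for men, 55 for women),
#' and annual wage. Early-retirement lengths are gamma-distributed with a
#' configurable mean (default 9.5 years, the cohort's reported average).
#' All records are synthetic.
#'
#' @param n Number of records.
#' @param p_male Proportion of men (default 0.8; the source cohort is an
#'   industrial workforce and predominantly male).
#' @param mean_early_years Mean early-retirement length in years.
#' @param annual_wage Annual wage in dollars (recycled).
#' @param seed RNG seed.
#' @return Tibble `sex`, `legal_age`, `actual_age`, `annual_wage`.
#' @export
generate_retirement_records <- function(n, p_male = 0.8,
                                        mean_early_years = 9.5,
                                        annual_wage = 275.38 / 9.5 * 10,
                                        seed = 1L) {
  if (n < 1) abort("`n` must be >= 1.")
  set.seed(seed)
  sex <- ifelse(runif(n) < p_male, "male", "female")
  legal <- ifelse(sex == "male", 60, 55)
  early <- rgamma(n, shape = 4, scale = mean_early_years / 4)
  tibble::tibble(
    sex = sex,
    legal_age = legal,
    actual_age = pmax(legal - early, 30),
    annual_wage = rep_len(annual_wage, n)
  )
}

#' Productivity loss from early retirement
#'
#' Loss per record = `max(0, legal_age - actual_age) * average_wage`:
#' the length of early retirement due to ill health times the average
#' wage. The legal retirement age defaults by sex (60 men / 55 women)
#' when no `legal_age` column is present.
#'
#' @param records Tibble with `actual_age` and either `legal_age` or
#'   `sex`.
#' @param average_wage Average annual wage in dollars (>= 0).
#' @return `records` with columns `early_years` and `loss` added.
#' @examples
#' productivity_loss(
#'   tibble::tibble(sex = c("male", "female"), actual_age = c(50, 50)),
#'   average_wage = 100
#' )
#' @export
productivity_loss <- function(records, average_wage) {
  if (average_wage < 0) abort("`average_wage` must be non-negative.")
  if (!"legal_age" %in% names(records)) {
    if (!"sex" %in% names(records)) {
      abort("`records` needs a `legal_age` or `sex` column.")
    }
    records$legal_age <- ifelse(records$sex == "male", 60, 55)
  }
  records$early_years <- pmax(0, records$legal_age - records$actual_age)
  records$loss <- records$early_years * average_wage
  records
}

#' Assemble a runnable parameter set from re-estimated rates
#'
#' Binds re-estimated event rates (e.g. from [estimate_rates()] on a
#' synthetic cohort) with the fixed inputs of a base parameter set
#' (relative risks, costs, utilities, scalars) into a validated
#' `htn_params`. A non-empty estimate table must cover every
#' (stage, endpoint) pair the transition model needs; missing endpoints
#' are reported by name. An empty table returns the base set unchanged.
#'
#' @param estimates Tibble `stage`, `event`, `mean`, `ci_low`, `ci_high`
#'   (per 1000 person-years). May be empty.
#' @param base An `htn_params` supplying everything else; defaults to
#'   [default_parameters()].
#' @return A validated `htn_params`.
#' @export
assemble_parameter_set <- function(estimates, base = default_parameters()) {
  validate_parameters(base)
  if (is.null(estimates) || nrow(estimates) == 0) return(base)
  need <- tidyr::expand_grid(stage = 1:2, event = event_levels())
  have <- dplyr::distinct(estimates, .data$stage, .data$event)
  miss <- dplyr::anti_join(need, have, by = c("stage", "event"))
  if (nrow(miss) > 0) {
    abort(paste0("Cannot assemble parameter set; missing rate estimate(s): ",
                 paste(paste0("stage ", miss$stage, " ", miss$event),
                       collapse = ", ")))
  }
  base$rates <- dplyr::select(
    dplyr::arrange(estimates, .data$stage,
                   match(.data$event, event_levels())),
    "stage", "event", "mean", "ci_low", "ci_high"
  )
  validate_parameters(base)
}
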