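# Shared fixtures, built in code. The base parameter set is loaded once per
# test run; helpers derive edited copies for degenerate / null scenarios.

base_params <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- default_parameters()
    cache
  }
})

# All event rates and the progression probability set to zero: nobody ever
# leaves stage 1 alive or dead.
zero_event_params <- function(params = base_params()) {
  params$rates$mean <- 0
  params$rates$ci_low <- 0
  params$rates$ci_high <- 0
  params$progression$mean <- 0
  params$progression$ci_low <- 0
  params$progression$ci_high <- 0
  validate_parameters(params)
}

# Treatment stripped of every effect and every cost difference: relative
# risks 1 (progression effect neutralised per mode by the caller), zero
# drug-arm productivity reduction, zero drug cost.
null_treatment_params <- function(params = base_params(),
                                  progression_neutral = 1) {
  params$rrs$mean <- 1
  params$rrs$ci_low <- 1
  params$rrs$ci_high <- 1
  i <- params$rrs$stage == 1 & params$rrs$endpoint == "progression"
  params$rrs$mean[i] <- progression_neutral
  params$rrs$ci_low[i] <- progression_neutral
  params$rrs$ci_high[i] <- progression_neutral
  params$costs$mean[params$costs$item == "drug"] <- 0
  params$productivity_reduction_drug <- 0
  validate_parameters(params)
}

# Collapse every sampling distribution to a point mass at the base value.
point_mass_params <- function(params = base_params()) {
  params$rates$ci_low <- params$rates$mean
  params$rates$ci_high <- params$rates$mean
  params$rrs$ci_low <- params$rrs$mean
  params$rrs$ci_high <- params$rrs$mean
  params$costs$rel_range <- 0
  params$utilities$ci_low <- params$utilities$mean
  params$utilities$ci_high <- params$utilities$mean
  params$progression$ci_low <- params$progression$mean
  params$progression$ci_high <- params$progression$mean
  validate_parameters(params)
}

# Random multiplicative perturbation of rates, progression, costs and
# utilities; used by the engine-agreement and conservation property tests.
perturb_params <- function(params = base_params(), seed = 1) {
  set.seed(seed)
  jitter <- function(x, sd = 0.15) x * exp(rnorm(length(x), 0, sd))
  params$rates$mean <- jitter(params$rates$mean)
  params$rates$ci_low <- pmin(params$rates$ci_low, params$rates$mean)
  params$rates$ci_high <- pmax(params$rates$ci_high, params$rates$mean)
  params$progression$mean <- min(0.9, jitter(params$progression$mean, 0.1))
  params$progression$ci_low <- min(params$progression$ci_low,
                                   params$progression$mean)
  params$progression$ci_high <- max(params$progression$ci_high,
                                    params$progression$mean)
  params$costs$mean <- jitter(params$costs$mean, 0.1)
  u <- params$utilities$mean
  u[u > 0] <- pmin(0.99, jitter(u[u > 0], 0.05))
  params$utilities$mean <- u
  params$utilities$ci_low <- pmin(params$utilities$ci_low, u)
  params$utilities$ci_high <- pmax(params$utilities$ci_high, u)
  validate_parameters(params)
}

# Paper-style quick run configs (small n where microsimulation is involved).
cohort_config <- function(horizon = 15, ...) {
  run_config(horizon_years = horizon, n_individuals = 1000, ...)
}
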