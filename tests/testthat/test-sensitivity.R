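test_that("the default tornado grid covers every uncertain input", {
  g <- tornado_grid(base_params())
  expect_true(all(c("rate.1.stroke", "rr.1.progression", "cost.productivity",
                    "utility.hypertension", "progression",
                    "discount_rate") %in% g$parameter))
  expect_equal(nrow(g), 18 + 1 + 11 + 7 + 5 + 1)
  expect_true(all(g$low <= g$high))
})

test_that("tornado entries are sorted and invariant to input order", {
  p <- base_params()
  cfg <- run_config(8)
  g <- tornado_grid(p)[c(1, 3, 20, 30, 40), ]
  t1 <- one_way_tornado(p, cfg, grid = g)
  expect_equal(t1$width, sort(t1$width, decreasing = TRUE))
  t2 <- one_way_tornado(p, cfg, grid = g[sample(nrow(g)), ])
  expect_equal(t1$parameter, t2$parameter)
  expect_equal(t1$width, t2$width, tolerance = 1e-12)
})

test_that("degenerate ranges give zero width; unknown parameters error", {
  p <- base_params()
  cfg <- run_config(8)
  g0 <- tibble::tibble(parameter = "cost.drug", low = 88.92, high = 88.92)
  t0 <- one_way_tornado(p, cfg, grid = g0)
  expect_equal(nrow(t0), 1)
  expect_equal(t0$width, 0, tolerance = 1e-9)
  gbad <- tibble::tibble(parameter = "cost.unobtainium", low = 1, high = 2)
  expect_error(one_way_tornado(p, cfg, grid = gbad), "Unknown")
  ginv <- tibble::tibble(parameter = "cost.drug", low = 2, high = 1)
  expect_error(one_way_tornado(p, cfg, grid = ginv), "low <= high")
})

test_that("the discount rate is evaluated at its printed bounds", {
  p <- base_params()
  cfg <- run_config(15)
  g <- tibble::tibble(parameter = "discount_rate", low = 0, high = 0.08)
  tor <- one_way_tornado(p, cfg, grid = g)
  # oracle: evaluate the comparison directly at each bound
  nmb_at <- function(rate) {
    q <- base_case_table(set_model_parameter(p, "discount_rate", rate),
                         cfg)$comparison
    p$wtp_per_gdp * q$delta_qaly - q$delta_cost
  }
  expect_equal(tor$nmb_low, nmb_at(0), tolerance = 1e-9)
  expect_equal(tor$nmb_high, nmb_at(0.08), tolerance = 1e-9)
  expect_gt(tor$width, 0)
})

test_that("a point-mass PSA reproduces the base case", {
  p <- point_mass_params()
  cfg <- run_config(15)
  psa <- run_psa(p, cfg, n_draws = 2, seed = 4)
  d <- solve_cohort(p, "drug", cfg)
  n <- solve_cohort(p, "non_drug", cfg)
  expect_equal(psa$draws$cost_drug, rep(d$cost, 2), tolerance = 1e-9)
  expect_equal(psa$draws$qaly_drug, rep(d$qalys, 2), tolerance = 1e-9)
  expect_equal(psa$draws$cost_non_drug, rep(n$cost, 2), tolerance = 1e-9)
  expect_equal(psa$draws$qaly_non_drug, rep(n$qalys, 2), tolerance = 1e-9)
})

test_that("PSA draws are reproducible under a fixed seed and respect bounds", {
  p <- base_params()
  cfg <- run_config(8)
  a <- run_psa(p, cfg, n_draws = 50, seed = 21)
  b <- run_psa(p, cfg, n_draws = 50, seed = 21)
  expect_identical(a$draws, b$draws)
  draws <- sample_parameter_draws(p, 500, seed = 8)
  util_cols <- grep("^utility\\.", colnames(draws))
  expect_true(all(draws[, util_cols] >= 0 & draws[, util_cols] <= 1))
  expect_true(all(draws[, grep("^cost\\.", colnames(draws))] >= 0))
  expect_true(all(draws[, "progression"] >= 0 & draws[, "progression"] <= 1))
  expect_true(all(draws >= 0))
})

test_that("the CEAC equals brute-force per-draw NMB classification", {
  psa <- run_psa(base_params(), run_config(15), n_draws = 200, seed = 31)
  grid <- c(0, 5000, 10438.66, 31315.98)
  cc <- ceac(psa, grid)
  for (i in seq_along(grid)) {
    brute <- mean(vapply(seq_len(200), function(j) {
      grid[i] * psa$draws$delta_qaly[j] - psa$draws$delta_cost[j] > 0
    }, logical(1)))
    expect_identical(cc$prob_cost_effective[i], brute)
  }
  expect_identical(cc$prob_cost_effective[1], mean(psa$draws$delta_cost < 0))
  expect_true(all(cc$prob_cost_effective >= 0 & cc$prob_cost_effective <= 1))
  expect_error(ceac(psa, numeric(0)), "non-empty")
  expect_error(ceac(psa, c(-1, 10)), "non-negative")
})

test_that("all-dominant draws give probability 1 at every threshold", {
  psa <- run_psa(base_params(), run_config(15), n_draws = 40, seed = 3)
  psa$draws$delta_cost <- -abs(psa$draws$delta_cost) - 1
  psa$draws$delta_qaly <- abs(psa$draws$delta_qaly) + 0.01
  cc <- ceac(psa, c(0, 1e3, 1e5))
  expect_true(all(cc$prob_cost_effective == 1))
})

test_that("Welch t statistics match the textbook formula", {
  x <- c(10.2, 11.4, 9.8, 10.9, 10.5)
  y <- c(9.1, 9.9, 10.1, 9.5, 9.0)
  psa <- structure(list(
    draws = tibble::tibble(draw = 1:5, cost_drug = x, cost_non_drug = y,
                           qaly_drug = x / 10, qaly_non_drug = y / 10,
                           delta_cost = x - y, delta_qaly = (x - y) / 10),
    n_draws = 5
  ), class = "psa_result")
  tt <- psa_t_tests(psa)
  # brute-force Welch: t = (mx - my) / sqrt(sx2/n + sy2/n)
  sx2 <- var(x); sy2 <- var(y); n <- 5
  t_manual <- (mean(x) - mean(y)) / sqrt(sx2 / n + sy2 / n)
  df_manual <- (sx2 / n + sy2 / n)^2 /
    ((sx2 / n)^2 / (n - 1) + (sy2 / n)^2 / (n - 1))
  p_manual <- 2 * pt(-abs(t_manual), df_manual)
  expect_equal(tt$statistic[tt$outcome == "cost"], t_manual,
               tolerance = 1e-12)
  expect_equal(tt$df[tt$outcome == "cost"], df_manual, tolerance = 1e-12)
  expect_equal(tt$p_value[tt$outcome == "cost"], p_manual, tolerance = 1e-12)

  # identical samples: t = 0, p = 1
  psa$draws$cost_non_drug <- x
  psa$draws$qaly_non_drug <- x / 10
  tt0 <- psa_t_tests(psa)
  expect_equal(tt0$statistic, c(0, 0))
  expect_equal(tt0$p_value, c(1, 1))
})

test_that("the Welch test attains nominal type-I error under the null", {
  set.seed(606)
  n_rep <- 2000
  reject <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    x <- rnorm(40, mean = 5, sd = 1.3)
    y <- rnorm(40, mean = 5, sd = 1.3)
    psa <- structure(list(
      draws = tibble::tibble(draw = seq_along(x), cost_drug = x,
                             cost_non_drug = y, qaly_drug = x,
                             qaly_non_drug = y, delta_cost = x - y,
                             delta_qaly = 0),
      n_draws = length(x)
    ), class = "psa_result")
    reject[i] <- psa_t_tests(psa)$p_value[1] < 0.05
  }
  # binomial 3-sigma band around 0.05 at 2000 replicates
  expect_gt(mean(reject), 0.05 - 3 * sqrt(0.05 * 0.95 / n_rep))
  expect_lt(mean(reject), 0.05 + 3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("scenario runs cover the documented settings", {
  sc <- run_scenarios(base_params())
  expect_equal(nrow(sc), 4)
  expect_setequal(sc$scenario,
                  c("base_8y", "base_15y", "horizon_55y",
                    "no_productivity_15y"))
  expect_equal(sc$horizon_years[sc$scenario == "horizon_55y"], 55)
  # custom scenario table
  one <- run_scenarios(base_params(),
                       tibble::tibble(name = "short", horizon_years = 3L,
                                      include_productivity = TRUE))
  expect_equal(nrow(one), 1)
  expect_equal(one$horizon_years, 3)
})
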