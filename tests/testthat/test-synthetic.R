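test_that("person-time generation respects zero rates and seeding", {
  rates0 <- tibble::tibble(stage = 1, event = "stroke", rate = 0)
  pt0 <- generate_person_time(200, rates0, seed = 2)
  expect_equal(sum(pt0$case), 0)
  expect_true(all(pt0$years > 0))

  pt_a <- generate_person_time(500, seed = 10)
  pt_b <- generate_person_time(500, seed = 10)
  expect_identical(pt_a, pt_b)
  # both stages, every endpoint
  expect_equal(nrow(pt_a), 500 * 18)
  expect_setequal(unique(pt_a$stage), c(1, 2))
})

test_that("empirical rates match the generating hazards", {
  rates <- tibble::tibble(stage = 1, event = "stroke", rate = 2.9)
  pt <- generate_person_time(5e4, rates, seed = 14)
  py <- sum(pt$years)
  k <- sum(pt$case)
  emp <- 1000 * k / py
  se <- 1000 * sqrt(k) / py  # Poisson SE on the rate scale
  expect_lt(abs(emp - 2.9), 3 * se)
  # follow-up interval is chosen to give the cohort's 8.23-year mean
  pt_all <- generate_person_time(2e4, tibble::tibble(
    stage = 1, event = "stroke", rate = 0), seed = 3)
  expect_equal(mean(pt_all$years), 8.23, tolerance = 0.02)
  expect_gte(min(pt_all$years), 1.90)
  expect_lte(max(pt_all$years), 14.56)
})

test_that("exact Poisson intervals match an independent implementation", {
  est <- estimate_rate_ci(100, 10000)
  expect_equal(est$mean, 10)
  # oracle: stats::poisson.test exact interval, scaled to per-1000
  ref <- poisson.test(100, 10000)$conf.int * 1000
  expect_equal(est$ci_low, ref[1], tolerance = 1e-9)
  expect_equal(est$ci_high, ref[2], tolerance = 1e-9)

  z <- estimate_rate_ci(0, 500)
  expect_equal(z$mean, 0)
  expect_equal(z$ci_low, 0)
  expect_gt(z$ci_high, 0)

  expect_error(estimate_rate_ci(5, 0), "positive")
  expect_error(estimate_rate_ci(-1, 10), "non-negative")
})

test_that("interval coverage sits at the nominal level", {
  set.seed(123)
  true_rate <- 6           # per 1000 py
  py <- 10000              # expect ~60 events
  n_rep <- 500
  k <- rpois(n_rep, true_rate / 1000 * py)
  est <- estimate_rate_ci(k, py)
  covered <- est$ci_low <= true_rate & true_rate <= est$ci_high
  expect_gte(mean(covered), 0.93)
  expect_lte(mean(covered), 0.97)
})

test_that("rate estimates recover generating parameters cohort-wide", {
  pt <- generate_person_time(1e5, seed = 42)
  est <- estimate_rates(pt)
  truth <- attr(pt, "true_rates")
  joined <- merge(est, truth, by = c("stage", "event"))
  se <- 1000 * sqrt(pmax(joined$events, 1)) / joined$person_years
  expect_true(all(abs(joined$mean - joined$rate) <= 3 * se))
})

test_that("productivity loss is the early-retirement span times the wage", {
  rec <- tibble::tibble(sex = c("male", "female", "male"),
                        actual_age = c(60, 50, 50))
  out <- productivity_loss(rec, average_wage = 100)
  expect_equal(out$loss, c(0, 500, 1000))  # legal ages 60/55/60
  # explicit legal age wins over sex defaults
  rec2 <- tibble::tibble(legal_age = 55, actual_age = 58)
  expect_equal(productivity_loss(rec2, 100)$loss, 0)  # never negative
  expect_error(productivity_loss(tibble::tibble(actual_age = 50), 10),
               "legal_age")
  expect_error(productivity_loss(rec, -5), "non-negative")
})

test_that("productivity loss is piecewise linear in retirement age", {
  ages <- seq(40, 70, by = 1)
  rec <- tibble::tibble(sex = "male", actual_age = ages)
  loss <- productivity_loss(rec, 100)$loss
  expect_true(all(loss >= 0))
  expect_true(all(diff(loss) <= 0))           # non-increasing in actual age
  expect_equal(loss[ages >= 60], rep(0, sum(ages >= 60)))
  expect_equal(diff(loss[ages <= 60]), rep(-100, sum(ages <= 60) - 1))
})

test_that("assembly binds estimates to fixed inputs and names gaps", {
  base <- base_params()
  expect_identical(assemble_parameter_set(NULL, base), base)
  empty <- base$rates[0, c("stage", "event", "mean", "ci_low", "ci_high")]
  expect_identical(assemble_parameter_set(empty, base), base)

  est <- base$rates
  est <- est[!(est$stage == 1 & est$event == "mi"), ]
  expect_error(assemble_parameter_set(est, base), "stage 1 mi")

  full <- base$rates
  full$mean <- full$mean * 1.01
  full$ci_high <- pmax(full$ci_high, full$mean)
  out <- assemble_parameter_set(full, base)
  expect_s3_class(out, "htn_params")
  expect_equal(out$rates$mean, full$mean, tolerance = 1e-12)
  expect_identical(out$rrs, base$rrs)  # fixed inputs pass through
})

test_that("synthetic retirement records respect the legal-age structure", {
  rec <- generate_retirement_records(1000, seed = 6)
  expect_true(all(rec$legal_age[rec$sex == "male"] == 60))
  expect_true(all(rec$legal_age[rec$sex == "female"] == 55))
  expect_true(all(rec$actual_age <= rec$legal_age))
  expect_identical(rec, generate_retirement_records(1000, seed = 6))
  early <- rec$legal_age - rec$actual_age
  expect_equal(mean(early), 9.5, tolerance = 0.2)
})

test_that("a large synthetic cohort closes the loop to the base-case results", {
  pt <- generate_person_time(2e5, seed = 2024)
  est <- estimate_rates(pt)
  recovered <- assemble_parameter_set(
    est[, c("stage", "event", "mean", "ci_low", "ci_high")], base_params()
  )
  cfg <- run_config(15)
  for (arm in c("drug", "non_drug")) {
    got <- solve_cohort(recovered, arm, cfg)
    want <- solve_cohort(base_params(), arm, cfg)
    expect_equal(got$qalys, want$qalys, tolerance = 0.01)
    expect_equal(got$cost, want$cost, tolerance = 0.05)
  }
})
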