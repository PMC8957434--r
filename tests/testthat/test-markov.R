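test_that("discount factors follow the configured convention", {
  spec <- markov_spec(annual_discount = 0.05)
  expect_equal(discount_factor(0, spec), 1)
  expect_equal(discount_factor(12, spec), 1 / 1.05)
  expect_equal(discount_factor(1, spec), 1.05^(-1 / 12))
  step <- markov_spec(annual_discount = 0.05, discount_timing = "annual_step")
  expect_equal(discount_factor(0:11, step), rep(1, 12))
  expect_equal(discount_factor(12:23, step), rep(1 / 1.05, 12))
  expect_error(discount_factor(-1, spec), "non-negative")
})

test_that("a cohort with no transitions and no discounting stays put", {
  model <- markov_spec(annual_discount = 0)
  res <- run_cohort(model, strategy_spec("stay", 0, 100))
  expect_equal(res$discounted_pfs_months, 24)
  expect_true(all(res$trace$occupancy_pfs == 1))
  expect_equal(res$discounted_cost, 2400)
  expect_equal(res$discounted_qaly, 24 * 0.76 / 12)
})

test_that("certain transition absorbs the whole cohort in one cycle", {
  res <- run_cohort(markov_spec(), strategy_spec("gone", 1, 100))
  expect_lte(res$discounted_pfs_months, 1)
  expect_true(all(res$trace$occupancy_pfs[-1] == 0))
  expect_error(strategy_spec("bad", 1.2, 100), "0, 1")
})

test_that("occupancy is conserved and PFS occupancy never increases", {
  set.seed(31)
  for (p in c(0, runif(25), 1)) {
    res <- run_cohort(markov_spec(), strategy_spec("x", p, 50))
    sums <- res$trace$occupancy_pfs + res$trace$occupancy_pd
    expect_equal(sums, rep(1, 25), tolerance = 1e-12)
    expect_true(all(diff(res$trace$occupancy_pfs) <= 1e-15))
    expect_true(all(res$trace$occupancy_pfs >= 0))
  }
})

test_that("trace accumulation equals the geometric closed form", {
  base <- run_cohort(markov_spec(), strategy_spec("x", 0.0118, 117.16))
  expect_equal(base$discounted_pfs_months,
               closed_form_pfs_months(0.0118, 1.05^(-1 / 12), 24),
               tolerance = 1e-12)
  expect_equal(base$discounted_pfs_months, 19.78513, tolerance = 1e-5)
  expect_equal(closed_form_pfs_months(0, 1, 24), 24)
  expect_equal(closed_form_pfs_months(0.0251, 1, 24), 17.73842,
               tolerance = 1e-5)

  set.seed(17)
  for (i in 1:200) {
    p <- runif(1)
    disc <- runif(1, 0, 0.3)
    model <- markov_spec(annual_discount = disc)
    res <- run_cohort(model, strategy_spec("x", p, 1, utility_pfs = 1))
    expect_equal(res$discounted_pfs_months,
                 closed_form_pfs_months(p, (1 + disc)^(-1 / 12), 24),
                 tolerance = 1e-9)
  }
})

test_that("outcomes are proportional through discounted PFS-months", {
  res <- run_cohort(markov_spec(), strategy_spec("x", 0.0251, 78.10))
  expect_equal(res$discounted_cost, res$discounted_pfs_months * 78.10)
  expect_equal(res$discounted_qaly, res$discounted_pfs_months * 0.76 / 12)
})

test_that("cost and QALYs decrease in transition probability and discount", {
  months <- function(p, d) {
    run_cohort(markov_spec(annual_discount = d),
               strategy_spec("x", p, 100))$discounted_pfs_months
  }
  expect_true(months(0.01, 0.05) > months(0.02, 0.05))
  expect_true(months(0.02, 0.05) > months(0.1, 0.05))
  expect_true(months(0.01, 0) > months(0.01, 0.05))
  expect_true(months(0.01, 0.05) > months(0.01, 0.2))
})

test_that("reward conventions bracket each other: start >= half >= end", {
  for (p in c(0.0118, 0.0251, 0.2)) {
    acc <- sapply(c("start_of_cycle", "half_cycle", "end_of_cycle"),
      function(timing) {
        run_cohort(markov_spec(reward_timing = timing),
                   strategy_spec("x", p, 1))$discounted_pfs_months
      })
    expect_true(acc[1] >= acc[2] && acc[2] >= acc[3])
    expect_equal(acc[["half_cycle"]],
                 (acc[["start_of_cycle"]] + acc[["end_of_cycle"]]) / 2,
                 tolerance = 1e-12)
  }
})

test_that("the vectorised accumulator matches run_cohort for every convention", {
  set.seed(23)
  p <- runif(20)
  for (timing in c("end_of_cycle", "start_of_cycle", "half_cycle")) {
    for (dtiming in c("continuous_monthly", "annual_step")) {
      model <- markov_spec(reward_timing = timing, discount_timing = dtiming)
      fast <- rfacea:::accumulate_pfs_months(p, model)
      slow <- sapply(p, function(pi) {
        run_cohort(model, strategy_spec("x", pi, 1))$discounted_pfs_months
      })
      expect_equal(fast, slow, tolerance = 1e-12)
    }
  }
})

test_that("the optional alive-PD variant accrues PD utility", {
  model <- markov_spec()
  plain <- run_cohort(model, strategy_spec("x", 0.05, 10))
  alive <- run_cohort(model, strategy_spec("x", 0.05, 10, pd_alive = TRUE))
  expect_gt(alive$discounted_qaly, plain$discounted_qaly)
  expect_equal(alive$discounted_cost, plain$discounted_cost)
})
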