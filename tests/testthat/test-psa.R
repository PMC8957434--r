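test_that("beta moment matching reproduces the PFS-utility distribution", {
  fit <- beta_from_mean_range(0.76, 0.61, 0.91, "ci95")
  expect_equal(fit$sd, 0.3 / 3.92)
  expect_equal(fit$shape1, 22.91, tolerance = 1e-3)
  expect_equal(fit$shape2, 7.23, tolerance = 1e-3)
  # round trips: fitted mean and sd equal the targets to machine precision
  expect_equal(fit$shape1 / (fit$shape1 + fit$shape2), 0.76,
               tolerance = 1e-12)
  nu <- fit$shape1 + fit$shape2
  expect_equal(sqrt(fit$shape1 * fit$shape2 / (nu^2 * (nu + 1))), fit$sd,
               tolerance = 1e-9)
})

test_that("a symmetric beta has equal shapes", {
  fit <- beta_from_mean_range(0.5, 0.3, 0.7)
  expect_equal(fit$shape1, fit$shape2)
})

test_that("gamma moment matching reproduces the cost distribution", {
  fit <- gamma_from_mean_range(117.16, 58.58, 234.32, "ci95")
  expect_equal(fit$sd, 175.74 / 3.92)
  expect_equal(fit$shape, 6.83, tolerance = 1e-2)
  expect_equal(fit$scale, 17.16, tolerance = 1e-2)
  expect_equal(fit$shape * fit$scale, 117.16, tolerance = 1e-12)
  expect_equal(sqrt(fit$shape) * fit$scale, fit$sd, tolerance = 1e-12)
})

test_that("infeasible or invalid moments are refused", {
  expect_error(beta_from_mean_range(0.01, 0, 1), "Infeasible")
  expect_error(beta_from_mean_range(1.2, 0.5, 0.9), "strictly in")
  expect_error(gamma_from_mean_range(-5, 1, 10), "positive")
  expect_error(gamma_from_mean_range(5, 10, 1), "below")
})

test_that("min-max range semantics widen the matched sd", {
  ci <- beta_from_mean_range(0.76, 0.61, 0.91, "ci95")
  mm <- beta_from_mean_range(0.76, 0.61, 0.91, "minmax")
  expect_equal(mm$sd, 0.3 / sqrt(12))
  expect_gt(mm$sd, ci$sd)
})

test_that("the PSA is reproducible and leaves the caller's RNG alone", {
  strategies <- base_strategies()
  set.seed(123)
  before <- rnorm(1)
  a <- run_psa(strategies, n_draws = 300, seed = 9)
  b <- run_psa(strategies, n_draws = 300, seed = 9)
  expect_identical(a$samples, b$samples)
  set.seed(123)
  expect_identical(before, rnorm(1))
})

test_that("an all-fixed PSA degenerates to the base case", {
  strategies <- base_strategies()
  params <- default_parameters(strategies)
  params$distribution <- "fixed"
  psa <- run_psa(strategies, params, n_draws = 50, seed = 1)
  base <- run_cohort(markov_spec(), strategies$comparator)
  expect_equal(psa$samples$cost_comparator,
               rep(base$discounted_cost, 50), tolerance = 1e-12)
  expect_equal(psa$samples$qaly_comparator,
               rep(base$discounted_qaly, 50), tolerance = 1e-12)
})

test_that("sampled parameter means concentrate on their targets", {
  strategies <- base_strategies()
  psa <- run_psa(strategies, n_draws = 4000, seed = 2)
  s <- psa$samples
  sd_u <- 0.3 / 3.92
  expect_lt(abs(mean(s$u_pfs) - 0.76), 3 * sd_u / sqrt(4000))
  expect_true(all(s$u_pfs > 0 & s$u_pfs < 1))
  expect_true(all(s$p_comparator >= 0 & s$p_comparator <= 1))
  expect_true(all(s$c_comparator >= 0))
  # discount is a fixed parameter: never varies
  expect_true(all(s$discount == 0.05))
})

test_that("earlier parameter substreams survive appending a parameter", {
  strategies <- base_strategies()
  params <- default_parameters(strategies)
  full <- run_psa(strategies, params, n_draws = 200, seed = 5)
  extended <- params
  extended <- rbind(extended, extended[nrow(extended), ])
  extended$name[nrow(extended)] <- "discount2"
  extended$distribution[nrow(extended)] <- "beta"
  prefix <- run_psa(strategies, extended, n_draws = 200, seed = 5)
  expect_identical(full$samples$p_comparator, prefix$samples$p_comparator)
  expect_identical(full$samples$u_pfs, prefix$samples$u_pfs)
})

test_that("acceptability curves partition probability one", {
  strategies <- base_strategies()
  psa <- run_psa(strategies, n_draws = 500, seed = 3)
  curve <- ceac(psa, seq(0, 20000, by = 1000))
  expect_equal(curve$prob_comparator + curve$prob_reference,
               rep(1, nrow(curve)))
  expect_true(all(curve$prob_comparator >= 0 & curve$prob_comparator <= 1))
  expect_error(ceac(psa, numeric(0)), "non-empty")
})

test_that("a degenerate PSA gives a CEAC step exactly at the base-case ICER", {
  strategies <- base_strategies()
  params <- default_parameters(strategies)
  params$distribution <- "fixed"
  psa <- run_psa(strategies, params, n_draws = 20, seed = 1)
  model <- markov_spec()
  base_icer <- icer(run_cohort(model, strategies$comparator),
                    run_cohort(model, strategies$reference))$icer
  curve <- ceac(psa, c(base_icer - 1, base_icer + 1))
  expect_equal(curve$prob_comparator, c(0, 1))
})

test_that("CEAC is non-decreasing in WTP when every draw gains effect", {
  strategies <- base_strategies()
  psa <- run_psa(strategies, n_draws = 800, seed = 4)
  s <- psa$samples
  gains <- s$qaly_comparator > s$qaly_reference
  curve <- ceac(psa, seq(0, 30000, by = 500))
  if (all(gains)) {
    expect_true(all(diff(curve$prob_comparator) >= 0))
  } else {
    # restrict to the effect-gaining draws and recheck monotonicity
    psa$samples <- s[gains, ]
    sub <- ceac(psa, seq(0, 30000, by = 500))
    expect_true(all(diff(sub$prob_comparator) >= 0))
  }
})
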