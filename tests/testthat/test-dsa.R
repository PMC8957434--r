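test_that("the PFS utility dominates the tornado under the absolute-NMB target", {
  strategies <- base_strategies()
  tornado <- one_way(default_parameters(strategies), strategies)
  expect_s3_class(tornado, "tornado")
  expect_equal(tornado$param[1], "u_pfs")
  expect_true(all(diff(tornado$swing) <= 1e-9))
  # the PD utility never enters the absorbing model: zero swing, ranked last
  expect_equal(tornado$swing[tornado$param == "u_pd"], 0)
})

test_that("a degenerate range yields zero swing and ranks last", {
  strategies <- base_strategies()
  params <- default_parameters(strategies)
  params$low[params$name == "c_reference"] <- params$base[params$name == "c_reference"]
  params$high[params$name == "c_reference"] <- params$base[params$name == "c_reference"]
  tornado <- one_way(params, strategies)
  expect_equal(tornado$swing[tornado$param == "c_reference"], 0)
})

test_that("tornado swings are invariant to parameter evaluation order", {
  strategies <- base_strategies()
  params <- default_parameters(strategies)
  fwd <- one_way(params, strategies)
  rev_ <- one_way(params[rev(seq_len(nrow(params))), ], strategies)
  expect_equal(fwd[order(fwd$param), ]$swing,
               rev_[order(rev_$param), ]$swing, tolerance = 1e-12)
})

test_that("NMB responds exactly linearly to cost parameters", {
  strategies <- base_strategies()
  params <- default_parameters(strategies)
  months <- run_cohort(markov_spec(),
                       strategies$comparator)$discounted_pfs_months
  tornado <- one_way(params, strategies)
  row <- tornado[tornado$param == "c_comparator", ]
  # doubling the monthly cost lowers the strategy NMB by extra cost x months
  expect_equal(row$nmb_base - row$nmb_at_high,
               (row$high - row$base) * months, tolerance = 1e-9)
  # linearity: the NMB-per-dollar slope is identical on both sides of base
  expect_equal((row$nmb_base - row$nmb_at_high) / (row$high - row$base),
               (row$nmb_at_low - row$nmb_base) / (row$base - row$low),
               tolerance = 1e-9)
})

test_that("incremental-NMB tornado ranks the reference transition probability high", {
  strategies <- base_strategies()
  tornado <- one_way(default_parameters(strategies), strategies,
                     nmb_target = "incremental")
  expect_true("p_reference" %in% tornado$param[1:2])
})

test_that("two-way grid labels agree with direct decisions", {
  strategies <- base_strategies()
  params <- default_parameters(strategies)
  grid <- two_way(params, "u_pfs", "p_comparator", strategies,
                  grid_points = 3)
  expect_equal(nrow(grid), 9L)
  model <- markov_spec()
  for (i in c(1, 5, 9)) {
    ctx <- rfacea:::apply_overrides(model, strategies, 10888, stats::setNames(
      list(grid$value_a[i], grid$value_b[i]),
      c("utility_pfs", "comparator.monthly_prob")
    ))
    expect_equal(grid$preferred[i],
                 decide(run_cohort(ctx$model, ctx$strategies$comparator),
                        run_cohort(ctx$model, ctx$strategies$reference),
                        10888))
  }
  expect_error(two_way(params, "u_pfs", "u_pfs", strategies), "different")
})

test_that("a degenerate two-way grid carries a single label", {
  strategies <- base_strategies()
  params <- default_parameters(strategies)
  for (nm in c("u_pfs", "p_comparator")) {
    eps <- 1e-9 * params$base[params$name == nm]
    params$low[params$name == nm] <- params$base[params$name == nm] - eps
    params$high[params$name == nm] <- params$base[params$name == nm] + eps
  }
  grid <- two_way(params, "u_pfs", "p_comparator", strategies,
                  grid_points = 2)
  expect_equal(length(unique(grid$preferred)), 1L)
})

test_that("a parameter with no effect on either strategy has no threshold", {
  strategies <- base_strategies()
  params <- default_parameters(strategies)
  expect_true(is.na(threshold_analysis(params, "u_pd", strategies)))
})

test_that("the threshold on willingness-to-pay is the base-case ICER", {
  strategies <- base_strategies()
  params <- tibble::tibble(
    name = "wtp", label = "WTP", base = 10888, low = 0, high = 20000,
    distribution = "fixed", target = "wtp"
  )
  crossing <- threshold_analysis(params, "wtp", strategies)
  model <- markov_spec()
  base_icer <- icer(run_cohort(model, strategies$comparator),
                    run_cohort(model, strategies$reference))$icer
  expect_equal(crossing, base_icer, tolerance = 1e-4)
})

test_that("bisection agrees with a dense grid scan on the comparator probability", {
  strategies <- base_strategies()
  params <- default_parameters(strategies)
  crossing <- threshold_analysis(params, "p_comparator", strategies,
                                 tol = 1e-8)
  # independent oracle: closed-form NMB difference on a 1e5-point grid
  model <- markov_spec()
  d <- (1 + model$annual_discount)^(-1 / 12)
  m_ref <- closed_form_pfs_months(strategies$reference$monthly_prob, d, 24)
  nmb_ref <- 10888 * m_ref * 0.76 / 12 - m_ref * 78.10
  xs <- seq(0.0059, 0.0236, length.out = 1e5)
  m <- closed_form_pfs_months(xs, d, 24)
  diff_nmb <- (10888 * m * 0.76 / 12 - m * 117.16) - nmb_ref
  flip <- which(diff_nmb[-1] * diff_nmb[-length(diff_nmb)] < 0)
  expect_length(flip, 1L)
  expect_lt(abs(crossing - xs[flip]), 2 * diff(xs[1:2]))
})
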