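#' Moment-matched beta and gamma distributions
#'
#' Fits a beta (for probabilities and utilities) or gamma (for costs)
#' distribution to a base value and plausible range by the method of
#' moments. The mean is the base value; the standard deviation is read
#' from the range either as a 95% interval, `sd = (high - low)/3.92`
#' (default), or as the min-max of a uniform,
#' `sd = (high - low)/sqrt(12)`.
#'
#' For the beta, `alpha + beta = mean(1 - mean)/sd^2 - 1` and
#' `alpha = mean (alpha + beta)`; the moments are infeasible when
#' `sd^2 >= mean(1 - mean)`. For the gamma, `shape = (mean/sd)^2` and
#' `scale = sd^2/mean`. Both fits reproduce their target mean and sd
#' exactly.
#'
#' @param mean Target mean (in (0, 1) for beta, positive for gamma).
#' @param low,high Range bounds, `low < high`.
#' @param range_semantics `"ci95"` or `"minmax"` (see above).
#' @return A named list: `shape1`/`shape2` (beta) or `shape`/`scale`
#'   (gamma), plus the matched `mean` and `sd`.
#' @export
#' @examples
#' beta_from_mean_range(0.76, 0.61, 0.91)   # PFS utility
#' gamma_from_mean_range(117.16, 58.58, 234.32)
beta_from_mean_range <- function(mean, low, high,
                                 range_semantics = c("ci95", "minmax")) {
  sd <- range_sd(low, high, match.arg(range_semantics))
  if (mean <= 0 || mean >= 1) {
    stop("Beta `mean` must lie strictly in (0, 1).", call. = FALSE)
  }
  if (sd^2 >= mean * (1 - mean)) {
    stop("Infeasible beta moments: sd^2 = ", signif(sd^2, 4),
         " >= mean(1-mean) = ", signif(mean * (1 - mean), 4), call. = FALSE)
  }
  nu <- mean * (1 - mean) / sd^2 - 1
  list(shape1 = mean * nu, shape2 = (1 - mean) * nu, mean = mean, sd = sd)
}

#' @rdname beta_from_mean_range
#' @export
gamma_from_mean_range <- function(mean, low, high,
                                  range_semantics = c("ci95", "minmax")) {
  sd <- range_sd(low, high, match.arg(range_semantics))
  if (mean <= 0) {
    stop("Gamma `mean` must be positive.", call. = FALSE)
  }
  list(shape = (mean / sd)^2, scale = sd^2 / mean, mean = mean, sd = sd)
}

range_sd <- function(low, high, range_semantics) {
  if (low >= high) stop("`low` must be below `high`.", call. = FALSE)
  switch(range_semantics,
    ci95 = (high - low) / 3.92,
    minmax = (high - low) / sqrt(12)
  )
}

#' Attach fitted distributions to a parameter table
#'
#' @inheritParams run_psa
#' @return `params` with extra columns `sd`, `par1`, `par2` (beta
#'   shape1/shape2 or gamma shape/scale; `NA` for `fixed`).
#' @export
psa_distributions <- function(params, range_semantics = c("ci95", "minmax")) {
  range_semantics <- match.arg(range_semantics)
  # a zero-width range carries no uncertainty regardless of family
  params$distribution[params$high <= params$low] <- "fixed"
  fitted <- purrr::pmap(params, function(name, base, low, high, distribution,
                                         ...) {
    switch(distribution,
      fixed = list(par1 = NA_real_, par2 = NA_real_, sd = 0),
      beta = {
        f <- beta_from_mean_range(base, low, high, range_semantics)
        list(par1 = f$shape1, par2 = f$shape2, sd = f$sd)
      },
      gamma = {
        f <- gamma_from_mean_range(base, low, high, range_semantics)
        list(par1 = f$shape, par2 = f$scale, sd = f$sd)
      },
      stop("Unknown distribution '", distribution, "' for parameter ",
           name, call. = FALSE)
    )
  })
  dplyr::bind_cols(params, purrr::list_rbind(
    purrr::map(fitted, tibble::as_tibble)
  ))
}

# Discounted PFS-months, vectorised over draws. `p` (and optionally
# `annual_discount`) are vectors; the per-cycle weights implement the
# model's reward-timing convention (end: weight 1 on cycles 1..N; start:
# on 0..N-1; half-cycle: 1/2 at both ends).
accumulate_pfs_months <- function(p, model,
                                  annual_discount = model$annual_discount) {
  n <- model$horizon_cycles
  wt <- switch(model$reward_timing,
    end_of_cycle = c(0, rep(1, n)),
    start_of_cycle = c(rep(1, n), 0),
    half_cycle = c(0.5, rep(1, n - 1), 0.5)
  )
  months <- 0
  for (t in 0:n) {
    if (wt[t + 1] == 0) next
    disc <- switch(model$discount_timing,
      continuous_monthly = (1 + annual_discount)^(-t / 12),
      annual_step = (1 + annual_discount)^(-floor(t / 12))
    )
    months <- months + wt[t + 1] * (1 - p)^t * disc
  }
  months
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo resampling of the full model: every non-`fixed` parameter
#' is drawn independently from its moment-matched distribution, both
#' strategies are re-run per draw, and the discounted costs and QALYs are
#' recorded. Each parameter uses its own RNG substream seeded as
#' `seed + row index` in declaration order, so adding a parameter at the
#' end of the table does not perturb the draws of earlier ones; the
#' caller's RNG state is untouched.
#'
#' @param strategies Named list `comparator`/`reference` of
#'   [strategy_spec()]s.
#' @param params Parameter table ([default_parameters()] layout).
#' @param model A [markov_spec()].
#' @param n_draws Number of Monte Carlo repetitions.
#' @param seed Integer root seed.
#' @param wtp Willingness-to-pay used by [glance()] summaries.
#' @param range_semantics Passed to the moment matchers.
#' @return An object of class `psa_result`; its `samples` tibble has one
#'   row per draw with the sampled parameter values and per-strategy
#'   `cost_*`/`qaly_*` outcomes.
#' @seealso [ceac()]
#' @export
run_psa <- function(strategies, params = default_parameters(strategies, model),
                    model = markov_spec(), n_draws = 10000L, seed = 42L,
                    wtp = 10888, range_semantics = c("ci95", "minmax")) {
  range_semantics <- match.arg(range_semantics)
  if (n_draws < 1) stop("`n_draws` must be at least 1.", call. = FALSE)
  fitted <- psa_distributions(params, range_semantics)

  draws <- purrr::map(seq_len(nrow(fitted)), function(i) {
    row <- fitted[i, ]
    if (row$distribution == "fixed") {
      rep(row$base, n_draws)
    } else {
      withr::with_seed(as.integer(seed) + i, switch(row$distribution,
        beta = stats::rbeta(n_draws, row$par1, row$par2),
        gamma = stats::rgamma(n_draws, shape = row$par1, scale = row$par2)
      ))
    }
  })
  names(draws) <- fitted$name

  # Resolve each target path to its per-draw vector, falling back to the
  # base-case value for targets not in the table.
  value_for <- function(target, default) {
    hit <- fitted$name[fitted$target == target]
    if (length(hit)) draws[[hit[1]]] else rep(default, n_draws)
  }
  comp <- strategies$comparator
  ref <- strategies$reference
  p_c <- value_for("comparator.monthly_prob", comp$monthly_prob)
  p_r <- value_for("reference.monthly_prob", ref$monthly_prob)
  c_c <- value_for("comparator.monthly_cost", comp$monthly_cost)
  c_r <- value_for("reference.monthly_cost", ref$monthly_cost)
  u_pfs <- value_for("utility_pfs", comp$utility_pfs)
  u_pd <- value_for("utility_pd", comp$utility_pd)
  disc <- value_for("model.annual_discount", model$annual_discount)

  m_c <- accumulate_pfs_months(p_c, model, disc)
  m_r <- accumulate_pfs_months(p_r, model, disc)
  qaly_c <- m_c * u_pfs / 12
  qaly_r <- m_r * u_pfs / 12
  if (isTRUE(comp$pd_alive) || isTRUE(ref$pd_alive)) {
    alive <- accumulate_pfs_months(rep(0, n_draws), model, disc)
    if (isTRUE(comp$pd_alive)) qaly_c <- qaly_c + (alive - m_c) * u_pd / 12
    if (isTRUE(ref$pd_alive)) qaly_r <- qaly_r + (alive - m_r) * u_pd / 12
  }

  samples <- dplyr::bind_cols(
    tibble::tibble(draw = seq_len(n_draws)),
    tibble::as_tibble(draws),
    tibble::tibble(
      pfs_months_comparator = m_c, pfs_months_reference = m_r,
      cost_comparator = m_c * c_c, cost_reference = m_r * c_r,
      qaly_comparator = qaly_c, qaly_reference = qaly_r
    )
  )
  structure(
    list(samples = samples, params = fitted, model = model,
         strategies = strategies, n_draws = n_draws, seed = seed,
         wtp = wtp, range_semantics = range_semantics),
    class = "psa_result"
  )
}

# Per-draw preferred-strategy indicator at one WTP, with the NMB tie
# broken toward the cheaper strategy and then toward the reference.
comparator_preferred <- function(samples, wtp) {
  nmb_c <- wtp * samples$qaly_comparator - samples$cost_comparator
  nmb_r <- wtp * samples$qaly_reference - samples$cost_reference
  nmb_c > nmb_r |
    (nmb_c == nmb_r & samples$cost_comparator < samples$cost_reference)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA draws in which
#' each strategy has the higher net monetary benefit (ties resolved as in
#' [decide()]). The two probabilities partition 1 at every grid point.
#'
#' @param psa A [run_psa()] result.
#' @param wtp_grid Numeric vector of WTP values, dollars per QALY.
#' @return A tibble of class `ceac_curve` with columns `wtp`,
#'   `prob_comparator`, `prob_reference`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 20000, by = 100)) {
  stopifnot(inherits(psa, "psa_result"))
  if (!length(wtp_grid)) {
    stop("`wtp_grid` must be non-empty.", call. = FALSE)
  }
  prob <- vapply(wtp_grid, function(w) {
    mean(comparator_preferred(psa$samples, w))
  }, numeric(1))
  out <- tibble::tibble(
    wtp = wtp_grid,
    prob_comparator = prob,
    prob_reference = 1 - prob
  )
  class(out) <- c("ceac_curve", class(out))
  out
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("PSA: %d draws (seed %d, %s ranges)\n",
              x$n_draws, x$seed, x$range_semantics))
  print(glance(x))
  invisible(x)
}

#' @rdname tidy.cohort_result
#' @export
tidy.psa_result <- function(x, ...) x$samples

#' @rdname tidy.cohort_result
#' @export
glance.psa_result <- function(x, ...) {
  s <- x$samples
  tibble::tibble(
    n_draws = x$n_draws,
    mean_cost_comparator = mean(s$cost_comparator),
    mean_cost_reference = mean(s$cost_reference),
    mean_qaly_comparator = mean(s$qaly_comparator),
    mean_qaly_reference = mean(s$qaly_reference),
    wtp = x$wtp,
    prob_comparator_preferred = mean(comparator_preferred(s, x$wtp))
  )
}
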