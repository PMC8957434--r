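#' Two-state Markov cohort model specification
#'
#' The model has two health states — progression-free survival (PFS) and
#' an absorbing "progressive disease or death" (PD) state — stepped over
#' monthly cycles. Rewards (follow-up cost, quality-adjusted life) accrue
#' in PFS and are discounted at an annual rate.
#'
#' Reward timing and the discrete form of the discount are configurable,
#' because cohort models built in different tools differ in these
#' conventions and the difference is material over short horizons:
#' `end_of_cycle` credits cycle `t` with the occupancy surviving to `t`,
#' `start_of_cycle` with the occupancy entering the cycle, and
#' `half_cycle` with the average of the two (the usual half-cycle
#' correction). `continuous_monthly` discounting uses
#' `(1 + r)^(-t/12)`; `annual_step` uses `(1 + r)^(-floor(t/12))`.
#'
#' @param horizon_cycles Number of monthly cycles (default 24, i.e. the
#'   two-year surveillance window).
#' @param cycle_length_months Cycle length in months (fixed at 1 for the
#'   monthly model; kept explicit for clarity).
#' @param annual_discount Annual discount rate applied to both costs and
#'   QALYs, in [0, 1].
#' @param reward_timing One of `"end_of_cycle"`, `"start_of_cycle"`,
#'   `"half_cycle"`.
#' @param discount_timing One of `"continuous_monthly"`, `"annual_step"`.
#' @return A list of class `markov_spec`.
#' @export
markov_spec <- function(horizon_cycles = 24L,
                        cycle_length_months = 1,
                        annual_discount = 0.05,
                        reward_timing = c("end_of_cycle", "start_of_cycle",
                                          "half_cycle"),
                        discount_timing = c("continuous_monthly",
                                            "annual_step")) {
  reward_timing <- match.arg(reward_timing)
  discount_timing <- match.arg(discount_timing)
  if (horizon_cycles < 1 || horizon_cycles != round(horizon_cycles)) {
    stop("`horizon_cycles` must be a positive integer.", call. = FALSE)
  }
  if (annual_discount < 0 || annual_discount > 1) {
    stop("`annual_discount` must lie in [0, 1].", call. = FALSE)
  }
  structure(
    list(
      states = c("PFS", "PD_or_death"),
      absorbing = "PD_or_death",
      horizon_cycles = as.integer(horizon_cycles),
      cycle_length_months = cycle_length_months,
      annual_discount = annual_discount,
      reward_timing = reward_timing,
      discount_timing = discount_timing
    ),
    class = "markov_spec"
  )
}

#' Surveillance strategy parameters
#'
#' @param name Strategy label.
#' @param monthly_prob Monthly PFS-to-PD transition probability.
#' @param monthly_cost Follow-up cost per PFS month, in dollars.
#' @param utility_pfs Utility weight of the PFS state (per year, in [0, 1]).
#' @param utility_pd Utility weight of a non-absorbing PD variant; unused
#'   unless `pd_alive = TRUE` (the default model treats PD-or-death as
#'   absorbing with zero reward, since the state pools progression with
#'   death).
#' @param pd_alive If `TRUE`, QALYs also accrue in PD at `utility_pd`.
#' @return A list of class `strategy_spec`.
#' @export
#' @examples
#' two_three <- strategy_spec("two_three_month", 0.0118, 117.16)
#' run_cohort(markov_spec(), two_three)
strategy_spec <- function(name, monthly_prob, monthly_cost,
                          utility_pfs = 0.76, utility_pd = 0.68,
                          pd_alive = FALSE) {
  if (monthly_prob < 0 || monthly_prob > 1) {
    stop("`monthly_prob` must lie in [0, 1].", call. = FALSE)
  }
  if (monthly_cost < 0) {
    stop("`monthly_cost` must be non-negative.", call. = FALSE)
  }
  if (utility_pfs < 0 || utility_pfs > 1 || utility_pd < 0 || utility_pd > 1) {
    stop("Utilities must lie in [0, 1].", call. = FALSE)
  }
  structure(
    list(name = name, monthly_prob = monthly_prob,
         monthly_cost = monthly_cost, utility_pfs = utility_pfs,
         utility_pd = utility_pd, pd_alive = pd_alive),
    class = "strategy_spec"
  )
}

#' Discount factor at a cycle index
#'
#' @param cycle_index Cycle index (0-based); vectorised.
#' @param spec A [markov_spec()].
#' @return Discount factor(s) in (0, 1]; 1 at cycle 0.
#' @export
discount_factor <- function(cycle_index, spec = markov_spec()) {
  if (any(cycle_index < 0)) {
    stop("`cycle_index` must be non-negative.", call. = FALSE)
  }
  r <- spec$annual_discount
  months <- cycle_index * spec$cycle_length_months
  switch(spec$discount_timing,
    continuous_monthly = (1 + r)^(-months / 12),
    annual_step = (1 + r)^(-floor(months / 12))
  )
}

# Per-cycle reward weights (t = 0..N) for a given occupancy path `occ`
# and discount vector `disc`, under the model's reward timing. The sum of
# the weights is the discounted state-months.
reward_weights <- function(occ, disc, reward_timing) {
  n <- length(occ) - 1L
  at_end <- c(0, (occ * disc)[-1L])
  at_start <- c((occ * disc)[seq_len(n)], 0)
  switch(reward_timing,
    end_of_cycle = at_end,
    start_of_cycle = at_start,
    half_cycle = (at_end + at_start) / 2
  )
}

#' Run the cohort model for one strategy
#'
#' Propagates the full cohort from PFS through the absorbing PD-or-death
#' state over `horizon_cycles` monthly cycles:
#' `S_PFS(t) = S_PFS(t - 1) * (1 - p)`. Discounted PFS-months are
#' accumulated under the model's reward-timing convention; the discounted
#' cost is `monthly_cost` per discounted PFS-month and the discounted
#' QALYs are `utility_pfs / 12` per discounted PFS-month (utilities are
#' annual weights).
#'
#' @param model A [markov_spec()].
#' @param strategy A [strategy_spec()].
#' @return An object of class `cohort_result` with elements `trace` (a
#'   tibble `cycle, occupancy_pfs, occupancy_pd, discount, pfs_months,
#'   cost, qaly`, where the reward columns are per-cycle discounted
#'   accruals), `discounted_pfs_months`, `discounted_cost`,
#'   `discounted_qaly`, plus the input specs.
#' @seealso [closed_form_pfs_months()] for the geometric-series oracle.
#' @export
run_cohort <- function(model, strategy) {
  stopifnot(inherits(model, "markov_spec"), inherits(strategy, "strategy_spec"))
  n <- model$horizon_cycles
  t <- 0:n
  occ_pfs <- (1 - strategy$monthly_prob)^t
  occ_pd <- 1 - occ_pfs
  disc <- discount_factor(t, model)

  w_pfs <- reward_weights(occ_pfs, disc, model$reward_timing)
  months <- sum(w_pfs)
  cost <- w_pfs * strategy$monthly_cost
  qaly <- w_pfs * strategy$utility_pfs / 12
  if (isTRUE(strategy$pd_alive)) {
    w_pd <- reward_weights(occ_pd, disc, model$reward_timing)
    qaly <- qaly + w_pd * strategy$utility_pd / 12
  }

  trace <- tibble::tibble(
    cycle = t,
    occupancy_pfs = occ_pfs,
    occupancy_pd = occ_pd,
    discount = disc,
    pfs_months = w_pfs,
    cost = cost,
    qaly = qaly
  )
  structure(
    list(
      strategy = strategy,
      model = model,
      trace = trace,
      discounted_pfs_months = months,
      discounted_cost = sum(cost),
      discounted_qaly = sum(qaly)
    ),
    class = "cohort_result"
  )
}

#' Closed-form discounted PFS-months
#'
#' Independent geometric-series oracle for the end-of-cycle accumulation:
#' with `r = (1 - p) * monthly_discount`, the discounted PFS-months over
#' `cycles` cycles equal `r (1 - r^cycles) / (1 - r)` (and `cycles`
#' exactly when `r = 1`).
#'
#' @param p Monthly transition probability.
#' @param monthly_discount Per-cycle discount factor (e.g.
#'   `1.05^(-1/12)`).
#' @param cycles Number of cycles.
#' @return Discounted PFS-months; vectorised over `p` and
#'   `monthly_discount`.
#' @export
closed_form_pfs_months <- function(p, monthly_discount = 1, cycles = 24L) {
  if (any(p < 0 | p > 1)) {
    stop("`p` must lie in [0, 1].", call. = FALSE)
  }
  r <- (1 - p) * monthly_discount
  out <- ifelse(abs(1 - r) < 1e-12,
                cycles,
                r * (1 - r^cycles) / (1 - r))
  # p = 1: the whole cohort is absorbed at the first transition (r = 0).
  out[r == 0] <- 0
  out
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf(
    "Cohort run: %s (p = %.4f/month, %d cycles, %s + %s)\n",
    x$strategy$name, x$strategy$monthly_prob, x$model$horizon_cycles,
    x$model$reward_timing, x$model$discount_timing
  ))
  cat(sprintf(
    "  discounted PFS-months %.3f | cost $%.2f | QALYs %.4f\n",
    x$discounted_pfs_months, x$discounted_cost, x$discounted_qaly
  ))
  invisible(x)
}

#' Tidy a cohort run
#'
#' @param x A `cohort_result`.
#' @param ... Unused.
#' @return `tidy()` returns the per-cycle trace; `glance()` a one-row
#'   summary of the discounted outcomes.
#' @export
tidy.cohort_result <- function(x, ...) x$trace

#' @rdname tidy.cohort_result
#' @export
glance.cohort_result <- function(x, ...) {
  tibble::tibble(
    strategy = x$strategy$name,
    discounted_pfs_months = x$discounted_pfs_months,
    discounted_cost = x$discounted_cost,
    discounted_qaly = x$discounted_qaly,
    reward_timing = x$model$reward_timing,
    discount_timing = x$model$discount_timing
  )
}
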