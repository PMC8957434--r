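#' Survival, hazard rate and transition probability conversions
#'
#' Conversions under a constant-hazard (declining-exponential, DEALE)
#' assumption. A cumulative survival `S` observed at horizon `T` months
#' implies the constant monthly rate `-log(S)/T`; a constant rate `r`
#' acting for `dt` months implies the transition probability
#' `1 - exp(-r dt)`; and a constant per-cycle probability `p` compounds to
#' `(1 - p)^cycles` cumulative survival. The three functions round-trip to
#' machine precision.
#'
#' @param survival Cumulative survival proportion, in (0, 1].
#' @param horizon_months Observation horizon in months.
#' @return `rate_from_survival()`: constant hazard per month.
#' @export
#' @examples
#' rate <- rate_from_survival(0.752, 24)
#' prob_from_rate(rate, 1)            # monthly transition probability
#' survival_from_prob(0.0118, 24)     # back to ~0.752
rate_from_survival <- function(survival, horizon_months) {
  if (any(survival <= 0)) {
    stop("`survival` must be positive (> 0).", call. = FALSE)
  }
  if (any(survival > 1)) {
    stop("`survival` must be at most 1.", call. = FALSE)
  }
  if (any(horizon_months <= 0)) {
    stop("`horizon_months` must be positive.", call. = FALSE)
  }
  -log(survival) / horizon_months
}

#' @rdname rate_from_survival
#' @param rate Constant hazard per month, non-negative.
#' @param dt_months Cycle length in months.
#' @export
prob_from_rate <- function(rate, dt_months = 1) {
  if (any(rate < 0)) {
    stop("`rate` must be non-negative.", call. = FALSE)
  }
  if (any(dt_months <= 0)) {
    stop("`dt_months` must be positive.", call. = FALSE)
  }
  1 - exp(-rate * dt_months)
}

#' @rdname rate_from_survival
#' @param monthly_prob Per-cycle transition probability, in [0, 1].
#' @param cycles Number of cycles.
#' @export
survival_from_prob <- function(monthly_prob, cycles) {
  if (any(monthly_prob < 0 | monthly_prob > 1)) {
    stop("`monthly_prob` must lie in [0, 1].", call. = FALSE)
  }
  (1 - monthly_prob)^cycles
}
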