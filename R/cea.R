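#' Construct a strategy outcome
#'
#' A minimal container for a strategy's discounted cost and effect, either
#' taken from a [run_cohort()] result or entered directly (e.g. from a
#' published summary table).
#'
#' @param name Strategy label.
#' @param discounted_cost Discounted cost, dollars.
#' @param discounted_qaly Discounted effect, QALYs.
#' @param discounted_pfs_months Optional discounted PFS-months.
#' @return A list of class `strategy_outcome`.
#' @export
strategy_outcome <- function(name, discounted_cost, discounted_qaly,
                             discounted_pfs_months = NA_real_) {
  stopifnot(is.finite(discounted_cost), is.finite(discounted_qaly))
  structure(
    list(name = name, discounted_cost = discounted_cost,
         discounted_qaly = discounted_qaly,
         discounted_pfs_months = discounted_pfs_months),
    class = "strategy_outcome"
  )
}

as_strategy_outcome <- function(x) {
  if (inherits(x, "strategy_outcome")) return(x)
  if (inherits(x, "cohort_result")) {
    return(strategy_outcome(x$strategy$name, x$discounted_cost,
                            x$discounted_qaly, x$discounted_pfs_months))
  }
  stop("Expected a `strategy_outcome` or `cohort_result`.", call. = FALSE)
}

#' Incremental cost-effectiveness ratio
#'
#' Compares a comparator strategy against a reference: incremental cost
#' `delta_cost` and effect `delta_effect` are comparator minus reference,
#' and when the comparator is both more effective and more costly (or
#' less of both) the ICER `delta_cost / delta_effect` is defined.
#' Dominance is classified from the signs: a comparator that gains effect
#' at no extra cost dominates; one that loses effect at no saving is
#' dominated; equal effects leave the ICER undefined.
#'
#' @param comparator,reference [strategy_outcome()]s or [run_cohort()]
#'   results.
#' @return An object of class `cea_result` with `delta_cost`,
#'   `delta_effect`, `icer` (NA unless defined) and `classification`, one
#'   of `"icer_defined"`, `"comparator_dominates"`,
#'   `"comparator_dominated"`, `"equal_effect"`.
#' @export
#' @examples
#' two_three <- strategy_outcome("two_three_month", 2212.66, 1.196)
#' three_four <- strategy_outcome("three_four_month", 1268.92, 1.029)
#' icer(two_three, three_four)
icer <- function(comparator, reference) {
  comparator <- as_strategy_outcome(comparator)
  reference <- as_strategy_outcome(reference)
  dc <- comparator$discounted_cost - reference$discounted_cost
  de <- comparator$discounted_qaly - reference$discounted_qaly
  classification <- if (de == 0) {
    "equal_effect"
  } else if (de > 0 && dc <= 0) {
    "comparator_dominates"
  } else if (de < 0 && dc >= 0) {
    "comparator_dominated"
  } else {
    "icer_defined"
  }
  structure(
    list(
      comparator = comparator$name,
      reference = reference$name,
      delta_cost = dc,
      delta_effect = de,
      icer = if (classification == "equal_effect") NA_real_ else dc / de,
      classification = classification
    ),
    class = "cea_result"
  )
}

#' Net monetary benefit
#'
#' `NMB = wtp * discounted_qaly - discounted_cost`. The strategy with the
#' higher NMB at a given willingness-to-pay is preferred; for two
#' strategies with a positive incremental effect this is equivalent to
#' comparing the ICER to the threshold.
#'
#' @param outcome A [strategy_outcome()] or [run_cohort()] result.
#' @param wtp Willingness-to-pay threshold, dollars per QALY.
#' @return NMB in dollars.
#' @export
nmb <- function(outcome, wtp = 10888) {
  outcome <- as_strategy_outcome(outcome)
  if (wtp < 0) stop("`wtp` must be non-negative.", call. = FALSE)
  wtp * outcome$discounted_qaly - outcome$discounted_cost
}

#' Choose the preferred strategy at a threshold
#'
#' Picks the strategy with the higher net monetary benefit. An exact NMB
#' tie resolves to the cheaper strategy (conservative-spending
#' convention), and to the reference if costs also tie.
#'
#' @inheritParams icer
#' @inheritParams nmb
#' @return The preferred strategy's name.
#' @export
decide <- function(comparator, reference, wtp = 10888) {
  comparator <- as_strategy_outcome(comparator)
  reference <- as_strategy_outcome(reference)
  nmb_c <- nmb(comparator, wtp)
  nmb_r <- nmb(reference, wtp)
  if (nmb_c > nmb_r) return(comparator$name)
  if (nmb_c < nmb_r) return(reference$name)
  if (comparator$discounted_cost < reference$discounted_cost) comparator$name
  else reference$name
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("CEA: %s vs %s\n", x$comparator, x$reference))
  cat(sprintf("  delta cost $%.2f | delta effect %.3f QALY | %s",
              x$delta_cost, x$delta_effect, x$classification))
  if (x$classification == "icer_defined") {
    cat(sprintf(" | ICER $%.2f/QALY", x$icer))
  }
  cat("\n")
  invisible(x)
}

#' @rdname tidy.cohort_result
#' @export
tidy.cea_result <- function(x, ...) {
  tibble::tibble(
    comparator = x$comparator,
    reference = x$reference,
    delta_cost = x$delta_cost,
    delta_effect = x$delta_effect,
    icer = x$icer,
    classification = x$classification
  )
}
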