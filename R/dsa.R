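#' Default sensitivity-analysis parameter table
#'
#' Builds the parameter table driving the deterministic and probabilistic
#' sensitivity analyses. Transition probabilities and monthly costs range
#' over 50%-200% of their base value; utilities use explicit plausible
#' ranges; the discount rate varies from 0 up to its base and is held
#' `fixed` in the probabilistic analysis. Each row carries a `target`
#' path naming what it perturbs: `comparator.*` / `reference.*` fields of
#' the two [strategy_spec()]s, the shared utilities, or
#' `model.annual_discount`.
#'
#' @param strategies Named list with elements `comparator` and
#'   `reference`, each a [strategy_spec()].
#' @param model A [markov_spec()].
#' @param utility_pfs_range,utility_pd_range Length-2 plausible ranges for
#'   the utilities.
#' @return A tibble with columns `name`, `label`, `base`, `low`, `high`,
#'   `distribution`, `target`.
#' @export
#' @examples
#' strategies <- list(
#'   comparator = strategy_spec("two_three_month", 0.0118, 117.16),
#'   reference = strategy_spec("three_four_month", 0.0251, 78.10)
#' )
#' default_parameters(strategies)
default_parameters <- function(strategies,
                               model = markov_spec(),
                               utility_pfs_range = c(0.61, 0.91),
                               utility_pd_range = c(0.54, 0.82)) {
  comp <- strategies$comparator
  ref <- strategies$reference
  params <- tibble::tribble(
    ~name, ~label, ~base, ~low, ~high, ~distribution, ~target,
    "p_comparator", paste0("PFS to PD, ", comp$name),
      comp$monthly_prob, 0.5 * comp$monthly_prob, 2 * comp$monthly_prob,
      "beta", "comparator.monthly_prob",
    "p_reference", paste0("PFS to PD, ", ref$name),
      ref$monthly_prob, 0.5 * ref$monthly_prob, 2 * ref$monthly_prob,
      "beta", "reference.monthly_prob",
    "c_comparator", paste0("Monthly cost, ", comp$name),
      comp$monthly_cost, 0.5 * comp$monthly_cost, 2 * comp$monthly_cost,
      "gamma", "comparator.monthly_cost",
    "c_reference", paste0("Monthly cost, ", ref$name),
      ref$monthly_cost, 0.5 * ref$monthly_cost, 2 * ref$monthly_cost,
      "gamma", "reference.monthly_cost",
    "u_pfs", "Utility of PFS",
      comp$utility_pfs, utility_pfs_range[1], utility_pfs_range[2],
      "beta", "utility_pfs",
    "u_pd", "Utility of PD",
      comp$utility_pd, utility_pd_range[1], utility_pd_range[2],
      "beta", "utility_pd",
    "discount", "Annual discount rate",
      model$annual_discount, 0, model$annual_discount,
      "fixed", "model.annual_discount"
  )
  bad <- params$low > params$base | params$base > params$high
  if (any(bad)) {
    stop("Parameter ranges must satisfy low <= base <= high: ",
         paste(params$name[bad], collapse = ", "), call. = FALSE)
  }
  params
}

# Apply named overrides (target path -> value) to a model/strategies/wtp
# bundle. Unknown targets are a configuration error.
apply_overrides <- function(model, strategies, wtp, overrides) {
  for (target in names(overrides)) {
    value <- overrides[[target]]
    switch(target,
      comparator.monthly_prob = strategies$comparator$monthly_prob <- value,
      reference.monthly_prob = strategies$reference$monthly_prob <- value,
      comparator.monthly_cost = strategies$comparator$monthly_cost <- value,
      reference.monthly_cost = strategies$reference$monthly_cost <- value,
      utility_pfs = {
        strategies$comparator$utility_pfs <- value
        strategies$reference$utility_pfs <- value
      },
      utility_pd = {
        strategies$comparator$utility_pd <- value
        strategies$reference$utility_pd <- value
      },
      model.annual_discount = model$annual_discount <- value,
      wtp = wtp <- value,
      stop("Unknown parameter target: ", target, call. = FALSE)
    )
  }
  list(model = model, strategies = strategies, wtp = wtp)
}

# NMB of both strategies after applying overrides.
eval_nmb <- function(model, strategies, wtp, overrides = list()) {
  ctx <- apply_overrides(model, strategies, wtp, overrides)
  comp <- run_cohort(ctx$model, ctx$strategies$comparator)
  ref <- run_cohort(ctx$model, ctx$strategies$reference)
  c(comparator = nmb(comp, ctx$wtp), reference = nmb(ref, ctx$wtp))
}

#' One-way sensitivity analysis (tornado)
#'
#' Re-runs the model with each parameter at its low and high bound, all
#' others held at base, and records the target net monetary benefit. The
#' result is sorted by swing (the absolute NMB difference between the two
#' bounds), the ordering a tornado diagram displays.
#'
#' @param params Parameter table from [default_parameters()] (or a
#'   compatible tibble).
#' @param strategies Named list `comparator`/`reference` of
#'   [strategy_spec()]s.
#' @param model A [markov_spec()].
#' @param wtp Willingness-to-pay threshold, dollars per QALY.
#' @param nmb_target `"comparator"` tracks the comparator strategy's
#'   absolute NMB; `"incremental"` tracks the NMB difference
#'   comparator - reference.
#' @return A tibble of class `tornado` with columns `param`, `label`,
#'   `base`, `low`, `high`, `nmb_base`, `nmb_at_low`, `nmb_at_high`,
#'   `swing`, sorted by decreasing swing.
#' @export
one_way <- function(params, strategies, model = markov_spec(), wtp = 10888,
                    nmb_target = c("comparator", "incremental")) {
  nmb_target <- match.arg(nmb_target)
  pick <- function(x) {
    if (nmb_target == "comparator") x[["comparator"]]
    else x[["comparator"]] - x[["reference"]]
  }
  base_nmb <- pick(eval_nmb(model, strategies, wtp))
  rows <- purrr::pmap(params, function(name, label, base, low, high, target,
                                       ...) {
    at <- function(value) {
      pick(eval_nmb(model, strategies, wtp,
                    stats::setNames(list(value), target)))
    }
    lo <- at(low)
    hi <- at(high)
    tibble::tibble(
      param = name, label = label, base = base, low = low, high = high,
      nmb_base = base_nmb, nmb_at_low = lo, nmb_at_high = hi,
      swing = abs(hi - lo)
    )
  })
  out <- dplyr::arrange(purrr::list_rbind(rows), dplyr::desc(swing))
  class(out) <- c("tornado", class(out))
  out
}

#' Two-way sensitivity analysis
#'
#' Evaluates the NMB-preferred strategy over a Cartesian grid spanning
#' the ranges of two parameters, all others at base.
#'
#' @inheritParams one_way
#' @param param_a,param_b Names (from `params$name`) of the two
#'   parameters to cross; they must differ.
#' @param grid_points Number of grid points per axis (>= 2).
#' @return A tibble with columns `param_a`, `value_a`, `param_b`,
#'   `value_b`, `preferred`.
#' @export
two_way <- function(params, param_a, param_b, strategies,
                    model = markov_spec(), wtp = 10888, grid_points = 11L) {
  if (identical(param_a, param_b)) {
    stop("`param_a` and `param_b` must be different parameters.",
         call. = FALSE)
  }
  if (grid_points < 2) {
    stop("`grid_points` must be at least 2.", call. = FALSE)
  }
  row_a <- params[params$name == param_a, ]
  row_b <- params[params$name == param_b, ]
  if (nrow(row_a) != 1L || nrow(row_b) != 1L) {
    stop("Both parameters must appear exactly once in `params`.",
         call. = FALSE)
  }
  grid <- tidyr::expand_grid(
    value_a = seq(row_a$low, row_a$high, length.out = grid_points),
    value_b = seq(row_b$low, row_b$high, length.out = grid_points)
  )
  grid$preferred <- purrr::map2_chr(grid$value_a, grid$value_b, function(a, b) {
    ctx <- apply_overrides(model, strategies, wtp, stats::setNames(
      list(a, b), c(row_a$target, row_b$target)
    ))
    decide(run_cohort(ctx$model, ctx$strategies$comparator),
           run_cohort(ctx$model, ctx$strategies$reference), ctx$wtp)
  })
  tibble::tibble(param_a = param_a, param_b = param_b, grid)
}

#' Threshold analysis on one parameter
#'
#' Finds the parameter value(s) in `[low, high]` at which the preferred
#' strategy flips, i.e. where the incremental NMB
#' (comparator - reference) changes sign. The range is first scanned on a
#' fine grid to bracket sign changes; each bracket is then refined by
#' bisection (`stats::uniroot`) to `tol` times the range width. With no
#' sign change the result is `NA`; a non-monotone NMB difference yields
#' every crossing found, with a warning.
#'
#' @inheritParams one_way
#' @param param_name Name of the parameter to scan (use `"wtp"` with a
#'   `params` row targeting `wtp` to solve for the threshold ICER).
#' @param tol Relative bisection tolerance on the parameter range.
#' @param grid_n Scan resolution used to bracket roots.
#' @return Numeric vector of crossing values (`NA_real_` if none).
#' @export
threshold_analysis <- function(params, param_name, strategies,
                               model = markov_spec(), wtp = 10888,
                               tol = 1e-6, grid_n = 256L) {
  if (tol <= 0) stop("`tol` must be positive.", call. = FALSE)
  row <- params[params$name == param_name, ]
  if (nrow(row) != 1L) {
    stop("`param_name` must appear exactly once in `params`.", call. = FALSE)
  }
  g <- function(value) {
    x <- eval_nmb(model, strategies, wtp,
                  stats::setNames(list(value), row$target))
    x[["comparator"]] - x[["reference"]]
  }
  xs <- seq(row$low, row$high, length.out = grid_n)
  ys <- vapply(xs, g, numeric(1))
  flips <- which(ys[-1] * ys[-length(ys)] < 0)
  exact <- xs[ys == 0]
  if (!length(flips) && !length(exact)) {
    return(NA_real_)
  }
  roots <- vapply(flips, function(i) {
    stats::uniroot(g, lower = xs[i], upper = xs[i + 1],
                   tol = tol * (row$high - row$low))$root
  }, numeric(1))
  roots <- sort(unique(c(roots, exact)))
  if (length(roots) > 1L) {
    warning("NMB difference is non-monotone over the range; returning all ",
            length(roots), " crossings.", call. = FALSE)
  }
  roots
}
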