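#' Pool study-level proportions
#'
#' Inverse-variance pooling of 2-year recurrence-free survival proportions,
#' either fixed-effect or DerSimonian-Laird random-effects. On the raw
#' scale the within-study variance is the binomial `p(1-p)/n`; on the logit
#' scale it is `1/(n p (1-p))` and the estimate and 95% CI are
#' back-transformed. The random-effects estimate collapses to the
#' fixed-effect estimate whenever the DL between-study variance is zero.
#'
#' Studies with observed proportions of exactly 0 or 1 cannot be pooled on
#' the logit scale; a continuity correction `(x + 0.5)/(n + 1)` is applied
#' to those studies with a warning.
#'
#' @param studies A study table (see [generate_study_set()]); only
#'   `n_patients` and `rfs_24mo` are used, so pass one group at a time.
#' @param method `"random_DL"` (default) or `"fixed"`.
#' @param scale `"raw"` (default) or `"logit"`.
#' @param conf_mult Normal CI multiplier; 1.96 for a 95% interval.
#'
#' @return An object of class `pooled_proportion`: a list with `estimate`,
#'   `ci_low`, `ci_high`, `se`, `q_stat`, `df`, `p_het`, `i2`, `tau2`,
#'   `method`, `scale`, `k`, `n_patients`.
#' @seealso [heterogeneity()]
#' @export
#' @examples
#' studies <- emulate_paper_cohort(seed = 1)
#' pool_proportions(dplyr::filter(studies, group == "two_three_month"))
pool_proportions <- function(studies,
                             method = c("random_DL", "fixed"),
                             scale = c("raw", "logit"),
                             conf_mult = 1.96) {
  method <- match.arg(method)
  scale <- match.arg(scale)
  if (is.null(studies) || nrow(studies) == 0L) {
    stop("At least one study is required.", call. = FALSE)
  }
  p <- studies$rfs_24mo
  n <- studies$n_patients
  if (scale == "logit" && any(p <= 0 | p >= 1)) {
    degenerate <- p <= 0 | p >= 1
    warning(sum(degenerate), " study proportion(s) at 0 or 1; applying ",
            "continuity correction (x + 0.5)/(n + 1) for logit pooling.",
            call. = FALSE)
    x <- round(p * n)
    p[degenerate] <- (x[degenerate] + 0.5) / (n[degenerate] + 1)
  }

  if (scale == "raw") {
    y <- p
    v <- p * (1 - p) / n
  } else {
    y <- stats::qlogis(p)
    v <- 1 / (n * p * (1 - p))
  }

  het <- dl_heterogeneity(y, v)
  w <- if (method == "random_DL") 1 / (v + het$tau2) else 1 / v
  est <- sum(w * y) / sum(w)
  se <- sqrt(1 / sum(w))
  lo <- est - conf_mult * se
  hi <- est + conf_mult * se
  if (scale == "logit") {
    est <- stats::plogis(est)
    lo <- stats::plogis(lo)
    hi <- stats::plogis(hi)
  }

  structure(
    c(list(estimate = est, ci_low = lo, ci_high = hi, se = se),
      het,
      list(method = method, scale = scale,
           k = length(y), n_patients = sum(n))),
    class = "pooled_proportion"
  )
}

#' Heterogeneity statistics for a set of studies
#'
#' Cochran's Q with fixed-effect inverse-variance weights, its chi-square
#' p-value on k - 1 degrees of freedom, Higgins' I-squared
#' `max(0, (Q - df)/Q)`, and the DerSimonian-Laird between-study variance
#' `tau2 = max(0, (Q - df) / (sum(w) - sum(w^2)/sum(w)))`. A single study
#' gives Q = 0, df = 0, I2 = 0, tau2 = 0 and a p-value reported as 1.
#'
#' @inheritParams pool_proportions
#' @return A tibble with columns `q_stat`, `df`, `p_het`, `i2`, `tau2`.
#' @export
heterogeneity <- function(studies, scale = c("raw", "logit")) {
  scale <- match.arg(scale)
  if (is.null(studies) || nrow(studies) == 0L) {
    stop("At least one study is required.", call. = FALSE)
  }
  p <- studies$rfs_24mo
  n <- studies$n_patients
  if (scale == "raw") {
    y <- p
    v <- p * (1 - p) / n
  } else {
    y <- stats::qlogis(p)
    v <- 1 / (n * p * (1 - p))
  }
  tibble::as_tibble(dl_heterogeneity(y, v))
}

# Q, I2 and DL tau2 from effect estimates y with within-study variances v.
dl_heterogeneity <- function(y, v) {
  k <- length(y)
  if (k == 1L) {
    return(list(q_stat = 0, df = 0L, p_het = 1, i2 = 0, tau2 = 0))
  }
  w <- 1 / v
  mu <- sum(w * y) / sum(w)
  q <- sum(w * (y - mu)^2)
  df <- k - 1L
  p_het <- stats::pchisq(q, df, lower.tail = FALSE)
  i2 <- if (q > 0) max(0, (q - df) / q) else 0
  tau2 <- max(0, (q - df) / (sum(w) - sum(w^2) / sum(w)))
  list(q_stat = q, df = df, p_het = p_het, i2 = i2, tau2 = tau2)
}

#' @export
print.pooled_proportion <- function(x, ...) {
  cat(sprintf(
    "Pooled proportion (%s, %s scale): %.3f (95%% CI %.3f-%.3f)\n",
    x$method, x$scale, x$estimate, x$ci_low, x$ci_high
  ))
  cat(sprintf(
    "  k = %d studies, %d patients; Q = %.3f (df = %d, p = %.3f), I2 = %.1f%%, tau2 = %.5f\n",
    x$k, x$n_patients, x$q_stat, x$df, x$p_het, 100 * x$i2, x$tau2
  ))
  invisible(x)
}

#' Tidy a pooled proportion
#'
#' @param x A `pooled_proportion`.
#' @param ... Unused.
#' @return `tidy()` gives a one-row tibble with the estimate and interval;
#'   `glance()` gives the heterogeneity statistics.
#' @export
tidy.pooled_proportion <- function(x, ...) {
  tibble::tibble(
    estimate = x$estimate,
    ci_low = x$ci_low,
    ci_high = x$ci_high,
    method = x$method,
    scale = x$scale,
    k = x$k,
    n_patients = x$n_patients
  )
}

#' @rdname tidy.pooled_proportion
#' @export
glance.pooled_proportion <- function(x, ...) {
  tibble::tibble(
    q_stat = x$q_stat, df = x$df, p_het = x$p_het,
    i2 = x$i2, tau2 = x$tau2
  )
}
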