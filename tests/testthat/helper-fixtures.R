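# Base-case strategies: monthly transition probabilities 1.18% / 2.51%,
# monthly follow-up costs $117.16 / $78.10, PFS utility 0.76.
base_strategies <- function() {
  list(
    comparator = strategy_spec("two_three_month", 0.0118, 117.16),
    reference = strategy_spec("three_four_month", 0.0251, 78.10)
  )
}

# Tiny study table from explicit proportions and sizes.
toy_studies <- function(p, n, group = "two_three_month") {
  tibble::tibble(
    study_id = sprintf("s%02d", seq_along(p)),
    group = group,
    n_patients = as.integer(n),
    rfs_24mo = p,
    design = "RCT"
  )
}

# Lightweight configuration for end-to-end pipeline tests.
light_config <- function(...) {
  cfg <- default_config(...)
  cfg$psa$n_draws <- 400L
  cfg$psa$wtp_grid <- seq(0, 20000, by = 2000)
  cfg$dsa$grid_points <- 4L
  cfg
}
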