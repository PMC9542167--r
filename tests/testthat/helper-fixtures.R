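# Shared fixtures, all generated in code.

# The fictitious binary trial with a common stratum OR of 0.50 for A and no
# interaction on the log-odds scale.
table2_cells <- function() cell_params(0.50, 0.333, 0.091, 0.048)

# Continuous cells with exact means per cell, zero residual noise.
noiseless_cells <- function(means = c(0, 1, 2, 3)) {
  cell_params(means[1], means[2], means[3], means[4],
              outcome_type = "continuous", sigma = 0)
}

# Balanced noiseless dataset: per_cell records in each cell, y = cell mean.
noiseless_trial <- function(means = c(0, 1, 2, 3), per_cell = 5) {
  grid <- expand.grid(z_a = c(0, 1), z_b = c(0, 1))
  z_a <- rep(grid$z_a, each = per_cell)
  z_b <- rep(grid$z_b, each = per_cell)
  mu <- c(`00` = means[1], `10` = means[2], `01` = means[3], `11` = means[4])
  y <- mu[paste0(z_a, z_b)]
  trial_data(z_a, z_b, unname(y), outcome_type = "continuous")
}

# Binary cells equal to `base` in the B = 0 stratum, with the B = 1 stratum's
# p11 moved so the log-OR interaction equals `delta`.
cells_with_logor_interaction <- function(delta, base = table2_cells()) {
  lor0 <- log(conditional_effect(base, 0, "odds_ratio"))
  odds11 <- (base$p01 / (1 - base$p01)) * exp(lor0 + delta)
  cell_params(base$p00, base$p10, base$p01, odds11 / (1 + odds11))
}

# A qualitative interaction: A harmful without B, beneficial with B.
qualitative_interaction_cells <- function() {
  cell_params(0.20, 0.45, 0.30, 0.22)
}

random_binary_dataset <- function(n = 120) {
  cells <- cell_params(stats::runif(1, 0.2, 0.8), stats::runif(1, 0.2, 0.8),
                       stats::runif(1, 0.2, 0.8), stats::runif(1, 0.2, 0.8))
  z_a <- stats::rbinom(n, 1, 0.5)
  z_b <- stats::rbinom(n, 1, 0.5)
  p <- mapply(function(a, b) cells[[paste0("p", a, b)]], z_a, z_b)
  trial_data(z_a, z_b, stats::rbinom(n, 1, p), "binary")
}

random_continuous_dataset <- function(n = 120) {
  z_a <- stats::rbinom(n, 1, 0.5)
  z_b <- stats::rbinom(n, 1, 0.5)
  mu <- stats::rnorm(4, 0, 2)
  idx <- 1 + z_a + 2 * z_b
  trial_data(z_a, z_b, stats::rnorm(n, mu[idx], 1), "continuous")
}

# Force all four cells non-empty (regenerate until valid).
random_dataset_four_cells <- function(outcome = c("binary", "continuous"),
                                      n = 120) {
  outcome <- match.arg(outcome)
  repeat {
    d <- if (outcome == "binary") random_binary_dataset(n)
         else random_continuous_dataset(n)
    counts <- cross_tabulate(d)
    if (all(counts$n > 0) &&
        (outcome == "continuous" ||
         all(counts$events > 0 & counts$events < counts$n)))
      return(d)
  }
}
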