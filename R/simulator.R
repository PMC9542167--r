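#' Configuration for a simulated 2x2 factorial trial
#'
#' Defines a potential-outcomes data-generating mechanism: the four cell
#' parameters, the sample size, the allocation probabilities for the two
#' independent Bernoulli randomizations, a mandatory seed (no implicit
#' global randomness), and optionally a usual-practice assignment mechanism
#' for treatment B and/or a treatment-discontinuation (intercurrent event)
#' mechanism.
#'
#' @param cells a [cell_params] object.
#' @param n total sample size (>= 4).
#' @param seed integer seed; every simulated trial is reproducible from its
#'   config.
#' @param alloc_a,alloc_b probability of assignment to A and to B
#'   (independent randomizations; defaults 0.5 each).
#' @param usual_practice optional list
#'   `list(pi_b_given_a0 =, pi_b_given_a1 =)`: probabilities of receiving B
#'   under usual practice in each A arm.  When the two differ, receipt of B
#'   depends on A and the conditional usual-practice estimand is undefined.
#' @param intercurrent optional list
#'   `list(disc_prob_by_cell = c(p00, p10, p01, p11), outcome_shift_on_disc =)`:
#'   per-cell probability of treatment discontinuation; discontinued
#'   participants have their outcome drawn from the cell parameter shifted
#'   by `outcome_shift_on_disc` (probabilities clipped to \[0.01, 0.99\]).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(cells, n, seed, alloc_a = 0.5, alloc_b = 0.5,
                              usual_practice = NULL, intercurrent = NULL) {
  stopifnot(inherits(cells, "cell_params"))
  if (!is.numeric(n) || n < 4) stop("n must be >= 4")
  if (missing(seed) || is.null(seed) || !is.numeric(seed))
    stop("seed is mandatory (integer)")
  check_prob(alloc_a, "alloc_a"); check_prob(alloc_b, "alloc_b")
  if (!is.null(usual_practice)) {
    if (!all(c("pi_b_given_a0", "pi_b_given_a1") %in% names(usual_practice)))
      stop("usual_practice needs pi_b_given_a0 and pi_b_given_a1")
    check_prob(usual_practice$pi_b_given_a0, "pi_b_given_a0")
    check_prob(usual_practice$pi_b_given_a1, "pi_b_given_a1")
  }
  if (!is.null(intercurrent)) {
    if (length(intercurrent$disc_prob_by_cell) != 4)
      stop("intercurrent$disc_prob_by_cell must hold four probabilities ",
           "(cells (0,0), (1,0), (0,1), (1,1))")
    for (p in intercurrent$disc_prob_by_cell) check_prob(p, "disc_prob")
    if (is.null(intercurrent$outcome_shift_on_disc))
      intercurrent$outcome_shift_on_disc <- 0
  }
  structure(list(cells = cells, n = as.integer(n), seed = as.integer(seed),
                 alloc_a = alloc_a, alloc_b = alloc_b,
                 usual_practice = usual_practice, intercurrent = intercurrent),
            class = "simulation_config")
}

#' Read a simulation config from JSON or YAML
#' @param path config file; keys as in [simulation_config()], with the cell
#'   parameters nested under `cells`.
#' @return A `simulation_config`.
#' @export
simulation_config_from_file <- function(path) {
  cfg <- read_config_file(path)
  cells <- cell_params(cfg$cells$p00, cfg$cells$p10, cfg$cells$p01,
                       cfg$cells$p11, cfg$cells$outcome_type,
                       sigma = cfg$cells$sigma)
  simulation_config(cells, n = cfg$n, seed = cfg$seed,
                    alloc_a = if (is.null(cfg$alloc_a)) 0.5 else cfg$alloc_a,
                    alloc_b = if (is.null(cfg$alloc_b)) 0.5 else cfg$alloc_b,
                    usual_practice = cfg$usual_practice,
                    intercurrent = cfg$intercurrent)
}

# Draw outcomes given realized (z_a, z_b), from cell parameters.
#' @noRd
draw_outcomes <- function(cells, z_a, z_b, shift = 0) {
  mu <- mapply(function(a, b) cell_mean(cells, a, b), z_a, z_b)
  if (cells$outcome_type == "binary") {
    p <- pmin(pmax(mu + shift, 0.01), 0.99)
    if (all(shift == 0)) p <- mu   # untouched parameters stay exact
    stats::rbinom(length(mu), 1, p)
  } else {
    stats::rnorm(length(mu), mu + shift, cells$sigma)
  }
}

# Truth map: oracle value of every defined target x measure combination.
#' @noRd
truth_map <- function(cells, pi_up, pi0 = pi_up, pi1 = pi_up) {
  measures <- if (cells$outcome_type == "binary")
    c("risk_difference", "risk_ratio", "odds_ratio") else "mean_difference"
  rows <- list()
  for (m in measures) {
    for (tg in TARGETS) {
      if (tg == "A_USUAL_PRACTICE") {
        marg <- up_marginal_effect(cells, pi0, pi1, m)
        e0 <- to_link_scale(conditional_effect(cells, 0, m), m)
        e1 <- to_link_scale(conditional_effect(cells, 1, m), m)
        cond_def <- (abs(pi0 - pi1) < 1e-12) && (abs(e1 - e0) <= 1e-8)
        rows[[length(rows) + 1L]] <- data.frame(
          target = tg, measure = m, up_scale = "marginal",
          truth = marg, defined = TRUE)
        rows[[length(rows) + 1L]] <- data.frame(
          target = tg, measure = m, up_scale = "conditional",
          truth = if (cond_def) from_link_scale(e0, m) else NA_real_,
          defined = cond_def)
      } else {
        spec <- estimand_spec(tg, m, pi = NULL)
        rows[[length(rows) + 1L]] <- data.frame(
          target = tg, measure = m, up_scale = NA_character_,
          truth = true_estimand_value(cells, spec), defined = TRUE)
      }
    }
  }
  do.call(rbind, rows)
}

#' @noRd
new_simulated_trial <- function(data, truth, config) {
  structure(list(data = data, truth = truth, config = config),
            class = "simulated_trial")
}

#' @export
print.simulated_trial <- function(x, ...) {
  cat(sprintf("Simulated 2x2 trial (seed %d):\n", x$config$seed))
  print(x$data)
  invisible(x)
}

#' Simulate a 2x2 factorial randomized trial
#'
#' Each participant is independently randomized: `Z_A ~ Bernoulli(alloc_a)`,
#' `Z_B ~ Bernoulli(alloc_b)`; the outcome is then drawn from the assigned
#' cell's distribution (`Bernoulli(p_ab)` or `Normal(mu_ab, sigma)`).  The
#' returned object carries the dataset, the config, and the oracle truth map
#' (every estimand x measure, with the usual-practice values evaluated at
#' `pi = alloc_b`).  Any intercurrent-event mechanism in the config is *not*
#' applied here; pass the result through [apply_intercurrent_events()].
#'
#' @param config a [simulation_config()] without a `usual_practice` block.
#' @return A `simulated_trial`: list with `data` ([trial_data]), `truth`
#'   (data.frame of oracle values) and `config`.
#' @export
simulate_factorial <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$usual_practice))
    stop("config has a usual_practice block; use simulate_usual_practice()")
  with_seed(config$seed, {
    z_a <- stats::rbinom(config$n, 1, config$alloc_a)
    z_b <- stats::rbinom(config$n, 1, config$alloc_b)
    y <- draw_outcomes(config$cells, z_a, z_b)
    data <- trial_data(z_a, z_b, y, config$cells$outcome_type)
    new_simulated_trial(data, truth_map(config$cells, config$alloc_b), config)
  })
}

#' Simulate a cohort with usual-practice assignment of treatment B
#'
#' Treatment A is randomized (`Z_A ~ Bernoulli(alloc_a)`) but treatment B is
#' received according to usual practice: `Z_B ~ Bernoulli(pi_b_given_a)`
#' with the probability depending on the realized A arm.  When
#' `pi_b_given_a0 != pi_b_given_a1`, receipt of B depends on A and the truth
#' map marks the conditional usual-practice estimand undefined.
#'
#' @param config a [simulation_config()] with a `usual_practice` block.
#' @return A `simulated_trial`.
#' @export
simulate_usual_practice <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  up <- config$usual_practice
  if (is.null(up))
    stop("config lacks a usual_practice block; use simulate_factorial()")
  with_seed(config$seed, {
    z_a <- stats::rbinom(config$n, 1, config$alloc_a)
    pi_b <- ifelse(z_a == 1, up$pi_b_given_a1, up$pi_b_given_a0)
    z_b <- stats::rbinom(config$n, 1, pi_b)
    y <- draw_outcomes(config$cells, z_a, z_b)
    data <- trial_data(z_a, z_b, y, config$cells$outcome_type)
    pi_marg <- config$alloc_a * up$pi_b_given_a1 +
      (1 - config$alloc_a) * up$pi_b_given_a0
    new_simulated_trial(
      data, truth_map(config$cells, pi_marg,
                      pi0 = up$pi_b_given_a0, pi1 = up$pi_b_given_a1),
      config)
  })
}

#' Apply a treatment-discontinuation mechanism to a simulated trial
#'
#' Draws a per-participant discontinuation indicator from the cell-specific
#' probability; discontinued participants have their outcome redrawn from
#' the cell parameter shifted by `outcome_shift_on_disc` (binary
#' probabilities clipped to \[0.01, 0.99\]).  Treatment labels are left
#' as-randomized, so downstream analyses of the returned data implement a
#' treatment-policy strategy: the intercurrent event is part of the
#' treatment condition being compared.
#'
#' Discontinuation draws use their own seeded stream (derived from the
#' config seed), so the operation is reproducible and independent of the
#' global RNG state.
#'
#' @param trial a `simulated_trial` whose config has an `intercurrent` block.
#' @return A `simulated_trial` with (possibly) modified outcomes; the
#'   logical discontinuation indicator is attached to the data as attribute
#'   `"discontinued"`.
#' @export
apply_intercurrent_events <- function(trial) {
  stopifnot(inherits(trial, "simulated_trial"))
  ic <- trial$config$intercurrent
  if (is.null(ic)) stop("config lacks an intercurrent block")
  data <- trial$data
  cells <- trial$config$cells
  cell_idx <- 1L + data$z_a + 2L * data$z_b  # (0,0),(1,0),(0,1),(1,1)
  disc_p <- ic$disc_prob_by_cell[cell_idx]
  out <- with_seed(trial$config$seed + 500009L, {
    disc <- stats::rbinom(nrow(data), 1, disc_p) == 1
    if (any(disc)) {
      y_new <- draw_outcomes(cells, data$z_a[disc], data$z_b[disc],
                             shift = ic$outcome_shift_on_disc)
      data$y[disc] <- y_new
      data <- trial_data(data$z_a, data$z_b, data$y,
                         cells$outcome_type, id = data$id)
    }
    attr(data, "discontinued") <- disc
    data
  })
  new_simulated_trial(out, trial$truth, trial$config)
}
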