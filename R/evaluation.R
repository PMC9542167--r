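#' Monte-Carlo evaluation of factorial-trial estimators
#'
#' Repeatedly simulates trials from `config`, estimates every requested
#' (estimand, strategy) pair on each replicate, and summarizes bias,
#' empirical SE, mean model-based SE and confidence-interval coverage
#' against the closed-form oracle truth.  Replicate `r` uses seed
#' `base_seed + r`, so studies are reproducible and replicates independent.
#'
#' Bias and coverage are assessed on the link scale (log odds ratio etc.),
#' where the estimators are asymptotically normal.  The interaction test's
#' rejection rate at the 5% level is reported alongside.  Replicates whose
#' fit fails (e.g. separation at small n) are excluded and counted; more
#' than 5% failures aborts the study.
#'
#' @param config a [simulation_config()]; a `usual_practice` block routes to
#'   [simulate_usual_practice()], otherwise [simulate_factorial()] is used,
#'   and an `intercurrent` block is applied via
#'   [apply_intercurrent_events()].
#' @param specs list of [estimand_spec] objects.
#' @param strategies character vector drawn from `"factorial"`,
#'   `"multiarm"`, `"two_stage"`; recycled over `specs` pairs (full grid).
#' @param n_reps number of replicates (>= 2).
#' @param base_seed integer base seed.
#' @param level confidence level for coverage.
#' @param truth optional numeric vector (link scale), one entry per spec,
#'   overriding the oracle truth — used when the estimand's target
#'   population differs from the simulated design (e.g. usual-practice
#'   truth with A-dependent B receipt evaluated against factorial data).
#' @param alpha significance level for the two-stage pre-test.
#' @return A `simulation_summary` data.frame: one row per (spec, strategy)
#'   with columns `target`, `measure`, `strategy`, `n_reps`, `n_failed`,
#'   `truth` (link scale), `mean_estimate`, `bias`, `mc_error_bias`
#'   (`empirical_se / sqrt(n_reps)`), `empirical_se`, `mean_model_se`,
#'   `coverage`, `rejection_rate`.
#' @export
run_simulation_study <- function(config, specs, strategies, n_reps,
                                 base_seed, level = 0.95, truth = NULL,
                                 alpha = 0.05) {
  stopifnot(inherits(config, "simulation_config"), n_reps >= 2)
  if (inherits(specs, "estimand_spec")) specs <- list(specs)
  strategies <- match.arg(strategies,
                          c("factorial", "multiarm", "two_stage"),
                          several.ok = TRUE)
  if (!is.null(truth) && length(truth) != length(specs))
    stop("truth override must have one value per spec")

  truths <- vapply(seq_along(specs), function(i) {
    if (!is.null(truth)) return(truth[i])
    to_link_scale(true_estimand_value(config$cells, specs[[i]]),
                  specs[[i]]$measure)
  }, numeric(1))

  grid <- expand.grid(spec = seq_along(specs), strategy = strategies,
                      stringsAsFactors = FALSE)
  est <- array(NA_real_, dim = c(n_reps, nrow(grid)))
  se <- array(NA_real_, dim = c(n_reps, nrow(grid)))
  cover <- array(NA, dim = c(n_reps, nrow(grid)))
  int_reject <- rep(NA, n_reps)
  failed <- logical(n_reps)

  simulate_one <- function(seed) {
    cfg <- config; cfg$seed <- seed
    tr <- if (is.null(cfg$usual_practice)) simulate_factorial(cfg)
          else simulate_usual_practice(cfg)
    if (!is.null(cfg$intercurrent)) tr <- apply_intercurrent_events(tr)
    tr
  }

  for (r in seq_len(n_reps)) {
    trial <- simulate_one(base_seed + r)
    ok <- tryCatch({
      ia <- interaction_assessment(trial$data, specs[[1]]$measure, level)
      int_reject[r] <- ia$p_value < alpha
      for (g in seq_len(nrow(grid))) {
        sp <- specs[[grid$spec[g]]]
        e <- switch(grid$strategy[g],
          factorial = estimate_estimand(trial$data, sp, "factorial", level),
          multiarm  = estimate_estimand(trial$data, sp, "multiarm", level),
          two_stage = two_stage_estimator(trial$data, sp, alpha, level))
        est[r, g] <- e$estimate_link
        se[r, g] <- e$se_link
        tt <- truths[grid$spec[g]]
        # epsilon keeps zero-width CIs from degenerate noiseless fits from
        # missing the truth through rounding error alone
        eps <- 1e-8 * max(1, abs(tt))
        cover[r, g] <- (e$ci_low - eps <= tt) && (tt <= e$ci_high + eps)
      }
      TRUE
    }, error = function(err) FALSE)
    failed[r] <- !ok
  }

  n_fail <- sum(failed)
  if (n_fail / n_reps > 0.05)
    stop(sprintf("%d of %d replicates failed to fit (> 5%%)", n_fail, n_reps))
  keep <- !failed
  out <- lapply(seq_len(nrow(grid)), function(g) {
    sp <- specs[[grid$spec[g]]]
    e <- est[keep, g]; s <- se[keep, g]
    emp_se <- stats::sd(e)
    data.frame(target = sp$target, measure = sp$measure,
               strategy = grid$strategy[g],
               n_reps = sum(keep), n_failed = n_fail,
               truth = truths[grid$spec[g]],
               mean_estimate = mean(e),
               bias = mean(e) - truths[grid$spec[g]],
               mc_error_bias = emp_se / sqrt(sum(keep)),
               empirical_se = emp_se,
               mean_model_se = mean(s),
               coverage = mean(cover[keep, g]),
               rejection_rate = mean(int_reject[keep]),
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, out),
            class = c("simulation_summary", "data.frame"),
            level = level, base_seed = base_seed)
}

#' @export
print.simulation_summary <- function(x, digits = 4, ...) {
  cat(sprintf("Simulation study: %d replicates (base seed %d), %d failed\n",
              x$n_reps[1] + x$n_failed[1], attr(x, "base_seed"),
              x$n_failed[1]))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a simulation summary to CSV and JSON
#' @param summary a `simulation_summary`.
#' @param path_csv,path_json output paths (either may be `NULL` to skip).
#' @return The summary, invisibly.
#' @export
write_simulation_summary <- function(summary, path_csv = NULL,
                                     path_json = NULL) {
  stopifnot(inherits(summary, "simulation_summary"))
  if (!is.null(path_csv))
    utils::write.csv(as.data.frame(summary), path_csv, row.names = FALSE)
  if (!is.null(path_json))
    jsonlite::write_json(as.data.frame(summary), path_json,
                         dataframe = "rows", digits = NA, auto_unbox = TRUE)
  invisible(summary)
}

#' Two-stage (interaction pre-test) estimator — a negative control
#'
#' Pre-tests the interaction at level `alpha`; if non-significant returns
#' the factorial estimate, otherwise the multiarm estimate.  This data-
#' driven model selection distorts the sampling distribution of the chosen
#' estimator, and its confidence intervals under-cover under moderate
#' interactions; it is implemented here only so the distortion can be
#' demonstrated, not as a recommended analysis.
#'
#' @param data a [trial_data] object with all four cells non-empty.
#' @param spec an [estimand_spec].
#' @param alpha pre-test significance level.
#' @param level confidence level of the returned interval.
#' @return An `effect_estimate` with strategy `"two_stage"`; the branch
#'   taken is recorded in the `note` field.
#' @export
two_stage_estimator <- function(data, spec, alpha = 0.05, level = 0.95) {
  ia <- interaction_assessment(data, spec$measure, level)
  branch <- if (ia$p_value >= alpha) "factorial" else "multiarm"
  out <- estimate_estimand(data, spec, branch, level)
  out$strategy <- "two_stage"
  out$note <- sprintf(
    "interaction pre-test p = %.4g (alpha = %g): %s branch taken",
    ia$p_value, alpha, branch)
  out
}
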