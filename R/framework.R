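#' Run the four-step estimand framework on a factorial trial dataset
#'
#' Executes, for a declared set of estimands (exactly one flagged primary):
#'
#' 1. records the estimand declarations, including any free-text
#'    intercurrent-event strategy labels (metadata only — computation always
#'    analyses outcomes as-randomized, i.e. treatment policy);
#' 2. estimates each estimand with the adjusted factorial estimator
#'    (the primary analysis strategy);
#' 3. assesses the interaction: estimate, confidence interval, p-value, and
#'    a CI-spread diagnostic (the ratio of the natural-scale CI limits for
#'    ratio measures, their difference for difference measures);
#' 4. re-estimates each estimand with the matching multiarm (or weighted
#'    multiarm) estimator as sensitivity analysis, and classifies
#'    concordance between the two.
#'
#' The concordance rule is a documented convention of this package:
#' `consistent` when each point estimate lies inside the other analysis's
#' confidence interval (link scale); `discordant` when the two point
#' estimates fall on opposite sides of the null; `indeterminate` otherwise.
#' The rule is symmetric in which analysis is labelled primary.
#'
#' All numbers are produced by the estimators module; the framework only
#' orchestrates.
#'
#' @param data a [trial_data] object.
#' @param specs a list of [estimand_spec] objects, exactly one with
#'   `primary = TRUE` (a single spec is taken as primary).
#' @param level confidence level.
#' @return A `framework_report`: list with `estimand_declarations`,
#'   `results` (per spec: `spec`, `primary_result`, `sensitivity_result`,
#'   `concordance`, `concordance_trace`), `primary_result`,
#'   `sensitivity_result` and `concordance` for the primary spec, and
#'   `interaction_result` (with `ci_spread` and `ci_spread_type` fields).
#' @examples
#' cells <- cell_params(0, 1, 2, 3, outcome_type = "continuous", sigma = 0.5)
#' trial <- simulate_factorial(simulation_config(cells, n = 800, seed = 11))
#' rep <- run_framework(trial$data,
#'                      list(estimand_spec("A_GIVEN_NO_B", "mean_difference",
#'                                         primary = TRUE)))
#' rep
#' @export
run_framework <- function(data, specs, level = 0.95) {
  stopifnot(inherits(data, "trial_data"))
  if (nrow(data) == 0) stop("empty dataset")
  if (inherits(specs, "estimand_spec")) specs <- list(specs)
  if (!length(specs)) stop("at least one estimand_spec is required")
  for (s in specs) stopifnot(inherits(s, "estimand_spec"))
  n_primary <- sum(vapply(specs, function(s) isTRUE(s$primary), logical(1)))
  if (length(specs) == 1L && n_primary == 0L) {
    specs[[1]]$primary <- TRUE
    n_primary <- 1L
  }
  if (n_primary != 1L)
    stop("exactly one estimand_spec must be flagged primary")
  primary_idx <- which(vapply(specs, function(s) isTRUE(s$primary),
                              logical(1)))

  measure <- specs[[primary_idx]]$measure
  interaction <- interaction_assessment(data, measure, level)
  if (interaction$link == "identity") {
    interaction$ci_spread <- interaction$ci_high_natural -
      interaction$ci_low_natural
    interaction$ci_spread_type <- "difference of CI limits"
  } else {
    interaction$ci_spread <- interaction$ci_high_natural /
      interaction$ci_low_natural
    interaction$ci_spread_type <- "ratio of CI limits"
  }

  results <- lapply(specs, function(sp) {
    prim <- estimate_estimand(data, sp, "factorial", level)
    sens <- estimate_estimand(data, sp, "multiarm", level)
    conc <- classify_concordance(prim, sens)
    list(spec = sp, primary_result = prim, sensitivity_result = sens,
         concordance = conc$class, concordance_trace = conc$trace)
  })

  structure(list(
    estimand_declarations = specs,
    results = results,
    primary_result = results[[primary_idx]]$primary_result,
    sensitivity_result = results[[primary_idx]]$sensitivity_result,
    concordance = results[[primary_idx]]$concordance,
    interaction_result = interaction,
    level = level,
    n = nrow(data)), class = "framework_report")
}

# Mutual-CI-containment concordance rule; symmetric by construction.  The
# small epsilon keeps zero-width CIs from degenerate (noiseless) fits from
# failing containment through rounding error alone.
#' @noRd
classify_concordance <- function(a, b) {
  eps <- 1e-8 * max(1, abs(a$estimate_link), abs(b$estimate_link))
  within_ab <- b$ci_low - eps <= a$estimate_link &&
    a$estimate_link <= b$ci_high + eps
  within_ba <- a$ci_low - eps <= b$estimate_link &&
    b$estimate_link <= a$ci_high + eps
  if (within_ab && within_ba) {
    list(class = "consistent",
         trace = "each point estimate lies inside the other analysis's CI")
  } else if (sign(a$estimate_link) * sign(b$estimate_link) < 0) {
    list(class = "discordant",
         trace = "point estimates fall on opposite sides of the null")
  } else {
    list(class = "indeterminate",
         trace = paste("point estimates agree in direction but at least one",
                       "falls outside the other analysis's CI"))
  }
}

#' @export
print.framework_report <- function(x, ...) {
  cat(render_report(x, "text"))
  invisible(x)
}

#' Render a framework report as JSON or text
#'
#' The text format prints an estimand-by-estimator table (primary row before
#' sensitivity row for each estimand, primary estimand first) with
#' natural-scale estimates and confidence intervals to two decimals, then
#' the interaction assessment and concordance.  The JSON format is lossless:
#' [parse_framework_report()] reconstructs an equal report object.
#'
#' @param report a `framework_report`.
#' @param format `"json"` or `"text"`.
#' @return A single string.
#' @export
render_report <- function(report, format = c("json", "text")) {
  stopifnot(inherits(report, "framework_report"))
  format <- match.arg(format)
  if (format == "json") {
    l <- list(
      level = report$level, n = report$n,
      estimand_declarations = lapply(report$estimand_declarations, function(s)
        s[c("target", "measure", "pi", "up_scale", "primary", "ie_strategy")]),
      results = lapply(report$results, function(r) list(
        spec = r$spec[c("target", "measure", "pi", "up_scale", "primary",
                        "ie_strategy")],
        primary_result = effect_estimate_to_list(r$primary_result),
        sensitivity_result = effect_estimate_to_list(r$sensitivity_result),
        concordance = r$concordance,
        concordance_trace = r$concordance_trace)),
      interaction_result = c(
        effect_estimate_to_list(report$interaction_result),
        list(ci_spread = report$interaction_result$ci_spread,
             ci_spread_type = report$interaction_result$ci_spread_type)))
    as.character(jsonlite::toJSON(l, digits = NA, auto_unbox = TRUE,
                                  null = "null"))
  } else {
    render_report_text(report)
  }
}

#' @noRd
render_report_text <- function(report) {
  fmt <- function(e) sprintf("%.2f (%.2f, %.2f)", e$estimate_natural,
                             e$ci_low_natural, e$ci_high_natural)
  ord <- order(!vapply(report$results, function(r) isTRUE(r$spec$primary),
                       logical(1)))
  lines <- c(
    sprintf("Estimand framework report (n = %d, %.0f%% CI)", report$n,
            100 * report$level),
    "",
    sprintf("%-28s %-24s %-22s %s", "Estimand", "Estimator", "Estimate (CI)",
            "Concordance"))
  for (r in report$results[ord]) {
    lab <- paste0(r$spec$target, if (isTRUE(r$spec$primary)) " [primary]")
    lines <- c(lines,
      sprintf("%-28s %-24s %-22s %s", lab, "primary (factorial)",
              fmt(r$primary_result), r$concordance),
      sprintf("%-28s %-24s %-22s", "",
              paste0("sensitivity (", r$sensitivity_result$strategy, ")"),
              fmt(r$sensitivity_result)))
  }
  ia <- report$interaction_result
  lines <- c(lines, "",
    sprintf("Interaction (%s): %.2f (%.2f, %.2f), p = %.3g; %s = %.1f",
            ia$measure, ia$estimate_natural, ia$ci_low_natural,
            ia$ci_high_natural, ia$p_value, ia$ci_spread_type, ia$ci_spread),
    "")
  for (s in report$estimand_declarations) {
    if (!is.null(s$ie_strategy))
      lines <- c(lines, sprintf("Intercurrent events (%s): %s", s$target,
                                s$ie_strategy))
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Reconstruct a framework report from its JSON rendering
#' @param json a string produced by `render_report(report, "json")`.
#' @return A `framework_report` equal (up to numerically lossless
#'   round-tripping) to the original.
#' @export
parse_framework_report <- function(json) {
  l <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  spec_from <- function(s)
    estimand_spec(s$target, s$measure, pi = s$pi,
                  up_scale = if (is.null(s$up_scale)) "marginal" else s$up_scale,
                  primary = isTRUE(s$primary), ie_strategy = s$ie_strategy)
  results <- lapply(l$results, function(r) list(
    spec = spec_from(r$spec),
    primary_result = effect_estimate_from_list(r$primary_result),
    sensitivity_result = effect_estimate_from_list(r$sensitivity_result),
    concordance = r$concordance,
    concordance_trace = r$concordance_trace))
  ia <- effect_estimate_from_list(l$interaction_result)
  ia$ci_spread <- l$interaction_result$ci_spread
  ia$ci_spread_type <- l$interaction_result$ci_spread_type
  primary_idx <- which(vapply(results, function(r) isTRUE(r$spec$primary),
                              logical(1)))
  structure(list(
    estimand_declarations = lapply(l$estimand_declarations, spec_from),
    results = results,
    primary_result = results[[primary_idx]]$primary_result,
    sensitivity_result = results[[primary_idx]]$sensitivity_result,
    concordance = results[[primary_idx]]$concordance,
    interaction_result = ia,
    level = l$level, n = l$n), class = "framework_report")
}
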