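#' Cell-level outcome parameters for a 2x2 factorial design
#'
#' `cell_params` stores the ground-truth outcome parameter of each treatment
#' cell: the event probability (binary outcome) or outcome mean (continuous)
#' under joint assignment (z_a, z_b).  All closed-form estimand values and
#' every simulation scenario derive from these four numbers.
#'
#' Binary probabilities must lie strictly inside (0, 1): odds- and risk-ratio
#' arithmetic is undefined at the boundary, and the closed-form oracle is
#' kept exact rather than continuity-corrected.
#'
#' @param p00,p10,p01,p11 outcome probability or mean for cells
#'   (z_a, z_b) = (0,0), (1,0), (0,1), (1,1).
#' @param outcome_type `"binary"` or `"continuous"`.
#' @param sigma residual standard deviation (continuous outcomes only;
#'   must be >= 0, with 0 meaning a degenerate noiseless outcome).
#' @return An object of class `cell_params`.
#' @examples
#' # A fictitious binary trial where treatment A halves the odds of the event
#' # in both strata of B (no interaction on the log-odds scale):
#' cells <- cell_params(p00 = 0.50, p10 = 0.333, p01 = 0.091, p11 = 0.048)
#' conditional_effect(cells, stratum_b = 0, measure = "odds_ratio")  # 0.50
#' marginal_effect(cells, pi_b = 0.5, measure = "odds_ratio")        # 0.56
#' @export
cell_params <- function(p00, p10, p01, p11,
                        outcome_type = c("binary", "continuous"),
                        sigma = NULL) {
  outcome_type <- match.arg(outcome_type)
  p <- c(p00 = p00, p10 = p10, p01 = p01, p11 = p11)
  if (!is.numeric(p) || any(!is.finite(p)))
    stop("cell parameters must be finite numerics")
  if (outcome_type == "binary") {
    if (any(p <= 0 | p >= 1))
      stop("binary cell probabilities must lie strictly in (0, 1)")
    if (!is.null(sigma)) stop("sigma applies to continuous outcomes only")
  } else {
    if (is.null(sigma) || !is.numeric(sigma) || sigma < 0)
      stop("continuous outcomes require sigma >= 0")
  }
  structure(list(p00 = p00, p10 = p10, p01 = p01, p11 = p11,
                 outcome_type = outcome_type, sigma = sigma),
            class = "cell_params")
}

#' @export
print.cell_params <- function(x, ...) {
  cat(sprintf("Cell parameters (%s outcome%s):\n", x$outcome_type,
              if (x$outcome_type == "continuous")
                sprintf(", sigma = %g", x$sigma) else ""))
  m <- matrix(c(x$p00, x$p01, x$p10, x$p11), 2, 2, byrow = TRUE,
              dimnames = list(c("A = 0", "A = 1"), c("B = 0", "B = 1")))
  print(m)
  invisible(x)
}

#' Read cell parameters from a JSON or YAML config file
#'
#' Expects keys `p00`, `p10`, `p01`, `p11`, `outcome_type` and (continuous
#' only) `sigma`.  The format is inferred from the file extension
#' (`.json` vs `.yaml`/`.yml`).
#'
#' @param path path to the config file.
#' @return A [cell_params] object.
#' @export
cell_params_from_config <- function(path) {
  cfg <- read_config_file(path)
  cell_params(p00 = cfg$p00, p10 = cfg$p10, p01 = cfg$p01, p11 = cfg$p11,
              outcome_type = cfg$outcome_type, sigma = cfg$sigma)
}

# Mean/risk of cell (a, b).
#' @noRd
cell_mean <- function(cells, a, b) {
  cells[[paste0("p", a, b)]]
}

#' Specify a factorial-trial estimand for treatment A
#'
#' The four estimands differ in how treatment B enters the treatment
#' condition: absent (`A_GIVEN_NO_B`), present (`A_GIVEN_B`), given according
#' to usual practice (`A_USUAL_PRACTICE`, with `pi` the proportion receiving
#' B in practice), or as part of the combination A+B vs neither
#' (`A_PLUS_B`).
#'
#' For the usual-practice estimand the summary measure can be interpreted
#' marginally (population-averaged over B use, the default and the
#' recommended choice) or conditionally on the B stratum; the conditional
#' version is only well defined when the two stratum-specific effects
#' coincide.
#'
#' @param target one of `"A_GIVEN_NO_B"`, `"A_GIVEN_B"`,
#'   `"A_USUAL_PRACTICE"`, `"A_PLUS_B"`.
#' @param measure one of `"mean_difference"`, `"risk_difference"`,
#'   `"risk_ratio"`, `"odds_ratio"`.
#' @param pi proportion of patients receiving treatment B under usual
#'   practice, in \[0, 1\]; required exactly when
#'   `target = "A_USUAL_PRACTICE"`.
#' @param up_scale `"marginal"` (default) or `"conditional"`; usual-practice
#'   estimand only.
#' @param primary flag a spec as the primary estimand when several are
#'   passed to [run_framework()].
#' @param ie_strategy free-text label recording how intercurrent events are
#'   handled (e.g. `"treatment policy"`); recorded in reports, not computed
#'   with.
#' @return An object of class `estimand_spec`.
#' @export
estimand_spec <- function(target, measure, pi = NULL,
                          up_scale = c("marginal", "conditional"),
                          primary = FALSE, ie_strategy = NULL) {
  target <- match.arg(target, TARGETS)
  measure <- match.arg(measure, MEASURES)
  up_scale <- match.arg(up_scale)
  if (target == "A_USUAL_PRACTICE") {
    if (is.null(pi))
      stop("A_USUAL_PRACTICE requires pi (proportion receiving B in practice)")
    check_prob(pi, "pi")
  } else if (!is.null(pi)) {
    stop("pi is only meaningful for target = \"A_USUAL_PRACTICE\"")
  }
  structure(list(target = target, measure = measure, pi = pi,
                 up_scale = if (target == "A_USUAL_PRACTICE") up_scale else NULL,
                 primary = isTRUE(primary),
                 ie_strategy = ie_strategy),
            class = "estimand_spec")
}

#' @export
print.estimand_spec <- function(x, ...) {
  desc <- switch(x$target,
    A_GIVEN_NO_B = "effect of A in the absence of B",
    A_GIVEN_B = "effect of A in the presence of B",
    A_USUAL_PRACTICE = sprintf(
      "effect of A with B given per usual practice (pi = %g, %s)",
      x$pi, x$up_scale),
    A_PLUS_B = "effect of the A+B combination vs neither")
  cat(sprintf("Estimand %s (%s), measure: %s%s\n", x$target, desc, x$measure,
              if (x$primary) " [primary]" else ""))
  invisible(x)
}

#' @noRd
spec_label <- function(spec) {
  paste0(spec$target, if (!is.null(spec$pi)) sprintf("(pi=%g)", spec$pi),
         ":", spec$measure)
}

# ---- closed-form effect arithmetic -----------------------------------------

#' Stratum-specific (conditional) effect of treatment A
#'
#' The effect of A vs no-A within one stratum of B, on the requested summary
#' measure's natural scale (ratios returned as ratios, not logs).
#'
#' @param cells a [cell_params] object.
#' @param stratum_b 0 or 1, the B stratum.
#' @param measure summary measure (ratio measures require a binary outcome).
#' @return A single number.
#' @export
conditional_effect <- function(cells, stratum_b, measure) {
  stopifnot(inherits(cells, "cell_params"), stratum_b %in% c(0, 1))
  measure <- match.arg(measure, MEASURES)
  check_measure_outcome(measure, cells$outcome_type)
  effect_from_means(cell_mean(cells, 1, stratum_b),
                    cell_mean(cells, 0, stratum_b), measure)
}

#' Marginal (population-averaged) effect of treatment A
#'
#' Averages the cell-level outcome parameters over a population in which a
#' proportion `pi_b` receives treatment B, then forms the effect of A on the
#' requested measure: the outcome under A = a is
#' `(1 - pi_b) * p_{a0} + pi_b * p_{a1}`.  For noncollapsible measures (the
#' odds ratio) this generally differs from a common stratum-specific effect.
#'
#' @inheritParams conditional_effect
#' @param pi_b proportion of the population receiving treatment B.
#' @return A single number on the measure's natural scale.
#' @export
marginal_effect <- function(cells, pi_b, measure) {
  stopifnot(inherits(cells, "cell_params"))
  check_prob(pi_b, "pi_b")
  measure <- match.arg(measure, MEASURES)
  check_measure_outcome(measure, cells$outcome_type)
  m1 <- (1 - pi_b) * cells$p10 + pi_b * cells$p11
  m0 <- (1 - pi_b) * cells$p00 + pi_b * cells$p01
  effect_from_means(m1, m0, measure)
}

# Usual-practice effect allowing B receipt to differ by A arm
# (pi0 = P(B | A = 0), pi1 = P(B | A = 1)); the marginal-scale oracle.
#' @noRd
up_marginal_effect <- function(cells, pi0, pi1, measure) {
  m1 <- (1 - pi1) * cells$p10 + pi1 * cells$p11
  m0 <- (1 - pi0) * cells$p00 + pi0 * cells$p01
  effect_from_means(m1, m0, measure)
}

#' Interaction between treatments A and B on a measure's link scale
#'
#' The interaction contrast (link-scale effect of A in stratum B = 1) minus
#' (link-scale effect of A in stratum B = 0), where the link is the identity
#' for mean/risk differences, the log for risk ratios and the log-odds for
#' odds ratios.  Zero means no interaction on that scale; interaction is
#' scale-specific, so a table with no log-odds interaction typically shows a
#' nonzero risk-difference interaction.
#'
#' @inheritParams conditional_effect
#' @return A single number on the link scale.
#' @export
interaction_on_scale <- function(cells, measure) {
  measure <- match.arg(measure, MEASURES)
  e1 <- to_link_scale(conditional_effect(cells, 1, measure), measure)
  e0 <- to_link_scale(conditional_effect(cells, 0, measure), measure)
  e1 - e0
}

#' True (oracle) value of a factorial-trial estimand
#'
#' Computes the exact population value of the requested estimand from the
#' cell-level parameters: `A_GIVEN_NO_B` and `A_GIVEN_B` are the stratum
#' effects, `A_PLUS_B` contrasts cell (1,1) against cell (0,0), and
#' `A_USUAL_PRACTICE` is the marginal mixture effect at `spec$pi` (or, on
#' the conditional scale, the common stratum effect — defined only when the
#' two stratum effects agree on the link scale to within 1e-8, otherwise an
#' error of class `"estimand_undefined"` is signalled, never a silent
#' number).
#'
#' @inheritParams conditional_effect
#' @param spec an [estimand_spec].
#' @return A single number on the measure's natural scale.
#' @export
true_estimand_value <- function(cells, spec) {
  stopifnot(inherits(cells, "cell_params"), inherits(spec, "estimand_spec"))
  measure <- spec$measure
  check_measure_outcome(measure, cells$outcome_type)
  switch(spec$target,
    A_GIVEN_NO_B = conditional_effect(cells, 0, measure),
    A_GIVEN_B    = conditional_effect(cells, 1, measure),
    A_PLUS_B     = effect_from_means(cells$p11, cells$p00, measure),
    A_USUAL_PRACTICE = {
      if (identical(spec$up_scale, "conditional")) {
        e0 <- to_link_scale(conditional_effect(cells, 0, measure), measure)
        e1 <- to_link_scale(conditional_effect(cells, 1, measure), measure)
        if (abs(e1 - e0) > 1e-8)
          stop_undefined_estimand(paste0(
            "conditional usual-practice estimand undefined: stratum effects ",
            "differ on the link scale (", format(e0), " vs ", format(e1), ")"))
        from_link_scale(e0, measure)
      } else {
        marginal_effect(cells, spec$pi, measure)
      }
    }
  )
}

#' @noRd
check_measure_outcome <- function(measure, outcome_type) {
  if (measure == "mean_difference" && outcome_type != "continuous")
    stop("mean_difference requires a continuous outcome")
  if (measure %in% c("risk_difference", "risk_ratio", "odds_ratio") &&
      outcome_type != "binary")
    stop(measure, " requires a binary outcome")
  invisible(TRUE)
}
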