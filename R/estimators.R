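#' Fit an analysis model to a 2x2 factorial trial dataset
#'
#' Fits one of the four analysis models on the link scale implied by the
#' summary measure:
#'
#' * `factorial_adjusted`: `g(E[Y]) = alpha + beta_a Z_A + beta_b Z_B` — the
#'   at-the-margins model, adjusted for the other factor.  This is the model
#'   behind every factorial estimator; for noncollapsible measures (odds
#'   ratio) the adjustment is what makes the estimator target the stratum
#'   effect rather than a design-dependent marginal quantity.
#' * `factorial_unadjusted`: `g(E[Y]) = alpha + beta_a Z_A` — provided only
#'   to demonstrate the noncollapsibility bias of omitting Z_B; never routed
#'   to an estimand.
#' * `multiarm`: `g(E[Y]) = alpha + beta_a0 Z_A0 + beta_0b Z_0B +
#'   beta_ab Z_AB`, with mutually exclusive cell dummies (A alone, B alone,
#'   both) and the (0,0) cell as reference — the inside-the-table model.
#' * `interaction`: `g(E[Y]) = alpha + beta_a Z_A + beta_b Z_B +
#'   beta_int Z_A Z_B` — a reparameterization of the multiarm model, used to
#'   assess the no-interaction assumption.
#'
#' Fitting machinery by measure: `mean_difference` — least squares with
#' model-based covariance and a t reference; `odds_ratio` — logistic
#' regression (IRLS, tolerance 1e-8, max 100 iterations); `risk_ratio` —
#' log-link binomial with an explicit error on non-convergence;
#' `risk_difference` — identity-link least squares on the 0/1 outcome with
#' heteroskedasticity-robust (HC0 sandwich) covariance and a normal
#' reference.
#'
#' @param data a [trial_data] object.
#' @param model one of `"factorial_adjusted"`, `"factorial_unadjusted"`,
#'   `"multiarm"`, `"interaction"`.
#' @param measure summary measure; must be compatible with the outcome type.
#' @return An object of class `factorial_fit` with components `model`,
#'   `coef`, `vcov`, `n`, `link`, `converged`, `n_iterations`, `measure`,
#'   `df` (residual df for t-based inference, `Inf` for normal) and the
#'   underlying `stats` fit in `fit`.
#' @examples
#' cells <- cell_params(0, 1, 2, 3, outcome_type = "continuous", sigma = 1)
#' trial <- simulate_factorial(simulation_config(cells, n = 400, seed = 7))
#' fit <- fit_model(trial$data, "factorial_adjusted", "mean_difference")
#' coef(fit)
#' @export
fit_model <- function(data,
                      model = c("factorial_adjusted", "factorial_unadjusted",
                                "multiarm", "interaction"),
                      measure = MEASURES) {
  stopifnot(inherits(data, "trial_data"))
  model <- match.arg(model)
  measure <- match.arg(measure)
  check_measure_outcome(measure, outcome_type(data))
  check_cells_for_model(data, model)

  df <- model_frame(data, model)
  form <- stats::as.formula(paste("y ~", paste(setdiff(names(df), "y"),
                                               collapse = " + ")))
  link <- measure_link(measure)
  if (measure == "mean_difference") {
    fit <- stats::lm(form, data = df)
    vc <- zap_degenerate_vcov(fit)
    res <- new_factorial_fit(model, fit, vc, measure, link,
                             df_resid = stats::df.residual(fit),
                             converged = TRUE, n_iter = 1L)
  } else if (measure == "risk_difference") {
    fit <- stats::lm(form, data = df)
    vc <- sandwich::vcovHC(fit, type = "HC0")
    res <- new_factorial_fit(model, fit, vc, measure, link,
                             df_resid = Inf, converged = TRUE, n_iter = 1L)
  } else {
    fam <- if (measure == "odds_ratio") stats::binomial("logit")
           else stats::binomial("log")
    ctrl <- stats::glm.control(epsilon = 1e-8, maxit = 100)
    start <- if (measure == "risk_ratio")
      c(log(max(mean(df$y), 1e-4)), rep(0, ncol(df) - 1L)) else NULL
    fit <- tryCatch(
      suppressWarnings(stats::glm(form, family = fam, data = df,
                                  control = ctrl, start = start)),
      error = function(e) stop(sprintf(
        "%s model (%s) failed to fit: %s", model, measure, conditionMessage(e)),
        call. = FALSE))
    if (!fit$converged)
      stop(sprintf("%s model (%s) did not converge in 100 IRLS iterations%s",
                   model, measure,
                   if (measure == "risk_ratio")
                     " (log-binomial fits can fail near the risk boundary)"
                   else ""), call. = FALSE)
    if (any(abs(stats::coef(fit)) > 15))
      stop(sprintf(paste0("%s model (%s): coefficient diverged ",
                          "(|estimate| > 15 on the link scale), likely ",
                          "complete separation in one of the cells"),
                   model, measure), call. = FALSE)
    res <- new_factorial_fit(model, fit, stats::vcov(fit), measure, link,
                             df_resid = Inf, converged = fit$converged,
                             n_iter = fit$iter)
  }
  res
}

# Build the per-model regressor frame with the canonical coefficient names.
#' @noRd
model_frame <- function(data, model) {
  z_a <- data$z_a; z_b <- data$z_b
  switch(model,
    factorial_adjusted = data.frame(y = data$y, beta_a = z_a, beta_b = z_b),
    factorial_unadjusted = data.frame(y = data$y, beta_a = z_a),
    multiarm = data.frame(y = data$y,
                          beta_a0 = as.integer(z_a == 1 & z_b == 0),
                          beta_0b = as.integer(z_a == 0 & z_b == 1),
                          beta_ab = as.integer(z_a == 1 & z_b == 1)),
    interaction = data.frame(y = data$y, beta_a = z_a, beta_b = z_b,
                             beta_int = z_a * z_b)
  )
}

#' @noRd
check_cells_for_model <- function(data, model) {
  counts <- table(factor(data$z_a, 0:1), factor(data$z_b, 0:1))
  if (model %in% c("multiarm", "interaction")) {
    if (any(counts == 0)) {
      empty <- which(counts == 0, arr.ind = TRUE)
      stop(sprintf("%s model requires all four cells non-empty; cell (z_a=%d, z_b=%d) is empty",
                   model, empty[1, 1] - 1L, empty[1, 2] - 1L), call. = FALSE)
    }
  } else {
    if (any(rowSums(counts) == 0))
      stop(model, " model requires both levels of z_a present", call. = FALSE)
    if (model == "factorial_adjusted" && any(colSums(counts) == 0))
      stop(model, " model requires both levels of z_b present", call. = FALSE)
  }
  invisible(TRUE)
}

# Exact-fit least squares (noiseless synthetic data) leaves residual variance
# at rounding-error level; zero it so degenerate fits report se = 0 rather
# than a meaningless 1e-16-scale standard error.
#' @noRd
zap_degenerate_vcov <- function(fit) {
  res <- stats::residuals(fit)
  scale2 <- max(mean(fit$model$y^2), 1)
  vc <- suppressWarnings(stats::vcov(fit))  # "essentially perfect fit"
  if (stats::df.residual(fit) > 0 &&
      sum(res^2) / stats::df.residual(fit) < 1e-20 * scale2)
    vc[] <- 0
  vc
}

#' @noRd
new_factorial_fit <- function(model, fit, vc, measure, link, df_resid,
                              converged, n_iter) {
  cf <- stats::coef(fit)
  names(cf)[names(cf) == "(Intercept)"] <- "alpha"
  dimnames(vc) <- list(names(cf), names(cf))
  structure(list(model = model, coef = cf, vcov = vc,
                 n = stats::nobs(fit), link = link, measure = measure,
                 converged = converged, n_iterations = n_iter,
                 df = df_resid, fit = fit),
            class = "factorial_fit")
}

#' @export
coef.factorial_fit <- function(object, ...) object$coef

#' @export
vcov.factorial_fit <- function(object, ...) object$vcov

#' @export
residuals.factorial_fit <- function(object, ...) stats::residuals(object$fit, ...)

#' @export
predict.factorial_fit <- function(object, ...) stats::predict(object$fit, ...)

#' @export
print.factorial_fit <- function(x, digits = 4, ...) {
  cat(sprintf("%s model (%s, %s link), n = %d\n",
              x$model, x$measure, x$link, x$n))
  print(round(x$coef, digits))
  invisible(x)
}

#' @export
summary.factorial_fit <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  z <- object$coef / se
  p <- 2 * stats::pt(-abs(z), df = object$df)
  tab <- cbind(Estimate = object$coef, `Std. Error` = se,
               `z value` = z, `Pr(>|z|)` = p)
  structure(list(model = object$model, measure = object$measure,
                 n = object$n, coefficients = tab),
            class = "summary.factorial_fit")
}

#' @export
print.summary.factorial_fit <- function(x, ...) {
  cat(sprintf("%s model (%s), n = %d\n", x$model, x$measure, x$n))
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

# ---- effect estimates ------------------------------------------------------

#' @noRd
new_effect_estimate <- function(spec, strategy, estimate_link, se_link, df,
                                level, measure, note = NULL) {
  if (se_link == 0) {
    z <- NA_real_
    p <- if (abs(estimate_link) < 1e-8) 1 else 0
    ci <- c(estimate_link, estimate_link)
  } else {
    z <- estimate_link / se_link
    p <- 2 * stats::pt(-abs(z), df = df)
    crit <- stats::qt(1 - (1 - level) / 2, df = df)
    ci <- estimate_link + c(-1, 1) * crit * se_link
  }
  out <- list(
    estimand = spec, strategy = strategy,
    estimate_link = estimate_link, se_link = se_link,
    ci_low = ci[1], ci_high = ci[2], p_value = p,
    estimate_natural = from_link_scale(estimate_link, measure),
    ci_low_natural = from_link_scale(ci[1], measure),
    ci_high_natural = from_link_scale(ci[2], measure),
    level = level, measure = measure, link = measure_link(measure),
    df = df)
  if (!is.null(note)) out$note <- note
  structure(out, class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, digits = 3, ...) {
  lab <- if (!is.null(x$estimand)) x$estimand$target else "contrast"
  cat(sprintf("%s [%s strategy, %s]\n", lab, x$strategy, x$measure))
  nat <- x$link != "identity"
  cat(sprintf("  estimate%s: %.*f (%.0f%% CI %.*f to %.*f), p = %.3g\n",
              if (nat) " (ratio scale)" else "", digits, x$estimate_natural,
              100 * x$level, digits, x$ci_low_natural, digits,
              x$ci_high_natural, x$p_value))
  if (nat)
    cat(sprintf("  link scale: %.*f (SE %.*f)\n", digits, x$estimate_link,
                digits, x$se_link))
  if (!is.null(x$note)) cat("  note: ", x$note, "\n", sep = "")
  invisible(x)
}

#' Linear combination of fitted coefficients with delta-method inference
#'
#' Computes `w' beta_hat` with variance `w' V w` from the fitted model's
#' covariance matrix, a Wald confidence interval and two-sided p-value
#' (t reference when the fit carries finite residual df, normal otherwise),
#' and the back-transformed natural-scale estimate for log/logit links.
#'
#' @param fit a [factorial_fit].
#' @param weights named numeric vector; names must be coefficient names of
#'   `fit`.
#' @param level confidence level.
#' @param spec optional [estimand_spec] recorded on the result.
#' @param strategy strategy label recorded on the result.
#' @return An object of class `effect_estimate`.
#' @export
linear_combination <- function(fit, weights, level = 0.95, spec = NULL,
                               strategy = "contrast") {
  stopifnot(inherits(fit, "factorial_fit"))
  if (is.null(names(weights)) || any(!nzchar(names(weights))))
    stop("weights must be a fully named numeric vector")
  unknown <- setdiff(names(weights), names(fit$coef))
  if (length(unknown))
    stop("unknown coefficient name(s): ", paste(unknown, collapse = ", "))
  w <- stats::setNames(numeric(length(fit$coef)), names(fit$coef))
  w[names(weights)] <- weights
  est <- sum(w * fit$coef)
  v <- drop(t(w) %*% fit$vcov %*% w)
  new_effect_estimate(spec, strategy, est, sqrt(max(v, 0)), fit$df, level,
                      fit$measure)
}

#' Estimate a factorial-trial estimand
#'
#' Routes an estimand specification to its estimator:
#'
#' * factorial strategy (always the *adjusted* model): `beta_a` for
#'   `A_GIVEN_NO_B`, `A_GIVEN_B` and `A_USUAL_PRACTICE`;
#'   `beta_a + beta_b` for `A_PLUS_B`.  Unbiased under no interaction (for
#'   the odds ratio, for the conditional effect).
#' * multiarm strategy: `beta_a0` for `A_GIVEN_NO_B`,
#'   `beta_ab - beta_0b` for `A_GIVEN_B`, `beta_ab` for `A_PLUS_B`, and the
#'   pi-weighted combination [weighted_usual_practice()] for
#'   `A_USUAL_PRACTICE` (strategy tag `weighted_multiarm`).  No interaction
#'   assumption required.
#'
#' For the marginal usual-practice odds ratio no unbiased estimator exists
#' under either strategy (the odds ratio is noncollapsible); the estimate is
#' returned with an explanatory `note` and targets the conditional effect.
#'
#' @param data a [trial_data] object.
#' @param spec an [estimand_spec].
#' @param strategy `"factorial"` or `"multiarm"`.
#' @param level confidence level.
#' @return An `effect_estimate`.
#' @examples
#' cells <- cell_params(0.50, 0.333, 0.091, 0.048)
#' trial <- simulate_factorial(simulation_config(cells, n = 2000, seed = 1))
#' estimate_estimand(trial$data,
#'                   estimand_spec("A_GIVEN_NO_B", "odds_ratio"),
#'                   strategy = "factorial")
#' @export
estimate_estimand <- function(data, spec,
                              strategy = c("factorial", "multiarm"),
                              level = 0.95) {
  stopifnot(inherits(spec, "estimand_spec"))
  strategy <- match.arg(strategy)
  note <- NULL
  if (spec$target == "A_USUAL_PRACTICE" && spec$measure == "odds_ratio" &&
      identical(spec$up_scale, "marginal"))
    note <- paste("no unbiased estimator is available for the marginal",
                  "usual-practice odds ratio (noncollapsible measure);",
                  "the reported estimate targets the conditional effect")
  if (strategy == "factorial") {
    fit <- fit_model(data, "factorial_adjusted", spec$measure)
    w <- switch(spec$target,
      A_GIVEN_NO_B = , A_GIVEN_B = , A_USUAL_PRACTICE = c(beta_a = 1),
      A_PLUS_B = c(beta_a = 1, beta_b = 1))
    out <- linear_combination(fit, w, level, spec, "factorial")
  } else {
    fit <- fit_model(data, "multiarm", spec$measure)
    if (spec$target == "A_USUAL_PRACTICE") {
      out <- weighted_usual_practice(fit, spec$pi, level, spec)
    } else {
      w <- switch(spec$target,
        A_GIVEN_NO_B = c(beta_a0 = 1),
        A_GIVEN_B = c(beta_ab = 1, beta_0b = -1),
        A_PLUS_B = c(beta_ab = 1))
      out <- linear_combination(fit, w, level, spec, "multiarm")
    }
  }
  if (!is.null(note)) out$note <- note
  out
}

#' Weighted usual-practice estimator from a multiarm fit
#'
#' The multiarm estimator for the usual-practice estimand:
#' `(1 - pi) * beta_a0 + pi * (beta_ab - beta_0b)`, where `pi` is the
#' proportion of patients assumed to receive treatment B in practice.  `pi`
#' is treated as a fixed constant (no variance contribution).  Unbiased when
#' B-receipt in practice does not depend on A and when the stratum effects
#' estimated under randomized B transfer to usual-practice B assignment.
#'
#' @param fit a multiarm [factorial_fit].
#' @param pi proportion receiving B under usual practice, in \[0, 1\].
#' @param level confidence level.
#' @param spec optional [estimand_spec] recorded on the result.
#' @return An `effect_estimate` with strategy `"weighted_multiarm"`.
#' @export
weighted_usual_practice <- function(fit, pi, level = 0.95, spec = NULL) {
  stopifnot(inherits(fit, "factorial_fit"))
  if (fit$model != "multiarm")
    stop("weighted_usual_practice requires a multiarm fit")
  check_prob(pi, "pi")
  linear_combination(fit,
                     c(beta_a0 = 1 - pi, beta_ab = pi, beta_0b = -pi),
                     level, spec, "weighted_multiarm")
}

#' Assess the treatment A x treatment B interaction
#'
#' Fits the interaction model and reports the interaction coefficient
#' `beta_int` on the measure's link scale with confidence interval and
#' p-value, plus the ratio-scale interaction for log/logit links.  This is
#' step 3 of the estimand framework: the size and uncertainty of the
#' interaction gauge the plausibility of the no-interaction assumption
#' behind the factorial estimators.
#'
#' @param data a [trial_data] object with all four cells non-empty.
#' @param measure summary measure.
#' @param level confidence level.
#' @return An `effect_estimate` with strategy `"interaction"`.
#' @export
interaction_assessment <- function(data, measure, level = 0.95) {
  fit <- fit_model(data, "interaction", measure)
  linear_combination(fit, c(beta_int = 1), level, NULL, "interaction")
}

#' Serialize a fit or effect estimate to JSON
#'
#' Full double precision; coefficient names, link and measure are recorded.
#'
#' @param x a `factorial_fit` or `effect_estimate`.
#' @return A JSON string.
#' @export
to_json <- function(x) {
  if (inherits(x, "factorial_fit")) {
    jsonlite::toJSON(list(model = x$model, coef = as.list(x$coef),
                          vcov = x$vcov, n = x$n, link = x$link,
                          measure = x$measure, converged = x$converged,
                          n_iterations = x$n_iterations),
                     digits = NA, auto_unbox = TRUE)
  } else if (inherits(x, "effect_estimate")) {
    jsonlite::toJSON(effect_estimate_to_list(x), digits = NA,
                     auto_unbox = TRUE)
  } else {
    stop("to_json supports factorial_fit and effect_estimate objects")
  }
}

#' @noRd
effect_estimate_to_list <- function(x) {
  out <- list(estimand = if (is.null(x$estimand)) NULL else
         x$estimand[c("target", "measure", "pi", "up_scale", "primary",
                      "ie_strategy")],
       strategy = x$strategy, estimate_link = x$estimate_link,
       se_link = x$se_link, ci_low = x$ci_low, ci_high = x$ci_high,
       p_value = x$p_value, estimate_natural = x$estimate_natural,
       ci_low_natural = x$ci_low_natural, ci_high_natural = x$ci_high_natural,
       level = x$level, measure = x$measure, link = x$link,
       df = if (is.finite(x$df)) x$df else NULL)
  if (!is.null(x$note)) out$note <- x$note
  out
}

#' @noRd
effect_estimate_from_list <- function(l) {
  spec <- if (is.null(l$estimand)) NULL else
    estimand_spec(l$estimand$target, l$estimand$measure, pi = l$estimand$pi,
                  up_scale = if (is.null(l$estimand$up_scale)) "marginal"
                             else l$estimand$up_scale,
                  primary = isTRUE(l$estimand$primary),
                  ie_strategy = l$estimand$ie_strategy)
  out <- list(
    estimand = spec, strategy = l$strategy, estimate_link = l$estimate_link,
    se_link = l$se_link, ci_low = l$ci_low, ci_high = l$ci_high,
    p_value = l$p_value, estimate_natural = l$estimate_natural,
    ci_low_natural = l$ci_low_natural, ci_high_natural = l$ci_high_natural,
    level = l$level, measure = l$measure, link = l$link,
    df = if (is.null(l$df)) Inf else l$df)
  if (!is.null(l$note)) out$note <- l$note
  structure(out, class = "effect_estimate")
}
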