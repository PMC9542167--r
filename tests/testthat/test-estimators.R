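test_that("noiseless additive data is fit exactly by every model", {
  d <- noiseless_trial(means = c(0, 1, 2, 3), per_cell = 6)
  fit <- fit_model(d, "factorial_adjusted", "mean_difference")
  expect_equal(unname(coef(fit)[c("beta_a", "beta_b")]), c(1, 2),
               tolerance = 1e-10)
  fit_int <- fit_model(d, "interaction", "mean_difference")
  expect_equal(unname(coef(fit_int)["beta_int"]), 0, tolerance = 1e-10)
  ia <- interaction_assessment(d, "mean_difference")
  expect_equal(ia$estimate_link, 0, tolerance = 1e-10)
  expect_equal(ia$p_value, 1)

  d2 <- noiseless_trial(means = c(0, 1, 2, 5), per_cell = 6)
  ma <- estimate_estimand(d2, estimand_spec("A_GIVEN_NO_B", "mean_difference"),
                          "multiarm")
  expect_equal(ma$estimate_link, 1, tolerance = 1e-10)
  comb <- estimate_estimand(d2, estimand_spec("A_PLUS_B", "mean_difference"),
                            "multiarm")
  expect_equal(comb$estimate_link, 5, tolerance = 1e-10)
})

test_that("linear_combination reproduces single coefficients and hand contrasts", {
  d2 <- noiseless_trial(means = c(0, 1, 2, 5), per_cell = 6)
  fit <- fit_model(d2, "multiarm", "mean_difference")
  lc <- linear_combination(fit, c(beta_a0 = 1))
  expect_equal(lc$estimate_link, unname(coef(fit)["beta_a0"]))
  expect_equal(lc$se_link, sqrt(vcov(fit)["beta_a0", "beta_a0"]))
  contrast <- linear_combination(fit, c(beta_ab = 1, beta_0b = -1))
  expect_equal(contrast$estimate_link, 3, tolerance = 1e-10)
  expect_error(linear_combination(fit, c(beta_zz = 1)), "unknown coefficient")
  expect_error(linear_combination(fit, c(1, 2)), "named")
})

test_that("contrast variance agrees with a nonparametric bootstrap", {
  trial <- simulate_factorial(simulation_config(table2_cells(), n = 2000,
                                                seed = 2203))
  fit <- fit_model(trial$data, "factorial_adjusted", "odds_ratio")
  lc <- linear_combination(fit, c(beta_a = 1, beta_b = 1))
  set.seed(404)
  boots <- replicate(500, {
    idx <- sample(nrow(trial$data), replace = TRUE)
    d <- trial$data
    db <- trial_data(d$z_a[idx], d$z_b[idx], d$y[idx], "binary")
    fb <- fit_model(db, "factorial_adjusted", "odds_ratio")
    sum(coef(fb)[c("beta_a", "beta_b")])
  })
  expect_equal(lc$se_link^2, var(boots), tolerance = 0.15)
  # and the delta-method variance is exactly the expanded covariance formula
  v <- vcov(fit)
  expect_equal(lc$se_link^2,
               v["beta_a", "beta_a"] + v["beta_b", "beta_b"] +
                 2 * v["beta_a", "beta_b"])
})

test_that("weighted usual-practice estimator interpolates the multiarm contrasts", {
  d2 <- noiseless_trial(means = c(0, 1, 2, 5), per_cell = 6)
  fit <- fit_model(d2, "multiarm", "mean_difference")
  w0 <- weighted_usual_practice(fit, 0)
  expect_equal(w0$estimate_link,
               linear_combination(fit, c(beta_a0 = 1))$estimate_link)
  expect_equal(w0$se_link, linear_combination(fit, c(beta_a0 = 1))$se_link)
  w1 <- weighted_usual_practice(fit, 1)
  expect_equal(w1$estimate_link,
               linear_combination(fit, c(beta_ab = 1, beta_0b = -1))$estimate_link)
  expect_equal(weighted_usual_practice(fit, 0.5)$estimate_link,
               0.5 * 1 + 0.5 * 3, tolerance = 1e-10)
  ffit <- fit_model(d2, "factorial_adjusted", "mean_difference")
  expect_error(weighted_usual_practice(ffit, 0.5), "multiarm")
})

test_that("interaction and multiarm models are reparameterizations of each other", {
  set.seed(7042)
  for (i in 1:15) {
    outcome <- if (i %% 2 == 0) "binary" else "continuous"
    measure <- if (outcome == "binary")
      sample(c("odds_ratio", "risk_difference"), 1) else "mean_difference"
    d <- random_dataset_four_cells(outcome)
    fm <- fit_model(d, "multiarm", measure)
    fi <- fit_model(d, "interaction", measure)
    ci <- coef(fi); cm <- coef(fm)
    expect_equal(unname(cm["beta_a0"]), unname(ci["beta_a"]),
                 tolerance = 1e-6)
    expect_equal(unname(cm["beta_0b"]), unname(ci["beta_b"]),
                 tolerance = 1e-6)
    expect_equal(unname(cm["beta_ab"]),
                 unname(ci["beta_a"] + ci["beta_b"] + ci["beta_int"]),
                 tolerance = 1e-6)
    # contrast covariance maps the variances onto each other
    lc <- linear_combination(fi, c(beta_a = 1, beta_b = 1, beta_int = 1))
    expect_equal(lc$se_link^2, vcov(fm)["beta_ab", "beta_ab"],
                 tolerance = 1e-6)
  }
})

test_that("balanced identity-link factorial estimate equals the margin-mean difference", {
  set.seed(88)
  d <- noiseless_trial(means = c(0.3, 1.1, 2.7, 3.5), per_cell = 8)
  d <- trial_data(d$z_a, d$z_b, d$y + rnorm(nrow(d), 0, 0.4), "continuous")
  fit <- fit_model(d, "factorial_adjusted", "mean_difference")
  expect_equal(unname(coef(fit)["beta_a"]),
               mean(d$y[d$z_a == 1]) - mean(d$y[d$z_a == 0]),
               tolerance = 1e-10)
})

test_that("natural-scale CIs are the exponentials of link-scale CIs", {
  trial <- simulate_factorial(simulation_config(table2_cells(), n = 800,
                                                seed = 15))
  for (strategy in c("factorial", "multiarm")) {
    e <- estimate_estimand(trial$data,
                           estimand_spec("A_GIVEN_B", "odds_ratio"), strategy)
    expect_identical(e$ci_low_natural, exp(e$ci_low))
    expect_identical(e$ci_high_natural, exp(e$ci_high))
    expect_true(e$ci_low <= e$estimate_link && e$estimate_link <= e$ci_high)
  }
  rr <- estimate_estimand(trial$data,
                          estimand_spec("A_GIVEN_NO_B", "risk_ratio"),
                          "multiarm")
  expect_identical(rr$estimate_natural, exp(rr$estimate_link))
})

test_that("risk-difference fits use the sandwich covariance", {
  trial <- simulate_factorial(simulation_config(table2_cells(), n = 600,
                                                seed = 77))
  fit <- fit_model(trial$data, "factorial_adjusted", "risk_difference")
  lmfit <- stats::lm(y ~ z_a + z_b, data = as.data.frame(trial$data))
  expect_equal(unname(diag(vcov(fit))),
               unname(diag(sandwich::vcovHC(lmfit, type = "HC0"))),
               tolerance = 1e-12)
})

test_that("empty cells and missing arms are explicit fit-time errors", {
  d <- trial_data(z_a = c(0, 1, 0, 1), z_b = c(0, 0, 0, 0),
                  y = c(0, 1, 1, 0), outcome_type = "binary")
  expect_error(fit_model(d, "multiarm", "odds_ratio"), "cell \\(z_a=0, z_b=1\\)")
  expect_error(fit_model(d, "factorial_adjusted", "odds_ratio"), "z_b")
  d_one_arm <- trial_data(z_a = rep(1, 4), z_b = c(0, 1, 0, 1),
                          y = c(0, 1, 1, 0), outcome_type = "binary")
  expect_error(fit_model(d_one_arm, "factorial_unadjusted", "odds_ratio"),
               "z_a")
})

test_that("separation is reported as an explicit error", {
  # cell (1,1) has only events: the multiarm logit coefficient diverges
  z_a <- rep(c(0, 1, 0, 1), each = 30)
  z_b <- rep(c(0, 0, 1, 1), each = 30)
  y <- ifelse(z_a == 1 & z_b == 1, 1, rbinom(120, 1, 0.4))
  set.seed(5)
  d <- trial_data(z_a, z_b, ifelse(z_a == 1 & z_b == 1, 1,
                                   rbinom(120, 1, 0.4)), "binary")
  expect_error(fit_model(d, "multiarm", "odds_ratio"),
               "separation|converge")
})

test_that("fit and estimate objects serialize to JSON with full precision", {
  trial <- simulate_factorial(simulation_config(table2_cells(), n = 400,
                                                seed = 99))
  fit <- fit_model(trial$data, "multiarm", "odds_ratio")
  j <- jsonlite::fromJSON(to_json(fit))
  expect_equal(j$coef$beta_a0, unname(coef(fit)["beta_a0"]))
  expect_identical(j$link, "logit")
  e <- estimate_estimand(trial$data,
                         estimand_spec("A_GIVEN_NO_B", "odds_ratio"),
                         "multiarm")
  je <- jsonlite::fromJSON(to_json(e))
  expect_equal(je$estimate_link, e$estimate_link)
  expect_identical(je$strategy, "multiarm")
})
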