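# Closed-form effect arithmetic on cell-level parameters.  The fictitious
# table (50%, 33.3%, 9.1%, 4.8%) has a common stratum OR of 0.50 for A and
# 0.10 for B, no interaction on the log-odds scale, and a marginal OR of
# 0.56 when half the population receives B — the canonical demonstration of
# odds-ratio noncollapsibility.

test_that("stratum-specific and marginal odds ratios reproduce the fictitious table", {
  cells <- table2_cells()
  expect_equal(conditional_effect(cells, 0, "odds_ratio"), 0.50,
               tolerance = 0.005)
  expect_equal(conditional_effect(cells, 1, "odds_ratio"), 0.50,
               tolerance = 0.01)
  expect_equal(marginal_effect(cells, 0.5, "odds_ratio"), 0.56,
               tolerance = 0.005)
  # effect of B obtained by the documented factor swap (columns exchanged)
  swapped <- cell_params(cells$p00, cells$p01, cells$p10, cells$p11)
  expect_equal(conditional_effect(swapped, 0, "odds_ratio"), 0.10,
               tolerance = 0.005)
})

test_that("interaction is zero on the log-odds scale but not on the risk-difference scale", {
  cells <- table2_cells()
  expect_equal(interaction_on_scale(cells, "odds_ratio"), 0, tolerance = 0.02)
  # direct arithmetic on the printed cells: (0.048-0.091) - (0.333-0.50)
  expect_equal(interaction_on_scale(cells, "risk_difference"), 0.124,
               tolerance = 1e-12)
  # additive construction is exactly null on the risk-difference scale
  expect_equal(interaction_on_scale(cell_params(0.2, 0.4, 0.3, 0.5),
                                    "risk_difference"), 0)
})

test_that("true_estimand_value matches direct odds/risk arithmetic", {
  cells <- table2_cells()
  # combination effect: odds of cell (1,1) vs cell (0,0)
  expect_equal(true_estimand_value(cells, estimand_spec("A_PLUS_B", "odds_ratio")),
               (0.048 / 0.952) / (0.50 / 0.50), tolerance = 1e-12)
  expect_equal(true_estimand_value(cells, estimand_spec("A_GIVEN_NO_B", "odds_ratio")),
               0.50, tolerance = 0.005)
  # null A effect in both strata gives zero for every A estimand except A_PLUS_B
  null_cells <- cell_params(0.3, 0.3, 0.6, 0.6)
  for (tg in c("A_GIVEN_NO_B", "A_GIVEN_B")) {
    expect_equal(true_estimand_value(null_cells,
                                     estimand_spec(tg, "risk_difference")), 0)
  }
  expect_equal(true_estimand_value(null_cells,
                 estimand_spec("A_USUAL_PRACTICE", "risk_difference", pi = 0.4)),
               0)
})

test_that("degenerate usual-practice mixtures reduce to stratum effects", {
  cells <- table2_cells()
  expect_equal(marginal_effect(cells, 0, "odds_ratio"),
               conditional_effect(cells, 0, "odds_ratio"))
  expect_equal(marginal_effect(cells, 1, "odds_ratio"),
               conditional_effect(cells, 1, "odds_ratio"))
  # null A effect in one stratum: RD marginal is the pi-weighted stratum mix
  rd0 <- conditional_effect(cells, 0, "risk_difference")
  rd1 <- conditional_effect(cells, 1, "risk_difference")
  expect_equal(marginal_effect(cells, 0.3, "risk_difference"),
               0.7 * rd0 + 0.3 * rd1)
})

test_that("collapsible measures mix linearly in pi; the OR attenuates toward 1", {
  set.seed(31)
  for (i in 1:50) {
    cells <- cell_params(runif(1, .05, .95), runif(1, .05, .95),
                         runif(1, .05, .95), runif(1, .05, .95))
    pi_b <- runif(1)
    rd0 <- conditional_effect(cells, 0, "risk_difference")
    rd1 <- conditional_effect(cells, 1, "risk_difference")
    expect_equal(marginal_effect(cells, pi_b, "risk_difference"),
                 (1 - pi_b) * rd0 + pi_b * rd1, tolerance = 1e-12)
  }
  # common conditional OR != 1 with unequal stratum baselines: marginal OR
  # lies strictly between the conditional OR and 1
  cells <- table2_cells()
  or_cond <- conditional_effect(cells, 0, "odds_ratio")
  or_marg <- marginal_effect(cells, 0.5, "odds_ratio")
  expect_true(or_marg > or_cond && or_marg < 1)

  # the collapsible mixture is exactly linear, hence monotone, in pi
  rd0 <- conditional_effect(cells, 0, "risk_difference")
  rd1 <- conditional_effect(cells, 1, "risk_difference")
  pis <- seq(0, 1, by = 0.05)
  rds <- vapply(pis, function(p) marginal_effect(cells, p, "risk_difference"),
                numeric(1))
  expect_equal(rds, (1 - pis) * rd0 + pis * rd1, tolerance = 1e-12)

  # the marginal OR varies continuously in pi and every interior value is
  # attenuated toward 1 relative to the common conditional OR
  fine <- seq(0, 1, by = 0.01)
  ors <- vapply(fine, function(p) marginal_effect(cells, p, "odds_ratio"),
                numeric(1))
  expect_lt(max(abs(diff(ors))), 0.01)
  expect_true(all(ors[-c(1, length(ors))] > min(ors[c(1, length(ors))])))
  expect_true(all(ors < 1))
})

test_that("no interaction on a scale makes the three A estimands coincide", {
  set.seed(57)
  for (i in 1:20) {
    # build cells with exactly zero log-odds interaction
    p00 <- runif(1, .1, .9); p01 <- runif(1, .1, .9)
    lor <- rnorm(1)
    p10 <- plogis(qlogis(p00) + lor)
    p11 <- plogis(qlogis(p01) + lor)
    cells <- cell_params(p00, p10, p01, p11)
    expect_equal(interaction_on_scale(cells, "odds_ratio"), 0,
                 tolerance = 1e-12)
    v0 <- true_estimand_value(cells, estimand_spec("A_GIVEN_NO_B", "odds_ratio"))
    v1 <- true_estimand_value(cells, estimand_spec("A_GIVEN_B", "odds_ratio"))
    vup <- true_estimand_value(cells,
             estimand_spec("A_USUAL_PRACTICE", "odds_ratio", pi = runif(1),
                           up_scale = "conditional"))
    expect_equal(v0, v1, tolerance = 1e-10)
    expect_equal(vup, v0, tolerance = 1e-10)
  }
})

test_that("conditional usual-practice estimand is flagged undefined when strata disagree", {
  cells <- cell_params(0.5, 0.4, 0.3, 0.1)  # strong OR interaction
  expect_error(
    true_estimand_value(cells,
      estimand_spec("A_USUAL_PRACTICE", "odds_ratio", pi = 0.5,
                    up_scale = "conditional")),
    class = "estimand_undefined")
  # the marginal version stays defined
  expect_true(is.finite(true_estimand_value(cells,
    estimand_spec("A_USUAL_PRACTICE", "odds_ratio", pi = 0.5))))
})

test_that("oracle values agree with a brute-force enumeration over cell membership", {
  # independent oracle: enumerate the joint (a, b) population explicitly and
  # apply textbook measure formulas to the enumerated expectations
  brute <- function(cells, spec) {
    ey <- function(a, wb) {
      # expected outcome under A = a with B-membership weights wb = (P(B=0), P(B=1))
      wb[1] * cells[[paste0("p", a, 0)]] + wb[2] * cells[[paste0("p", a, 1)]]
    }
    wb <- switch(spec$target,
      A_GIVEN_NO_B = c(1, 0), A_GIVEN_B = c(0, 1),
      A_USUAL_PRACTICE = c(1 - spec$pi, spec$pi),
      A_PLUS_B = NULL)
    if (spec$target == "A_PLUS_B") {
      m1 <- cells$p11; m0 <- cells$p00
    } else {
      m1 <- ey(1, wb); m0 <- ey(0, wb)
    }
    switch(spec$measure,
      risk_difference = m1 - m0,
      risk_ratio = m1 / m0,
      odds_ratio = (m1 * (1 - m0)) / (m0 * (1 - m1)),
      mean_difference = m1 - m0)
  }
  set.seed(99)
  for (i in 1:1000) {
    cells <- cell_params(runif(1, .05, .95), runif(1, .05, .95),
                         runif(1, .05, .95), runif(1, .05, .95))
    tg <- sample(c("A_GIVEN_NO_B", "A_GIVEN_B", "A_USUAL_PRACTICE",
                   "A_PLUS_B"), 1)
    ms <- sample(c("risk_difference", "risk_ratio", "odds_ratio"), 1)
    spec <- estimand_spec(tg, ms,
                          pi = if (tg == "A_USUAL_PRACTICE") runif(1))
    expect_equal(true_estimand_value(cells, spec), brute(cells, spec),
                 tolerance = 1e-14)
  }
})

test_that("boundary probabilities and incompatible measures are rejected", {
  expect_error(cell_params(0, 0.3, 0.4, 0.5), "strictly")
  expect_error(cell_params(0.2, 1, 0.4, 0.5), "strictly")
  cells <- table2_cells()
  expect_error(conditional_effect(cells, 0, "mean_difference"), "continuous")
  cc <- noiseless_cells()
  expect_error(conditional_effect(cc, 0, "odds_ratio"), "binary")
  expect_error(estimand_spec("A_GIVEN_NO_B", "odds_ratio", pi = 0.5), "pi")
  expect_error(estimand_spec("A_USUAL_PRACTICE", "odds_ratio"), "pi")
})

test_that("cell parameters read back from JSON and YAML configs", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"p00":0.5,"p10":0.333,"p01":0.091,"p11":0.048,
               "outcome_type":"binary"}', path)
  cj <- cell_params_from_config(path)
  expect_equal(cj$p10, 0.333)
  ypath <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("p00: 0", "p10: 1", "p01: 2", "p11: 3",
               "outcome_type: continuous", "sigma: 1.5"), ypath)
  cy <- cell_params_from_config(ypath)
  expect_equal(cy$sigma, 1.5)
  expect_identical(cy$outcome_type, "continuous")
})
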