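make_2x2 <- function(n1, e1, n0, e0) {
  # n1 cases with e1 exposed, n0 controls with e0 exposed
  y <- rep(c(1, 0), c(n1, n0))
  x <- c(rep(c(1, 0), c(e1, n1 - e1)), rep(c(1, 0), c(e0, n0 - e0)))
  list(y = y, x = x)
}

test_that("ML engine reproduces the closed-form 2x2 odds ratio", {
  d <- make_2x2(100, 30, 100, 10)
  res <- fit_logistic_ml(regression_spec(d$y, d$x))
  expect_equal(res$or_, (30 * 90) / (70 * 10), tolerance = 1e-6)
  expect_equal(res$n_cases_exposed, 30)
  expect_equal(res$n_controls_exposed, 10)
  # label swap negates the log odds ratio
  res2 <- fit_logistic_ml(regression_spec(1 - d$y, d$x))
  expect_equal(res2$beta, -res$beta, tolerance = 1e-8)
})

test_that("degenerate designs are rejected with clear errors", {
  d <- make_2x2(50, 10, 50, 5)
  expect_error(regression_spec(d$y, rep(0, 100)), "constant")
  expect_error(regression_spec(rep(1, 100), d$x), "single class")
  # separation: exposure perfectly predicts outcome
  sep <- make_2x2(20, 20, 20, 0)
  expect_error(fit_logistic_ml(regression_spec(sep$y, sep$x)), "firth")
})

test_that("Firth engine matches the penalized-likelihood oracle and Haldane 2x2", {
  # zero-cell table: 0/50 exposed cases, 10/50 exposed controls
  d <- make_2x2(50, 0, 50, 10)
  res <- fit_logistic_firth(regression_spec(d$y, d$x, engine = "firth"))
  haldane <- (0.5 * 40.5) / (50.5 * 10.5)
  expect_equal(res$or_, haldane, tolerance = 1e-4)
  # independent numerical maximization of the penalized likelihood
  X <- cbind(1, d$x)
  expect_equal(res$beta, firth_oracle(X, d$y)[2], tolerance = 1e-4)
  # non-degenerate table agrees with the oracle too
  d2 <- make_2x2(80, 25, 120, 12)
  res2 <- fit_logistic_firth(regression_spec(d2$y, d2$x, engine = "firth"))
  expect_equal(res2$beta, firth_oracle(cbind(1, d2$x), d2$y)[2],
               tolerance = 1e-4)
})

test_that("Firth estimates stay finite under complete separation", {
  sep <- make_2x2(20, 20, 20, 0)
  res <- fit_logistic_firth(regression_spec(sep$y, sep$x, engine = "firth"))
  expect_true(is.finite(res$beta))
  expect_true(res$converged)
  # symmetric balanced null: OR is 1 up to numerical tolerance
  nul <- make_2x2(100, 20, 100, 20)
  res0 <- fit_logistic_firth(regression_spec(nul$y, nul$x, engine = "firth"))
  expect_equal(res0$or_, 1, tolerance = 1e-6)
  # fit_burden falls back to Firth on separation with a warning
  expect_warning(fb <- fit_burden(regression_spec(sep$y, sep$x)), "Firth")
  expect_true(is.finite(fb$beta))
  expect_equal(fb$engine, "firth")
})

test_that("Bonferroni adjustment is clipped, monotone arithmetic", {
  d <- make_2x2(100, 30, 100, 10)
  res <- fit_logistic_ml(regression_spec(d$y, d$x, bonferroni_m = 14))
  expect_equal(res$p_adjusted, min(1, 14 * res$p_raw))
  expect_gte(res$p_adjusted, res$p_raw)
  # p_adjusted nondecreasing in m, clipped at 1
  ps <- vapply(c(1, 14, 1e5, 1e7), function(m)
    fit_logistic_ml(regression_spec(d$y, d$x, bonferroni_m = m))$p_adjusted,
    numeric(1))
  expect_true(all(diff(ps) >= 0))
  expect_equal(ps[4], 1)
})

test_that("subset burden reports all subsets and flags low information", {
  set.seed(1)
  n <- 400
  cases <- data.frame(case_status = "case", sex = sample(c("m", "f"), n, TRUE))
  covars <- data.frame(sex = cases$sex, pc1 = rnorm(n))
  carrier <- rbinom(n, 1, 0.2) == 1
  flags <- list(severe = rbinom(n, 1, 0.4) == 1,
                rare_subset = c(TRUE, TRUE, rep(FALSE, n - 2)))
  res <- suppressWarnings(
    subset_burden(cases, flags, carrier, covars, m = 14))
  expect_setequal(res$subset, c("severe", "rare_subset"))
  expect_equal(res$p_adjusted, pmin(1, 14 * res$p_raw))
})

test_that("severity adjustment attenuates mediated effects and is inert when orthogonal", {
  set.seed(2)
  n <- 4000
  # mediation: carrier raises severity, severity raises the subset outcome
  carrier <- rbinom(n, 1, 0.3) == 1
  severe <- rbinom(n, 1, plogis(-1 + 1.5 * carrier)) == 1
  outcome <- rbinom(n, 1, plogis(-1 + 1.2 * severe)) == 1
  cases <- data.frame(case_status = "case",
                      severity = ifelse(severe, "moderate_severe_profound",
                                        "mild"))
  covars <- data.frame(pc1 = rnorm(n))
  unadj <- subset_burden(cases, list(out = outcome), carrier, covars, m = 1)
  adj <- severity_adjusted_burden(cases, list(out = outcome), carrier, covars,
                                  m = 1)
  expect_lt(abs(adj$beta), abs(unadj$beta))
  # constant severity column is dropped with a warning; result is unadjusted
  cases2 <- data.frame(case_status = "case", severity = "mild")
  cases2 <- cases2[rep(1, n), , drop = FALSE]
  adj2 <- suppressWarnings(
    severity_adjusted_burden(cases2, list(out = outcome), carrier, covars,
                             m = 1))
  expect_equal(adj2$beta, unadj$beta, tolerance = 1e-8)
})

test_that("a twofold severe-stratum enrichment survives Bonferroni in most cohorts", {
  set.seed(20)
  hits <- vapply(1:30, function(i) {
    n <- 1000
    carrier <- rbinom(n, 1, 0.2) == 1
    # severe-stratum membership with a true odds ratio of 2 for carriers
    severe <- rbinom(n, 1, plogis(-0.7 + log(2) * carrier)) == 1
    cases <- data.frame(case_status = "case")[rep(1, n), , drop = FALSE]
    res <- subset_burden(cases, list(severe = severe), carrier,
                         data.frame(pc1 = rnorm(n)), m = 14)
    res$p_adjusted < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.7)
})

test_that("Wald test at the null rejects at close to the nominal rate", {
  set.seed(3)
  reps <- 400
  rej <- vapply(seq_len(reps), function(i) {
    n <- 2000
    x <- rbinom(n, 1, 0.1)
    y <- rbinom(n, 1, 0.3)
    fit_logistic_ml(regression_spec(y, x))$p_raw < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})
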