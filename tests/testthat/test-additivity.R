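sim_joint <- function(n = 3000, beta_rare = log(3), beta_pgs = -0.4,
                      gamma = 0, seed = 1) {
  set.seed(seed)
  carrier <- rbinom(n, 1, 0.1)
  pgs <- rnorm(n)
  p <- plogis(-0.5 + beta_rare * carrier + beta_pgs * pgs +
                gamma * carrier * pgs)
  list(y = rbinom(n, 1, p), carrier = carrier, pgs = pgs,
       covars = data.frame(sex = sample(c("m", "f"), n, TRUE),
                           pc1 = rnorm(n), pc2 = rnorm(n)))
}

test_that("information criteria match independent arithmetic and glm", {
  d <- sim_joint(800, seed = 10)
  mm <- multimodel_inference(d$y, d$carrier, d$pgs, d$covars)
  # oracle: stats::glm on the same four formulas
  df <- data.frame(y = d$y, carrier = d$carrier, pgs = d$pgs, d$covars)
  fits <- list(
    covariates_only = glm(y ~ sex + pc1 + pc2, binomial, df),
    pgs_only = glm(y ~ sex + pc1 + pc2 + pgs, binomial, df),
    rare_only = glm(y ~ sex + pc1 + pc2 + carrier, binomial, df),
    rare_plus_pgs = glm(y ~ sex + pc1 + pc2 + pgs + carrier, binomial, df))
  for (nm in names(fits)) {
    row <- mm[mm$model == nm, ]
    expect_equal(row$loglik, as.numeric(logLik(fits[[nm]])), tolerance = 1e-6)
    expect_equal(row$aic, AIC(fits[[nm]]), tolerance = 1e-6)
    expect_equal(row$bic, BIC(fits[[nm]]), tolerance = 1e-6)
    # hand arithmetic: aic = 2k - 2 loglik
    expect_equal(row$aic, 2 * row$k - 2 * row$loglik, tolerance = 1e-10)
    expect_equal(row$aicc,
                 row$aic + 2 * row$k * (row$k + 1) / (nrow(df) - row$k - 1),
                 tolerance = 1e-10)
  }
  # k = 3 (intercept + 2 terms), loglik = -100 -> AIC = 206
  expect_equal(2 * 3 - 2 * (-100), 206)
})

test_that("deltas are nonnegative with one zero, and invariant to loglik shifts", {
  d <- sim_joint(800, seed = 11)
  mm <- multimodel_inference(d$y, d$carrier, d$pgs, d$covars)
  for (crit in c("delta_aic", "delta_aicc", "delta_bic")) {
    expect_true(all(mm[[crit]] >= 0))
    expect_equal(sum(mm[[crit]] == 0), 1)
  }
  # nested models: adding terms never lowers the log-likelihood
  ll <- setNames(mm$loglik, mm$model)
  expect_gte(ll["pgs_only"], ll["covariates_only"])
  expect_gte(ll["rare_only"], ll["covariates_only"])
  expect_gte(ll["rare_plus_pgs"], ll["pgs_only"])
  expect_gte(ll["rare_plus_pgs"], ll["rare_only"])
  # a constant added to all logliks leaves deltas unchanged
  shift <- 7.3
  aic_shifted <- 2 * mm$k - 2 * (mm$loglik + shift)
  expect_equal(aic_shifted - min(aic_shifted), mm$delta_aic, tolerance = 1e-10)
})

test_that("AICc converges to AIC for large n", {
  for (k in c(5, 10, 15)) {
    correction <- 2 * k * (k + 1) / (1e5 - k - 1)
    expect_lt(correction, 0.01)
  }
})

test_that("interaction test recovers signs and falls back to Firth under separation", {
  d <- sim_joint(6000, beta_rare = log(4), beta_pgs = 0.5, gamma = 0,
                 seed = 12)
  res <- interaction_test(d$y, d$carrier, d$pgs, d$covars)
  expect_equal(res$term, c("carrier", "pgs", "carrier:pgs"))
  expect_gt(res$estimate[res$term == "carrier"], 0)
  expect_gt(res$estimate[res$term == "pgs"], 0)
  expect_equal(res$p_adjusted, pmin(1, 11 * res$p_raw))
  # complete separation in the carrier term: Firth keeps estimates finite
  y <- c(rep(1, 30), rep(0, 30))
  carrier <- y
  pgs <- rnorm(60)
  expect_warning(sep <- interaction_test(y, carrier, pgs, NULL), "Firth")
  expect_true(all(is.finite(sep$estimate)))
  expect_equal(unique(sep$engine), "firth")
})

test_that("interaction coefficient is near zero when the truth is additive", {
  d <- sim_joint(8000, gamma = 0, seed = 13)
  res <- interaction_test(d$y, d$carrier, d$pgs, d$covars)
  inter <- res[res$term == "carrier:pgs", ]
  expect_lt(abs(inter$estimate), 3 * inter$se)
})

test_that("model selection prefers the generating model", {
  d <- sim_joint(6000, beta_rare = log(4), beta_pgs = -0.5, seed = 14)
  mm <- multimodel_inference(d$y, d$carrier, d$pgs, d$covars)
  expect_equal(attr(mm, "ranking")[["aic"]], "rare_plus_pgs")
  expect_equal(attr(mm, "ranking")[["bic"]], "rare_plus_pgs")
  # pure-noise outcome: BIC should back the covariates-only model
  set.seed(15)
  wins <- vapply(1:60, function(i) {
    n <- 1500
    y <- rbinom(n, 1, 0.3)
    mm0 <- multimodel_inference(y, rbinom(n, 1, 0.1), rnorm(n),
                                data.frame(pc1 = rnorm(n)))
    attr(mm0, "ranking")[["bic"]] == "covariates_only"
  }, logical(1))
  expect_gte(mean(wins), 0.8)
})

test_that("reporting-score selection finds the causal trait and logs ties", {
  d <- sim_joint(4000, beta_pgs = -0.6, seed = 16)
  set.seed(17)
  scores <- list(adhd = rnorm(4000), cognitive = d$pgs, noise = rnorm(4000))
  sel <- select_reporting_score(d$y, d$carrier, scores, d$covars)
  expect_equal(unname(sel$best[["aic"]]), "cognitive")
  expect_equal(unname(sel$best[["bic"]]), "cognitive")
  # single candidate trivially wins
  one <- select_reporting_score(d$y, d$carrier, list(only = d$pgs), d$covars)
  expect_equal(unname(one$best[["aic"]]), "only")
  # exact duplicates tie; first in name order is kept, with a message
  expect_message(
    dup <- select_reporting_score(d$y, d$carrier,
                                  list(b_trait = d$pgs, a_trait = d$pgs),
                                  d$covars),
    "tie")
  expect_equal(unname(dup$best[["aic"]]), "a_trait")
})
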