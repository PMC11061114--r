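test_that("population prior uses the reference frequency or the combined formula", {
  expect_equal(population_prior(5, 1000, 1e-3, 25000, TRUE), 1e-3)
  # combined in-sample + reference formula when the reference is unusable
  expect_equal(population_prior(5, 1000, NA, 25000, FALSE), 4 / 26000)
  # singleton floors at q_min
  expect_equal(population_prior(1, 1000, NA, 25000, FALSE), 100 / 3e7)
  expect_equal(population_prior(1, 1000, NA, 25000, FALSE, q_min = 1e-6), 1e-6)
  expect_error(population_prior(1, 0, NA, 25000, FALSE), "positive")
  expect_error(population_prior(0, 10, NA, 25000, FALSE), ">= 1")
})

test_that("de novo posterior matches a direct plug-in of the formula", {
  site <- make_trio_site(pro = 1L, mo = 0L, fa = 0L, pl_other = 100L)
  q <- 100 / 3e7
  call <- call_de_novo(site, q)
  # independent arithmetic: normalized likelihoods from PL = (100, 0, 100)
  l_het <- c(1e-10, 1, 1e-10); l_het <- l_het / sum(l_het)
  l_ref <- c(1, 1e-10, 1e-10); l_ref <- l_ref / sum(l_ref)
  p_dn_data <- l_het[2] * l_ref[1] * l_ref[1]
  p_miss_data <- l_het[2] * (l_ref[2] * l_ref[1] + l_ref[1] * l_ref[2])
  prior_dn <- 1 / 3e7
  prior_miss <- 1 - (1 - q)^4
  expected <- prior_dn * p_dn_data /
    (prior_dn * p_dn_data + prior_miss * p_miss_data)
  expect_equal(call$p_dn, expected, tolerance = 1e-12)
  expect_gt(call$p_dn, 0.99)
  expect_equal(call$confidence, "HIGH")
})

test_that("caller fails hom-ref probands, uninformative PLs and low allele balance", {
  homref <- make_trio_site(pro = 0L)
  expect_equal(call_de_novo(homref, 1e-4)$confidence, "FAIL")
  expect_lt(call_de_novo(homref, 1e-4)$p_dn, 1e-6)
  flat <- make_trio_site(pro = 1L)
  flat[, c("pro_pl_homref", "pro_pl_het", "pro_pl_homalt")] <- 0L
  expect_equal(call_de_novo(flat, 1e-4)$confidence, "FAIL")
  skewed <- make_trio_site(pro = 1L, alt_frac = 0.05)
  expect_equal(call_de_novo(skewed, 1e-4)$confidence, "FAIL")
})

test_that("p_dn decreases monotonically in the prior frequency", {
  site <- make_trio_site(pro = 1L)
  qs <- c(100 / 3e7, 1e-4, 1e-3, 1e-2, 0.1, 0.49)
  p <- vapply(qs, function(q) call_de_novo(site, q)$p_dn, numeric(1))
  expect_true(all(diff(p) < 0))
})

test_that("expected de novo count is mutation-rate arithmetic with panel filters", {
  # sum of rates 1e-4 over 417 trios: lambda = 2 * 417 * 1e-4
  panel <- make_panel(sprintf("G%02d", 1:10), mu_lof = 1e-5)
  expect_equal(expected_de_novo(panel, 417, "lof"), 0.0834)
  expect_equal(expected_de_novo(panel, 0, "lof"), 0)
  expect_equal(expected_de_novo(panel, 200, "lof"),
               2 * expected_de_novo(panel, 100, "lof"))
  # weak-evidence, non-brain and biallelic genes are excluded
  mixed <- make_panel(c("A", "B", "C", "D"),
                      evidence = c("definitive", "other", "definitive",
                                   "definitive"),
                      requirement = c("monoallelic", "monoallelic",
                                      "biallelic", "monoallelic"),
                      brain = c(TRUE, TRUE, TRUE, FALSE), mu_lof = 1e-5)
  expect_equal(expected_de_novo(mixed, 100, "lof"), 2 * 100 * 1e-5)
  # hemizygous genes count male trios only
  hemi <- make_panel(c("A", "X1"),
                     requirement = c("monoallelic", "x_hemizygous"),
                     mu_lof = 1e-5)
  expect_equal(expected_de_novo(hemi, 100, "lof", n_male_trios = 60),
               2 * 100 * 1e-5 + 2 * 60 * 1e-5)
})

test_that("Poisson tail equals brute-force pmf summation", {
  # oracle: explicit sum of exp(-lambda) lambda^k / k!
  brute <- function(obs, lambda)
    1 - sum(exp(-lambda) * lambda^(0:(obs - 1)) / factorial(0:(obs - 1)))
  expect_equal(poisson_enrichment(3, 1), brute(3, 1), tolerance = 1e-12)
  expect_equal(poisson_enrichment(3, 1), 0.0803014, tolerance = 1e-6)
  for (lambda in c(0.1, 1, 5, 20))
    for (obs in c(1, 2, 10, 50))
      expect_lt(abs(poisson_enrichment(obs, lambda) - brute(obs, lambda)),
                1e-12)
  expect_equal(poisson_enrichment(0, 5), 1)
  expect_equal(poisson_enrichment(2, 0), .Machine$double.xmin)
})

test_that("Fisher's sum of logs matches the chi-square tail", {
  r <- combine_fisher(c(0.5, 0.5))
  expect_equal(r$chi2, -2 * 2 * log(0.5), tolerance = 1e-10)
  expect_equal(r$df, 4)
  expect_equal(r$p_combined, 0.5966, tolerance = 1e-4)
  expect_equal(combine_fisher(c(1, 1))$chi2, 0)
  expect_equal(combine_fisher(c(1, 1))$p_combined, 1)
  # single p-value is the identity
  expect_equal(combine_fisher(0.123)$p_combined, 0.123, tolerance = 1e-12)
  # combining concordant evidence strengthens it
  expect_lt(combine_fisher(c(0.01, 0.01))$p_combined, 0.01)
  expect_error(combine_fisher(numeric(0)), "no p-values")
  expect_warning(r0 <- combine_fisher(c(0, 0.5)), "clipped")
  expect_true(is.finite(r0$chi2))
})

test_that("stratified enrichment combines per-kit Poisson tests", {
  panel <- make_panel("GENE0001", mu_lof = 1e-4)
  sites <- rbind(make_trio_site(kit = "kit1", trio_id = "TRIO0001"),
                 make_trio_site(kit = "kit1", trio_id = "TRIO0002"))
  calls <- call_de_novo(sites, 1e-4)
  calls <- cbind(sites[, c("class", "capture_kit")], calls)
  roster <- data.frame(trio_id = c("TRIO0001", "TRIO0002"),
                       capture_kit = "kit1",
                       proband_sex = c("male", "female"))
  res <- stratified_enrichment(calls, roster, panel, "lof")
  # single stratum: combined p equals the stratum's Poisson p
  expect_equal(res$combined$p, res$per_kit$p, tolerance = 1e-12)
  expect_equal(res$per_kit$observed, 2)
  expect_equal(res$per_kit$expected, 2 * 2 * 1e-4)
  # strata present in the roster but with zero trios simply never appear
  expect_equal(nrow(res$per_kit), 1)
})

test_that("de novo subset regression corrects p-values and survives separation", {
  set.seed(19)
  n <- 500
  trio_cases <- data.frame(case_status = "case")[rep(1, n), , drop = FALSE]
  dn <- rbinom(n, 1, 0.1) == 1
  covars <- data.frame(sex = sample(c("m", "f"), n, TRUE), pc1 = rnorm(n))
  flags <- list(severe = rbinom(n, 1, 0.4) == 1)
  res <- denovo_subset_regression(trio_cases, dn, flags, covars, m = 14)
  expect_equal(res$p_adjusted, pmin(1, 14 * res$p_raw))
  # all carriers inside one subset: complete separation, Firth takes over
  sep_flag <- list(sep = dn)
  res2 <- suppressWarnings(
    denovo_subset_regression(trio_cases, dn, sep_flag, covars, m = 14))
  expect_true(is.finite(res2$beta))
  expect_equal(res2$engine, "firth")
})

test_that("caller is perfect on noiseless simulated trios", {
  cfg <- small_config(n_trios = 200, trio_noise = 0, seed = 77,
                      dn_rate_multiplier = 40)
  panel <- simulate_gene_panel(cfg)
  tr <- simulate_trios(cfg, panel)
  q <- population_prior(tr$ac_insample, tr$an_insample, tr$ref_af_fin,
                        tr$ref_an_fin, tr$ref_usable)
  calls <- call_de_novo(tr, q)
  expect_true(sum(tr$true_dn) > 0)
  expect_equal(mean(calls$confidence[tr$true_dn] == "HIGH"), 1)
  expect_equal(sum(calls$confidence[!tr$true_dn] == "HIGH"), 0)
})
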