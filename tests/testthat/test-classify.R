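test_that("damage classification applies strict score thresholds", {
  v <- make_variants(4,
    consequence = c("missense", "missense", "stop_gained", "stop_gained"),
    lof_hc = c(FALSE, FALSE, FALSE, TRUE),
    mpc = c(2.5, 2.0, NA, NA), cadd = c(18, 18, 35, 35))
  got <- classify_damage(v, "heterozygous")
  expect_equal(got, c("DAMAGING_MISSENSE",  # mpc 2.5 > 2
                      "NOT_DAMAGING",       # mpc 2.0 fails strict inequality
                      "NOT_DAMAGING",       # LOF without high-confidence flag
                      "HC_LOF"))
  # homozygous context switches to CADD
  hom <- make_variants(3, consequence = "missense",
                       mpc = c(3, 1, NA), cadd = c(19, 25, 20))
  expect_equal(classify_damage(hom, "homozygous"),
               c("NOT_DAMAGING", "DAMAGING_MISSENSE", "NOT_DAMAGING"))
  # missing scores fail closed
  expect_equal(classify_damage(make_variants(1, consequence = "missense"),
                               "heterozygous"), "NOT_DAMAGING")
  expect_warning(
    got <- classify_damage(make_variants(1, consequence = "weird"), "heterozygous"),
    "unknown consequence")
  expect_equal(got, "NOT_DAMAGING")
})

test_that("rarity filter modes follow the reference-database rules", {
  v <- make_variants(3,
    ref_ac = c(0L, 0L, 5L), ref_hom = c(0L, 0L, 0L),
    present_in_controls = c(FALSE, TRUE, FALSE))
  expect_equal(rarity_filter(v, "dominant_burden"), c(TRUE, TRUE, FALSE))
  # homozygote filter ignores the allele count
  expect_equal(rarity_filter(v, "recessive_burden"), c(TRUE, TRUE, TRUE))
  expect_equal(rarity_filter(v, "subset_comparison"), c(TRUE, FALSE, FALSE))
  # missing reference fields fail closed, with a logged count
  vm <- make_variants(2, ref_ac = c(NA_integer_, 0L))
  expect_message(got <- rarity_filter(vm, "dominant_burden"), "1 variant")
  expect_equal(got, c(FALSE, TRUE))
})

test_that("Finnish enrichment requires twofold frequency or total absence", {
  v <- make_variants(4,
    af_fin = c(1e-3, 1e-3, 0, 8e-4),
    af_nfe = c(4e-4, 6e-4, 0, 4e-4),
    ref_ac = c(10L, 10L, 0L, 12L))
  expect_equal(finnish_enriched(v), c(TRUE,   # 2.5-fold
                                      FALSE,  # 1.67-fold
                                      TRUE,   # absent from the reference db
                                      TRUE))  # exactly twofold: ties count
})

test_that("carrier flags respect inheritance requirement and zygosity", {
  panel <- make_panel(c("DOM1", "REC1", "WEAK1", "XH1"),
                      evidence = c("definitive", "strong", "other", "strong"),
                      requirement = c("monoallelic", "biallelic",
                                      "monoallelic", "x_hemizygous"))
  v <- rbind(
    make_variants(1, variant_id = "hc", gene = "DOM1",
                  consequence = "stop_gained", lof_hc = TRUE),
    make_variants(1, variant_id = "recmis", gene = "REC1",
                  consequence = "missense", cadd = 25),
    make_variants(1, variant_id = "bimis", gene = "REC1",
                  consequence = "missense", mpc = 2.5),
    make_variants(1, variant_id = "weak", gene = "WEAK1",
                  consequence = "stop_gained", lof_hc = TRUE),
    make_variants(1, variant_id = "xh", gene = "XH1",
                  consequence = "stop_gained", lof_hc = TRUE))
  g <- data.frame(
    individual_id = c("A", "B", "C", "D", "E"),
    variant_id = c("hc", "recmis", "bimis", "weak", "xh"),
    genotype = c("het", "hom", "het", "het", "hemi"),
    stringsAsFactors = FALSE)
  cs <- carrier_status(g, v, panel, individuals = c("A", "B", "C", "D", "E"))
  expect_equal(cs$carriers$dominant_carrier, c(TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(cs$carriers$recessive_carrier, c(FALSE, TRUE, FALSE, FALSE, FALSE))
  # hemizygous path can be switched off
  cs2 <- carrier_status(g, v, panel, count_x_hemizygous = FALSE,
                        individuals = c("A", "B", "C", "D", "E"))
  expect_false(cs2$carriers$dominant_carrier[5])
  expect_error(
    carrier_status(data.frame(individual_id = "A", variant_id = "nope",
                              genotype = "het"), v, panel),
    "unknown variant")
})

test_that("diagnostic predicates compose order-independently", {
  cfg <- small_config(seed = 9)
  sim <- simulate_cohort(cfg)
  panel <- simulate_gene_panel(cfg)
  vt <- simulate_variant_table(cfg, sim$truth, panel)
  v <- vt$variants
  # evaluate the pure predicates in both orders; the conjunction must agree
  a <- rarity_filter(v, "dominant_burden") &
    classify_damage(v, "heterozygous") != "NOT_DAMAGING"
  b <- classify_damage(v, "heterozygous") != "NOT_DAMAGING" &
    rarity_filter(v, "dominant_burden")
  expect_identical(a, b)
})

test_that("yield arithmetic rounds half away from zero and handles edge cases", {
  expect_equal(round_half_away(0.125, 2), 0.13)
  expect_equal(round_half_away(-0.125, 2), -0.13)
  expect_equal(round_half_away(2.5), 3)
  tab <- diagnostic_summary(data.frame(
    subset = c("a", "b", "empty"),
    dominant = c(10L, 0L, 0L), recessive = c(5L, 0L, 0L),
    denominator = c(100L, 50L, 0L)))
  expect_equal(tab$total, c(15L, 0L, 0L))
  expect_equal(tab$total_pct[2], 0)             # zero carriers: 0.0%, not NA
  expect_true(is.na(tab$total_pct[3]))          # empty subset: undefined
  expect_equal(tab$dominant_pct[1], 10)
})

test_that("subset yields weighted by subset size reproduce the overall rate", {
  cfg <- small_config(seed = 5)
  sim <- simulate_cohort(cfg)
  panel <- simulate_gene_panel(cfg)
  vt <- simulate_variant_table(cfg, sim$truth, panel)
  cs <- carrier_status(vt$genotypes, vt$variants, panel,
                       individuals = sim$cohort$id)
  yl <- diagnostic_yield(cs$carriers, sim$cohort, classified = cs$classified)
  overall <- yl[yl$subset == "all_cases", ]
  parts <- yl[yl$subset %in% c("moderate_severe_profound",
                               "mild_or_unspecified"), ]
  # severity strata partition the cases
  expect_equal(sum(parts$denominator), overall$denominator)
  expect_equal(sum(parts$total), overall$total)
  weighted <- sum(parts$total_pct_direct * parts$denominator) /
    overall$denominator
  expect_equal(weighted, overall$total_pct_direct, tolerance = 0.02)
})
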