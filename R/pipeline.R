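#' Run the full simulate-to-inference pipeline
#'
#' Executes the stages in dependency order on a synthetic cohort: simulate
#' (cohort, panel, variants, trios), classify (carrier status and diagnostic
#' yield), de novo (calling plus capture-kit-stratified enrichment), burden
#' (case-control and severity-adjusted regressions), polygenic scores
#' (normalization and case-control contrasts) and additivity (interaction
#' test and multimodel inference). Each stage writes its tables under
#' \code{outdir} together with a manifest recording the seed, thresholds and
#' record counts; a failure halts the run with the stage name in the error.
#'
#' @param config a \code{\link{sim_config}}.
#' @param outdir output directory (created if missing); NULL keeps
#'   everything in memory.
#' @return named list of stage outputs, invisibly also written to
#'   \code{outdir}.
#' @export
run_pipeline <- function(config = sim_config(), outdir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  emit <- function(x, name) {
    if (!is.null(outdir) && is.data.frame(x))
      write_tsv(x, file.path(outdir, paste0(name, ".tsv")))
    x
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  counts <- list()

  sim <- stage("simulate", {
    cs <- simulate_cohort(config)
    panel <- simulate_gene_panel(config)
    vt <- simulate_variant_table(config, cs$truth, panel)
    trios <- simulate_trios(config, panel)
    list(cohort = emit(cs$cohort, "cohort"), truth = cs$truth,
         panel = emit(panel, "panel"),
         variants = emit(vt$variants, "variants"),
         genotypes = emit(vt$genotypes, "genotypes"),
         trios = emit(trios, "trios"))
  })
  counts$simulate <- c(individuals = nrow(sim$cohort),
                       variants = nrow(sim$variants),
                       trio_sites = nrow(sim$trios))

  cls <- stage("classify", {
    cs <- carrier_status(sim$genotypes, sim$variants, sim$panel,
                         individuals = sim$cohort$id)
    yield <- diagnostic_yield(cs$carriers, sim$cohort,
                              classified = cs$classified)
    list(carriers = emit(cs$carriers, "carriers"),
         classified = emit(cs$classified, "classified"),
         yield = emit(yield, "yield"))
  })
  counts$classify <- c(dominant_carriers = sum(cls$carriers$dominant_carrier),
                       recessive_carriers = sum(cls$carriers$recessive_carrier))

  dn <- stage("denovo", if (nrow(sim$trios) == 0) NULL else {
    q <- population_prior(sim$trios$ac_insample, sim$trios$an_insample,
                          sim$trios$ref_af_fin, sim$trios$ref_an_fin,
                          sim$trios$ref_usable)
    calls <- call_de_novo(sim$trios, q)
    site_calls <- cbind(sim$trios[, c("class", "capture_kit", "gene")],
                        calls)
    trio_meta <- trio_roster(sim$trios)
    enr <- lapply(c("lof", "mis", "syn"), function(cl)
      stratified_enrichment(site_calls, trio_meta, sim$panel, cl))
    names(enr) <- c("lof", "mis", "syn")
    enrichment <- do.call(rbind, lapply(enr, function(e)
      cbind(e$per_kit, chi2 = NA_real_, df = NA_integer_)))
    combined <- do.call(rbind, lapply(enr, `[[`, "combined"))
    list(calls = emit(calls, "denovo_calls"),
         enrichment_per_kit = emit(enrichment, "denovo_enrichment_per_kit"),
         enrichment_combined = emit(combined, "denovo_enrichment_combined"))
  })

  covars <- function(d) cbind(
    data.frame(sex = d$sex),
    d[, grep("^pc", names(d)), drop = FALSE])

  burd <- stage("burden", {
    coh <- sim$cohort
    m <- match(coh$id, cls$carriers$individual_id)
    dom <- cls$carriers$dominant_carrier[m]
    rec <- cls$carriers$recessive_carrier[m]
    y <- coh$case_status == "case"
    dominant <- fit_burden(regression_spec(y, dom, covars(coh), "ml"))
    recessive <- fit_logistic_firth(
      regression_spec(y, rec, covars(coh), "firth"))
    cases <- coh[y, , drop = FALSE]
    flags <- list(
      moderate_severe_profound =
        cases$severity == "moderate_severe_profound",
      relative_with_id = cases$relative_with_id,
      epilepsy = cases$epilepsy,
      sensory_disability = cases$sensory_disability,
      dysmorphism = cases$dysmorphism,
      psychosis = cases$psychosis,
      behavioral = cases$behavioral)
    subs <- subset_burden(cases, flags, dom[y],
                          cbind(covars(cases), batch = cases$batch))
    list(dominant = emit(dominant, "burden_dominant"),
         recessive = emit(recessive, "burden_recessive"),
         subsets = emit(subs, "burden_subsets"))
  })

  pgs <- stage("pgs", {
    coh <- sim$cohort
    is_ctrl <- coh$case_status == "control"
    traits <- config$pgs_traits
    norm <- lapply(traits, function(tr)
      normalize_scores(coh[[paste0("pgs_", tr)]], is_ctrl))
    names(norm) <- traits
    contrasts <- do.call(rbind, lapply(traits, function(tr) {
      cc <- case_control_contrast(norm[[tr]], coh$case_status, covars(coh))
      cbind(trait = tr, cc$contrast)
    }))
    list(normalized = norm, contrasts = emit(contrasts, "pgs_contrasts"))
  })

  add <- stage("additivity", {
    coh <- sim$cohort
    m <- match(coh$id, cls$carriers$individual_id)
    dom <- cls$carriers$dominant_carrier[m]
    y <- coh$case_status == "case"
    sel <- select_reporting_score(y, dom, pgs$normalized, covars(coh))
    score <- pgs$normalized[[sel$best[["aic"]]]]
    inter <- interaction_test(y, dom, score, covars(coh))
    mmi <- multimodel_inference(y, dom, score, covars(coh))
    list(selected_trait = sel, interaction = emit(inter, "interaction"),
         models = emit(mmi, "model_comparison"))
  })

  manifest <- list(
    seed = config$seed,
    config = unclass(config),
    thresholds = list(mpc = 2, cadd = 20, q_min = 100 / 3e7,
                      p_high = 0.99, ab_high = 0.3, dp_high = 10,
                      p_fail = 0.5, ab_fail = 0.1,
                      bonferroni_subsets = 14, bonferroni_interaction = 11),
    counts = counts,
    r_version = as.character(getRversion()))
  if (!is.null(outdir))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)

  results <- list(sim = sim, classify = cls, denovo = dn, burden = burd,
                  pgs = pgs, additivity = add, manifest = manifest)
  if (!is.null(outdir))
    writeLines(make_report(results), file.path(outdir, "report.md"))
  invisible(results)
}

#' Render a human-readable report from pipeline outputs
#'
#' One markdown document summarizing diagnostic yield, burden odds ratios,
#' de novo enrichment, polygenic-score contrasts and the model-comparison
#' deltas. Sections whose stage output is absent are marked absent rather
#' than dropped.
#'
#' @param results list returned by \code{\link{run_pipeline}}.
#' @return character vector of markdown lines.
#' @export
make_report <- function(results) {
  fmt_tab <- function(df) {
    if (is.null(df) || !nrow(df)) return("(absent)")
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) signif(x, 4))
    c(paste(names(df), collapse = " | "),
      paste(rep("---", ncol(df)), collapse = " | "),
      apply(df, 1, paste, collapse = " | "))
  }
  out <- c("# Cohort analysis report", "",
           sprintf("Seed: %d", results$manifest$seed), "",
           "## Diagnostic yield", fmt_tab(results$classify$yield), "",
           "## Rare-variant burden",
           fmt_tab(rbind(cbind(comparison = "dominant_case_control",
                               results$burden$dominant),
                         cbind(comparison = "recessive_case_control",
                               results$burden$recessive))), "",
           "### Case-subset burden", fmt_tab(results$burden$subsets), "",
           "## De novo enrichment (combined across capture kits)",
           if (is.null(results$denovo)) "(absent: no trios supplied)"
           else fmt_tab(results$denovo$enrichment_combined), "",
           "## Polygenic-score contrasts", fmt_tab(results$pgs$contrasts), "",
           "## Rare-by-common additivity",
           fmt_tab(results$additivity$interaction), "",
           "### Model comparison", fmt_tab(results$additivity$models))
  out
}
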