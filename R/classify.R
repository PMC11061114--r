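#' Classify variant damage category
#'
#' A variant is \code{HC_LOF} if it is a high-confidence loss-of-function
#' call (stop-gained, splice-disrupting or frameshift with the
#' high-confidence flag and no warnings), \code{DAMAGING_MISSENSE} if it is a
#' missense variant with MPC > 2 in heterozygous context or CADD > 20 in
#' homozygous context (strict inequalities; missing scores fail the
#' threshold), otherwise \code{NOT_DAMAGING}. Unknown consequence strings are
#' classified \code{NOT_DAMAGING} with a warning.
#'
#' @param variants data.frame with columns consequence, lof_hc, mpc, cadd.
#' @param context "heterozygous" or "homozygous"; length 1 or one per variant.
#' @param mpc_threshold,cadd_threshold damage thresholds (strict).
#' @return character vector of categories, one per variant.
#' @export
classify_damage <- function(variants, context = "heterozygous",
                            mpc_threshold = 2, cadd_threshold = 20) {
  if (!all(context %in% c("heterozygous", "homozygous")))
    stop("context must be 'heterozygous' or 'homozygous'")
  context <- rep_len(context, nrow(variants))
  csq <- as.character(variants$consequence)
  unknown <- !(csq %in% .known_consequences)
  if (any(unknown))
    warning(sprintf("%d variant(s) with unknown consequence treated as NOT_DAMAGING",
                    sum(unknown)))
  cat_ <- rep("NOT_DAMAGING", nrow(variants))
  lof <- !is.na(variants$lof_hc) & variants$lof_hc & csq %in% .lof_consequences
  cat_[lof] <- "HC_LOF"
  mis <- csq == "missense" & !lof
  het_dam <- mis & context == "heterozygous" &
    !is.na(variants$mpc) & variants$mpc > mpc_threshold
  hom_dam <- mis & context == "homozygous" &
    !is.na(variants$cadd) & variants$cadd > cadd_threshold
  cat_[het_dam | hom_dam] <- "DAMAGING_MISSENSE"
  cat_
}

#' Reference-database rarity filter
#'
#' Three modes mirror the three analysis paths: \code{dominant_burden}
#' passes variants unreported in the reference database (allele count 0);
#' \code{recessive_burden} passes variants with no reference homozygotes
#' (reference allele count is irrelevant); \code{subset_comparison}
#' additionally requires absence from the study's own population controls.
#' Missing reference fields fail closed (variant excluded) with a message
#' reporting how many were dropped.
#'
#' @param variants data.frame with ref_ac, ref_hom, present_in_controls.
#' @param mode one of "dominant_burden", "recessive_burden",
#'   "subset_comparison".
#' @return logical vector, TRUE where the variant passes.
#' @export
rarity_filter <- function(variants,
                          mode = c("dominant_burden", "recessive_burden",
                                   "subset_comparison")) {
  mode <- match.arg(mode)
  pass <- switch(mode,
    dominant_burden = variants$ref_ac == 0,
    recessive_burden = variants$ref_hom == 0,
    subset_comparison = variants$ref_ac == 0 &
      !variants$present_in_controls)
  n_missing <- sum(is.na(pass))
  if (n_missing > 0) {
    message(sprintf("rarity_filter(%s): %d variant(s) with missing reference fields excluded",
                    mode, n_missing))
    pass[is.na(pass)] <- FALSE
  }
  pass
}

#' Flag Finnish-enriched variants
#'
#' A variant is Finnish-enriched if its Finnish reference allele frequency is
#' nonzero and at least twofold the maximum across all other reference
#' populations (ties count as enriched), or if it is absent from the
#' reference database entirely (reference allele count 0).
#'
#' @param variants data.frame with \code{af_fin}, other \code{af_*}
#'   population-frequency columns, and \code{ref_ac}.
#' @param af_cols names of the non-Finnish frequency columns; defaults to
#'   every column matching \code{^af_} except \code{af_fin}.
#' @return logical vector.
#' @export
finnish_enriched <- function(variants, af_cols = NULL) {
  if (is.null(af_cols))
    af_cols <- setdiff(grep("^af_", names(variants), value = TRUE), "af_fin")
  other <- if (length(af_cols))
    do.call(pmax, c(variants[af_cols], na.rm = TRUE)) else
    rep(0, nrow(variants))
  other[!is.finite(other)] <- 0
  absent <- variants$ref_ac == 0
  enriched <- !is.na(variants$af_fin) & variants$af_fin > 0 &
    variants$af_fin >= 2 * other
  absent | enriched
}

#' Per-individual carrier status from genotypes, classified variants and panel
#'
#' An individual is a dominant carrier if they have at least one diagnostic
#' heterozygous variant (HC-LOF or damaging missense, passing the rarity
#' filter) in a monoallelic-requirement panel gene with definitive or strong
#' evidence and brain/cognition effects; hemizygous genotypes in
#' x_hemizygous-requirement genes count toward the dominant flag when
#' \code{count_x_hemizygous} is on. A recessive carrier has at least one
#' diagnostic homozygous variant in a biallelic-requirement gene. An
#' individual may be both.
#'
#' @param genotypes data.frame (individual_id, variant_id, genotype in
#'   het/hom/hemi).
#' @param variants variant table (see \code{\link{simulate_variant_table}}).
#' @param panel gene panel table.
#' @param mode_dominant,mode_recessive rarity modes for the het and hom paths.
#' @param count_x_hemizygous count male hemizygous genotypes in
#'   x_hemizygous-requirement genes under the dominant flag.
#' @param individuals optional character vector of all individual ids, so
#'   that non-carriers appear with FALSE flags.
#' @return list with \code{carriers} (individual_id, dominant_carrier,
#'   recessive_carrier) and \code{classified} (one row per genotype record
#'   with category, zygosity context, diagnostic and Finnish-enrichment
#'   flags).
#' @export
carrier_status <- function(genotypes, variants, panel,
                           mode_dominant = "dominant_burden",
                           mode_recessive = "recessive_burden",
                           count_x_hemizygous = TRUE,
                           individuals = NULL) {
  unknown <- setdiff(genotypes$variant_id, variants$variant_id)
  if (length(unknown))
    stop(sprintf("genotypes reference %d unknown variant id(s), e.g. '%s'",
                 length(unknown), unknown[1]))
  idx <- match(genotypes$variant_id, variants$variant_id)
  v <- variants[idx, , drop = FALSE]
  gidx <- match(v$gene, panel$gene)
  in_panel <- !is.na(gidx) &
    panel$evidence[gidx] %in% c("definitive", "strong") &
    panel$brain_cognition[gidx]
  requirement <- ifelse(is.na(gidx), NA_character_,
                        panel$allelic_requirement[gidx])

  zygosity <- ifelse(genotypes$genotype == "hom", "homozygous", "heterozygous")
  category <- classify_damage(v, context = zygosity)
  damaging <- category != "NOT_DAMAGING"

  het_like <- genotypes$genotype %in% c("het", "hemi")
  dom_gene <- in_panel & (requirement == "monoallelic" |
    (count_x_hemizygous & requirement == "x_hemizygous" &
       genotypes$genotype == "hemi"))
  dom_diag <- het_like & damaging & dom_gene %in% TRUE &
    rarity_filter(v, mode_dominant)

  rec_gene <- in_panel & requirement == "biallelic"
  rec_diag <- genotypes$genotype == "hom" & damaging & rec_gene %in% TRUE &
    rarity_filter(v, mode_recessive)

  classified <- data.frame(
    individual_id = genotypes$individual_id,
    variant_id = genotypes$variant_id,
    gene = v$gene, genotype = genotypes$genotype,
    zygosity_context = zygosity, category = category,
    diagnostic = dom_diag | rec_diag,
    diagnostic_dominant = dom_diag, diagnostic_recessive = rec_diag,
    finnish_enriched = finnish_enriched(v),
    stringsAsFactors = FALSE)

  ids <- individuals %||% sort(unique(genotypes$individual_id))
  carriers <- data.frame(
    individual_id = ids,
    dominant_carrier = ids %in% classified$individual_id[dom_diag],
    recessive_carrier = ids %in% classified$individual_id[rec_diag],
    stringsAsFactors = FALSE)
  list(carriers = carriers, classified = classified)
}

#' Diagnostic-yield arithmetic
#'
#' Computes counts and percentages of diagnosed individuals from dominant and
#' recessive carrier counts, overall or per subset. Percentages are rounded
#' half-away-from-zero: the dominant and recessive rates at
#' \code{digits_overall} decimals, composition splits (LOF vs damaging
#' missense within each inheritance mode) at \code{digits_composition}
#' decimals. The total rate is reported two ways: \code{total_pct}, the sum
#' of the already-rounded dominant and recessive rates (the composition
#' convention used when a figure's overall rate must equal the sum of its
#' displayed parts), and \code{total_pct_direct}, rounded directly from
#' total/denominator. Empty subsets (denominator 0) report \code{NA}
#' percentages rather than 0.
#'
#' @param counts data.frame with columns \code{dominant}, \code{recessive},
#'   \code{denominator}, optionally \code{subset}, \code{dominant_lof},
#'   \code{recessive_lof}.
#' @param digits_overall,digits_composition decimal places for rate and
#'   composition percentages.
#' @return data.frame of counts and rounded percentages, one row per input
#'   row.
#' @export
diagnostic_summary <- function(counts, digits_overall = 2,
                               digits_composition = 1) {
  req <- c("dominant", "recessive", "denominator")
  if (!all(req %in% names(counts)))
    stop("counts needs columns dominant, recessive, denominator")
  out <- counts
  out$total <- counts$dominant + counts$recessive
  pct <- function(num, den, d) {
    p <- ifelse(den > 0, round_half_away(100 * num / den, d), NA_real_)
    p
  }
  out$dominant_pct <- pct(counts$dominant, counts$denominator, digits_overall)
  out$recessive_pct <- pct(counts$recessive, counts$denominator, digits_overall)
  out$total_pct <- out$dominant_pct + out$recessive_pct
  out$total_pct_direct <- pct(out$total, counts$denominator, digits_overall)
  zero <- !is.na(out$total_pct_direct) & out$total == 0
  out$total_pct[zero] <- 0
  if ("dominant_lof" %in% names(counts)) {
    out$dominant_lof_pct <- pct(counts$dominant_lof, counts$dominant,
                                digits_composition)
    out$dominant_missense_pct <- pct(counts$dominant - counts$dominant_lof,
                                     counts$dominant, digits_composition)
  }
  if ("recessive_lof" %in% names(counts)) {
    out$recessive_lof_pct <- pct(counts$recessive_lof, counts$recessive,
                                 digits_composition)
    out$recessive_missense_pct <- pct(counts$recessive - counts$recessive_lof,
                                      counts$recessive, digits_composition)
  }
  out
}

#' Diagnostic yield by cohort subset from carrier flags
#'
#' Builds the count table for \code{\link{diagnostic_summary}} from
#' per-individual carrier flags and a cohort table: one row overall (all
#' cases) plus one row per requested subset of cases. LOF splits are taken
#' from the classified variant detail when supplied.
#'
#' @param carriers carriers data.frame from \code{\link{carrier_status}}.
#' @param cohort cohort data.frame (id, case_status, subset columns).
#' @param subsets named list of logical expressions over cohort columns,
#'   given as functions of the cohort data.frame; default splits by severity
#'   and family history.
#' @param classified optional classified detail from
#'   \code{\link{carrier_status}} to add LOF/missense splits.
#' @param ... passed to \code{\link{diagnostic_summary}}.
#' @return the yield table from \code{\link{diagnostic_summary}}.
#' @export
diagnostic_yield <- function(carriers, cohort, subsets = NULL,
                             classified = NULL, ...) {
  cases <- cohort[cohort$case_status == "case", , drop = FALSE]
  m <- match(cases$id, carriers$individual_id)
  dom <- carriers$dominant_carrier[m] %in% TRUE
  rec <- carriers$recessive_carrier[m] %in% TRUE
  if (is.null(subsets))
    subsets <- list(
      moderate_severe_profound = function(d)
        d$severity == "moderate_severe_profound",
      mild_or_unspecified = function(d)
        d$severity %in% c("mild", "unspecified"),
      no_relative_with_id = function(d) !d$relative_with_id,
      relative_with_id = function(d) d$relative_with_id)
  lof_by <- function(keep, flag_col) {
    if (is.null(classified)) return(NA_integer_)
    det <- classified[classified$individual_id %in% cases$id[keep] &
                        classified[[flag_col]], , drop = FALSE]
    # count individuals whose (first) diagnostic variant is HC_LOF
    first <- det[!duplicated(det$individual_id), , drop = FALSE]
    sum(first$category == "HC_LOF")
  }
  rows <- list(data.frame(
    subset = "all_cases", dominant = sum(dom), recessive = sum(rec),
    denominator = nrow(cases),
    dominant_lof = lof_by(rep(TRUE, nrow(cases)), "diagnostic_dominant"),
    recessive_lof = lof_by(rep(TRUE, nrow(cases)), "diagnostic_recessive"),
    stringsAsFactors = FALSE))
  for (nm in names(subsets)) {
    keep <- subsets[[nm]](cases) %in% TRUE
    rows[[nm]] <- data.frame(
      subset = nm, dominant = sum(dom & keep), recessive = sum(rec & keep),
      denominator = sum(keep),
      dominant_lof = lof_by(keep, "diagnostic_dominant"),
      recessive_lof = lof_by(keep, "diagnostic_recessive"),
      stringsAsFactors = FALSE)
  }
  counts <- do.call(rbind, rows)
  rownames(counts) <- NULL
  if (all(is.na(counts$dominant_lof)))
    counts$dominant_lof <- counts$recessive_lof <- NULL
  diagnostic_summary(counts, ...)
}
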