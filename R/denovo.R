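#' Population allele-frequency prior for de novo calling
#'
#' Uses the reference-database Finnish allele frequency when the reference
#' record is usable; otherwise the combined frequency of the study samples
#' and the reference panel, \eqn{(AC_{in} - 1) / (AN_{in} + AN_{ref,FIN})}
#' (the proband's own allele is subtracted). The result is floored at
#' \code{q_min} so that singletons do not produce a zero prior.
#'
#' @param ac_insample in-sample allele count (>= 1: the proband's allele is
#'   counted).
#' @param an_insample in-sample allele number (> 0).
#' @param ref_af_fin reference Finnish allele frequency (may be NA).
#' @param ref_an_fin reference Finnish allele number.
#' @param ref_usable logical: reference record passed quality control and has
#'   consistent exome/genome frequencies.
#' @param q_min prior floor (default 100 / 3e7, the caller-family
#'   convention).
#' @return numeric prior frequency q, vectorized.
#' @export
population_prior <- function(ac_insample, an_insample, ref_af_fin,
                             ref_an_fin, ref_usable, q_min = 100 / 3e7) {
  if (any(an_insample == 0)) stop("an_insample must be positive")
  if (any(ac_insample < 1)) stop("ac_insample must be >= 1")
  use_ref <- ref_usable & !is.na(ref_af_fin)
  q <- ifelse(use_ref, ref_af_fin,
              (ac_insample - 1) / (an_insample + ref_an_fin))
  pmax(q, q_min)
}

.pl_lik <- function(pl_homref, pl_het, pl_homalt) {
  l <- cbind(10^(-pl_homref / 10), 10^(-pl_het / 10), 10^(-pl_homalt / 10))
  l / rowSums(l)
}

#' Call de novo variants from trio genotype likelihoods
#'
#' Per-member genotype likelihoods are recovered from phred-scaled PLs and
#' normalized. The posterior probability that a site is a true de novo
#' mutation weighs the de novo data likelihood (proband het, both parents
#' hom-ref) against the likelihood that a parental het was missed:
#' \deqn{P(DN|data) = \frac{\pi_{dn} P(data|DN)}{\pi_{dn} P(data|DN) + \pi_{miss}(q) P(data|missed het)}}
#' with \eqn{\pi_{dn} = 1/3\times10^7} and
#' \eqn{\pi_{miss} = 1 - (1-q)^4} (any of the four parental alleles).
#' A site is only a candidate de novo when het is the proband's most likely
#' genotype; other sites report \code{p_dn = 0} and FAIL, matching the
#' published caller's restriction to putative de novo (proband-het) calls.
#' Confidence tiers combine the posterior with proband allele balance and
#' depth; FAIL calls are excluded from enrichment counting.
#'
#' @param trios trio-site data.frame as produced by
#'   \code{\link{simulate_trios}} (per-member PL/AD/DP columns).
#' @param q population-frequency prior per site (see
#'   \code{\link{population_prior}}).
#' @param prior_dn de novo prior probability.
#' @param p_high,ab_high,dp_high HIGH-tier thresholds on posterior, allele
#'   balance and depth.
#' @param p_fail,ab_fail FAIL-tier thresholds.
#' @param p_medium MEDIUM-tier posterior threshold (between FAIL and HIGH).
#' @return data.frame: trio_id, variant_id, p_dn, confidence, prior_q.
#' @export
call_de_novo <- function(trios, q, prior_dn = 1 / 3e7,
                         p_high = 0.99, ab_high = 0.3, dp_high = 10,
                         p_fail = 0.5, ab_fail = 0.1, p_medium = 0.9) {
  stopifnot(length(q) %in% c(1L, nrow(trios)), all(q > 0 & q < 1))
  q <- rep_len(q, nrow(trios))
  lp <- .pl_lik(trios$pro_pl_homref, trios$pro_pl_het, trios$pro_pl_homalt)
  lm <- .pl_lik(trios$mo_pl_homref, trios$mo_pl_het, trios$mo_pl_homalt)
  lf <- .pl_lik(trios$fa_pl_homref, trios$fa_pl_het, trios$fa_pl_homalt)
  p_data_dn <- lp[, 2] * lm[, 1] * lf[, 1]
  p_data_miss <- lp[, 2] * (lm[, 2] * lf[, 1] + lm[, 1] * lf[, 2])
  prior_miss <- 1 - (1 - q)^4
  num <- prior_dn * p_data_dn
  den <- num + prior_miss * p_data_miss
  p_dn <- ifelse(den > 0, num / den, 0)
  # not a putative de novo unless het is the proband's most likely genotype
  candidate <- lp[, 2] >= lp[, 1] & lp[, 2] >= lp[, 3]
  p_dn[!candidate] <- 0

  ab <- ifelse(trios$pro_dp > 0,
               trios$pro_ad_alt / (trios$pro_ad_ref + trios$pro_ad_alt), 0)
  ab[!is.finite(ab)] <- 0
  uninformative <- trios$pro_pl_homref == trios$pro_pl_het &
    trios$pro_pl_het == trios$pro_pl_homalt
  confidence <- rep("LOW", nrow(trios))
  confidence[p_dn > p_medium] <- "MEDIUM"
  confidence[p_dn > p_high & ab >= ab_high & trios$pro_dp >= dp_high] <- "HIGH"
  confidence[p_dn <= p_fail | ab < ab_fail | uninformative] <- "FAIL"
  data.frame(trio_id = trios$trio_id, variant_id = trios$variant_id,
             p_dn = p_dn, confidence = confidence, prior_q = q,
             stringsAsFactors = FALSE)
}

#' Expected de novo count from per-gene mutation rates
#'
#' Restricts the panel to definitive/strong evidence, brain/cognition genes
#' with monoallelic, X-heterozygous or X-hemizygous allelic requirement, and
#' returns \eqn{\lambda = 2 n_{trios} \sum_g \mu_{class,g}}, counting
#' X-hemizygous genes over male-proband trios only.
#'
#' @param panel gene panel with mu_syn, mu_mis, mu_lof columns.
#' @param n_trios number of trios in the stratum.
#' @param class one of "syn", "mis", "lof".
#' @param n_male_trios number of male-proband trios (defaults to
#'   \code{n_trios}, i.e. hemizygous genes counted over all trios).
#' @return expected count lambda (>= 0).
#' @export
expected_de_novo <- function(panel, n_trios, class = c("lof", "mis", "syn"),
                             n_male_trios = n_trios) {
  class <- match.arg(class)
  mu <- panel[[paste0("mu_", class)]]
  keep <- panel$evidence %in% c("definitive", "strong") &
    panel$brain_cognition &
    panel$allelic_requirement %in% c("monoallelic", "x_heterozygous",
                                     "x_hemizygous")
  if (!any(keep)) return(0)
  hemi <- panel$allelic_requirement == "x_hemizygous"
  2 * n_trios * sum(mu[keep & !hemi]) + 2 * n_male_trios * sum(mu[keep & hemi])
}

#' One-sided Poisson enrichment p-value
#'
#' \eqn{p = P(X \ge observed)} for \eqn{X \sim Poisson(\lambda)};
#' zero observed gives p = 1, and the degenerate \eqn{\lambda = 0} with
#' positive observed count reports the smallest positive double rather
#' than 0.
#'
#' @param observed nonnegative integer count.
#' @param lambda expected count (>= 0).
#' @return upper-tail probability.
#' @export
poisson_enrichment <- function(observed, lambda) {
  stopifnot(observed >= 0, lambda >= 0, observed == round(observed))
  if (observed == 0) return(1)
  if (lambda == 0) return(.Machine$double.xmin)
  max(stats::ppois(observed - 1, lambda, lower.tail = FALSE),
      .Machine$double.xmin)
}

#' Fisher's sum-of-logs p-value combination
#'
#' \eqn{\chi^2 = -2 \sum_i \ln p_i} on 2k degrees of freedom. Zero p-values
#' are clipped to the smallest positive normal double with a warning; a
#' single p-value is returned unchanged (identity, not an error).
#'
#' @param p vector of p-values in (0, 1].
#' @return list(chi2, df, p_combined).
#' @export
combine_fisher <- function(p) {
  if (length(p) == 0) stop("no p-values to combine")
  if (any(p < 0 | p > 1)) stop("p-values must lie in (0, 1]")
  if (any(p == 0)) {
    warning("zero p-value(s) clipped to smallest positive normal double")
    p[p == 0] <- .Machine$double.xmin
  }
  chi2 <- -2 * sum(log(p))
  df <- 2L * length(p)
  list(chi2 = chi2, df = df,
       p_combined = stats::pchisq(chi2, df = df, lower.tail = FALSE))
}

#' Capture-kit-stratified de novo enrichment
#'
#' Counts HIGH-confidence de novo calls of one mutation class per capture
#' kit, compares each to its mutation-rate expectation with a one-sided
#' Poisson test, and combines the per-kit p-values with Fisher's sum of
#' logs. Kit strata with zero trios are dropped (not padded with p = 1).
#'
#' @param calls output of \code{\link{call_de_novo}} joined back to sites
#'   (must carry class and capture_kit columns; pass
#'   \code{cbind(trios, calls[...])} or use the site table with call columns
#'   merged).
#' @param trios data.frame of unique trios (trio_id, capture_kit,
#'   proband_sex) defining stratum sizes.
#' @param panel gene panel.
#' @param class mutation class to test ("lof", "mis", "syn").
#' @return list with \code{per_kit} data.frame (stratum, expected, observed,
#'   p) and \code{combined} (chi2, df, p, expected, observed).
#' @export
stratified_enrichment <- function(calls, trios, panel,
                                  class = c("lof", "mis", "syn")) {
  class <- match.arg(class)
  stopifnot(all(c("confidence", "class", "capture_kit") %in% names(calls)))
  trios <- unique(trios[, c("trio_id", "capture_kit", "proband_sex")])
  kits <- sort(unique(trios$capture_kit))
  rows <- list()
  for (k in kits) {
    tk <- trios[trios$capture_kit == k, , drop = FALSE]
    if (!nrow(tk)) next
    lam <- expected_de_novo(panel, nrow(tk), class,
                            n_male_trios = sum(tk$proband_sex == "male"))
    obs <- sum(calls$confidence == "HIGH" & calls$class == class &
                 calls$capture_kit == k)
    rows[[k]] <- data.frame(stratum = k, class = class, expected = lam,
                            observed = obs, p = poisson_enrichment(obs, lam),
                            stringsAsFactors = FALSE)
  }
  per_kit <- do.call(rbind, rows)
  rownames(per_kit) <- NULL
  fis <- combine_fisher(per_kit$p)
  list(per_kit = per_kit,
       combined = data.frame(stratum = "combined", class = class,
                             expected = sum(per_kit$expected),
                             observed = sum(per_kit$observed),
                             chi2 = fis$chi2, df = fis$df,
                             p = fis$p_combined, stringsAsFactors = FALSE))
}

#' De novo carrier burden across diagnostic subsets
#'
#' Among trio-sequenced cases, regresses each diagnostic-subset flag on the
#' de novo carrier flag with sex, principal components and sequencing batch
#' as covariates (ML engine with Firth fallback under separation), Bonferroni
#' corrected for the configured number of diagnostic comparisons.
#'
#' @param trio_cases cohort rows for cases with a sequenced trio.
#' @param dn_carrier logical vector: carries a HIGH-confidence de novo
#'   variant.
#' @param subset_flags named list of logical outcome flags.
#' @param covariates data.frame of covariates.
#' @param m Bonferroni comparison count.
#' @return data.frame as \code{\link{subset_burden}}.
#' @export
denovo_subset_regression <- function(trio_cases, dn_carrier, subset_flags,
                                     covariates, m = 14) {
  subset_burden(trio_cases, subset_flags, dn_carrier, covariates,
                m = m, engine = "ml")
}
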