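#' Configuration for the synthetic cohort generator
#'
#' Bundles every knob of the generator into a validated list. The defaults
#' describe the cohort structure the downstream analyses assume: a
#' case-control study from a founder population with roughly one quarter of
#' cases carrying a rare dominant-acting variant, a standard-normal polygenic
#' score with a protective-direction effect on case status, and trios
#' sequenced on a small number of capture kits. Case status follows an
#' additive logistic liability:
#' \deqn{logit P(case) = \beta_0 + \beta_R R + \beta_S S + \gamma R S}
#' where \eqn{R} is dominant rare-variant carrier status, \eqn{S} the causal
#' polygenic score, and \eqn{\gamma = 0} encodes the additive (no-interaction)
#' truth.
#'
#' @param n_cases,n_controls target numbers of cases and controls.
#' @param n_trios number of proband-mother-father trios.
#' @param n_genes_panel number of genes in the simulated curated panel
#'   (including weak-evidence and non-brain decoy genes).
#' @param carrier_freq_dominant population frequency of dominant rare-variant
#'   carriers (Bernoulli per individual).
#' @param carrier_freq_recessive population frequency of homozygous carriers
#'   of recessive-acting variants; these do not enter the liability and exist
#'   to exercise the recessive classification path.
#' @param beta0 log-odds intercept (baseline prevalence on the logit scale).
#' @param beta_rare log-odds added per dominant carrier.
#' @param beta_pgs log-odds per standard deviation of the causal polygenic
#'   score (negative: higher cognitive-trait score is protective).
#' @param gamma_interaction carrier-by-score interaction log-odds; 0 is the
#'   additive truth.
#' @param n_pcs number of ancestry principal components (independent standard
#'   normals with zero true effect).
#' @param n_batches,n_capture_kits numbers of sequencing batches / exome
#'   capture kits, assigned uniformly.
#' @param severity_carrier_odds odds multiplier by which carriers are enriched
#'   in the moderate/severe/profound severity stratum among cases.
#' @param severity_probs base severity distribution among non-carrier cases
#'   (mild, moderate_severe_profound, unspecified).
#' @param pgs_traits names of simulated polygenic scores; the first is the
#'   causal score \eqn{S}, the rest are independent noise traits.
#' @param prob_relative probability a case reports a relative with ID or a
#'   learning disability.
#' @param comorbidity_probs named probabilities of the comorbidity flags among
#'   cases (epilepsy, sensory_disability, dysmorphism, psychosis, behavioral).
#' @param dn_rate_multiplier multiplier on the mutation-rate-implied de novo
#'   planting rate in trios (1 = null; >1 simulates enrichment).
#' @param trio_noise probability of a noisy genotype-likelihood record per
#'   trio member at planted or inherited sites (0 = noiseless fixtures).
#' @param max_draw_factor rejection-sampling cap: at most
#'   \code{max_draw_factor * (n_cases + n_controls)} individuals are drawn
#'   before the generator gives up with an error.
#' @param seed integer seed fixing all randomness; two runs with an equal
#'   config are identical.
#' @return a validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_cases = 1096, n_controls = 4791, n_trios = 450,
                       n_genes_panel = 1142,
                       carrier_freq_dominant = 0.05,
                       carrier_freq_recessive = 0.004,
                       beta0 = stats::qlogis(0.01),
                       beta_rare = log(4), beta_pgs = -0.35,
                       gamma_interaction = 0,
                       n_pcs = 10, n_batches = 3, n_capture_kits = 3,
                       severity_carrier_odds = 2,
                       severity_probs = c(mild = 0.50,
                                          moderate_severe_profound = 0.30,
                                          unspecified = 0.20),
                       pgs_traits = c("cognitive_performance",
                                      "educational_attainment",
                                      "intelligence", "ADHD"),
                       prob_relative = 0.45,
                       comorbidity_probs = c(epilepsy = 0.20,
                                             sensory_disability = 0.15,
                                             dysmorphism = 0.25,
                                             psychosis = 0.08,
                                             behavioral = 0.30),
                       dn_rate_multiplier = 1,
                       trio_noise = 0,
                       max_draw_factor = 1000,
                       seed = 1L) {
  counts <- c(n_cases = n_cases, n_controls = n_controls, n_trios = n_trios,
              n_genes_panel = n_genes_panel, n_pcs = n_pcs,
              n_batches = n_batches, n_capture_kits = n_capture_kits)
  if (any(counts[c("n_cases", "n_controls", "n_genes_panel", "n_batches",
                   "n_capture_kits")] <= 0) || n_trios < 0 || n_pcs < 0)
    stop("counts must be positive (n_trios and n_pcs may be zero)")
  .check_prob(carrier_freq_dominant, "carrier_freq_dominant")
  .check_prob(carrier_freq_recessive, "carrier_freq_recessive")
  .check_prob(trio_noise, "trio_noise")
  if (abs(sum(severity_probs) - 1) > 1e-8 || length(severity_probs) != 3)
    stop("severity_probs must be 3 probabilities summing to 1")
  if (severity_carrier_odds <= 0) stop("severity_carrier_odds must be positive")
  if (dn_rate_multiplier < 0) stop("dn_rate_multiplier must be nonnegative")
  if (length(pgs_traits) < 1) stop("at least one polygenic-score trait required")
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be a finite integer")
  cfg <- list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
              n_trios = as.integer(n_trios),
              n_genes_panel = as.integer(n_genes_panel),
              carrier_freq_dominant = carrier_freq_dominant,
              carrier_freq_recessive = carrier_freq_recessive,
              beta0 = beta0, beta_rare = beta_rare, beta_pgs = beta_pgs,
              gamma_interaction = gamma_interaction,
              n_pcs = as.integer(n_pcs), n_batches = as.integer(n_batches),
              n_capture_kits = as.integer(n_capture_kits),
              severity_carrier_odds = severity_carrier_odds,
              severity_probs = severity_probs,
              pgs_traits = pgs_traits,
              prob_relative = prob_relative,
              comorbidity_probs = comorbidity_probs,
              dn_rate_multiplier = dn_rate_multiplier,
              trio_noise = trio_noise,
              max_draw_factor = max_draw_factor,
              seed = seed)
  class(cfg) <- "sim_config"
  cfg
}

# derived sub-seeds keep each simulate_* function independently deterministic
.sub_seed <- function(config, offset) (config$seed + offset) %% .Machine$integer.max

#' Simulate a case-control cohort under the additive liability model
#'
#' Draws individuals (carrier status, causal polygenic score, covariates)
#' until the configured numbers of cases and controls are reached, assigning
#' case status by the logistic liability in \code{\link{sim_config}}.
#' Severity among cases is drawn with carriers enriched in the
#' moderate/severe/profound stratum by \code{severity_carrier_odds};
#' comorbidity and family-history flags are drawn independently among cases.
#' Covariates (sex, PCs, batch, capture kit) are independent of the liability
#' so that they can be carried as adjustment variables without confounding
#' the simulated truth.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with elements \code{cohort} (one row per individual) and
#'   \code{truth} (per-individual carrier truth plus the pre-threshold case
#'   probability \code{p_case}, against which the liability arithmetic can be
#'   re-checked exactly).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.sub_seed(config, 0L))
  need_cases <- config$n_cases
  need_controls <- config$n_controls
  cap <- ceiling(config$max_draw_factor * (need_cases + need_controls))
  chunk <- max(2L * (need_cases + need_controls), 1000L)

  got <- list()
  drawn <- 0L
  n_cases_got <- 0L
  n_controls_got <- 0L
  while ((n_cases_got < need_cases || n_controls_got < need_controls) &&
         drawn < cap) {
    m <- min(chunk, cap - drawn)
    R <- stats::rbinom(m, 1L, config$carrier_freq_dominant)
    Rrec <- stats::rbinom(m, 1L, config$carrier_freq_recessive)
    S <- stats::rnorm(m)
    p <- stats::plogis(config$beta0 + config$beta_rare * R +
                         config$beta_pgs * S +
                         config$gamma_interaction * R * S)
    y <- stats::rbinom(m, 1L, p)
    keep_case <- y == 1L
    keep_control <- !keep_case
    # keep only as many as still needed, preserving draw order
    ci <- which(keep_case)
    if (length(ci) > need_cases - n_cases_got)
      ci <- ci[seq_len(need_cases - n_cases_got)]
    oi <- which(keep_control)
    if (length(oi) > need_controls - n_controls_got)
      oi <- oi[seq_len(need_controls - n_controls_got)]
    sel <- sort(c(ci, oi))
    if (length(sel)) {
      got[[length(got) + 1L]] <- data.frame(
        dominant_carrier = R[sel] == 1L,
        recessive_carrier = Rrec[sel] == 1L,
        causal_score = S[sel], p_case = p[sel],
        case = y[sel] == 1L)
      n_cases_got <- n_cases_got + length(ci)
      n_controls_got <- n_controls_got + length(oi)
    }
    drawn <- drawn + m
  }
  if (n_cases_got < need_cases || n_controls_got < need_controls)
    stop(sprintf(
      "could not reach %d cases and %d controls within %d draws; beta0 = %.3f is likely degenerate",
      need_cases, need_controls, cap, config$beta0))
  base <- do.call(rbind, got)
  n <- nrow(base)
  id <- sprintf("IND%05d", seq_len(n))

  sex <- sample(c("male", "female"), n, replace = TRUE, prob = c(0.58, 0.42))
  pcs <- matrix(stats::rnorm(n * config$n_pcs), nrow = n)
  colnames(pcs) <- paste0("pc", seq_len(config$n_pcs))
  batch <- factor(sample(paste0("batch", seq_len(config$n_batches)), n, TRUE))
  kit <- factor(sample(paste0("kit", seq_len(config$n_capture_kits)), n, TRUE))

  # severity among cases: multinomial with carrier enrichment on the severe
  # stratum (odds multiplied by severity_carrier_odds for carriers)
  severity <- rep("none", n)
  is_case <- base$case
  pr <- config$severity_probs
  sev_levels <- c("mild", "moderate_severe_profound", "unspecified")
  for (carrier in c(FALSE, TRUE)) {
    idx <- which(is_case & base$dominant_carrier == carrier)
    if (!length(idx)) next
    w <- pr
    if (carrier) {
      odds <- w["moderate_severe_profound"] /
        (1 - w["moderate_severe_profound"]) * config$severity_carrier_odds
      w["moderate_severe_profound"] <- odds / (1 + odds)
      rest <- 1 - w["moderate_severe_profound"]
      w[c("mild", "unspecified")] <- w[c("mild", "unspecified")] /
        sum(pr[c("mild", "unspecified")]) * rest
    }
    severity[idx] <- sample(sev_levels, length(idx), TRUE, prob = w)
  }

  flags <- matrix(FALSE, n, length(config$comorbidity_probs),
                  dimnames = list(NULL, names(config$comorbidity_probs)))
  relative_with_id <- rep(FALSE, n)
  ci <- which(is_case)
  relative_with_id[ci] <- stats::runif(length(ci)) < config$prob_relative
  for (f in names(config$comorbidity_probs))
    flags[ci, f] <- stats::runif(length(ci)) < config$comorbidity_probs[[f]]

  # polygenic scores: first trait is the causal score, others independent noise
  pgs <- matrix(stats::rnorm(n * length(config$pgs_traits)), nrow = n)
  pgs[, 1] <- base$causal_score
  colnames(pgs) <- paste0("pgs_", config$pgs_traits)

  cohort <- data.frame(
    id = id, sex = sex,
    case_status = ifelse(is_case, "case", "control"),
    severity = factor(severity, levels = c(sev_levels, "none")),
    relative_with_id = relative_with_id,
    flags, pcs, batch = batch, capture_kit = kit, pgs,
    stringsAsFactors = FALSE)
  truth <- data.frame(id = id,
                      dominant_carrier = base$dominant_carrier,
                      recessive_carrier = base$recessive_carrier,
                      causal_score = base$causal_score,
                      p_case = base$p_case)
  list(cohort = cohort, truth = truth)
}

#' Simulate a curated gene panel with per-gene mutation rates
#'
#' Emulates a developmental-disorder gene panel: evidence level, allelic
#' requirement, a brain/cognition organ flag, and per-haplotype
#' per-generation mutation probabilities for synonymous, missense and
#' loss-of-function classes. Genes with weak evidence, non-brain effects or
#' mismatched allelic requirement act as decoys for the classification
#' filters. At least one dominant-eligible and one recessive-eligible gene is
#' guaranteed.
#'
#' @param config a \code{\link{sim_config}}.
#' @return data.frame with columns gene, evidence, allelic_requirement,
#'   brain_cognition, mu_syn, mu_mis, mu_lof.
#' @export
simulate_gene_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.sub_seed(config, 1L))
  n <- config$n_genes_panel
  gene <- sprintf("GENE%04d", seq_len(n))
  evidence <- sample(c("definitive", "strong", "other"), n, TRUE,
                     prob = c(0.45, 0.30, 0.25))
  req <- sample(c("monoallelic", "biallelic", "x_heterozygous",
                  "x_hemizygous", "other"), n, TRUE,
                prob = c(0.45, 0.30, 0.05, 0.08, 0.12))
  brain <- stats::runif(n) < 0.8
  # log-normal per-gene rates, typical exome scale, capped under 1e-3;
  # chosen so a full panel over a few hundred trios expects a handful of
  # de novo events per class
  mu_syn <- pmin(stats::rlnorm(n, log(5e-6), 0.7), 9e-4)
  mu_mis <- pmin(stats::rlnorm(n, log(1e-5), 0.7), 9e-4)
  mu_lof <- pmin(stats::rlnorm(n, log(2.5e-6), 0.8), 9e-4)
  panel <- data.frame(gene = gene, evidence = evidence,
                      allelic_requirement = req, brain_cognition = brain,
                      mu_syn = mu_syn, mu_mis = mu_mis, mu_lof = mu_lof,
                      stringsAsFactors = FALSE)
  eligible_dom <- panel$evidence != "other" & panel$brain_cognition &
    panel$allelic_requirement == "monoallelic"
  eligible_rec <- panel$evidence != "other" & panel$brain_cognition &
    panel$allelic_requirement == "biallelic"
  if (!any(eligible_dom)) {
    panel$evidence[1] <- "definitive"; panel$brain_cognition[1] <- TRUE
    panel$allelic_requirement[1] <- "monoallelic"
  }
  if (!any(eligible_rec)) {
    panel$evidence[2] <- "strong"; panel$brain_cognition[2] <- TRUE
    panel$allelic_requirement[2] <- "biallelic"
  }
  panel
}

.eligible_genes <- function(panel, requirement) {
  panel$gene[panel$evidence %in% c("definitive", "strong") &
               panel$brain_cognition &
               panel$allelic_requirement == requirement]
}

#' Simulate a variant table and genotypes consistent with carrier truth
#'
#' Emits one qualifying variant per truth carrier (heterozygous
#' high-confidence LOF or damaging missense in a monoallelic panel gene for
#' dominant carriers; homozygous in a biallelic gene for recessive carriers),
#' plus a set of decoy variants that each classification filter must reject:
#' sub-threshold MPC, boundary MPC, nonzero reference allele count, missing
#' LOF confidence, synonymous consequence, weak-evidence gene,
#' inheritance-mismatched gene, sub-threshold CADD homozygote, nonzero
#' reference homozygote count, and a control-shared variant (the last is only
#' placed on individuals who are already carriers, so carrier truth is
#' preserved under every rarity mode). Applying the classification rules
#' downstream reproduces the carrier truth exactly.
#'
#' @param config a \code{\link{sim_config}}.
#' @param truth carrier-truth table from \code{\link{simulate_cohort}}.
#' @param panel gene panel from \code{\link{simulate_gene_panel}}.
#' @return list with \code{variants} (one row per variant; annotation,
#'   in-sample and reference frequency fields) and \code{genotypes}
#'   (individual_id, variant_id, genotype in het/hom).
#' @export
simulate_variant_table <- function(config, truth, panel) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.sub_seed(config, 2L))
  dom_genes <- .eligible_genes(panel, "monoallelic")
  rec_genes <- .eligible_genes(panel, "biallelic")
  weak_genes <- panel$gene[panel$evidence == "other"]
  if (!length(weak_genes)) weak_genes <- panel$gene[1]

  vid <- 0L
  variants <- list()
  genotypes <- list()
  add_variant <- function(gene, consequence, lof_hc, mpc, cadd,
                          ref_ac = 0L, ref_hom = 0L,
                          af_fin = 0, af_nfe = 0, af_afr = 0, af_eas = 0,
                          present_in_controls = FALSE,
                          carriers = character(), genotype = "het") {
    vid <<- vid + 1L
    id <- sprintf("var%05d", vid)
    variants[[vid]] <<- data.frame(
      variant_id = id,
      chrom = as.character(sample(1:22, 1)), pos = sample.int(2e8, 1),
      ref = sample(c("A", "C", "G", "T"), 1),
      alt = sample(c("A", "C", "G", "T"), 1),
      gene = gene, consequence = consequence, lof_hc = lof_hc,
      mpc = mpc, cadd = cadd,
      ac_insample = NA_integer_, an_insample = NA_integer_,
      hom_insample = NA_integer_,
      af_fin = af_fin, af_nfe = af_nfe, af_afr = af_afr, af_eas = af_eas,
      ref_ac = ref_ac, ref_hom = ref_hom,
      present_in_controls = present_in_controls,
      stringsAsFactors = FALSE)
    if (length(carriers))
      genotypes[[length(genotypes) + 1L]] <<- data.frame(
        individual_id = carriers, variant_id = id, genotype = genotype,
        stringsAsFactors = FALSE)
    id
  }

  dom_carriers <- truth$id[truth$dominant_carrier]
  for (ind in dom_carriers) {
    if (stats::runif(1) < 0.478) {
      add_variant(sample(dom_genes, 1),
                  sample(.lof_consequences, 1), TRUE,
                  mpc = NA_real_, cadd = stats::runif(1, 25, 45),
                  carriers = ind)
    } else {
      add_variant(sample(dom_genes, 1), "missense", FALSE,
                  mpc = stats::runif(1, 2.2, 4.0),
                  cadd = stats::runif(1, 21, 35),
                  carriers = ind)
    }
  }
  rec_carriers <- truth$id[truth$recessive_carrier]
  for (ind in rec_carriers) {
    finnish <- stats::runif(1) < 0.5
    af_fin <- if (finnish) stats::runif(1, 5e-4, 5e-3) else 0
    if (stats::runif(1) < 0.115) {
      add_variant(sample(rec_genes, 1),
                  sample(.lof_consequences, 1), TRUE,
                  mpc = NA_real_, cadd = stats::runif(1, 25, 45),
                  ref_ac = if (finnish) sample(1:20, 1) else 0L,
                  af_fin = af_fin, af_nfe = af_fin / stats::runif(1, 2, 10),
                  carriers = ind, genotype = "hom")
    } else {
      add_variant(sample(rec_genes, 1), "missense", FALSE,
                  mpc = stats::runif(1, 0, 3),
                  cadd = stats::runif(1, 21, 35),
                  ref_ac = if (finnish) sample(1:20, 1) else 0L,
                  af_fin = af_fin, af_nfe = af_fin / stats::runif(1, 2, 10),
                  carriers = ind, genotype = "hom")
    }
  }

  # decoys: each must be rejected by exactly the filter it names
  any_ids <- truth$id
  pick <- function(k) sample(any_ids, min(k, length(any_ids)))
  add_variant(sample(dom_genes, 1), "missense", FALSE, mpc = 1.2,
              cadd = 12, carriers = pick(3))                       # low MPC
  add_variant(sample(dom_genes, 1), "missense", FALSE, mpc = 2.0,
              cadd = 19, carriers = pick(2))                       # boundary MPC
  add_variant(sample(dom_genes, 1), "stop_gained", TRUE, NA_real_, 35,
              ref_ac = 3L, af_nfe = 2e-5, carriers = pick(3))      # reference AC > 0
  add_variant(sample(dom_genes, 1), "stop_gained", FALSE, NA_real_, 34,
              carriers = pick(2))                                  # LOF not high-confidence
  add_variant(sample(dom_genes, 1), "synonymous", FALSE, NA_real_, 2,
              carriers = pick(3))                                  # benign consequence
  add_variant(sample(weak_genes, 1), "stop_gained", TRUE, NA_real_, 38,
              carriers = pick(2))                                  # weak-evidence gene
  add_variant(sample(rec_genes, 1), "missense", FALSE, mpc = 2.5,
              cadd = 30, carriers = pick(2))                       # het in biallelic-only gene
  add_variant(sample(rec_genes, 1), "missense", FALSE, mpc = 1.0,
              cadd = 15, carriers = pick(2), genotype = "hom")     # hom below CADD threshold
  add_variant(sample(rec_genes, 1), "stop_gained", TRUE, NA_real_, 36,
              ref_ac = 8L, ref_hom = 2L, af_fin = 1e-3, af_nfe = 1e-3,
              carriers = pick(2), genotype = "hom")                # reference homozygotes exist
  if (length(dom_carriers))
    add_variant(sample(dom_genes, 1), "stop_gained", TRUE, NA_real_, 33,
                present_in_controls = TRUE,
                carriers = sample(dom_carriers,
                                  min(2, length(dom_carriers))))   # shared with controls

  variants <- do.call(rbind, variants)
  genotypes <- if (length(genotypes)) do.call(rbind, genotypes) else
    data.frame(individual_id = character(), variant_id = character(),
               genotype = character(), stringsAsFactors = FALSE)
  # in-sample allele bookkeeping from the genotype table
  an <- 2L * nrow(truth)
  alleles <- c(het = 1L, hom = 2L)[genotypes$genotype]
  ac <- tapply(alleles, genotypes$variant_id, sum)
  hom <- tapply(genotypes$genotype == "hom", genotypes$variant_id, sum)
  variants$ac_insample <- as.integer(ac[variants$variant_id])
  variants$ac_insample[is.na(variants$ac_insample)] <- 0L
  variants$hom_insample <- as.integer(hom[variants$variant_id])
  variants$hom_insample[is.na(variants$hom_insample)] <- 0L
  variants$an_insample <- an
  rownames(variants) <- NULL
  list(variants = variants, genotypes = genotypes)
}

#' Simulate trio genotype-likelihood records with known de novo truth
#'
#' Plants true de novo variants at the mutation-rate-implied Poisson rate
#' (2 per-haplotype rate summed over the dominant-eligible panel, times
#' \code{dn_rate_multiplier}), plus inherited heterozygous sites that a
#' caller must not label de novo. Each site carries phred-scaled genotype
#' likelihoods (PL), allelic depths (AD) and depth (DP) for proband, mother
#' and father. With \code{trio_noise = 0} the records are noiseless: the true
#' genotype has PL 0 and alternatives PL 99, depth 40, balanced het reads.
#'
#' @param config a \code{\link{sim_config}}.
#' @param panel gene panel from \code{\link{simulate_gene_panel}}.
#' @return data.frame with one row per trio-site: trio metadata, per-member
#'   PL/AD/DP, population-frequency prior inputs, and the truth label
#'   \code{true_dn}. The full trio roster (including trios with no sites,
#'   which still count toward enrichment stratum sizes) is attached as
#'   attribute \code{"roster"} and retrievable with \code{\link{trio_roster}}.
#' @export
simulate_trios <- function(config, panel) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.sub_seed(config, 3L))
  n_trios <- config$n_trios
  if (n_trios == 0)
    return(.empty_trio_table())
  kits <- paste0("kit", sample.int(config$n_capture_kits, n_trios, TRUE))
  sexes <- sample(c("male", "female"), n_trios, TRUE, prob = c(0.58, 0.42))
  roster <- data.frame(trio_id = sprintf("TRIO%04d", seq_len(n_trios)),
                       capture_kit = kits, proband_sex = sexes,
                       stringsAsFactors = FALSE)

  sub <- panel[panel$evidence %in% c("definitive", "strong") &
                 panel$brain_cognition &
                 panel$allelic_requirement %in%
                 c("monoallelic", "x_heterozygous", "x_hemizygous"), ]
  if (!nrow(sub)) return(.empty_trio_table(roster))
  hemi <- sub$allelic_requirement == "x_hemizygous"
  noise <- config$trio_noise
  an_insample <- 2L * (config$n_cases + config$n_controls)
  male <- sexes == "male"

  # planted de novos: per trio and class, Poisson with the trio's eligible
  # rate (hemizygous genes contribute for male probands only)
  site <- list()
  for (class in c("syn", "mis", "lof")) {
    mu <- sub[[paste0("mu_", class)]]
    lam <- 2 * config$dn_rate_multiplier *
      (sum(mu[!hemi]) + ifelse(male, sum(mu[hemi]), 0))
    k <- stats::rpois(n_trios, lam)
    if (sum(k) == 0) next
    trio <- rep(seq_len(n_trios), k)
    gene <- character(length(trio))
    for (grp in c(TRUE, FALSE)) {            # male / female probands
      rows_g <- male[trio] == grp
      if (!any(rows_g)) next
      pool <- if (grp) seq_len(nrow(sub)) else which(!hemi)
      gene[rows_g] <- sub$gene[sample(pool, sum(rows_g), replace = TRUE,
                                      prob = sub[[paste0("mu_", class)]][pool])]
    }
    site[[class]] <- data.frame(
      trio = trio, gene = gene, class = class,
      pro_g = 1L, mo_g = 0L, fa_g = 0L, true_dn = TRUE,
      ref_usable = FALSE, ref_af_fin = NA_real_, ac_insample = 1L,
      stringsAsFactors = FALSE)
  }
  # inherited het sites transmitted from one parent: caller must reject these
  k_inh <- stats::rpois(n_trios, 2)
  if (sum(k_inh) > 0) {
    trio <- rep(seq_len(n_trios), k_inh)
    n_i <- length(trio)
    from_mother <- stats::runif(n_i) < 0.5
    site$inherited <- data.frame(
      trio = trio,
      gene = sub$gene[sample.int(nrow(sub), n_i, replace = TRUE)],
      class = sample(c("syn", "mis", "lof"), n_i, replace = TRUE),
      pro_g = 1L, mo_g = as.integer(from_mother),
      fa_g = as.integer(!from_mother), true_dn = FALSE,
      ref_usable = TRUE, ref_af_fin = stats::runif(n_i, 1e-4, 1e-2),
      ac_insample = sample(2:50, n_i, replace = TRUE),
      stringsAsFactors = FALSE)
  }
  if (!length(site)) return(.empty_trio_table(roster))
  s <- do.call(rbind, site)
  s <- s[order(s$trio), , drop = FALSE]
  n_s <- nrow(s)

  # per-member genotype-likelihood blocks, vectorized; a "noisy" member has
  # degraded alternative-genotype likelihoods and thin, unbalanced depth
  member_block <- function(true_g, prefix) {
    noisy <- stats::runif(n_s) < noise
    pl <- matrix(99L, n_s, 3)
    pl[cbind(seq_len(n_s), true_g + 1L)] <- 0L
    if (any(noisy)) {
      deg <- matrix(pmax(99L - sample(60:99, 3 * n_s, TRUE), 0L), n_s, 3)
      pl[noisy, ] <- deg[noisy, ]
      pl[cbind(seq_len(n_s), true_g + 1L)] <- 0L
    }
    dp <- rep(40L, n_s)
    alt <- c(0L, 20L, 40L)[true_g + 1L]
    if (any(noisy)) {
      dp[noisy] <- 5L + stats::rpois(sum(noisy), 4)
      alt[noisy] <- stats::rbinom(sum(noisy), dp[noisy],
                                  c(0.02, 0.5, 0.98)[true_g[noisy] + 1L])
    }
    out <- data.frame(pl[, 1], pl[, 2], pl[, 3], dp - alt, alt, dp)
    names(out) <- paste0(prefix, c("_pl_homref", "_pl_het", "_pl_homalt",
                                   "_ad_ref", "_ad_alt", "_dp"))
    out
  }
  out <- cbind(
    data.frame(trio_id = sprintf("TRIO%04d", s$trio),
               variant_id = sprintf("tv%06d", seq_len(n_s)),
               gene = s$gene, class = s$class,
               capture_kit = kits[s$trio], proband_sex = sexes[s$trio],
               stringsAsFactors = FALSE),
    member_block(rep(s$pro_g, length.out = n_s), "pro"),
    member_block(s$mo_g, "mo"),
    member_block(s$fa_g, "fa"),
    data.frame(ac_insample = s$ac_insample, an_insample = an_insample,
               ref_af_fin = s$ref_af_fin, ref_an_fin = 25000L,
               ref_usable = s$ref_usable, true_dn = s$true_dn))
  rownames(out) <- NULL
  attr(out, "roster") <- roster
  out
}

#' Trio roster of a simulated trio-site table
#'
#' Returns the full set of simulated trios (trio_id, capture_kit,
#' proband_sex), including trios without any site record; these still count
#' toward the stratum sizes of the enrichment test. Falls back to the unique
#' trios present in the site table when no roster attribute is attached
#' (e.g. after a round trip through TSV).
#'
#' @param trio_sites table from \code{\link{simulate_trios}}.
#' @return data.frame with one row per trio.
#' @export
trio_roster <- function(trio_sites) {
  r <- attr(trio_sites, "roster")
  if (!is.null(r)) return(r)
  unique(trio_sites[, c("trio_id", "capture_kit", "proband_sex")])
}

.empty_trio_table <- function(roster = NULL) {
  cols <- c("trio_id", "variant_id", "gene", "class", "capture_kit",
            "proband_sex",
            "pro_pl_homref", "pro_pl_het", "pro_pl_homalt",
            "pro_ad_ref", "pro_ad_alt", "pro_dp",
            "mo_pl_homref", "mo_pl_het", "mo_pl_homalt",
            "mo_ad_ref", "mo_ad_alt", "mo_dp",
            "fa_pl_homref", "fa_pl_het", "fa_pl_homalt",
            "fa_ad_ref", "fa_ad_alt", "fa_dp",
            "ac_insample", "an_insample", "ref_af_fin", "ref_an_fin",
            "ref_usable", "true_dn")
  out <- as.data.frame(matrix(nrow = 0, ncol = length(cols)))
  names(out) <- cols
  if (!is.null(roster)) attr(out, "roster") <- roster
  out
}
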