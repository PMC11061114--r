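# in-code fixtures shared across test files

small_config <- function(...) {
  args <- list(...)
  defaults <- list(n_cases = 150, n_controls = 300, n_trios = 30,
                   n_genes_panel = 80, beta0 = stats::qlogis(0.2),
                   carrier_freq_dominant = 0.1,
                   carrier_freq_recessive = 0.02, seed = 42L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# minimal variant row(s) with sane defaults; override any field
make_variants <- function(n = 1, ...) {
  v <- data.frame(
    variant_id = sprintf("v%03d", seq_len(n)),
    chrom = "1", pos = seq_len(n), ref = "A", alt = "T",
    gene = "GENE0001", consequence = "missense", lof_hc = FALSE,
    mpc = NA_real_, cadd = NA_real_,
    ac_insample = 1L, an_insample = 1000L, hom_insample = 0L,
    af_fin = 0, af_nfe = 0, af_afr = 0, af_eas = 0,
    ref_ac = 0L, ref_hom = 0L, present_in_controls = FALSE,
    stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) v[[nm]] <- over[[nm]]
  v
}

make_panel <- function(genes = "GENE0001", evidence = "definitive",
                       requirement = "monoallelic", brain = TRUE,
                       mu_syn = 1e-6, mu_mis = 2e-6, mu_lof = 5e-7) {
  data.frame(gene = genes,
             evidence = rep_len(evidence, length(genes)),
             allelic_requirement = rep_len(requirement, length(genes)),
             brain_cognition = rep_len(brain, length(genes)),
             mu_syn = rep_len(mu_syn, length(genes)),
             mu_mis = rep_len(mu_mis, length(genes)),
             mu_lof = rep_len(mu_lof, length(genes)),
             stringsAsFactors = FALSE)
}

# one trio-site record built from member genotypes (0 hom-ref, 1 het, 2 hom-alt)
make_trio_site <- function(pro = 1L, mo = 0L, fa = 0L, dp = 40L,
                           alt_frac = 0.5, trio_id = "TRIO0001",
                           variant_id = "tv000001", kit = "kit1",
                           sex = "female", pl_other = 99L) {
  pl <- function(g) { p <- rep(pl_other, 3); p[g + 1L] <- 0L; p }
  alt <- function(g) as.integer(round(dp * c(0, alt_frac, 1)[g + 1L]))
  p <- pl(pro); m <- pl(mo); f <- pl(fa)
  data.frame(trio_id = trio_id, variant_id = variant_id, gene = "GENE0001",
             class = "lof", capture_kit = kit, proband_sex = sex,
             pro_pl_homref = p[1], pro_pl_het = p[2], pro_pl_homalt = p[3],
             pro_ad_ref = dp - alt(pro), pro_ad_alt = alt(pro), pro_dp = dp,
             mo_pl_homref = m[1], mo_pl_het = m[2], mo_pl_homalt = m[3],
             mo_ad_ref = dp - alt(mo), mo_ad_alt = alt(mo), mo_dp = dp,
             fa_pl_homref = f[1], fa_pl_het = f[2], fa_pl_homalt = f[3],
             fa_ad_ref = dp - alt(fa), fa_ad_alt = alt(fa), fa_dp = dp,
             ac_insample = 1L, an_insample = 10000L,
             ref_af_fin = NA_real_, ref_an_fin = 25000L,
             ref_usable = FALSE, true_dn = pro == 1L && mo == 0L && fa == 0L,
             stringsAsFactors = FALSE)
}

# independent oracle for the Firth engine: direct numerical maximization of
# the penalized log-likelihood, written without reference to the package's
# Newton iteration
firth_oracle <- function(X, y) {
  negpll <- function(b) {
    eta <- drop(X %*% b)
    p <- 1 / (1 + exp(-eta))
    I <- t(X) %*% (X * (p * (1 - p)))
    -(sum(y * eta - log(1 + exp(eta))) + 0.5 * log(det(I)))
  }
  stats::optim(rep(0, ncol(X)), negpll, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))$par
}
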