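#!/usr/bin/env Rscript
# Generate the synthetic study cohort: individuals with covariates and
# polygenic scores, carrier truth, a curated gene panel with mutation rates,
# a variant table with genotypes, and trio genotype-likelihood records.
# Downstream scripts (02-06) consume these tables from results/sim/.

suppressPackageStartupMessages(library(idburden))

outdir <- "results/sim"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

config <- sim_config(seed = 20260925L)
write_config_yaml(config, file.path(outdir, "config.yaml"))

sim <- simulate_cohort(config)
panel <- simulate_gene_panel(config)
vt <- simulate_variant_table(config, sim$truth, panel)
trios <- simulate_trios(config, panel)

write_tsv(sim$cohort, file.path(outdir, "cohort.tsv"))
write_tsv(sim$truth, file.path(outdir, "truth.tsv"))
write_tsv(panel, file.path(outdir, "panel.tsv"))
write_tsv(vt$variants, file.path(outdir, "variants.tsv"))
write_variants_vcf(vt$variants, file.path(outdir, "variants.vcf"))
write_tsv(vt$genotypes, file.path(outdir, "genotypes.tsv"))
write_tsv(trios, file.path(outdir, "trios.tsv"))
write_tsv(trio_roster(trios), file.path(outdir, "trio_roster.tsv"))

cat(sprintf("cohort: %d cases, %d controls (%d dominant / %d recessive truth carriers)\n",
            sum(sim$cohort$case_status == "case"),
            sum(sim$cohort$case_status == "control"),
            sum(sim$truth$dominant_carrier),
            sum(sim$truth$recessive_carrier)))
cat(sprintf("panel: %d genes; variants: %d (%d genotype records); trio sites: %d (%d true de novo)\n",
            nrow(panel), nrow(vt$variants), nrow(vt$genotypes),
            nrow(trios), sum(trios$true_dn)))
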