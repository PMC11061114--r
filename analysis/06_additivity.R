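#!/usr/bin/env Rscript
# Rare-by-common additivity: choose the reporting polygenic score by
# information criterion, test the carrier-by-score interaction (Bonferroni
# m = 11), and compare the four nested case-status models by AIC/AICc/BIC.

suppressPackageStartupMessages(library(idburden))

cohort <- read_tsv("results/sim/cohort.tsv")
carriers <- read_tsv("results/carriers.tsv")
dom <- carriers$dominant_carrier[match(cohort$id, carriers$individual_id)]
y <- cohort$case_status == "case"
is_ctrl <- !y
covars <- cbind(data.frame(sex = cohort$sex),
                cohort[, grep("^pc", names(cohort))])

traits <- sub("^pgs_", "", grep("^pgs_", names(cohort), value = TRUE))
scores <- lapply(traits, function(tr)
  normalize_scores(cohort[[paste0("pgs_", tr)]], is_ctrl))
names(scores) <- traits

sel <- select_reporting_score(y, dom, scores, covars)
write_tsv(sel$table, "results/pgs_model_ranking.tsv")
cat(sprintf("reporting score by AIC: %s; by BIC: %s\n",
            sel$best[["aic"]], sel$best[["bic"]]))
score <- scores[[sel$best[["aic"]]]]

inter <- interaction_test(y, dom, score, covars, m = 11)
write_tsv(inter, "results/interaction.tsv")
print(inter, row.names = FALSE)
cat("the generator is additive (no interaction term), so the carrier:pgs\n")
cat("coefficient should be compatible with zero\n")

mm <- multimodel_inference(y, dom, score, covars)
mm$best_aicc <- mm$delta_aicc == 0
mm$best_bic <- mm$delta_bic == 0
write_tsv(mm, "results/model_comparison.tsv")
print(mm[, c("model", "k", "loglik", "delta_aic", "delta_aicc",
             "delta_bic")], row.names = FALSE)
cat(sprintf("winner by AICc: %s; by BIC: %s\n",
            attr(mm, "ranking")[["aicc"]], attr(mm, "ranking")[["bic"]]))
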