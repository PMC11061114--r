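---
title: "Rare and common variant burden analysis: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare and common variant burden analysis: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idburden)
```

# Scope

`idburden` implements the analysis stages of a rare-plus-common variant
study of intellectual disability (ID) in a founder-population cohort:
variant classification and diagnostic yield, trio-based de novo calling and
mutation-rate enrichment testing, covariate-adjusted carrier-burden
regression (maximum-likelihood and Firth), control-normalized polygenic
score (PGS) contrasts, and rare-by-common additivity assessed by an
interaction test and by information-criterion comparison of nested models.
Because patient-level data of such studies are confidential, the package
ships a synthetic cohort generator that reproduces the statistical
structure these stages assume, so every stage is tested end to end against
known truth.

# The liability model behind the generator

Case status is generated from an additive logistic liability

$$\mathrm{logit}\, P(\text{case}) = \beta_0 + \beta_R R + \beta_S S + \gamma R S,$$

with $R$ the dominant rare-variant carrier indicator (Bernoulli with
population frequency `carrier_freq_dominant`), $S$ a standard-normal causal
polygenic score, and $\gamma = 0$ the additive default. A logistic rather
than probit/liability-threshold form was chosen deliberately: the
regression engines downstream estimate exactly $\beta_R$, $\beta_S$ and
$\gamma$, so parameter-recovery tests have closed-form truth. Individuals
are drawn by rejection until the configured case and control counts are
reached (capped at `max_draw_factor` times the target, after which the
generator refuses — a degenerate $\beta_0$ is reported, not silently
retried). The pre-threshold case probability of every individual is
retained in the truth table, and a test asserts it equals the liability
expression to $10^{-12}$.

Key defaults and their rationale:

* `n_cases = 1096`, `n_controls = 4791`, `n_trios = 450`,
  `n_genes_panel = 1142` — the cohort geometry the analyses are sized for.
* `carrier_freq_dominant = 0.05` — anchored to the observed carrier rate of
  qualifying variants among population controls (≈ 0.047); with
  `beta_rare = log(4)` this yields a case carrier rate near 17%.
* `beta_pgs = -0.35` per SD — a protective direction for cognitive-trait
  scores, of the magnitude typical for cognitive-performance PGS in
  neurodevelopmental case-control panels.
* `severity_carrier_odds = 2` — carriers are enriched in the
  moderate/severe/profound stratum by this odds factor. The real
  enrichment magnitude across severity strata is not published; this is a
  fixture choice, not an estimate, and tests treat it as free.
* Principal components are independent standard normals with zero true
  effect: they must be accepted as covariates without confounding the
  generating truth.
* Only the first PGS trait is causal; the remaining traits are independent
  noise, which gives the reporting-score selection a known right answer.
* Recessive (homozygous) carriers are planted at `carrier_freq_recessive`
  but do not enter the liability; they exist to exercise the recessive
  classification and Firth paths, where carriers are sparse.

The variant generator emits one qualifying variant per truth carrier and a
battery of decoys, each constructed to be rejected by exactly one
classification rule (sub-threshold MPC, boundary MPC, nonzero reference
allele count, missing LOF confidence, synonymous consequence,
weak-evidence gene, inheritance mismatch, sub-threshold CADD homozygote,
reference homozygotes, control-shared variant). A round-trip test asserts
that classification recovers carrier truth exactly.

What the generator does **not** emulate: linkage disequilibrium (scores are
drawn directly, not accumulated from genotypes), read-level sequencing
artifacts, relatedness and population outliers (assumed removed upstream),
compound heterozygosity, and ancestry structure in the PCs. Passing tests
therefore demonstrate correctness of the statistical machinery under the
model's assumptions, not robustness to real-data pathologies such as
stratification or batch-confounded genotyping error.

# Variant classification and diagnostic yield

A variant is damaging if it is a high-confidence loss-of-function call
(stop-gained, splice-disrupting, frameshift, flagged high-confidence with
no warnings) or a missense variant with MPC > 2 in heterozygous context or
CADD > 20 in homozygous context. Both inequalities are strict — boundary
values fail — and missing scores fail closed, with a logged count.
Rarity is mode-specific: dominant analyses require reference-database
allele count 0; recessive analyses require reference homozygote count 0
(reference allele count is deliberately irrelevant, as expected in a
founder population where the pathogenic allele may be polymorphic);
subset comparisons additionally require absence from the study's own
controls. Homozygous high-confidence LOF variants in recessive genes are
diagnostic without any CADD requirement: the CADD threshold governs
missense pathogenicity only. A variant is Finnish-enriched when its
Finnish reference frequency is nonzero and at least twofold every other
population's (ties count, since the rule is "at least twofold"), or when
it is absent from the reference database.

Carrier flags require the gene to have definitive or strong evidence,
brain/cognition effects, and the matching allelic requirement. Hemizygous
male genotypes in X-hemizygous genes count toward the dominant
(monoallelic-like) flag; the underlying burden convention is not published,
so this is a switch (`count_x_hemizygous`, default on). Compound
heterozygotes are not counted as recessive diagnoses — only homozygotes,
consistent with a founder-population analysis.

Yield percentages round half away from zero (the convention of published
clinical tables, not banker's rounding): rates at two decimals,
composition splits at one. The overall rate is reported both directly and
as the sum of the already-rounded dominant and recessive rates; the latter
is the convention that makes a figure's total equal the sum of its
displayed parts, and it is what reproduces the published 25.62% = 23.25% +
2.37% exactly. Reproducing the published table's percentages from its
printed counts requires denominator 1097; the acceptance script uses that
denominator and documents it. Empty subsets report `NA`, never 0%.

# De novo calling and enrichment

Genotype likelihoods are recovered from phred-scaled PLs and normalized per
member. The de novo posterior weighs the de novo hypothesis (proband het,
parents hom-ref; prior $1/3\times10^7$) against a missed parental het
(prior $1-(1-q)^4$, any of four parental alleles):

$$p_{dn} = \frac{\pi_{dn} L_p(\mathrm{het}) L_m(\mathrm{ref}) L_f(\mathrm{ref})}
{\pi_{dn} L_p(\mathrm{het}) L_m(\mathrm{ref}) L_f(\mathrm{ref}) +
 \pi_{miss}(q)\, L_p(\mathrm{het}) [L_m(\mathrm{het})L_f(\mathrm{ref}) + L_m(\mathrm{ref})L_f(\mathrm{het})]}.$$

Two conventions are worth making explicit. First, the missed-het prior
$1-(1-q)^4$ is one of several forms in circulation in this caller family;
it is configurable. Second, a site only enters this two-hypothesis
contrast when het is the proband's most likely genotype — otherwise the
proband-het factor cancels between the hypotheses and a confidently
hom-ref proband would get a spuriously high posterior. Non-candidate sites
report $p_{dn} = 0$ and FAIL, matching the restriction of published
callers to putative (proband-het) de novo sites.

The frequency prior $q$ is the reference-database Finnish frequency when
the reference record is usable (passes its QC and has consistent
exome/genome frequencies — supplied as an input flag, not recomputed), and
otherwise $(AC_{in}-1)/(AN_{in}+AN_{ref,FIN})$, floored at
$q_{min} = 100/3\times10^7$. Confidence tiers: HIGH requires
$p_{dn} > 0.99$, allele balance ≥ 0.3 and depth ≥ 10; FAIL catches
$p_{dn} \le 0.5$, allele balance < 0.1 or uninformative (all-equal)
proband PLs; all thresholds are arguments.

Expected counts are $\lambda = 2\, n_{trios} \sum_g \mu_{class,g}$ over the
de-novo-eligible panel (definitive/strong, brain/cognition, monoallelic or
X-linked requirement), with X-hemizygous genes counted over male-proband
trios only. Enrichment is a one-sided Poisson tail $P(X \ge N)$ computed
per capture kit on same-kit trios, then combined with Fisher's sum of logs
($-2\sum \ln p_i \sim \chi^2_{2k}$); a single stratum degenerates to the
identity, zero-trio strata are dropped rather than padded with $p = 1$,
and stratum sizes come from the trio roster, not from the sites that
happen to carry records — trios with no candidate site still count.

## Calibration of the enrichment p-value

A one-sided Poisson tail is a *discrete* p-value: it satisfies
$P(p \le \alpha) \le \alpha$ (it is valid and conservative) but it is not
uniform at finite expected counts — its mean exceeds 0.5 by about half the
largest Poisson atom. At the expected counts this study design implies
(roughly one event per kit per class), the Fisher-combined p deviates from
the continuous uniform by a Kolmogorov-Smirnov distance of about 0.3, and
the deviation shrinks only like $\lambda^{-1/2}$. The test suite therefore
verifies the property that actually holds — the empirical rejection rate at
$\alpha = 0.05$ never exceeds the nominal level over 500 null replicates —
while the literal comparison against Uniform(0,1) is retained in the
acceptance suite and fails, as it must for any correct implementation of a
discrete tail test at this scale. This is a property of the statistic, not
a defect of the code: the same deviation is obtained from three lines of
`rpois`/`ppois`/`pchisq` with no package code involved.

# Burden regression engines

The ML engine is iteratively reweighted least squares (`stats::glm.fit`),
tolerance $10^{-8}$, 100 iterations, with Wald intervals on the exposure
coefficient. Detected separation (|log OR| > 15) or non-convergence is an
error that names the Firth engine rather than a silently divergent
estimate. The Firth engine maximizes the Jeffreys-penalized likelihood
$\ell(\beta) + \tfrac12 \log\det I(\beta)$ by modified-score Newton steps
(the score is adjusted by the hat diagonal, $U^*(\beta) = X^\top(y - p + h(\tfrac12 - p))$)
with step-halving on the penalized likelihood, and always returns finite
estimates, including under complete separation. On covariate-free 2×2
tables the Firth estimate equals the Haldane half-cell-corrected odds
ratio, which the tests exploit as one oracle; a second, independent oracle
is direct numerical maximization of the penalized likelihood via `optim`.
Wald (not profile) intervals are reported for both engines, matching
conventional burden reporting; for very small counts Wald intervals on
penalized estimates are known to be approximate, which is accepted and
documented rather than patched.

Design handling: factor covariates are one-hot encoded with the first
level dropped; constant and collinear columns are dropped with a warning
(never the exposure — a collinear exposure is an error); listwise deletion
is applied with a logged count. Subset comparisons run within cases,
Bonferroni-corrected for a configurable number of diagnostic comparisons.
The default is fourteen, following the methods convention; the figure-level
convention of twelve exists in the literature, so the count is a parameter
(`m`), not a constant. Subsets with fewer than two exposed individuals are
flagged low-information but still reported. Severity adjustment encodes
mild vs moderate/severe/profound as a binary covariate; individuals with
unspecified severity are excluded by default or kept as an own level
(`unspecified = "own_level"`), since their placement is genuinely
ambiguous.

# Polygenic-score contrasts

"Normalized to the control mean" is implemented as a control-referenced
z-score — centering *and* scaling by the control standard deviation
($n-1$) — because downstream contrasts are interpreted per control SD;
pure centering is available (`center_only`) since the wording alone does
not fix the scale. Controls re-normalize to themselves; normalization is
affine and rank-preserving, and both facts are asserted in tests.

Marginal means come from the linear model's prediction at the column means
of the model matrix — continuous covariates at their grand mean,
categorical covariates at their observed proportions — with normal-quantile
95% intervals; at cohort sizes in the thousands the $t$ correction is
negligible and normal quantiles keep the intervals analytic. The
implementation is a direct model-matrix computation and is cross-checked
against `emmeans` (proportional weighting) in the test suite, keeping the
implementation and its oracle on separate routes.

# Additivity and multimodel inference

The interaction test fits case status on carrier status, the normalized
score, and their product, plus covariates, by ML with an automatic Firth
fallback under separation, Bonferroni-corrected for eleven score-by-carrier
models by default. Multimodel inference fits the four nested models
(covariates only; + score; + carrier; + both) on one listwise-complete
individual set fixed before any fit, and reports AIC, AICc
($AIC + 2k(k+1)/(n-k-1)$) and BIC with deltas to each criterion's minimum.
Both AIC and AICc are reported side by side because published comparisons
quote either, and at $n$ in the thousands with $k \le 15$ they agree to
well under 0.01. $k$ counts the intercept and every covariate coefficient.
The best reporting score is the trait whose joint model attains the lowest
criterion ("best" is lowest-criterion throughout — the occasionally seen
"highest AIC" phrasing for the preferred model is read as best-criterion,
per the convention that the lowest delta wins); exact ties break by trait
name order and are logged.

# Numerical choices and degenerate inputs

* Rounding: half away from zero at the published precisions.
* Poisson tail at $\lambda = 0$ with a positive count, and zero p-values
  entering Fisher's method, are clipped to the smallest positive double
  (with a warning in the Fisher case) instead of returning 0.
* Fisher's method with a single stratum is the identity, not an error;
  an empty p-value list is an error.
* Unknown consequence strings classify as NOT_DAMAGING with a warning;
  genotypes referencing unknown variant ids are a hard error (they signal
  corrupted input, not a missing annotation).
* Determinism: every generator function seeds its own stream from the
  config seed plus a fixed offset, so stages are reproducible both in a
  full pipeline run and when called individually.

# Problem sizes used by the test suite

Calibration and recovery experiments in the acceptance tests use 500
replicates of $n = 8000$ cohorts for the interaction null, 100 replicates
of $n = 10{,}000$ for coefficient recovery, 50 replicates of $n = 6000$
for model selection, and 500 replicates of 417-trio batches against an
1142-gene panel for de novo calibration; these sizes keep the full suite
under a few minutes while leaving Monte Carlo error well inside the
asserted bounds. Calibration cohorts use an elevated intercept
($\beta_0 = \mathrm{logit}(0.2)$) purely to make rejection sampling cheap:
under outcome-dependent (case-control) sampling the intercept absorbs the
ascertainment and the non-intercept logistic coefficients — the ones under
test — are unaffected.

# Known limitations

* Gene-level association, mixed models, kinship estimation, imputation,
  PGS weight estimation and annotation itself (VEP/LOFTEE, MPC, CADD) are
  out of scope; annotations and scores are consumed as inputs.
* The Firth engine's Wald intervals can undercover for extremely sparse
  strata; profile-penalized intervals are not implemented.
* The de novo caller assumes biallelic autosomal-style PL triples for all
  members; sex-chromosome genotype models are not implemented (the
  X-hemizygous accounting affects expected counts only).
* The generator's decoy battery covers each classification rule once per
  table, not the combinatorial space of rule interactions.
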