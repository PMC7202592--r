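---
title: "Models and methods behind metbc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind metbc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metbc)
```

`metbc` re-implements, as a tested pipeline, the statistical machinery used
to analyse large panel-sequenced breast-cancer cohorts in which each tumor
is biopsied from local disease, a lymph node, or a distal metastasis. The
raw clinical cohorts this kind of analysis runs on are not publicly
depositable, so the package pairs every analysis stage with a synthetic
cohort generator that plants the published effect sizes and records ground
truth. This vignette explains the models, the tunable parameters, and the
design decisions, in the package's own terms.

## The cohort model

A cohort is a triple of sample metadata, alteration calls, and a gene
panel. Biopsy sites map deterministically to disease groups: breast and
chest wall are local disease (primaries and local recurrences), lymph node
is its own group, the named distal organs (liver, bone, lung, brain, skin,
pleura, pleural fluid, soft tissue, ovary, GI) are metastases, and any
unrecognised site is ambiguous. The mapping is exposed through
`site_group_map()` and overridable, because the assignment of rare sites
to groups is a judgment call that source datasets never document.
Ambiguous-group samples are generated but excluded from all group
comparisons.

Feature construction follows the field convention for targeted panels: a
gene is "mutated" when it harbors at least one short variant of any
functional class; copy-number and rearrangement events are separate
gene-by-class features (`CDKN1B.amplification` and `CDKN1B` are distinct
columns, and distinct members of the multiple-testing family). Mutation
load per megabase is the short-variant count divided by a configurable
panel footprint (default 1.1 Mb; any positive constant only rescales the
covariate). A sample is hypermutated when it carries short variants in
more than 25 distinct genes. Under the known/likely-only filter, variants
of unknown significance are dropped both from the flags and from the
load.

Tables are read and written as UTF-8 TSV with `"."` for missing values —
one documented dialect rather than a guessing reader.

## Enrichment scanning and permutation correction

The core statistic is a covariate-adjusted logistic regression per
feature:

$$\mathrm{logit}\, P(\text{metastasis}) = \beta_0 + \beta_1 x_{\text{feature}}
  + \beta_2 p_{ER} + \beta_3 x_{HER2} + \beta_4 \text{TMB},$$

with a two-sided Wald test on $\beta_1$. ER-positivity probability, HER2
amplification and mutation load are always included, because subtype
composition and load differ between local and metastatic disease and
confound naive prevalence comparisons. Fitting is iteratively reweighted
least squares to a step tolerance of 1e-8 (cap 100 iterations). Complete
or quasi-complete separation — routine for rare features — is detected by
a diverging coefficient and triggers a Firth-type penalized refit, which
keeps coefficients finite; the result is flagged. Features with fewer
than `min_count` events (default 10) in the tested context are skipped.

Family-wise error control uses the min-p max-statistic permutation
scheme: the outcome labels are permuted (covariates stay attached to
their samples, which is the literal reading of permuting "the variable of
interest"), the whole scan is rerun per permutation, and the most
significant raw p is recorded. A feature's corrected p is
$(1 + \#\{b: \min_j p_{jb} \le p_{\text{raw}}\})/(B+1)$, the add-one
estimator that cannot return zero, floored at the feature's own raw p.
Two numerical choices matter here:

* The permutation engine is compiled (RcppArmadillo). Per permutation, a
  single null fit plus a vectorised Rao score statistic ranks the whole
  family, and only the top `screen_k` (default 20) candidates are refit
  exactly to locate the minimum Wald p. Score and Wald orderings agree
  except at negligible margins; the acceptance suite verifies family-wise
  error control of the complete procedure empirically (200 global-null
  cohorts of n = 2000 with 100 features and 200 permutations each).
* Depletion is reported as an odds ratio below 1 in the same two-sided
  scan, not as a separate analysis.

Site-specific scans compare each metastatic site against all local
samples with the identical model; per-site permutation correction is
optional.

Supporting tests delegate to the standard R implementations behind the
package surface — `fisher.test` (exact and fixed-margin Monte-Carlo for
r×c tables), `wilcox.test` with tie-corrected normal approximation, and
`ks.test` — and the test suite holds them against independent brute-force
oracles (hypergeometric enumeration, pairwise win counts, exhaustive ECDF
gaps).

## Ensemble classifiers

Subtype imputation and tissue-of-origin classification share one ensemble
design: random forests (the `randomForest` implementation) in which every
tree is fit on a bootstrap stratified to equal class counts, so that
imbalanced labels do not bias the vote. The fraction of tree votes for a
class is that class's probability. `mtry` is chosen by 10-fold
cross-validation over $\{\sqrt p,\ p/4,\ p/2,\ p\}$ and the final model
refit at the optimum. Training samples are always scored by their
out-of-bag votes, never by resubstitution; the test suite checks this
by showing resubstitution accuracy exceeds OOB accuracy on noisy data
while the imputation path returns the OOB values. Permutation importance
permutes one feature at a time and reports the mean decrease in OOB
accuracy over five permutations. Trees are grown to purity with minimum
node size 1, the classic defaults. The test suite and acceptance runs use
300–500 trees; the 5,000-tree setting of a production analysis changes
only the Monte-Carlo noise floor, at proportional cost.

For ER imputation the predicted probability — not the hard label — is the
covariate handed to the enrichment scan, for unlabelled and labelled
samples alike (labelled samples contribute their OOB probability). Vote
ties at exactly 0.5 break to the alphabetically first class,
deterministically.

Tissue-of-origin models additionally mask every feature column of the
site-enriched genes before training (e.g. KRAS/KEAP1/STK11/EGFR for the
lung model), so that the classifier cannot trivially reuse the alteration
whose enrichment motivated the question, and they exclude mutation load
from the feature set. The ambiguity about whether load belongs in the
feature set is resolved as: included for subtype models, excluded for
tissue-of-origin models, both switchable.

Score-set comparisons use the two-sample KS test; covariate-adjusted
comparisons use a beta regression with logit mean link and log-scale
common precision, written against the beta likelihood directly and
maximised with BFGS (standard errors from the numerically evaluated
observed information). Vote fractions hit 0 and 1, so scores are shrunk
by $(p(n-1)+\tfrac12)/n$ before fitting.

## ESR1 hotspot analysis

ESR1 short variants are classified into the named ligand-binding-domain
hotspots (D538G, Y537S/N/C, E380Q, L536H, V422del); everything else is
pooled by its recurrence within the analyzed cohort — seen 2–3 times, or
once — with recurrence computed cohort-wide before any grouping so that
pooling is order-independent. Unparseable protein strings classify as
`other` with a warning, never dropped. The LBD boundary defaults to
residues 311–547; the receptor's domain structure supports any nearby
cut, so the interval is configuration, not code.

Hotspot-by-site (or histology) tables report each stratum's percentage
composition of ESR1 mutations plus the fraction of the stratum's samples
carrying any ESR1 mutation, and are tested with the r×c Fisher exact
test. The visceral contrast (liver, pleura, pleural fluid, brain, lung
versus bone) is a 2×2 Fisher test of D538G against the other named
hotspots. Long-tail enrichment builds per-sample carrier indicators for
recurrence-defined sets (seen once, seen twice, and the seen-once set
split by LBD membership) and runs the standard covariate-adjusted
logistic model per set; the LBD versus non-LBD contrast among singletons
is a Wald test on the difference of the two set coefficients — the
source analyses never specify their construction, and this is the
declared choice, flagged in the output.

## The pathology-report parser

ER status extraction is deliberately rule-based: find standalone
"ER"/"Estrogen" anchors (case-insensitive, token-bounded so HER2 never
matches), find status keyword stems (positive: *positive, detect,
expression*; negative: *negative, rare*), and accept the closest
anchor–keyword pair within 3 lines and 130 characters. Negation tokens
(*not, no, non*) between anchor and keyword flip the status once; double
negation is a documented non-goal. Lines matching boilerplate patterns
(interpretation guides, reporting-guideline text) are blanked before
matching. Distance ties resolve to the negative reading, the
conservative clinical default. The 130-character threshold is an
explicit, auditable config value: the original analysis tuned its
threshold on a training set it did not publish, so the package ships a
sensible default rather than a false precision.

The generator's report suite (four positive and four negative templates,
with and without boilerplate) parses at accuracy 1.0 by construction;
this shows internal consistency between generator and parser, not
performance on real OCR text, which is noisier in ways the templates do
not emulate.

## The synthetic cohort generator

The generator is the package's study design: its defaults *are* the
analysis conditions, and the acceptance suite measures recovery of the
planted values. Sampling is hierarchical: group → biopsy site → subtype,
histology and age → per-feature Bernoulli alteration vector → ESR1
hotspot assignment → lung-contaminant substitution → CHIP injection.

* **Sizes**: 4,512 local, 1,357 lymph-node, 5,034 metastatic, 713
  ambiguous samples.
* **Subtype**: HER2 amplification at 9.4% (metastases) / 8.7% (local);
  ER-positivity per site, with liver/bone high and brain/lung low,
  calibrated by a common logit shift so the metastasis-wide ER+/HER2−
  fraction is exactly 64% (48% for local disease). Site frequencies among
  metastases are not printed in the source figures as numbers; the
  defaults (liver 0.28, bone 0.20, lung 0.12, brain 0.08, soft tissue
  0.08, skin 0.07, pleura 0.05, pleural fluid 0.04, ovary 0.04, GI 0.04)
  are a realistic composition fixed once.
* **Alteration rates**: per-(gene, class) baselines split by ER status,
  with planted enrichments applied as odds multipliers on the logit
  scale — so probabilities stay valid — and each multiplier derived as
  odds(published context rate)/odds(published local rate). Filler genes
  (`BG…`) pad the panel to 287 members and carry a background rate chosen
  so mean short-variant counts land near the published 5.6 (local) and
  6.7 (metastases); 1% of samples draw a hypermutated tail. Genes are
  independent given covariates except the explicit lung-contaminant
  block, because the analyses model no covariance and the co-occurring
  KRAS/KEAP1/STK11 triplet is the one documented exception.
* **ESR1**: ER+ metastasis rates at named sites (liver 44%, pleura and
  pleural fluid 25%, lung 24%, bone 20%, brain 20%); the shared rate at
  unnamed sites is solved at config time so the metastasis-wide
  prevalence is exactly 18.3% (accounting for contaminants, which carry
  no ESR1), and the local ER+ rate is solved for 2.2% overall. Hotspot
  draws come from the published mixture (D538G 33.2%, Y537S 21.4%, …)
  with site tilts (D538G up in visceral sites, Y537S up in bone, E380Q up
  peripherally and in lobular histology) and an 8.9% chance of a second
  variant.
* **Contaminants**: 15% of lung-site "metastases" are drawn from a
  lung-primary profile (elevated KRAS/KEAP1/STK11/EGFR/LRP1B, CDKN2A/B
  deletions, with a 15% joint triplet) — the planted misdiagnosis signal.
* **CHIP**: DNMT3A clones appear with probability
  $\mathrm{logit}^{-1}(-7.6 + 0.078\,\text{age})$ (≈1% under 50, ≈10%
  over 70) and a beta-distributed VAF whose mean declines with age;
  tumor variants draw an age-flat VAF (mean 0.35).

What the generator does **not** emulate: co-mutation structure beyond the
contaminant block, panel-version heterogeneity, subclonal copy-number
dosage, OCR noise in report text, and survival/treatment history. Tests
that pass on this generator therefore demonstrate correctness of the
statistical machinery under the planted model, not performance claims on
real cohorts — in particular, the published real-data classifier
accuracies (93.8/96.6/91.7/85.9%, ER imputation 76%, parser 94%) are not
reproducible targets, and the package does not claim them.

## Problem sizes and determinism

Simulated cohorts at the full published scale (11,616 samples × 287
genes) generate in well under a second; the acceptance suite uses five
full-scale replicates for prevalence recovery, 200 global-null cohorts
(n = 2000, 100 features, 200 permutations) for the family-wise error
property, 20 seeds for the misdiagnosis pipeline (500 tumors per class
per classifier, 3,000-sample scoring cohorts) and 20 seeds for the CHIP
signature. All randomness flows through explicit integer seeds; identical
configuration and seed give byte-identical cohorts.

## Known limitations

Firth fallback and beta regression are in-package implementations
validated against closed forms and parameter-recovery tests rather than
external references. The score-screen inside the permutation engine is an
approximation whose family-wise validity is demonstrated empirically, not
proved. The parser handles a single negation per evidence span. The
generator's unprinted joint distributions (site × subtype × histology
beyond the published margins) default to independence within margins.
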