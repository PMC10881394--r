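---
title: "Models and design choices in cytovar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in cytovar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cytovar` analyses inter-individual variability in cytokine secretion
after standardized whole-blood stimulation. This vignette records the
statistical models the package implements, the assumptions behind
them, the tunable parameters and why their defaults are what they
are, what the synthetic-cohort generator does and does not emulate,
and the numerical decisions a maintainer would otherwise have to
reverse-engineer from the code.

## Outcome model

Every model treats the natural logarithm of a cytokine concentration
as a Gaussian outcome. Concentrations from multiplexed immunoassays
are positive, right-skewed and multiplicative in their error
structure, so the log-normal working model is standard; it also makes
regression coefficients interpretable after exponentiation as
fold-changes in concentration. Concentrations below an analyte's
lower limit of quantification (LLOQ) are clamped to the LLOQ before
the log — a floor, not an imputation — so no observation can
contribute spurious precision below what the assay resolves. The log
base is natural throughout, matching the exponentiation convention of
the effect-size displays.

## Induction profiling

A cytokine counts as *induced* by a stimulation when its
across-donor median deviates from the null-condition median by at
least 30% in relative terms, in either direction
(`threshold = 0.30`, configurable). The threshold is deliberately a
ratio test: it is invariant to the arbitrary concentration units of
each analyte. One degenerate case needs a rule of its own: when the
null-condition median sits at the LLOQ floor the ratio is
uninformative, so any stimulated median above the floor is called
induced.

The standardized log mean difference, `SLMD = mean(d)/sd(d)` with `d`
the per-donor paired log differences (stimulated minus null,
complete pairs only), is a paired effect size: the pairing removes
between-donor baseline variation from the denominator. Pairs with
zero difference variance give a non-finite SLMD; they are flagged
with a warning and excluded from clustering rather than silently
set to zero. Whether the original summary used log or raw
concentrations is not determined by the screen itself; the log scale
is the default here for consistency with the modelling scale, and
`log_scale = FALSE` is available.

Profile clustering is agglomerative with complete linkage and
Euclidean distance on both rows and columns. `stats::hclust` is
deterministic given its input order; for tied merge heights the pair
with the lower original index merges first, so permutation tests can
account for ties explicitly.

Responder detection runs k-means with k = 2 and 25 seeded restarts on
the log concentrations of an explicit cytokine set (the induced set
of the stimulation is the natural choice; the assay does not dictate
one). Cluster indices from k-means are arbitrary, so the cluster with
the larger centroid norm is *defined* to be the responder group. The
seed is a required argument — no ambient randomness anywhere in the
package. This split targets T cell receptor cross-linking
stimulations, where an Fc-gamma receptor polymorphism produces a
genuine non-responder subpopulation; all downstream analyses of such
a stimulation run on the responders only.

## The variable screen

For variable `v` and induced cytokine `y` the screen compares
`lm(y ~ v + age + sex + batch)` against `lm(y ~ age + sex + batch)`
with the Gaussian profile-likelihood ratio statistic
`n · ln(RSS_reduced / RSS_full)`, referred to chi-square with as many
degrees of freedom as parameters added. The chi-square reference is
the canonical choice for this deviance; an F-test would differ only
in small samples and the package's engine is validated against an
independent log-likelihood computation to 1e-10.

Eligibility guards against unestimable contrasts: numeric variables
always qualify; a categorical variable with L observed levels
qualifies only when at least `ceiling(L/2)` levels each hold at least
5% of the non-missing donors.

Multiplicity is controlled per stimulation with Benjamini–Yekutieli
(BY) correction over the *whole* variable-by-cytokine family of that
stimulation — families never pool across stimulations, and the
harmonic-constant inflation makes the FDR guarantee valid under the
arbitrary dependence that shared donors induce. The significance
gate is adjusted p < 0.01. Effect sizes are treatment-coded
coefficients (reference level "never" for smoking status,
configurable otherwise), exponentiated, with confidence intervals
from t quantiles at the residual degrees of freedom; a per-level
significance mark uses the coefficient t-test at p < 0.01.

The age-interaction variant adds `v:age` to the full model only, so
its LRT tests main effect and interaction jointly — the reduced model
stays the same, keeping the two variants directly comparable.

Missing data are handled by complete-case analysis per model pair,
with the donor count actually used (`n_used`) recorded in every
result row; nothing is imputed in the screen.

Pairwise group contrasts (for box-plot style displays) use two-sided
Wilcoxon rank-sum tests — exact for small tie-free groups, normal
approximation with tie correction otherwise, as `stats::wilcox.test`
decides — with Holm adjustment across the pairs. Holm is the default
because it controls FWER under any dependence with no distributional
assumptions; the method is a pass-through argument.

## Mediation by covariate elimination

The mediation screen asks a deliberately modest question: does the
variable still improve the model once a candidate mediator is
accounted for? Formally it compares
`lm(y ~ v × M + covariates)` against `lm(y ~ M + covariates)`; the
interaction is included by default so that a mediator whose effect
differs across levels of `v` is still fully absorbed (a
no-interaction variant exists). A mediator *eliminates* an
association when the baseline screen was significant and the
with-mediator test is not, both on BY-adjusted p-values at the same
α = 0.01 gate as the screen. Both p-values are always reported, so a
stricter or looser reading costs nothing. This is screening, not
causal mediation analysis: no natural direct/indirect effects are
estimated, and a "mediator" here may equally be a confounder or a
proxy — directionality is established only by the synthetic-data
recovery tests, where chains are planted by construction.

A caveat the acceptance simulations make visible: when the baseline
association sits just below the gate, *any* mediator can push it
over (power loss, not mediation). Interpreting eliminations is only
sound for baselines that clear the gate comfortably.

Mediator transforms are fixed per panel kind: raw cell counts enter
as `log(count + 0.5)` (the half-count offset handles zeros), protein
abundances as logs, CpG beta values untransformed (a logit-beta
option exists; betas bounded away from 0/1 make the difference
immaterial in practice).

CpG-to-cytokine association tests are restricted to sites within
1 Mb of the cytokine gene's transcription start site (closed
interval, same chromosome, 1-based coordinates) and adjusted for
age, sex, batch and a major cell-count covariate; the table-wide
FDR (Benjamini–Hochberg) gate is 0.05, looser than the screen's gate
because this stage is a candidate filter feeding the variance
models, not a headline claim.

## Response pQTL scanning

The scan regresses each induced cytokine on each SNP's additive
dosage (0/1/2) plus covariates. For speed the covariates are
projected out of phenotypes and genotypes once per scan
(Frisch–Waugh–Lovell); with the residual degrees of freedom
corrected for the projected columns this is *numerically identical*
to fitting every per-SNP model in full — that equality, at 1e-10
relative tolerance, is the engine's core correctness property and is
tested against a literal per-SNP OLS oracle. Missing dosages are
mean-imputed per SNP for the matrix path (with a logged count);
SNPs left with no residual variance after projection (e.g. perfect
LD with a conditioning SNP) are flagged untestable rather than
producing 0/0 statistics.

SNPs pass a MAF filter (strictly above 0.05, recomputed from
dosages). A record is *detected* when its raw p falls below the
class threshold — 1e-3 for cis (within 1 Mb of the cytokine gene
TSS), 1e-5 for trans — and *significant* when its Bonferroni-adjusted
p (over all tests the scan ran, detected or not) is below 0.05. The
dual thresholds are treated as reporting pre-filters ahead of a
single Bonferroni family; and the family is per scan (one
stimulation), recorded in the scan metadata, since pooling across
stimulations would mix families of different sizes. Cytokines
identical to the stimulation agonist are excluded: their measured
levels include the spiked-in protein and do not reflect endogenous
secretion.

Conditional scans append a conditioning SNP's dosage to the
covariates; genotype-by-smoking interaction tests compare
`dosage × smoking` against the additive model by LRT with BY
adjustment over the tested hits, reporting exponentiated interaction
coefficients with CIs.

## Variance decomposition

The LMG (Shapley) share of a regressor group is its sequential R²
gain averaged over all orderings of the groups; shares are
nonnegative, sum to the full-model R² (efficiency), and duplicate
groups receive equal shares (symmetry). A multi-level factor is one
group — all its treatment columns enter together — so "smoking
status" is one bar, not two. Exact mode enumerates all `2^p` subset
R² values (capped at p = 20; each subset is a fresh pivoted-QR fit,
chosen over incremental-QR memoisation because correctness, not
speed, is the contract at these sizes); sampled mode averages over
seeded random orderings and reports a Monte-Carlo standard error per
share. Collinear groups are permitted — subset R² remains
well-defined through the pivoted QR — with a warning.

Two inclusion gates coexist by design: the screen's display gate
(adjusted p < 0.01) and the variance models' inclusion gate
(q < 0.05). The pipeline uses the looser q < 0.05 to assemble
regressor sets — excluding a borderline variable from a variance
model biases the remaining shares upward — and records which gate
was used.

## The synthetic cohort generator

The generator is first-class, tested code: it produces every table
the pipeline consumes plus a ground-truth ledger, so each stage can
be validated by recovery of planted structure. Its defaults describe
the study conditions the package is validated under:

* 1,000 donors (955 in the validation experiments, the number of
  donors with publicly shareable data in the motivating cohort
  design), balanced by sex within equal decade strata spanning ages
  20–69, two technical batches;
* never/past/current smoking at 50/25/25%, with smoking history
  (years smoked, cigarettes per day, pack-years, years since
  quitting) drawn consistently with age; CMV seroprevalence 35%;
  BMI normal (24.5 ± 3.5 kg/m²);
* log-scale cytokine responses: per-cytokine baseline, a +2 log-fold
  induction for induced analytes, small age/sex/batch nuisance
  effects (0.008 per year, 0.2, 0.1), residual SD 1.0 — noise of the
  same order as the signal, so power is realistic rather than
  cosmetic;
* a ×1.5 planted smoking effect on IL-2 under the superantigen
  stimulation carried by past *and* current smokers — the persistent
  adaptive-immunity pattern — plus a BMI slope and full-mediation
  chains: CMV → effector-memory T cell counts → IFN-γ/TNF,
  smoking → plasma CEACAM6 → CXCL5 (innate), and
  smoking → AHRR-like CpG → IL-6;
* CpG betas on the logit scale: baseline minus a per-pack-year dose
  effect, reverting per year since cessation (past smokers only) —
  hypomethylation with dose, recovery after quitting;
* Hardy–Weinberg genotypes with one planted cis and one planted
  trans effect, plus null SNPs; MAFs in (0.05, 0.5];
* a 29.5% non-responder component for the T cell receptor
  cross-linking stimulation, simulated as a mixture at
  null-condition level.

Mediation chains write the *observed* mediator transform (centred)
into the cytokine, so conditioning on the mediator removes the
variable's path exactly — full mediation by construction, giving the
elimination screen an unambiguous positive control; a `direct`
coefficient turns chains into partial mediation when wanted.

Seeding is layered: one global seed drives a fixed, documented
offset per table (covariates, cells, proteins, methylation,
genotypes, cytokines, responders), so adding one table never
perturbs the draws of another and identical (config, seed) pairs are
bit-identical.

What the generator does **not** emulate — and therefore what passing
tests do not establish about real data: assay measurement-error
models and batch-by-plate artifacts beyond a single batch shift;
realistic correlation structure among cytokines, among cell subsets
or along the genome (LD exists only where planted); cell-composition
confounding of methylation; population structure or relatedness; and
informative missingness (generated tables are complete unless
damaged on purpose). Recovery results demonstrate that the
*procedures* are correct under their stated assumptions, not that
those assumptions hold in any particular cohort.

## Validation problem sizes

The test suite validates each criterion at the scale it is stated
for: null-screen false-flag rates over 50 cohorts of 955 donors with
136 eligible variables and 13 cytokines; detection of the planted
×1.5 smoking effect over 100 cohorts (CI coverage over 400 lighter
single-cytokine cohorts, to hold the Monte-Carlo error on the
coverage estimate near 1%); mediation directionality over 40
cohorts; the pQTL engine oracle at 1,000 SNPs × 4 cytokines with
family-wise error over 40 null scans of 2,000 SNPs; conditional-
analysis discrimination over 50 planted LD blocks (r² ≈ 0.64); and
variance-share recovery (6% planted) over 50 cohorts.
`scripts/acceptance.R` recomputes the same quantities with somewhat
fewer replicates per experiment so a full run stays within a few
minutes on one CPU; all of its randomness derives from `--seed`.

## Known limitations

Outcomes are Gaussian-on-log only — no GLMs, mixed models or
survival outcomes. The mediation stage is a screen, not an effect
decomposition. The pQTL scan assumes unrelated donors (no kinship
correction) and does no imputation or phasing. Exact LMG is
exponential in the number of groups; beyond 12 groups the pipeline
switches to sampled mode automatically. And the covariate-elimination
logic inherits the power caveat above: elimination calls are only
meaningful when the baseline association is comfortably significant.
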