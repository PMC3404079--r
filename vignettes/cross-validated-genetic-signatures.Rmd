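---
title: "Cross-validated immunogenetic prognostic signatures: methods and design"
author: "survSigCV"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-validated immunogenetic prognostic signatures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Cohorts typed for highly polymorphic immunogenetic loci — HLA class I and II
alleles, SNPs in immune-regulatory genes such as CTLA4, microsatellites such
as the FOXP3 (TC)n repeat — are routinely screened for markers of survival
after treatment. Single markers rarely carry much prognostic weight; the
hypothesis behind multi-marker signatures is that several variants acting on
one biological axis (here, T-cell regulation) are jointly informative where
each alone is marginal. `survSigCV` implements the complete analysis chain
for this setting: binary coding of raw allele calls, carrier-frequency
filtering, univariate Cox screening, multivariate signature construction by
backward elimination, honest evaluation through leave-one-out
cross-validated (LOOCV) risk groups, permutation calibration of the
resulting log-rank statistic, cross-endpoint validation of an
overall-survival (OS) model on relapse-free survival (RFS), and
time-dependent ROC curves. A synthetic-cohort generator with planted hazard
effects makes the entire chain testable without access to patient data.

# Variable coding

Raw input is two allele calls per subject per locus. Coding produces, for
every allele observed at a multi-allelic (HLA) or microsatellite locus,

* a **carrier-presence** indicator: 1 if the subject carries at least one
  copy, and
* a **homozygosity** indicator: 1 iff both calls equal the allele
  (0 for heterozygous carriers and for non-carriers).

SNPs are coded as unordered **genotype indicators** (`CT60*G/G`,
`CT60*A/G`, …) because the signature variable of interest is a genotype,
not an allele count. Microsatellite fragment lengths are taken verbatim as
allele labels, with no binning. Missing calls propagate conservatively:
with one call missing, presence of the observed allele is 1, presence of
any other allele is unknown (`NA`), homozygosity of the observed allele is
unknown, and homozygosity of any other allele is 0.

Only variables with carrier frequency at least `freqThreshold` (default
0.10, the conventional common-variant cut-off) enter the analysis; the
frequency is computed over subjects with a non-missing entry, because the
natural denominator under missingness is the informative subset.
Homozygosity columns face the same filter (a flag exempts them). On the
default synthetic panel at n = 284 this leaves about 71 coded variables.

## Identifiability screening

A Cox model is invariant to adding a constant to the linear predictor, so a
set of columns whose linear combination is *constant* is non-identifiable —
the canonical example being the three genotype indicators of one SNP, which
sum to 1 for every subject. Before any multivariate fit, an exact aliasing
screen removes constants, duplicates and such dependent columns, processing
candidates from rarest to most frequent so the *most frequent* member of an
aliased set is dropped — the usual reference-genotype convention. Mandatory
covariates are screened first and therefore never lost to aliasing.

# Survival primitives

The package carries its own censored-survival core (Kaplan–Meier
product-limit estimation, the two-sample log-rank test with hypergeometric
variance, and Newton–Raphson Cox partial-likelihood fitting with the Efron
tie correction by default, Breslow optionally). The Cox fitter is written in
C++ because the evaluation layer refits the model hundreds of thousands of
times (every permutation replicate re-runs the full LOOCV, and every LOOCV
fold re-runs the full backward elimination). Wald inference is used
throughout — `HR = exp(beta)` with 95% intervals `exp(beta ± 1.96·se)` —
matching the conventional reporting layout (variable, HR, 95% CI, p).

Numerical choices:

* Convergence when the score sup-norm falls below `1e-8` within 100
  iterations, with step-halving to guarantee likelihood ascent. Because the
  score is a sum over events, its attainable floor grows with n; if an
  accepted Newton step is numerically nil (sup-norm < 1e-9) while the score
  is already below 1e-4, the fit is accepted as converged at the
  floating-point floor.
* Monotone likelihood (separation) is flagged when any coefficient passes
  20 in absolute value; `fitCox()` raises an error naming the column. The
  internal selection engines use a tighter bound of 12 and a 40-iteration
  cap: a log hazard ratio of 12 is already far outside any plausible
  biological effect, and earlier detection keeps the permutation layer
  tractable. A binary column with no events in one of its two groups has
  provably monotone likelihood and is withheld from fold-level candidate
  sets up front.
* The exported fits were verified against `survival::coxph` (agreement to
  ~1e-9 over hundreds of random designs under both tie corrections) and
  against a brute-force grid search of the partial likelihood.

# Signature construction

`univariateScreen()` fits one single-covariate Cox model per variable
(pairwise-complete over missing entries) and flags significance at
`alpha = 0.05`. `backwardEliminate()` starts from **all**
frequency-filtered variables — not the univariate-significant subset, since
a joint signature may contain markers that are individually unremarkable —
and repeatedly removes the eligible variable with the largest Wald p while
that p exceeds `pRemove`, refitting after each removal. Mandatory
covariates (disease stage) are never eligible for removal. Ties at the
maximal p remove the lexicographically last name, so builds are fully
deterministic. `pRemove` defaults to 0.10: a stay threshold of 0.05 would
be inconsistent with signatures that retain borderline markers
(p ≈ 0.08) in their final model, and 0.10 is the common default for
elimination. A univariate-gated entry mode is available by flag.

The **prognostic index** of a subject is the Cox linear predictor of the
selected variables, `PI = Σ beta_i x_i`. (A literal "average" — division by
the number or sum of coefficients — could not change any median split, so
the linear predictor is used and documented as such.) High PI means high
predicted hazard. An empty model gives PI = 0 for everyone.

# Cross-validated risk classification

`loocvRiskClassify()` repeats the *entire* signature construction n times,
leaving one subject out each time: backward elimination runs from scratch
inside every fold, the training subjects' PIs define a median, and the
held-out subject is assigned to the high-risk group iff its PI under the
fold's model is **at or above** that median (ties go to high risk; an
empty fold model puts its held-out subject in the high-risk group by the
same rule). Medians of even-sized training sets are the mean of the two
central order statistics. Because every subject's label comes from a model
that never saw that subject, the pooled Kaplan–Meier curves of the two
groups are honest; `resubstitutionRiskClassify()` provides the optimistic
non-cross-validated contrast. `crossEndpointValidate()` runs the identical
fold loop with model building and the median computed on OS while the final
curves and log-rank statistic are evaluated on RFS.

**A caution that shapes the whole inference layer:** the log-rank statistic
of cross-validated groups does *not* follow a chi-square distribution under
the null. Fold models share n − 2 subjects, so assignments are strongly
correlated, and variables are selected for their association with the
outcome; in null simulations the nominal-0.05 asymptotic test rejects at
roughly 25%. The asymptotic p is therefore reported descriptively only, and
significance is assessed by permutation.

# Permutation inference

`permutationSignificance()` shuffles the (time, event) *pairs* among
subjects — genotypes fixed — and re-runs the complete LOOCV, per-fold
feature selection included, for each of B replicates. The permutation
significance level is the add-one tail fraction
`(1 + #{null ≥ observed}) / (1 + B)`, which is valid and never zero; the
tie boundary is counted (`≥`, the conservative choice). B defaults to 500;
test suites use 50 at reduced cohort sizes.

`compareWithCovariate()` asks whether genotypes add prognostic value beyond
stage: the statistic is `LR_d(combined) − LR_d(covariate-only)`, where the
combined model carries stage as a mandatory covariate in every fold and the
covariate-only model is the stage coefficient alone (no selection). The
null permutes whole genotype *rows* while (time, event, stage) triples stay
intact; the covariate-only statistic is genotype-free and is computed once.

All B permutation vectors are drawn up front from the seed, so serial and
parallel execution give bit-identical results, and a failed replicate can
be re-drawn deterministically from a reserve pool. A replicate whose
cross-validated split is degenerate (every subject in one group — typical
under the null when most fold models are empty and all PIs tie at the
median) contributes statistic 0: a split that separates nobody carries no
discriminating information. Treating such replicates as failures and
re-drawing them would bias the null sample, because the degeneracy is a
property of the procedure, not an accident. One consequence is that null
permutation p-values are *superuniform* (conservative) rather than exactly
uniform; level validity at conventional alphas is covered by the test
suite.

# Time-dependent ROC

`timeDependentROC()` implements the cumulative-case / dynamic-control
construction for censored data: sensitivity(c, t) = P(M > c | T ≤ t),
specificity(c, t) = P(M ≤ c | T > t), estimated through Bayes' rule from
the overall KM estimate and the KM estimate within the stratum above each
threshold. The threshold grid is the midpoints between consecutive unique
marker values with ∓∞ anchors, so the curve runs from (0,0) to (1,1);
P(M > c) is the empirical exceedance fraction. The KM-plug-in estimator is
not guaranteed monotone, so TP and FP are clipped to [0,1] and corrected by
cumulative maximum along the threshold sweep (a flag disables the
correction for diagnostics; the nearest-neighbour smoothed variant is out
of scope). AUC(t) is the trapezoidal area; with no censoring it reduces
*exactly* to the Mann–Whitney AUC between subjects with T ≤ t and T > t.
Default horizons are 60 and 84 months (5- and 7-year survival on the
months scale).

# The synthetic-cohort generator

`makeScenario()` provides three study conditions on a fixed default locus
panel (five multi-allelic HLA loci with Southern-European-style allele
frequencies, six biallelic CTLA4-region SNPs, one FOXP3 microsatellite):

* `null` — no genotype and no stage effect;
* `planted_five_marker` — five coded markers carry log hazard ratios
  ln(0.097), ln(0.387), ln(0.449), ln(1.948), ln(1.484) (B\*38, C\*15,
  C\*03, DRB1\*15 and the CT60 G/G genotype, with carrier frequencies
  between 0.10 and 0.35); the stage covariate is neutral so that each
  scenario isolates exactly one structure — analyses needing a prognostic
  stage on top of the markers set `stageLogHazard = log(2.062)` on the
  planted configuration;
* `stage_only` — stage alone carries ln(2.062) (prevalence 0.54, a
  high-stage majority; an exactly balanced binary covariate would make its
  own median split degenerate).

Genotypes are drawn under Hardy–Weinberg sampling (two i.i.d. allele draws
per locus). Event times follow an exponential baseline (0.0063/month;
Weibull available) under proportional hazards with per-subject hazard
multiplier `exp(Σ effects + stage effect)`; an additional relapse process
(rate 0.0069/month, same linear predictor) defines RFS as the minimum of
the death and relapse times, so RFS ≤ OS by construction and the two
endpoints are correlated but distinct. Censoring is the minimum of a
90-month administrative horizon and an independent uniform dropout time.
These constants were calibrated once so that the planted scenario yields
roughly 100/284 deaths, 155/284 relapse-or-death events and ~71 coded
variables surviving the 10% filter. Every operation derives its own RNG
stream from the master seed, so cohorts are reproducible component-wise.

What the generator does **not** emulate: linkage disequilibrium or
haplotype structure between loci (within a locus, multinomial sampling
does induce the natural negative correlation between alleles), population
stratification, genotyping error, and informative censoring. Passing tests
therefore demonstrate the statistical machinery under clean sampling
assumptions, not robustness to the artefacts of real typing data.

# Known limitations and behaviour worth knowing

* **Stepwise retention of null markers.** With ~60 candidates and ~100
  events, backward elimination at `pRemove = 0.10` retains a given null
  marker in roughly 13% of replicates — more than the stay threshold
  suggests, because a variable faces repeated tests across the elimination
  path. This is a property of stepwise selection at low
  events-per-variable, not of the implementation (which matches an
  independent `coxph`-based reference on clean designs); it is one reason
  the final signature must be judged by cross-validation and permutation,
  never by its in-sample p-values.
* **Degenerate splits.** Median splits of an empty or near-constant
  prognostic index assign everyone to the high-risk group; the exported
  classifiers refuse to compare a single group, while the permutation
  engines score such splits as zero discrimination (above).
* **Power at reduced sizes.** The cross-validated log-rank statistic has a
  heavy-tailed permutation null (selection can chase shuffled outcomes), so
  detecting even five genuine markers needs cohorts near the full design
  size; at half size the permutation p is frequently unremarkable. This
  mirrors the borderline permutation levels typical of signature studies of
  this scale.
* **Problem sizes in the test suite.** Simulation-based checks run at
  reduced sizes chosen for a single-CPU run: type-I error of the
  survival-shuffle test at n = 60 with a two-locus panel (B = 50, 100
  replicates); optimism contrasts at n = 60–120; marker recovery at the
  full n = 284 design (100 replicates); the bundled acceptance script runs
  the full-size pipeline once and its permutation tests at n = 220 with a
  four-locus panel (B = 50).
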