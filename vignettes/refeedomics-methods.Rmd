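---
title: "Statistical methods for medication-deconfounded multi-omics intervention analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for medication-deconfounded multi-omics intervention analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refeedomics)
```

## The analysis problem

Dietary intervention trials in hypertensive metabolic-syndrome patients
follow each subject across a baseline visit (V1), an early post-intervention
visit (V2, after a fast) and a late follow-up (V3, after months of a DASH
diet), measuring stool microbiome composition, gut functional-module
abundances, a deep immune-cell panel and clinical phenotypes at every visit.
Two features of such cohorts break naive per-feature testing:

1. **Medication changes are confounded with time.** Patients who improve
   reduce their antihypertensive doses between visits; any microbial taxon
   that responds to the drug (rather than to the diet) then shows a spurious
   "intervention effect".
2. **Samples are repeated measures.** Three samples per subject share a
   subject-level component, so pooled correlations and unpaired tests
   overstate their effective sample size.

`refeedomics` implements the statistical machinery for this setting:
deconfounded longitudinal screening, donor-aware ordination and PERMANOVA,
repeated-measures correlation networks, responder stratification and
leakage-safe response prediction — plus a synthetic cohort generator with
planted ground truth so each stage can be validated end to end without any
patient data.

## The deconfounded contrast screen

For each feature $y$ (a rarefied taxon abundance, module abundance, immune
measurement or clinical value) two nested Gaussian linear models are fitted:

$$
\mathcal{M}_0:\; y \sim \text{age} + \text{sex} + \text{patient} +
  \sum_d \tilde{D}_d, \qquad
\mathcal{M}_1:\; \mathcal{M}_0 + \text{visit},
$$

where $\tilde D_d$ is the normalized dose of drug $d$ (baseline dose
$\mapsto 1$, discontinuation $\mapsto 0$, see below). The likelihood-ratio
statistic is $n\log(\mathrm{RSS}_0/\mathrm{RSS}_1)$ with degrees of freedom
equal to the design-rank difference, i.e. Gaussian maximum likelihood.
Patient indicator columns make age and sex (and any other between-subject
covariate) exactly collinear; fitting uses pivoted least squares so the
aliased columns drop out of both models identically and the test is
unaffected. P-values are Benjamini–Hochberg adjusted within each measurement
space and gated at FDR < 0.1; survivors proceed to unpaired two-sided
Mann–Whitney post-hoc tests for each visit pair, BH-adjusted across the
three contrasts per feature and gated at FDR < 0.05. Cliff's delta
$\delta = \big(\#\{x_i > y_j\} - \#\{x_i < y_j\}\big)/nm$ is reported for
every contrast as the standardized signed effect size.

Design notes:

* The linear model operates on raw (rarefied) abundances; a rank-transform
  mode exists (`contrastConfig(rank_transform = TRUE)`) but is off by
  default, prioritising fidelity to the conventional pipeline over
  robustness to skew.
* The Mann–Whitney post-hoc is deliberately **unpaired** even though visits
  are paired within subject — again fidelity over optimality. Under
  repeated-measures correlation this makes the marginal test conservative;
  its null p-values are exactly uniform only when the within-subject
  correlation is zero, and stochastically larger than uniform otherwise.
  The test suite checks calibration in the independent regime and
  conservatism in the correlated regime.
* Medication normalization: for each (subject, drug) the reference is the
  baseline dose when the drug was taken at baseline, otherwise the lowest
  nonzero dose across visits (covering mid-study initiations). "Medication
  load" is the per-visit sum of normalized doses over agents; a count-based
  mode (`agent_sum_mode = "count"`) is available because the summary's
  original definition is ambiguous between dose sum and agent count.

## Diversity, ordination and donor-stratified PERMANOVA

Alpha diversity supports richness, Shannon ($-\sum p\ln p$; natural log,
configurable base), Pielou evenness, Simpson, inverse Simpson and the
bias-corrected Chao1 $S + F_1(F_1-1)/(2(F_2+1))$, which stays defined when
no doubletons exist. Beta diversity is Bray–Curtis
($\sum|x-y| / \sum(x+y)$, a semimetric — no triangle inequality is claimed)
for count data and Euclidean for immune profiles. Principal-coordinates
analysis Gower-double-centers $-D^2/2$ and returns
$\text{eigenvector}\times\sqrt{\text{eigenvalue}}$ coordinates for positive
eigenvalues; negative eigenvalues (possible for semimetric input) are
reported but contribute no axis. On genuinely Euclidean input the
coordinates reproduce the original distances to $10^{-8}$.

PERMANOVA partitions the squared-distance sums into between/within-group
components and permutes group labels **only within donors**, the correct
exchangeability for visit effects in repeated-measures designs. The p-value
uses the add-one rule $p = (1 + \#\{F^* \ge F\})/(1+B)$, so $p > 0$ always;
$B$ defaults to 999 (the permutation count is not canonical; it is
configurable). Strata in which every sample shares a group label contribute
no label variation; if all strata are degenerate the test returns $p = 1$
with a warning.

## Cross-space correlation triplets

The two-step association screen first computes average-rank Spearman
correlations between every feature pair of two measurement spaces, pooling
samples across visits, with $p$ from the $t$-approximation and BH adjustment
within the space pair (FDR < 0.05). Pooling repeated samples inflates the
nominal evidence, so a second, same-donor post-hoc step refits each
surviving edge as two rank mixed models,
$\mathrm{rank}(y) \sim \mathrm{rank}(x) + (1\,|\,\text{subject})$ and vice
versa, each compared to its intercept-plus-random-effect null by ML
likelihood ratio; the **larger** of the two p-values must stay below 0.05.
A response with no within-donor rank variation carries no within-donor
evidence; such degenerate fits return the conservative $p = 1$ rather than
an unstable boundary likelihood. Triplets (clinical, immune, microbiome)
are retained when at least two of the three pairwise edges are robust and
at least one member feature was independently flagged by the contrast
screen.

Known limitation: the pooled screen's $t$-approximation assumes independent
samples, so with three correlated samples per donor its null p-values are
anti-conservative and a structural trickle of spurious edges passes both
steps (the post-hoc only rejects donor-level coupling, not within-donor
noise alignment). In the synthetic benchmark with five planted triplets
among 12,500 candidates this floor limits precision to about 0.8 — which is
precisely why the published two-step design pairs the screen with an
intervention-hit gate.

## Responder stratification and prediction

Subjects are labeled responders from the medication-adjusted ambulatory
blood-pressure change between baseline and follow-up: a drop of at least 2
mmHg in 24-h systolic pressure without a medication increase, or any
medication reduction without a pressure rise. Both branch thresholds are
arguments, so an exact decision tree can be transcribed.

Prediction of the responder label uses a no-intercept ridge-penalized
logistic model minimising
$\tfrac12\lVert w\rVert^2 + C\sum_i \log(1+e^{-\tilde y_i x_i^\top w})$
with $C = 1$, solved by Newton iteration to gradient norm $\le 10^{-8}$
(the objective is strictly convex, so the optimum is unique; a 1-D
golden-section oracle cross-checks the solver). Features are z-scored.
Dimensionality is reduced by forward-stepwise selection: the candidate
whose addition to the current logistic model gives the smallest 1-df
likelihood-ratio p-value joins at each step (ties break by feature order;
a micro-ridge of $10^{-6}$ stabilizes fitting under separation); selection
runs to $k$ features — 10 in immunome mode, 5 in microbiome-transfer mode —
and flags steps with $p \ge 0.05$ rather than stopping early.

Evaluation is leave-one-subject-out: per fold, scaling statistics and the
entire selection path are computed from the training subjects only, and the
held-out subject is classified at decision threshold 0. This fold-internal
discipline is the module's central property; on label-randomized noise the
accuracy distribution is centered at chance. A known operating limitation,
documented rather than patched: when strong features separate the small
training set after two or three selections, the likelihood saturates and
later conditional gains of genuinely informative features become
indistinguishable from the best of hundreds of noise candidates, capping
LOSO accuracy on the synthetic five-feature benchmark near 0.77 even though
an oracle given the true features reaches 0.94. Cross-cohort transfer
trains one model on all training subjects (optionally restricted to a
feature filter) and applies it to an external table; selected features
missing externally are imputed at the training mean (zero after scaling).

## The synthetic cohort generator

`simulateCohort()` emulates the structure the analyses assume, not any real
taxonomy or immunology:

* **Compositional counts.** Latent per-feature log-abundances (base means
  spread with SD 1.5 across taxa) plus subject random intercepts and visit
  noise; proportions via softmax; counts drawn multinomially at log-normally
  distributed depth (default mean 20,000 reads, sdlog 0.25). Row sums equal
  sampled depths exactly.
* **Within-subject correlation** enters as the fraction
  (`within_subject_corr`, default 0.5) of unit latent variance carried by
  the subject intercept. The value is a free parameter chosen as a
  plausible middle ground — gut microbiome studies report strong
  individuality — not an estimate of any dataset.
* **Planted effects** are latent shifts on fasting-arm samples at the onset
  visit (reversible) or from onset onward (sustained), calibrated through
  $\Delta = \sqrt2\,\sigma\,\Phi^{-1}\!\big(\tfrac{|\delta|+1}{2}\big)$ so
  the unpaired V2-vs-V1 Cliff's delta hits its target; planted features are
  drawn from the upper half of base abundance so count noise does not
  swamp the calibration.
* **Medication.** Up to three antihypertensive agents per subject across
  five WHO-ATC-style classes; 60% of fasting-arm (25% of control-arm)
  subjects halve or stop one agent at V2, persisting to V3, and half of the
  responders reduce once more at follow-up — mirroring the observation that
  successful subjects cut medication yet keep the pressure benefit.
  Confounded taxa receive a latent shift linear in the change of the
  subject's summed normalized dose (strength 4 latent SD per unit change),
  so the marginal visit effect is clearly detectable while the dose
  covariates absorb it exactly in the latent model. Because the screen
  models raw abundances, the absorption is slightly imperfect on the count
  scale; empirically confounded features are flagged in <5% of runs versus
  >85% by the naive marginal test.
* **Responders.** A latent binary class (fraction 0.69, matching 22 of 32)
  drops 24-h systolic pressure by 8 mmHg (SD 2.5) at follow-up versus 0.3
  (SD 1.5) for non-responders; optionally, baseline immune features
  separate the classes by a configurable standardized distance for
  prediction benchmarks.
* **Triplets.** `plantTriplet()` blends a shared latent factor (with the
  cohort's within-subject structure) into one clinical, one immune and one
  microbiome feature. Loadings are calibrated per member,
  $\lambda_k = \sqrt{\rho\,(1+v_k)}$ with $v_k$ the member's deterministic
  mean variance, so the *observed* pooled Spearman correlation approaches
  the target even when members carry planted intervention effects. Negative
  targets use a two-factor 120° construction: three mutual correlations
  below $-1/2$ are impossible for a valid correlation matrix, so the
  magnitude is capped at 0.5 while the sign contract always holds. Taxa
  members are re-realized by a fresh multinomial draw, which slightly
  attenuates and compositionally echoes planted taxa correlations; the
  recovery benchmark therefore plants its microbiome members in the
  continuous functional-module space.

What passing the synthetic benchmarks does **not** show: robustness to real
phylogenetic correlation among taxa, immune-panel gating hierarchies,
zero-inflation beyond the multinomial, drift over more than three visits,
or batch effects. The generator is a test harness for the statistics, not a
microbiome simulator.

## Problem sizes and numerical choices

The validation suite runs cohorts of 35 subjects per arm (the trial's
scale) for screening properties, 30 subjects × 3 visits for network and
PERMANOVA properties (999 permutations, 100 replicates for type-I
calibration), 32 subjects × 494 features for prediction properties (50
null and 25 informative seeds), and 20–25 seeds for Monte-Carlo
calibrations; these sizes were chosen so the whole suite exercises the
study-scale regime.

Numerical conventions: Gaussian ML (not REML) throughout so likelihood
ratios are valid; BH families exactly as described (one per measurement
space at the screen stage, one of size three per feature post hoc, one per
unordered space pair for edges); rarefaction by sequential hypergeometric
draws (exact multivariate hypergeometric, without replacement) with
`floor(0.95 × smallest library)` auto depth; permutation p-values always
include the observed statistic; Newton solves to gradient norm $10^{-8}$
with step halving; all generators run from a single integer seed and
restore the caller's RNG state.
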