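---
title: "Mendelian randomisation of BCAA levels and type 2 diabetes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mendelian randomisation of BCAA levels and type 2 diabetes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcaamr)
```

## The question and the design

Circulating branched-chain amino acids (BCAAs: isoleucine, leucine,
valine) are among the strongest metabolomic correlates of future type 2
diabetes. Whether that association is causal matters: if impaired BCAA
catabolism raises diabetes risk, the pathway is a drug target; if the
association reflects reverse causality (early disease processes raising
BCAA levels) it is only a biomarker.

Mendelian randomisation treats genetic variants associated with BCAA
levels as instrumental variables. Because genotypes are fixed at
conception, a variant that raises BCAA levels should — if and only if
BCAA metabolism is causally implicated — also raise diabetes risk, in
proportion to its effect on the metabolite. The design needs three
ingredients, each a module of this package:

1. **SNP→exposure effects** $\gamma_j$: per-allele effects on metabolite
   level in SD units, from a GWAS meta-analysis (here: sample-size-weighted
   Z combination across platforms, lead-SNP selection at $p < 5\times10^{-8}$
   in 1 Mb windows).
2. **SNP→outcome effects** $\Gamma_j$: per-allele log-odds of disease from
   large case-control meta-analyses.
3. **An estimator** that combines them into a causal log-odds per 1-SD
   genetically predicted exposure.

## Estimators

The per-instrument Wald ratio is $\hat\theta_j = \Gamma_j / \gamma_j$ with
first-order standard error $se(\Gamma_j)/|\gamma_j|$. The default SE
deliberately ignores uncertainty in $\gamma_j$ — the convention for strong
instruments, where the exposure GWAS z-statistics are large; a
second-order delta SE (adding $\Gamma_j^2 se(\gamma_j)^2/\gamma_j^4$) is
available via `wald_ratio(second_order = TRUE)` for weak-instrument
sensitivity checks.

Independent instruments are pooled by fixed-effect inverse-variance
weighting (`ivw_pool()`), $\hat\theta = \sum w_j \hat\theta_j / \sum w_j$,
$w_j = se_j^{-2}$, with no overdispersion scaling: the genetic arm of this
design reports single pooled estimates without heterogeneity modelling,
and the observational arm (below) carries the heterogeneity statistics
instead.

Instruments in linkage disequilibrium are not independent, and IVW then
understates the pooled SE. `gls_pool()` implements generalised least
squares through the origin: with $\Omega_{jk} = \sigma_j\sigma_k\rho_{jk}$
built from the outcome SEs and the LD correlation matrix,

$$\hat\theta = (\gamma^\top\Omega^{-1}\gamma)^{-1}\gamma^\top\Omega^{-1}\Gamma,
\qquad se = (\gamma^\top\Omega^{-1}\gamma)^{-1/2}.$$

$\Omega$ is built from outcome-side SEs only (exposure-side correlation is
not double-counted), solved by linear solves rather than explicit
inversion, and refused when its reciprocal condition number falls below
$10^{-12}$ — the remedy at that point is stronger pruning, not numerical
heroics. With $\rho = I$ the GLS estimator reduces exactly to IVW, a
property the test suite checks to $10^{-10}$ on random instances.

Exposure-side scaling deserves a note. The original analysis scaled scores
to 1 SD of metabolite using internal weights from its largest cohort,
which are not recoverable from the printed tables. This package scales via
the meta-analytic $\gamma_j$ in SD units instead. Together with the
rounding of published inputs (two-decimal ORs and betas), worked-example
reproductions are therefore expected to agree to about ±0.10 on the OR
scale rather than exactly — e.g. the four-instrument isoleucine score
gives OR/SD 1.41 against a published 1.44.

## Harmonisation

Exposure and outcome studies may report effects on opposite alleles or
strands. `harmonise()` aligns them: allele swaps flip the sign of
$\Gamma$ and complement the EAF; strand mismatches are resolved through
A↔T / C↔G complements. Palindromic variants (A/T, G/C) cannot be resolved
by complementing; when their EAF lies in (0.42, 0.58) even frequency
cannot identify the strand, so the default policy excludes them (flagged,
with a reason code). The window and action are configurable because
cross-cohort strand inference conventions vary and the appropriate choice
depends on how the contributing studies were genotyped.

## The observational arm

Prospective per-SD biomarker–disease estimates (hazard ratios, odds
ratios, risk ratios) are pooled on the log scale as a common "relative
risk" — the usual approximation for an uncommon outcome — by the same
fixed-effect kernel as the IVW estimator (one pooling implementation, two
entry points, kept equal to $10^{-12}$ by a test). Heterogeneity is
quantified by Cochran's $Q$ and $I^2 = \max(0, (Q-(k-1))/Q)\cdot 100$,
truncated at zero. `compare_arms()` reports both arms, their CI overlap
and the ratio of point estimates, and deliberately invents no significance
test for their difference: the comparison is descriptive.

The bundled per-study observational table is **synthetic**: the source
publication prints only pooled per-SD estimates, so the fixture splits
each pooled value into six equally-weighted sub-study estimates that pool
back to the published value exactly. It demonstrates the machinery; it
carries no independent information about the real studies.

## Genetic scores and specificity

`build_score()` computes $S_i = \sum_j w_j G_{ij}$ (mean-imputing missing
dosages, consistent with the association scans); `scale_score_to_sd()`
rescales by the exposure-on-score regression slope so one scaled unit
predicts 1 SD of exposure. A valid instrument set should be *specific*:
`metabolome_scan()` regresses every standardised metabolite on the score
and flags associations at the Bonferroni level $\alpha/m$. Bonferroni is
the default because the source analysis states no multiplicity procedure
for its metabolome-wide figure and the conservative choice is the safer
default for claiming specificity; Benjamini–Hochberg is available where
discovery, not specificity, is the goal.

## The synthetic-data generator

The generator exists so that every pipeline stage has a testable oracle.
Its structure mirrors the minimal assumptions of the design:

* **Genotypes**: haplotypes from a latent Gaussian copula with a target
  correlation matrix, thresholded at the allele-frequency quantile and
  summed in pairs. Hardy–Weinberg holds by construction; block LD is
  specified with `ld_blocks()`. A copula rather than a coalescent
  simulator: it reproduces a target pairwise $r$ cheaply, at the cost that
  the realised dosage correlation is slightly attenuated relative to the
  latent $\rho$ — the generator records the realised matrix in an
  attribute for oracle use.
* **Exposure**: $X = \sum_j \gamma_j(G_j - 2f_j) + aU + \varepsilon$,
  standardised; the noise variance is set so total variance is 1, making
  the configured $\gamma_j$ directly per-allele effects in SD units
  (defaults 0.06–0.13 SD, the range of the published lead SNPs).
* **Confounding**: a single standard normal $U$ loading on both exposure
  ($a$) and outcome ($b$), defaults $a = b = 0.3$ — the minimal structure
  that biases observational estimates upward while leaving MR consistent,
  which is precisely the contrast the design exploits.
* **Outcome**: $P(D=1) = \text{logistic}(\beta_0 + \theta X + bU)$, with
  $\beta_0$ solved numerically for the configured prevalence (default
  10%); optional case-control subsampling keeps all cases plus a control
  fraction, which leaves logistic slopes valid for ORs. Default causal
  effect $\theta = \ln(1.5)$, the order of magnitude of the published
  per-SD estimates.
* **Summary-statistic shortcut**: `simulate_sumstats()` draws
  $\hat\gamma \sim N(\gamma, D_\gamma \rho D_\gamma)$ and
  $\hat\Gamma \sim N(\theta\gamma + \text{pleiotropy}, D_\Gamma \rho D_\Gamma)$
  with SEs from the configured sample sizes
  ($1/\sqrt{2f(1-f)n}$ for a unit-variance trait,
  $1/\sqrt{2f(1-f)n\phi(1-\phi)}$ for a logistic outcome with case share
  $\phi$), bypassing individual-level simulation. A test checks that the
  two routes give statistically indistinguishable estimator distributions
  at matched sample sizes.
* **Pleiotropy knob**: optional direct SNP→outcome effects, off by
  default (the design assumes their absence); used in negative-control
  tests to confirm that pleiotropy biases the naive estimator.

Default cohort sizes follow the study conditions the package emulates:
exposure GWAS n = 16,596, outcome n = 50,000 with a 15% case share, four
instruments with the published frequencies and effect sizes. What the
generator does **not** emulate: genome-scale LD maps, population
structure, relatedness, platform batch effects, or selection into
cohorts. Passing tests therefore validate the estimators under the
stated model, not robustness to those real-data complications.

All randomness flows from a single mandatory seed, split per stage by
hashing the stage name, so adding a stage never perturbs another stage's
draws and any artefact is a pure function of (config, seed).

## Numerical choices

* $z_{0.975}$ is pinned to 1.959964 (6 d.p.) so CI↔SE conversions are
  bit-for-bit reproducible.
* LD matrices are symmetrised as $(R+R^\top)/2$ (warning beyond $10^{-8}$
  asymmetry) and repaired to positive semi-definiteness by eigenvalue
  clipping with the diagonal restored to 1.
* Lead selection uses strict $p <$ threshold and breaks ties by
  (chromosome, position) ascending; the 1 Mb window is interpreted as
  ± window around the lead (the alternative — fixed tiling — is not used,
  and the choice is asserted by an all-pairs spacing invariant on every
  run).
* Greedy pruning by ascending p-value enforces $r^2 <$ bound against all
  kept variants, matching an exhaustive oracle in tests.
* Monomorphic variants, non-converging logistic fits and zero-variance
  traits are flagged untestable rather than raised as errors; collinear
  score variants fall through R's pivoting least squares with a warning.
* Cochran's $Q$ is snapped to zero below $10^{-10}$ (it is scale-invariant,
  so an absolute snap is safe) to keep $I^2$ exactly 0 for identical or
  single studies.

## Test problem sizes

The suite runs estimator-recovery studies at 500 replicates of the
summary-statistic generator (4 independent instruments at the default
study conditions; 8 instruments in two $\rho = 0.7$ blocks for the GLS
case), a 1,000-trait null specificity scan at n = 2,000 with a planted
trait at $R^2 = 0.05$, n = 5,000, 1,000-instance brute-force comparisons
for lead selection and pruning, and a 100-repeat null-calibration of the
end-to-end pipeline at n = 3,000 individuals. These sizes give stable
Monte-Carlo checks (3-MC-SE bands, coverage in [92%, 98%]) while keeping
the full suite around two minutes.

## Known limitations

* Estimation assumes valid instruments; beyond exclusion-based
  sensitivity analysis (`exclude_and_refit()`), no pleiotropy-robust
  estimator (MR-Egger, weighted median, mode-based) is implemented.
* First-order Wald SEs undercover slightly when instruments are weak;
  the second-order option mitigates but does not remove weak-instrument
  bias, and no winner's-curse correction is applied.
* The observational pooling treats HRs/ORs/RRs as exchangeable log
  relative risks; with common outcomes or long follow-up that
  approximation degrades.
* Heritability inputs (`heritability_fraction()`) are consumed as given;
  the package does not estimate heritability.
* No genome-build liftover, multi-allelic variants, or imputation-quality
  filtering; the association scans target desk-scale (~10^5 variants),
  not genome-wide performance.
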