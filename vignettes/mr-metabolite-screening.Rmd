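---
title: "Two-sample MR screening of metabolites: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample MR screening of metabolites: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`lipidmr` implements the full two-sample Mendelian randomization (MR)
workflow used to screen a panel of blood metabolites against a binary
disease outcome (the motivating application is lipid metabolites and
polycystic ovary syndrome), from GWAS summary statistics through a
classification verdict per metabolite. This vignette explains the model,
the defaults and the design decisions; it is the package's own account of
its methods.

## The causal model and its assumptions

For each exposure (a metabolite, in SD units) and outcome (a disease, on
the log-odds scale), each genetic instrument $j$ contributes summary
associations $(\hat\beta_{Xj}, \sigma_{Xj})$ and
$(\hat\beta_{Yj}, \sigma_{Yj})$. A valid instrument must be (1) associated
with the exposure, (2) independent of confounders, and (3) affect the
outcome only through the exposure. Under these assumptions each Wald ratio
$\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$, with first-order standard
error $\sigma_{Yj}/|\hat\beta_{Xj}|$, estimates the causal effect
$\theta$ (log-odds of disease per SD of exposure).

The five estimators and what each buys:

* **IVW** (primary): the precision-weighted mean of the Wald ratios,
  equivalently weighted least squares of outcome on exposure betas through
  the origin. Unbiased when all instruments are valid.
* **MR-Egger**: the same regression with a free intercept, after orienting
  all instruments so $\hat\beta_{Xj} > 0$. The intercept estimates average
  directional pleiotropy; the slope remains consistent under the InSIDE
  assumption even when all instruments are invalid.
* **Weighted median**: consistent when instruments carrying more than half
  of the total weight are valid.
* **Simple and weighted mode**: consistent when the largest group of
  instruments sharing one ratio value is valid; useful with few
  instruments.

An exposure is called significant only when the IVW p-value is below
$\alpha$ *and* all five estimates agree in sign — the direction-consistency
rule that demotes discordant signals to probable false positives.

## Instrument selection defaults

| parameter | default | units | why |
|---|---|---|---|
| `p_threshold` | 1e-5 | p-value | the usual relaxed threshold for metabolite GWAS, where few variants reach 5e-8 |
| `clump_r2` / `clump_kb` | 0.01 / 500 | r², kb | near-independence of instruments; pairs above r² = 0.01 within 500 kb are pruned greedily by p-value |
| `f_min` | 10 | F-statistic | the conventional weak-instrument floor; $F = (n-k-1)R^2/(k(1-R^2))$ with per-SNP $R^2 = 2\hat\beta^2 \mathrm{EAF}(1-\mathrm{EAF})$ on the unit-variance trait scale |
| `palindrome_window` | (0.42, 0.58) | EAF | palindromic (A/T, C/G) variants with intermediate frequency cannot be strand-resolved and are dropped |
| `alpha` | 0.05 | p-value | screening significance, applied to raw IVW p-values |
| `pathway_alpha` | 0.1 | p-value | exploratory threshold for over-representation on small metabolite panels |

Three conventions deserve explanation:

* The F-statistic formula contains $k$, the number of instruments, yet
  instrument strength is usually quoted per SNP. `compute_f()` offers both:
  `per_snp` (default, $k = 1$) and `joint` ($k = J$, summed $R^2$).
* The palindrome rule is implemented as the symmetric window
  $(0.42, 0.58)$: the literal reading "EAF > 0.42" would also delete
  frequencies near 1, which are not ambiguous. Outside the window,
  palindromes are aligned by EAF concordance (frequencies on opposite
  sides of 0.5 imply swapped coding).
* All boundary conventions are strict in the direction of their usual
  phrasing: keep $p <$ threshold, drop $F < 10$, prune $r^2 > 0.01$.

LD is consumed as a precomputed pairwise r² table rather than a genotype
reference panel; pairs absent from the table count as r² = 0 (with a
one-time warning), which keeps the package free of external downloads.

## Sensitivity battery and the verdict

`sensitivity_report()` bundles Cochran's Q (heterogeneity), the Egger
intercept test (directional pleiotropy), MR-PRESSO (global test, per-SNP
outliers with Bonferroni correction, distortion test and an
outlier-corrected IVW), leave-one-out IVW, and the Steiger directionality
test (instrument variance explained in exposure vs outcome, compared by a
Fisher-z test). The battery **passes** when Q, Egger-intercept and
PRESSO-global p-values all exceed $\alpha$ and Steiger supports the
forward orientation at p < $\alpha$.

`verdict()` applies its gates in order: not significant (IVW) → false
positive (sign disagreement, or a failed sensitivity battery — evidence of
pleiotropy or reversed direction makes the signal untrustworthy) → not
replicated (when a replication study is supplied, the random-effects meta
p must clear $\alpha$) → pathogenic / protective by sign. Replication
results are combined by inverse-variance fixed-effect and
DerSimonian–Laird random-effects meta-analysis; both are always reported,
and the gate uses the random-effects p-value (identical to fixed when
$\tau^2 = 0$).

A Benjamini–Hochberg column is added to the verdict table for
transparency, but the screen is gated on raw IVW p-values, matching common
practice for hypothesis-generating metabolite screens.

## Numerical choices

* **IVW variance model**: multiplicative random effects by default, the
  fixed-effect SE scaled by $\sqrt{\max(1, Q/(J-1))}$ — the common
  behaviour of MR software; a `fixed` flag is available.
* **Egger SEs** use a residual scale floored at 1 and t-tests on $J - 2$
  degrees of freedom.
* **Weighted median**: interpolation of the ordered ratios against
  standardized cumulative weights at 0.5; SE from a parametric bootstrap
  $\theta_j^* \sim N(\hat\theta_j, \hat\sigma_j)$ (default 1000
  replicates, seeded).
* **Modes**: Gaussian kernel density with bandwidth
  $\phi \cdot 0.9\min(\mathrm{sd}, \mathrm{IQR}/1.349)J^{-1/5}$, argmax on
  a 512-point grid spanning the ratio range ±3 bandwidths; identical
  ratios short-circuit to the common value with SE 0.
* **Empirical p-values** (MR-PRESSO) use $(1 + \#\mathrm{exceed})/(K+1)$,
  so the global p is floored at $1/(n_{\mathrm{sim}}+1)$. Consequence: the
  outlier test can only flag at Bonferroni level $0.05/J$ when
  $n_{\mathrm{sim}} + 1 > J/0.05$; with the default 1000 simulations this
  holds for panels up to 50 instruments.
* **Ties** in clumping break deterministically (smaller SE, then
  lexicographic SNP id); every stochastic routine takes an explicit seed
  and restores the caller's RNG state.
* Degenerate inputs fail loudly and early: zero exposure beta (degenerate
  Wald ratio), zero spread in exposure betas (singular Egger design),
  per-SNP $R^2 \ge 1$, empty datasets.

## What the generator emulates — and what it does not

`simulate_pair()` draws, per SNP: EAF from U(0.05, 0.95); a true exposure
effect with magnitude U(0.15, 0.45) SD and random sign (the
strong-instrument regime typical of metabolite lead variants at
p < 1e-5; F is then comfortably above 10); sampling noise at
$\mathrm{se} = 1/\sqrt{2n\,\mathrm{EAF}(1-\mathrm{EAF})}$ for both traits
(unit-variance scale; outcome effects are generated directly on the
log-odds scale); two-sided normal p-values. Defaults are 26 SNPs (a
typical metabolite instrument count), $n_{\mathrm{exp}} = 7824$ (a
metabolomics GWAS) and $n_{\mathrm{out}} = 113{,}238$ (a large
case-control meta-analysis). Twenty percent of SNPs get palindromic
coding and 30% of non-palindromic outcome rows are swapped or
strand-flipped, so harmonization is always exercised; scrambling draws
come last in the random stream, making a scrambled dataset the exact twin
of its unscrambled counterpart.

Pleiotropy regimes assign direct outcome effects to a configurable
fraction of invalid instruments, *oriented to the exposure-raising
allele*. This matters: with random exposure-effect signs, direct effects
drawn in the original allele coding would average to zero after the
Egger orientation — the regime would silently become balanced. Orienting
them keeps "directional" directional, so the Egger intercept estimates
`prop_invalid × pleiotropy_mean`.

Not modelled: real rsIDs/positions, population stratification, sample
overlap between exposure and outcome GWAS, case/control imbalance (only
effective sample size enters), allele-frequency differences between the
two studies (EAFs are shared, so palindrome alignment by EAF concordance
is noiseless — real data would occasionally misalign), and LD beyond
declared block r² values. Passing calibration tests on these synthetics
therefore demonstrates correctness of the statistical machinery, not
robustness to every artefact of real GWAS.

One deliberate asymmetry: under a strong causal effect the first-order
Wald SE understates the true ratio variance by the exposure-noise term
$\theta^2\sigma_{Xj}^2/\beta_{Xj}^2$, inflating Cochran's Q by roughly
$1 + \theta^2 n_{\mathrm{out}}/n_{\mathrm{exp}}$. That is a property of
the standard first-order pipeline, not a bug; calibration and recovery
studies in this package therefore use simulation regimes where
$\theta^2 n_{\mathrm{out}}/n_{\mathrm{exp}}$ is small (e.g. exposure GWAS
of 50,000 for the end-to-end screen).

## Problem sizes used in the shipped studies

The test-suite and `scripts/acceptance.R` run, per quantity: type-I error
over 1000–2000 null replicates (J = 50, $n_{\mathrm{exp}} = 8000$,
$n_{\mathrm{out}} = 10^5$); recovery of $\theta = 0.3$ over 300–500
replicates (Monte-Carlo uncertainty is reported as the standard deviation
of the estimator across replicates); robustness under 40% directional
pleiotropy (mean 0.1) over 300–500 replicates; MR-PRESSO detection of a
planted $+10\,\mathrm{se}$ outlier over 100–200 replicates at 300–500
null simulations each; Steiger orientation over 200 replicates; and one
end-to-end 10-exposure screen with 2 causal exposures and one
deliberately non-overlapping exposure to exercise the skip path.

## Known limitations

* No proxy-SNP lookup when an instrument is missing in the outcome — the
  exposure is simply analysed on the harmonizable subset (or skipped).
* No multivariable MR, MR-RAPS or radial variants; the five methods above
  are the estimator set.
* Binary-outcome variance explained for the Steiger test uses the same
  $2\hat\beta^2\mathrm{EAF}(1-\mathrm{EAF})$ formula on the observed
  log-odds scale, a pragmatic approximation.
* Pathway analysis is plain hypergeometric over-representation; no
  topology weighting, and the compound-to-pathway mapping is
  user-supplied.
* The `joint` F mode uses the median sample size across instruments when
  studies report per-SNP n.
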