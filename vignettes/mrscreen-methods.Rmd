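---
title: "Methods: genetic correlation and Mendelian randomization screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genetic correlation and Mendelian randomization screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrscreen)
```

## The problem

`mrscreen` implements a two-stage screen between a binary disease trait and a
panel of quantitative exposures — the motivating setting is a panel of
hundreds of blood metabolites screened against an inflammatory rheumatic
disease — using nothing but GWAS summary statistics.

1. **Stage one (correlation):** for every exposure, the genome-wide genetic
   correlation with the disease is estimated by bivariate LD score regression
   (LDSC). Exposures with a nominally significant correlation (p < 0.05, no
   multiple-testing correction by default, mirroring common screening
   practice; `mr_config(rg_p_adjust=)` enables one) proceed.
2. **Stage two (causation):** each selected exposure is taken through a
   two-sample Mendelian randomization (MR) battery with strict instrument
   screening, five estimators, a full sensitivity battery, and an iterative
   refinement loop that removes flagged instruments and re-fits until the
   analysis is clean.

## LD score regression

For SNP $j$ with LD score $\ell_j$ (the sum of $r^2$ with nearby SNPs), the
polygenic model implies

$$E[\chi^2_j] = \frac{N h^2}{M}\,\ell_j + 1 + Na,$$

where $M$ is the number of SNPs, $N$ the GWAS sample size, and the intercept
absorbs confounding inflation. `fit_h2()` regresses $\chi^2_j$ on
$N_j \ell_j / M$ with a free intercept. Weights combine the usual
over-counting correction $1/\ell_j$ with the heteroskedasticity correction
$1/(N h^2 \ell_j / M + 1)^2$; because the weights depend on $h^2$, the fit is
iterated twice from an unweighted start. The cross-trait version,
`fit_rg()`, regresses $z_{x,j} z_{y,j}$ on $\sqrt{N_x N_y}\,\ell_j/M$ to
estimate the genetic covariance, and

$$\hat r_g = \frac{\widehat{\mathrm{gencov}}}{\sqrt{\hat h^2_x \hat h^2_y}}.$$

Numerical choices:

* The two marginal regressions and the covariance regression run in
  *lockstep* (same SNPs, same jackknife blocks, same two weight passes from
  a common unweighted start). This makes `fit_rg(x, x)` return exactly 1 and
  makes `fit_rg(x, y)` symmetric in its arguments.
* Standard errors come from a delete-one-block jackknife over 200 contiguous
  equal-count SNP blocks in genome order (deletion is done on precomputed
  per-block sufficient statistics, so the jackknife is $O(M)$). For $r_g$
  the *ratio* is recomputed on every delete-one-block replicate; replicates
  with a non-positive $\hat h^2_x \hat h^2_y$ product are dropped.
* Weights are computed with the current slope clamped at zero and intercepts
  held at 1; the fitted intercepts themselves are free.
* $\hat r_g$ outside $[-1, 1]$ is reported with a warning, never clamped;
  a non-positive heritability estimate makes $r_g$ an explicit error.
* Sample overlap between the two GWAS inflates the cross-trait intercept but
  not the slope; `fit_rg(..., intercept_gencov=)` optionally constrains it.

## Instrument screening

`build_instruments()` applies the five-step screen in a fixed order:
exposure p-value threshold (default $5\times10^{-6}$), greedy LD clumping
($r^2 < 0.001$ within 10{,}000 kb; candidates visited by ascending p-value,
ties broken by SNP id for determinism; pairs missing from the LD table count
as independent), exclusion of instruments associated with the outcome (same
threshold — the release the disease GWAS comes from does not state a
separate one), exclusion of instruments matching a local confounder
blocklist (a stand-in for database lookups against known risk factors such
as age and smoking), and outright removal of palindromic (A/T, C/G)
variants — never frequency-inferred, since strand cannot be resolved from
the alleles alone. `harmonize_alleles()` then orients outcome effects onto
the exposure's effect allele, negating effects for swapped alleles,
complementing strand flips, and dropping (with a log entry) rows whose
alleles cannot be reconciled. Instruments absent from the outcome table are
dropped; proxy-SNP search is out of scope. Every removal lands in a ledger
(`removals_ledger()`) with its stage and reason, and the counts always sum:
candidates = kept + removals.

## Estimators

All estimators consume the harmonized set $(\hat\beta_{x,j}, \hat\beta_{y,j},
\sigma_{y,j})$; per-instrument Wald ratios are $r_j = \hat\beta_{y,j} /
\hat\beta_{x,j}$ with first-order SE $\sigma_{y,j}/|\hat\beta_{x,j}|$.

* **Random-effects IVW** (the headline method): zero-intercept weighted
  regression of outcome on exposure effects, weights $1/\sigma_{y,j}^2$.
  The multiplicative random-effects convention scales the fixed-effect SE by
  $\max(1, \sqrt{Q/(k-1)})$ — under-dispersion never shrinks the SE.
* **MR-Egger**: the same regression with a free intercept after orienting
  all exposure effects non-negative; the intercept estimates directional
  pleiotropy. SEs carry $\max(1, \sqrt{Q'/(k-2)})$ and p-values use a
  $t_{k-2}$ reference.
* **Weighted median**: the interpolated 50th weighted percentile of the
  ordered ratios (cumulative weights minus half the own weight). If a single
  instrument carries a majority of the weight its ratio is returned outright
  — the interpolation formula would otherwise smear a dominant, perfectly
  valid instrument toward its neighbour.
* **Simple/weighted mode**: the argmax over a 4096-point grid of the
  normal-kernel smoothed ratio density, bandwidth
  $\phi \cdot 0.9\,\min(\mathrm{sd}, \mathrm{mad})\,k^{-1/5}$ with
  $\phi = 1$ by default.
* Median and mode SEs come from a seeded parametric bootstrap (default 1000
  draws) resampling effects from their sampling distributions.

Minimum instrument counts: IVW falls back to the single-instrument Wald
ratio with a warning; Egger, median and modes report a method-unavailable
outcome below $k = 3$. Because the outcome is a binary disease, all
estimates are also reported as odds ratios with 95% CIs.

## Sensitivity battery

* **Cochran's Q** about the fixed-effect IVW estimate ($\chi^2_{k-1}$) and
  **Rucker's Q** about the Egger fit ($\chi^2_{k-2}$); the Egger fit nests
  the IVW fit, so $Q' \le Q$ always.
* **Egger intercept test** for directional pleiotropy ($t_{k-2}$).
* **MR-PRESSO**: the observed weighted residual sum of squares of
  leave-one-out-predicted outcome effects is compared to a parametric
  simulation null (both exposure and outcome effects redrawn around their
  leave-one-out predictions; 1000 seeded draws by default, vectorized via
  closed-form leave-one-out IVW slopes). Per-instrument tail probabilities
  are Bonferroni-corrected: Bonferroni-significant instruments are
  *outliers*, nominally-significant ones *potential outliers* — the only
  reading under which an analysis can show "no outliers but several
  potential outliers". The distortion test compares the outlier-removed IVW
  estimate to estimates from random same-size removals (two-sided); it is
  not applicable when nothing is flagged. A known property of the
  leave-one-out construction: a planted contamination many times larger
  than the outcome SEs biases the predictions *for the other instruments*,
  which can then be co-flagged; this is faithful to the method, and the
  refinement loop converges regardless.
* **Leave-one-out**: the IVW fit is recomputed $k$ times omitting one
  instrument. The source analyses never define "affected by a single SNP";
  we adopt a *significance-flip* rule — an instrument is influential iff
  omitting it flips the IVW p-value across $\alpha = 0.05$ in either
  direction. This is the single most consequential interpretive decision in
  the package (it is what drives multi-round refinement) and is exposed via
  `leave_one_out(alpha=)`.

## Iterative refinement

`run_refinement()` loops (at most `max_rounds = 5`; observed analyses of
this design go at most 3 deep):

1. run all five estimators and the full sensitivity battery;
2. if the PRESSO global test rejects, remove the outliers — or, when no
   instrument is Bonferroni-significant, the potential outliers (pleiotropy
   takes priority over influence, matching how such analyses are narrated);
3. otherwise, if leave-one-out flags influential instruments, remove them
   and continue — even from a non-significant state, since removal can
   restore significance as well as destroy it;
4. otherwise stop (`clean`). Dropping below 3 instruments mid-loop stops
   with `too_few_instruments` and verdict `not_evaluable`.

The verdict comes solely from the final round's random-effects IVW:
`causal_positive` (OR > 1, p < 0.05), `causal_negative` (OR < 1, p < 0.05),
else `no_causal`. Instrument counts strictly decrease across rounds, and
re-running the final instrument set reproduces the final round and stops
immediately.

## The synthetic world

`simulate_gwas_pair()` emulates the *inputs* of the screen with known ground
truth. True per-SNP effects are bivariate normal with variance $h^2/M$ and
correlation $r_g$ on the standardized-genotype scale; marginal effects mix
truth through block-equicorrelated LD; z-scores add unit noise (correlated
across traits by the sample-overlap fraction); reported effects are
$z \cdot \mathrm{se}$ with $\mathrm{se} = 1/\sqrt{2N\,\mathrm{maf}(1-\mathrm{maf})}$,
so $\chi^2 = z^2$ regardless of scale convention. Defaults, chosen once as a
plausible stated world: blocks of ~50 SNPs, within-block $r^2 = 0.1$ (LD
scores around the genome-wide average of ~6), MAF uniform on (0.05, 0.5),
16% palindromic variants (2 of the 12 unordered allele pairs), disease trait
on the observed linear scale (liability conversion out of scope; log-OR
labelling available via `scale = "logor"`, the numbers being identical).
Block *sizes* are jittered uniformly between 0.6x and 1.4x the mean: exactly
equal sizes would make the LD score constant (singular regression), while
heavy-tailed sizes would create correlated units larger than a jackknife
block and visibly understate the jackknife SE. `simulate_gwas_panel()`
shares one outcome across many exposures, each with its own $r_g$.

`simulate_mr_dataset()` plants MR ground truth directly: instrument exposure
effects drawn away from zero (|effect| 0.05–0.25, exposure SE 0.005–0.015,
outcome SE 0.01–0.03 — strong instruments of the kind that survive a
$5\times10^{-6}$ screen), outcome effects $\beta \hat\beta_x$ plus a
pleiotropy term per mode (`none`, `balanced`, `directional`, `outlier`),
with planted outliers recorded in the `truth` attribute.

What the generator does **not** emulate: realistic human LD maps,
allele-frequency/LD coupling, minor-allele effect-size coupling, liability
scale case-control traits, population stratification. A green test
establishes the *statistical machinery* is correct under the stated world,
not that the pipeline reproduces any particular published estimate — the
published headline numbers require the original full-scale GWAS inputs.

## Numerical and degenerate-input choices

* Weighted regressions use closed-form sufficient statistics; jackknife
  deletion reuses per-block sums.
* `p = 0` rows are invalid input (dropped on read); simulated p-values are
  floored at `1e-320` to stay in (0, 1].
* Constant LD scores, too few SNPs, non-positive heritability, and
  zero exposure effects in a Wald ratio are explicit, named errors.
* All stochastic components (bootstrap, PRESSO null, refinement) are seeded
  through a single `mr_config(seed=)` and restore the caller's RNG state.
* Tie-breaks: clumping ranks by (p, snp_id); the weighted-median dominance
  rule precedes interpolation; mode argmax takes the first grid maximum.

## Limitations

Single-exposure MR only (no multivariable or robust/penalized variants, no
Steiger filtering, no reverse-direction screen); clumping trusts the
supplied LD information and keeps everything if none is given; partitioned
LDSC and liability-scale conversion are out of scope. The confounder screen
is only as good as the supplied blocklist.
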