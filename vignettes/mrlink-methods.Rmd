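---
title: "Methods and design of mrlink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of mrlink}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mrlink)
```

# The problem

Two-sample Mendelian randomization (MR) estimates the causal effect of an
exposure on an outcome from published GWAS summary statistics, using
genetic variants as instruments. Validity rests on three assumptions per
SNP: relevance (the SNP is associated with the exposure), independence
(no confounding of the SNP-outcome relationship) and exclusion (the SNP
affects the outcome only through the exposure). The third assumption —
absence of horizontal pleiotropy — is the one most often violated in
practice, so the package pairs every causal estimate with the standard
sensitivity battery and treats a result as significant only when all of
it is quiet.

# Estimators

With aligned per-SNP effects `beta_exposure` (SE `se_exposure`) and
`beta_outcome` (SE `se_outcome`), the per-SNP Wald ratio is
`beta_outcome / beta_exposure` with first-order SE
`se_outcome / |beta_exposure|`. The first-order form ignores exposure
uncertainty; a second-order form is available via
`wald_ratios(second_order = TRUE)`. With strong instruments the
difference is negligible, but at large causal effects the first-order
SEs undersize the ratio variance, which inflates Cochran's Q — a known
behavior of the convention, worth remembering when Q fires without any
other pleiotropy signal.

**IVW.** `mr_ivw()` implements the inverse-variance-weighted estimator
in its regression form (zero-intercept weighted regression of outcome on
exposure betas, weights `1/se_outcome^2`), which is identical to the
weighted mean of Wald ratios; the test suite asserts the identity to
1e-10 on random inputs. "Random effects" is interpreted as
*multiplicative*: the fixed-effect SE is scaled by `sqrt(Q/(J-1))` when
that exceeds 1 and left alone otherwise. The floor prevents a
well-behaved dataset from being rewarded with an SE smaller than the
fixed-effect one. Additive (DerSimonian-Laird) and plain fixed-effect
variants are one flag away. IVW p-values are normal; with dozens of
instruments the refinement of a t reference would be cosmetic.

**MR-Egger.** `mr_egger()` adds an intercept to the weighted regression
after orienting every SNP to a non-negative exposure beta (the estimator
is not invariant to allele orientation; this is the standard
convention). The intercept estimates average directional pleiotropy.
SEs use the same multiplicative floor; p-values use t with J-2 degrees
of freedom because the Egger fit loses two parameters and J is often
small. A perfect (collinear) fit keeps its zero SEs rather than
producing NaN — noiseless oracle tests rely on this.

**Weighted median.** `mr_weighted_median()` orders the Wald ratios,
forms standardized mid-cumulative weights `s_j = (cumsum(w) - w/2) /
sum(w)` and interpolates at 0.5. The SE comes from a parametric
bootstrap (betas redrawn from their sampling distributions) because the
analytic alternative is itself an approximation of the same bootstrap;
the seed is a required argument so no published SE can be
irreproducible. The interpolated estimator tracks, but does not exactly
equal, the minimizer of the weighted absolute deviation objective: the
discrepancy is bounded by the gap between adjacent order statistics,
which is how the tests check it.

**MR-PRESSO.** `mr_presso()` computes the observed residual sum of
squares with leave-one-out IVW predictions and weights
`1/se_outcome^2`, then builds its null from `n_sim` parametric draws of
both beta vectors (exposure uncertainty included by default, as in the
method's original design; a flag disables it). The global p-value uses
the add-one estimator `(1 + #{RSS* >= RSS_obs})/(n_sim + 1)`, so it is
never exactly zero and never below `1/(n_sim+1)`. The per-SNP outlier
p-values are *empirical proportions* `#{resid* >= resid_obs}/n_sim`,
Bonferroni-adjusted over the J SNPs: with an add-one floor a per-SNP
p-value could never clear the Bonferroni bar at the default `n_sim =
1000` and J = 60 (floor 60/1001 > 0.05), which would make the outlier
test vacuous at its own defaults. Computation is done on a
SNP-id-sorted copy so results are invariant to row order. The distortion
test of the original method is deliberately not implemented;
remove-and-refit (`presso_corrected()`) is.

**MVMR.** `mvmr_ivw()` solves the weighted multivariable normal
equations through `lm`, reporting each exposure's direct effect. With a
single exposure it reproduces univariable IVW exactly (asserted to
1e-12), because `sigma^2` of the weighted fit *is* `Q/(J-1)`. A
per-exposure conditional instrument-strength approximation (residual
instrument signal after weighted projection on the other exposures,
scaled to reduce to the mean per-SNP F when E = 1) is attached and
warns below 10.

**Two-step mediation.** `run_mediation()` estimates β1
(exposure→mediator, univariable IVW on the exposure's instruments), β2
(mediator→outcome) and the total effect, and combines them in
`two_step_mediation()`. β2 defaults to the MVMR coefficient of the
mediator adjusted for the exposure, over the *mediator's* instruments —
the standard two-step choice, because an unadjusted β2 absorbs the
exposure's direct pathway whenever instruments act on both; a
`"univariable"` flag restores the plain IVW alternative. The indirect
effect is β1·β2 with first-order delta variance `β1²se2² + β2²se1²`
(cross term behind a flag; it is quadratically small). Covariance
between the two steps is assumed zero — exact when the three GWAS
samples do not overlap, and an explicit, documented approximation when
β2 and the total effect share the outcome GWAS. Negative proportions
are reported verbatim: inconsistent mediation (direct and indirect
paths of opposite sign) is information, not an error. A zero total
effect leaves the proportion `NA` with a warning while the indirect
effect is still returned.

# Harmonization and instruments

`harmonize()` matches SNPs by identifier (summary data are rsID-keyed;
positions differ across builds), aligns outcome betas to the exposure's
effect allele, resolves non-palindromic strand flips through allele
complements, and treats palindromic (A/T, G/C) SNPs by frequency: under
the default `"conservative"` policy a palindromic SNP is kept only when
both allele frequencies are on the same side of 0.5 and both are
outside [0.42, 0.58]. The 0.42 threshold is the common two-sample MR
default; the underlying studies rarely state their palindromic policy,
so this one is explicit and configurable, and a missing frequency drops
the SNP because the strand cannot be disambiguated. Every decision is
logged per SNP, and the audit actions always partition the shared SNP
set — an invariant the tests enforce.

`clump()` is the standard greedy algorithm (best remaining p-value
becomes an index SNP; same-chromosome neighbours within the window with
r² at or above threshold are removed), with lexical SNP-id tie-breaking
for determinism. It consumes a caller-supplied LD matrix rather than a
bundled reference panel: the algorithm is the portable content, the
panel is a large external resource, and a missing LD entry for an
in-window pair is an explicit error rather than a silent assumption of
independence. Defaults are r² < 0.001 in a 10,000-kb window.

Instrument strength uses `F = ((n-k-1)/k) * (R²/(1-R²))` with per-SNP
`R² = beta²/(beta² + se²·n)`, the approximation that needs no allele
frequencies; a `2p(1-p)beta²` variant sits behind a flag. Both the
joint F and the mean per-SNP F are reported since published F values
are frequently one or the other; the joint formula is primary.

# The synthetic-data generator

`simulate_two_sample()` draws, per SNP: a MAF from
`Uniform(maf_low, maf_high)` (defaults 0.05-0.45), a true exposure
effect `gamma ~ Normal(0, gamma_sd²)`, and standard errors from the
standardized-trait approximation `1/sqrt(2p(1-p)n)` — the right scale
for a biobank GWAS of a standardized score, and the reason sample sizes
are the generator's noise dial. Observed betas are normal around
`gamma` and `theta*gamma + alpha`, where `alpha` is the direct
(pleiotropic) SNP-outcome effect: zero, balanced, directional, or
correlated with `gamma` (an InSIDE violation). Case-control outcomes
are simulated directly on the log-odds scale; the pipeline only ever
sees summary statistics, so no individual-level disease model is
needed. Allele pairs include palindromic SNPs at a configurable
fraction so harmonization is genuinely exercised, and a `noiseless`
flag replaces sampling with means to enable exact oracles.

Default `gamma_sd = 0.022` gives the 60-instrument default set a total
variance explained near 1%, a realistic figure for a personality-trait
GWAS at biobank scale; it is configurable because nothing in the
analysed studies pins it. `gamma_fixed` replaces the normal draw with a
fixed magnitude or a uniform `(low, high)` range of magnitudes — the
range form matters because exactly constant exposure betas make the
Egger intercept unidentifiable (slope and intercept collinear).

`simulate_mediation_chain()` adds a mediator measured in its own
sample: shared-pathway SNPs carry `beta_xm * gamma` on the mediator and
`(beta_direct + beta_xm*beta_my) * gamma` on the outcome, and the
mediator gets its own instruments (null on the exposure) so that β2 is
identifiable. The true proportion mediated
`beta_xm*beta_my / (beta_direct + beta_xm*beta_my)` is recorded in the
truth slot. `simulate_ld_panel()` builds block-diagonal LD (pairwise
`rho` within blocks) with correlated effect draws and block spacing
larger than the default clumping window, making both the r² rule and
the window rule testable. `rho = 1` is rejected (the implied
correlation matrix must be positive definite); near-perfect LD is
simulated with `rho = 0.99`.

What the generator does **not** emulate: realistic LD from reference
panels, allele-frequency-dependent effect-size architecture, sample
overlap between the two GWAS, population stratification, and
binary-trait liability scale subtleties. Passing tests therefore
demonstrate correctness of the estimators under the model the
estimators themselves assume, not robustness to every pathology of real
data.

# Validation regimes

The simulation test conditions were fixed by power analysis before the
tests were run, and are deliberately *strong-instrument* regimes:

- **Calibration** (type-I error of IVW, Egger intercept, indirect
  effect): 60 SNPs, `gamma_fixed = c(0.05, 0.15)`, biobank sample
  sizes, null effects, 2000 replicates. The uniform effect range keeps
  the Egger design matrix well conditioned. Both multiplicative-floor
  corrections make the tests mildly conservative (observed rates near
  0.04-0.055 against the nominal 0.05).
- **Recovery**: true effect 0.157 (log of an odds ratio of 1.17), 1000
  replicates. Weak-instrument attenuation of regression-form IVW is
  approximately `theta * se_X²/E[gamma²]`; in this regime that is about
  1e-4, an order of magnitude below Monte-Carlo resolution, so an
  unbiased implementation passes a 3-Monte-Carlo-SE check and a biased
  one does not.
- **Median robustness**: 40% of SNPs get a constant directional
  pleiotropic effect of 0.01 against `gamma = 0.1` and an outcome
  sample of 1.5 million. The choice follows from the estimator's
  asymptotics: the weighted median's residual bias under one-sided
  contamination is of the order of the per-SNP ratio SE, so the ratio
  SE must sit near 0.014 for the median to stay within 0.02 of truth
  while IVW (bias `0.4 * 0.01/0.1 = 0.04`) does not.
- **MR-PRESSO**: one SNP shifted by 10 outcome SEs, `n_sim = 1000`, 200
  seeded runs; the planted SNP's residual is ~100 null variances, so
  detection should be essentially certain, and clean-data false flags
  are Bonferroni-controlled.
- **Mediation coverage**: chain with true proportion 0.223 (the
  flagship mediated-pathway configuration), 500 replicates, checking
  the delta CI's 95% coverage within [0.93, 0.97].

The full suite runs in under three minutes on one core; problem sizes
were chosen so each Monte-Carlo check has enough replicates for its
stated tolerance and no more.

# Numerical and design choices

- All floats in written tables and reports are formatted to 10
  significant digits; reports are byte-reproducible given a manifest
  and seed, with all internal seeds derived deterministically from the
  manifest seed.
- Clumping ties are broken by lexical SNP id; selection order is
  preserved everywhere so output is stable under input permutation.
- Strict inequalities follow the conventions of the quantities: p <
  5e-8 for instruments, p < 0.05/(number of outcomes) for the verdict.
- The verdict function is pure: it consumes only numbers that the
  report stores, so saved reports re-derive their own verdicts.
- `pleiotropy_frac` uses a deterministic count (`round(frac * J)`) so a
  "40% contaminated" study is exactly that, not binomially close to it.
- Reverse-direction MR is the same operation with tables swapped. With
  a strong forward effect the outcome's "instruments" are the causal
  SNPs seen through the forward effect, and a naive reverse IVW can be
  spuriously significant; in realistic mixtures (mediator-specific plus
  shared SNPs) the sensitivity suite fires and the verdict is negative.
  Steiger filtering, which would address this directly, is out of
  scope and documented as such.

# Known limitations

First-order Wald SEs understate ratio uncertainty when instruments are
modest and the causal effect large, inflating Q. The two-step delta
method assumes zero covariance between steps, an approximation whenever
β2 and the total effect share an outcome GWAS. The MVMR conditional F
is an approximation, not the full Sanderson-Windmeijer statistic. The
generator's LD model is exchangeable within blocks, far simpler than
real haplotype structure. None of these affect the estimators'
correctness under their own assumptions; all of them affect how far
simulation results generalize to real data.
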