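---
title: "Single-variant Mendelian randomization: model, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-variant Mendelian randomization: model, assumptions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpmr)
```

## The problem and the estimator

Observational associations between a dietary exposure and disease are
vulnerable to confounding and reverse causation. Mendelian randomization
(MR) sidesteps both by using a genetic variant as an instrumental variable:
genotypes are fixed at conception, so a variant that shifts the exposure
provides a natural randomization. The design rests on three assumptions —
the variant (1) affects the exposure, (2) is independent of
exposure–outcome confounders, and (3) affects the outcome only through the
exposure (no horizontal pleiotropy). Assumption 1 is checkable with
first-stage statistics; 2 and 3 are not checkable from summary data, which
is why the package's simulator includes a pleiotropy knob that violates
assumption 3 on purpose (see below).

With a single instrument the causal estimate is the **Wald ratio**

$$\hat\theta = \frac{\hat\beta_{GY}}{\hat\beta_{GX}},$$

the variant–outcome coefficient over the variant–exposure coefficient.
When the outcome is binary and $\hat\beta_{GY}$ is a log-odds ratio,
$\exp(\hat\beta_{GY})$ itself is the *per-allele* odds ratio, which is the
scale on which single-SNP MR results are conventionally published; the
per-exposure-unit OR is $\exp(\hat\theta)$.

Two standard errors are offered for the ratio. The first-order SE,
$\mathrm{se}(\hat\beta_{GY})/|\hat\beta_{GX}|$, treats the exposure beta as
fixed; it is the default because the published per-allele scale involves
only the outcome SE. The second-order (delta-method) SE,
$\sqrt{\mathrm{se}_Y^2/\beta_X^2 + \beta_Y^2\,\mathrm{se}_X^2/\beta_X^4}$,
adds the first-stage uncertainty and is what the simulation experiments
use, since there the exposure beta is itself estimated each replicate.
Confidence intervals and p-values use the normal reference throughout —
appropriate at GWAS sample sizes — with the exact quantile
(`qnorm(0.975)` = 1.959964..., not 1.96) so results are reproducible at
full precision.

## Combining independent samples

When two non-overlapping case-control samples inform the same disease, the
per-allele estimates are combined by fixed-effects inverse-variance
meta-analysis: weights $w_i = 1/\mathrm{se}_i^2$, combined beta
$\sum w_i b_i / \sum w_i$, combined SE $(\sum w_i)^{-1/2}$. The package is
deliberately fixed-effects only — with $k = 2$ studies a between-study
variance cannot be usefully estimated, and the analysis this package
packages specifies fixed effects unconditionally. Heterogeneity is still
quantified: Cochran's $Q = \sum w_i (b_i - \bar b)^2$ against
$\chi^2_{k-1}$, and $I^2 = \max(0, (Q - \mathrm{df})/Q) \cdot 100\%$. The
heterogeneity p-value is reported even when $I^2$ floors at zero, and
`fixed_effects_meta()` / `milk_mr_analysis()` flag any pair with
$I^2 > 50\%$ rather than switching models silently — in the built-in
fixture the Parkinson pair (0.048 vs 0.117 on the log-odds scale,
$I^2 = 82\%$) earns exactly that flag, and readers should weigh its
combined estimate accordingly.

## Harmonization

Summary statistics from different consortia may report the opposite
allele, the opposite strand, or both. `harmonize_to_instrument()` resolves
each record to the instrument's effect allele by the unique member of the
group {identity, swap, complement, complement+swap} that maps its allele
pair onto the instrument's; swapping negates the beta and reflects the
allele frequency. Palindromic pairs (A/T, C/G) are the tie-break case:
complement and swap coincide, so orientation is only decidable from allele
frequencies. They are kept only when both sides carry a frequency farther
than 0.08 from 0.5 (a conventional threshold; exposed as an argument) with
consistent orientation; otherwise they are dropped and counted.
Irreconcilable pairs are likewise dropped with a note rather than raising
an error, so one stray row cannot kill a batch run. Harmonization is
idempotent, and the report's six counters always partition the input — the
test suite enforces both by enumeration over all 12 ordered allele pairs.
The built-in rs4988235 fixture is T/C, so none of this machinery activates
for the packaged analysis; it exists for reuse with other instruments.

## Instrument strength

`variance_explained()` implements the Hardy–Weinberg identity
$r^2 = 2p(1-p)\beta_{GX}^2/\sigma_X^2$, where $\sigma_X$ is the **total**
phenotypic SD of the exposure (the brute-force oracle in the tests recovers
exactly this convention from the squared genotype–exposure correlation),
and `f_statistic()` the one-instrument F, $r^2(n-2)/(1-r^2)$. Published
strength figures are carried verbatim with `source = "reported"` and are
deliberately not reconciled: for the built-in milk instrument, $r^2$ = 2%
at $n$ = 73,715 implies F ≈ 1504 while the published F is 515 — the two
numbers evidently come from different underlying regressions, and the
report surfaces that inconsistency (`consistent = FALSE`) instead of
papering over it.

## What the simulator emulates — and what it does not

`sim_scenario()` encodes the data-generating process the estimator
assumes: a diallelic variant in Hardy–Weinberg equilibrium (dosage
$G \sim \mathrm{Bin}(2, p)$), exposure
$X = \beta_{GX} G + \mathcal N(0, \sigma)$, and outcome status drawn with
probability $\mathrm{logit}^{-1}(\alpha + \theta X + \gamma G)$, where
$\gamma$ (`pleiotropy_beta`) is the deliberate assumption-3 violation.
The two samples are independent; the outcome sample is ascertained by
rejection — population individuals are drawn and kept until the case and
control quotas fill, mirroring how case-control GWAS recruit — with a
draw cap (default $10^8$) guarding scenarios where cases are essentially
unobtainable. The exposure GWAS is an OLS fit; the outcome GWAS is a
logistic regression of status on dosage fitted by IRLS (tolerance
$10^{-10}$, 50 iterations max) on the genotype-collapsed table, which
carries the identical likelihood at a fraction of the cost. Fits that hit
the iteration cap or walk the slope past |log-OR| = 15 are reported as
separation, not returned as estimates.

Defaults mirror the milk instrument: allele frequency 0.7 (a European-like
placeholder — the source GWASs do not publish one), 17.1 g/day per allele,
residual SD 120 g/day, baseline log-odds −2.2 (≈ 10% background risk),
null causal effect. One point deserves emphasis: because the odds ratio is
non-collapsible, the per-allele log-OR a GWAS estimates is *not* exactly
$\theta \beta_{GX}$ even with no confounding. `marginal_log_or()` computes
the correct marginal target by numerical integration (genotype-conditional
case probabilities by adaptive quadrature at relative tolerance
$10^{-12}$, then the ML dosage slope on the expected case-control table),
and the recovery experiments measure bias against that quantity, not the
naive product.

Reproducibility uses a documented substream scheme: the scenario seed
seeds the generator once, `n` integers below $2^{31}-1$ are drawn, and
replicate $i$ uses the $i$-th — so replicates are mutually independent and
the whole experiment is bit-for-bit repeatable.

The simulator intentionally omits linkage disequilibrium, covariates,
population stratification, and overlapping-sample bias. Passing recovery
tests therefore show the *estimator and pipeline* are correct under the
model's own assumptions; they do not show that any real dataset satisfies
those assumptions.

## Validation sizing

The calibration experiments run 500 replicates of a scaled-down study —
exposure sample 5,000, 2,000 cases and 2,000 controls — which gives a
first-stage F around 40 (comfortably past the conventional weak-instrument
screen of 10) and a per-replicate ratio SE near 0.003, small enough that a
10% bias at $\theta$ = 0.005 per g/day would be detected with a wide
margin. Null CI coverage lands inside [0.92, 0.98] at these sizes; the
pleiotropy scenario ($\gamma$ = 0.05, $\theta$ = 0) shows a bias exceeding
ten standard errors of the replicate mean — a clean demonstration that
assumption-3 violations propagate straight into the Wald ratio.

## Numerical and reporting choices

* Input validation cross-checks a published p-value against $|b|/\mathrm{se}$
  on the **z scale** (10% relative, absolute below $z = 1$): rounded
  published betas can shift a small p by 30%+ while moving z by 1%, so a
  p-scale check would flag perfectly sound records.
* Published tables round betas to 3 decimals, so quantities recomputed
  from them can land on a display-rounding boundary. In the packaged
  fixture the MS GWAS upper CI bound recomputes to 0.99501, a hair above
  the 0.995 boundary, and so rounds to 1.00 where the source display shows
  0.99; recomputed meta p-values similarly agree to order of magnitude
  only. The tests assert ORs/CIs at two decimals and treat p-values on the
  $\log_{10}$ scale for this reason.
* Degenerate inputs: `se = 0` records are rejected at validation with
  row-numbered diagnostics; a single-study "meta-analysis" passes through
  with `q_df = 0`; heterogeneity on fewer than two estimates warns and
  returns $Q = 0$.
* Full precision is retained everywhere internally; rounding happens only
  in `print()` methods (ORs/CIs to 2 decimals, p to 3 significant
  figures).

## Limitations

Single-instrument MR cannot test assumptions 2 and 3, cannot model
non-linear dose-response from summary data, and offers no multi-variant
sensitivity estimators (IVW over many SNPs, MR-Egger, weighted median are
out of scope by design — with exactly one instrument they do not exist).
The fixed-effects combination assumes one common effect per disease;
where the data argue otherwise the package flags it but does not switch
models.
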