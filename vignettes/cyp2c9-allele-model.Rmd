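---
title: "Estimating CYP2C9 allele activities from a flurbiprofen metabolic ratio"
author: "cyp2c9mr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating CYP2C9 allele activities from a flurbiprofen metabolic ratio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyp2c9mr)
```

## The problem

CYP2C9 is a polymorphic cytochrome-P450 enzyme that clears roughly 15% of
clinically used drugs. In Western European populations three alleles
dominate: \*1 (wild type) and the reduced-activity variants \*2 and \*3.
Genotype-guided dose reduction for CYP2C9 substrates is widely proposed, so
a central quantitative question is: *how much activity does each allele
contribute, and how tightly does genotype actually pin down an individual's
metabolic capacity?*

The phenotyping metric used here is the urinary **metabolic ratio**

$$\mathrm{MR} = \frac{[\mathrm{OHF}]}{[\mathrm{FLB}]},$$

the concentration of the CYP2C9-dependent metabolite
4'-hydroxyflurbiprofen divided by that of the parent probe drug
flurbiprofen, measured in urine two hours after a small (8.75 mg) dose.
A high MR means high metabolic activity. Concentrations below the assay's
limit of quantification (50 nM for both analytes) are unreliable;
`apply_loq_filter()` excludes such records with a strict `<` rule — a value
*at* the LOQ is by definition still quantifiable.

## The allele model

Write $a_{i1}, a_{i2}, a_{i3}$ for the number of copies (0, 1 or 2) of
\*1, \*2, \*3 carried by subject $i$. The model is the zero-intercept
linear regression

$$\mathrm{MR}_i = \beta_1 a_{i1} + \beta_2 a_{i2} + \beta_3 a_{i3} +
\varepsilon_i .$$

There is no intercept because every diploid row satisfies
$a_{i1}+a_{i2}+a_{i3} = 2$: the three columns are collinear with the
constant, and omitting the intercept is what makes the coefficients
directly interpretable as *per-allele-copy MR contributions*. A genotype's
expected MR is then the sum of its two allele contributions
(co-dominant, additive expression), and its activity in percent of
wild type is $100(\beta_i+\beta_j)/(2\beta_1)$ — exactly 100 for \*1/\*1.

`allele_fit()` solves the least-squares problem by QR decomposition
(numerically stable), while still exposing the normal-equation quantities
$(X^\top X)^{-1}$, $\hat\sigma^2 = \mathrm{RSS}/(n-k)$ and the coefficient
covariance $\hat\sigma^2 (X^\top X)^{-1}$ that the standard errors and all
downstream error propagation use. Per-coefficient p-values are two-tailed
Student-t on $n-k$ degrees of freedom; values below representable
precision print as bounds (`< 1e-15`).

### Fitting from summary statistics

All subjects of a genotype share one design row, so the fit depends on the
data only through the per-genotype sufficient statistics
$(n_g, \bar y_g, s_g)$:

$$X^\top X = \sum_g n_g x_g x_g^\top, \qquad
  X^\top y = \sum_g n_g \bar y_g x_g,$$
$$\mathrm{RSS} = \sum_g (n_g-1) s_g^2 + \sum_g n_g (\bar y_g - \hat y_g)^2 .$$

`fit_from_summary()` implements exactly this, which is why a published
genotype table alone reproduces the individual-level fit — coefficients,
covariance and degrees of freedom — to machine precision
(`reference_summary()` carries the bundled 283-subject table, and the
equivalence is property-tested to 10 significant digits). This only works
on the untransformed scale: group means and SDs are not sufficient for a
transformed response, so `fit_from_summary()` refuses transformations.

```{r}
fit <- fit_from_summary(reference_summary())
summary(fit)
genotype_estimates(fit)
```

### Model variants and response scales

Two interaction variants probe the additive assumption:

* `variant = "homozygous"` adds one indicator for *any* homozygote
  (a single term, the minimal dominance check);
* `variant = "genotype"` is the cell-means model, one parameter per
  observed genotype.

`anova(reduced, full)` performs the extra-sum-of-squares F-test. On the
reference cohort neither variant improves on the additive model
(p ≈ 0.8), supporting co-dominant expression. The homozygosity indicator
is *not* identifiable in every cohort: if the only homozygotes present are
\*1/\*1 and no \*2/\*3 heterozygote occurs, the indicator is exactly
collinear with the allele counts and both fitters raise a singular-design
error. Similarly, an allele carried by no subject makes its column zero;
the default is an error naming the column, and `drop_unobserved = TRUE`
drops it instead.

`compare_transformations()` refits the additive model to MR, 1/MR,
log10(MR) and −log10(MR). Residual variances on different scales are not
comparable, so the report gives two scale-free diagnostics per scale — a
Shapiro–Wilk residual-normality statistic and the no-intercept
$R^2 = 1 - \mathrm{RSS}/\sum y^2$ — and ranks by normality with $R^2$ as
tiebreaker. The ranking is a report, not an automatic selection; the two
log scales are mirror images and always tie. On cohorts generated with
additive identity-scale truth, the identity scale ranks first.

## Group comparisons

Because the within-genotype variances differ several-fold, group
comparisons avoid the equal-variance assumption throughout:

* `welch_anova()` — Welch's heteroscedastic one-way F from the
  per-genotype summaries, with Welch–Satterthwaite denominator degrees of
  freedom. Groups below `min_n = 2` subjects carry no usable variance and
  are excluded with a message (the singleton \*3/\*3 group in the
  reference cohort).
* `tamhane_t2()` — all pairwise Welch t statistics with Satterthwaite df,
  declared significant against the Šidák family bound
  $1-(1-\alpha)^{1/m}$ for $m$ pairs. This is the T2 dialect; other
  software differs slightly in the df convention, which is why the chosen
  formulas are spelled out here.
* `flag_outliers()` — a subject is flagged iff
  $|\mathrm{MR}-\bar y_g| > k\, s_g$ (strict, default $k=3$), using the
  group's own moments *including* the candidate point, matching how such
  outliers are reported in genotype tables.
* `covariate_screen()` — two-sided Welch t of MR between the levels of a
  binary covariate (sex, smoking, oral contraception, vegetarian diet),
  missing values excluded pairwise.

## From activity to dose

Under the proportionality rule (dose ∝ MR), a genotype's recommended dose
is the wild-type dose scaled by its percent-of-wild-type activity
(`dose_table()`, `dose_recommendation()`). Two normalisations exist: the
model wild-type estimate $2\hat\beta_1$ (default, the dashed-line
reference of the MR histograms) and the measured \*1/\*1 mean, which is
what the "measured percent" column of a genotype table uses; both are
reported.

Within-genotype spread is translated to the dose scale two ways:

* `dose_interval()` returns $100(\bar y_g \pm k\, s_g)/\mathrm{MR}_{wt}$,
  floored at 0 — the transparent, documented formula. (Published dose
  ranges of this kind sometimes reflect an additional undocumented
  scaling; this package implements only the formula it states.)
* `fraction_outside(cv, delta)` gives the normal-theory probability
  $2\Phi(-\delta/\mathrm{cv})$ that an individual's optimum dose deviates
  by more than a fraction `delta` from the genotype average when the
  within-genotype coefficient of variation is `cv`. With both at 0.20 this
  is $2\Phi(-1) = 0.317$: **one in three** individuals more than 20% off —
  the quantitative core of the argument that genotype-only dosing is
  shaky when CVs are ≥ 20%. The reciprocal is rounded half away from zero
  and always printed next to the raw probability.

## The cohort simulator

`simulate_cohort()` generates cohorts with the statistical structure the
analysis assumes, so every stage is testable without external data:

1. **Genotypes** — two alleles drawn independently per subject
   (Hardy–Weinberg equilibrium). Default frequencies are the exact
   chromosome fractions of the reference cohort, (453, 67, 46)/566; the
   one-decimal percentages 80.0/11.8/8.1 are their display rounding (they
   sum to 99.9, so the exact fractions are used internally).
2. **Phenotypes** — subject mean $\mu_g$ = sum of the two allele effects
   (defaults 0.596, 0.405, 0.113); noise is multiplicative,
   $\mathrm{MR} = \mu_g(1+\varepsilon)$, $\varepsilon \sim N(0,
   \mathrm{cv}_g)$, redrawn while $\mathrm{MR}\le 0$. Default CVs are the
   observed per-genotype values (0.26, 0.20, 0.35, 0.34, 0.22); \*3/\*3,
   whose single carrier defines no CV, is set once to 0.30, the midrange
   of the observed values. `noise = "lognormal"` matches the same mean and
   CV with a lognormal draw, reproducing the right skew visible in real
   MR histograms; CV-matched truncated-normal and lognormal differ
   negligibly at CV ≤ 0.35 (truncation mass < 0.3%).
3. **Extras** — optional binary covariates with multiplicative effects,
   and back-filled concentration pairs (FLB uniform over the observed
   urinary range 0.82–64.7 µM, OHF = MR × FLB) for exercising the file
   readers and LOQ filter.

A single master seed derives fixed per-stage sub-seeds (genotypes:
seed + 1, phenotypes: seed + 2), so each stage is independently
reproducible and every generator is a pure function of (configuration,
seed).

`reconstruct_from_summary()` is the deterministic counterpart: each
genotype group becomes $\bar y_g + s_g z$ with $z$ the equally spaced
sequence $1..n$ centred and scaled to unit sample SD — a fixed, symmetric
pattern whose sample moments equal the summary *exactly*. Any statistic
that depends on the data only through $(n_g, \bar y_g, s_g)$ is therefore
identical between the reconstruction and the real (unavailable)
individual-level data; statistics that depend on higher moments (Shapiro
normality, skewness, outlier structure) are *not* faithful on the
reconstruction, and nothing in the package treats them as such.

### What the simulator does and does not emulate

It emulates HWE genotype sampling, additive allele effects, per-genotype
multiplicative noise with optional right skew, covariate effects and raw
concentration pairs. It does **not** emulate assay measurement error, LOQ
censoring mechanisms, urine-collection timing, linkage between covariates
and genotype, or pharmacokinetic time courses — so passing recovery tests
show the *statistical* machinery is correct under the model's own
assumptions, not that the model captures every feature of real cohorts.

### A note on heteroscedasticity

Per-genotype CVs imply error variances proportional to $\mu_g^2$, while
the OLS standard errors pool one residual variance. The pooled SE is
calibrated for $\hat\beta_1$ (whose information comes overwhelmingly from
the dominant \*1/\*1 group) but conservative — larger than the true
sampling SD — for $\hat\beta_2$ and $\hat\beta_3$, whose groups are less
variable than the pool; the package's simulation tests assert exactly
this pattern. For the same reason the classical nested F-test holds its
nominal level under iid errors but over-rejects somewhat under
CV-proportional noise; the Welch machinery is provided for the group
comparisons precisely because equal variances cannot be assumed.

## Numerical and design choices

* Sample SD uses the $n-1$ denominator everywhere (a singleton group has
  no SD, shown as `NA`/`.`).
* LOQ boundary: strict `<` (values at the LOQ are kept).
* If a cohort file carries both an `mr` column and a concentration pair
  that disagree by more than 1e-6 relative, the reader raises an error
  rather than silently preferring one source.
* Units are declared in the file header (`# units=nM|uM`) and normalised
  to nM internally.
* Rows whose genotype cannot be parsed (unknown allele, malformed label)
  are rejected with an error naming the offender — a cohort with failed
  genotypings must be filtered before import.
* `one_in_n` reciprocals round half away from zero; raw probabilities are
  always shown alongside.
* Display rounding (3 decimals for coefficients, integer percents)
  happens only in print methods and serialisers; all internal propagation
  is full precision.

## Problem sizes used by the test suite

The property and calibration tests run, per the package's own choice of
problem sizes: 1000 replicate cohorts of n = 283 for effect recovery and
SE calibration, 1000 replicates for the nested-F type-I rate under iid
noise, 100 random small cohorts (n ≤ 30) for the brute-force
least-squares cross-check (6 significant digits) and the
summary/individual equivalence (10 significant digits), and a 10⁵-draw
Monte-Carlo confirmation of the $2\Phi(-\delta/\mathrm{cv})$ tail
formula.

## Limitations

The package estimates allele contributions for the three-allele \*1/\*2/\*3
system only; rarer CYP2C9 alleles are rejected at parsing. The dose
translation is bare proportionality — no pharmacokinetic model, no
drug-specific dosing logic, and no clinical advice. Covariate screening is
marginal (one covariate at a time); the regression itself is not
covariate-adjusted.
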