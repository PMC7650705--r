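---
title: "Genomic prediction for early growth traits: models, calibration and design choices"
author: "yakGP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction for early growth traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(yakGP)
```

yakGP re-implements, as a tested and reusable pipeline, the genomic
evaluation workflow applied to early growth traits in a herd of 354
Ashidan yaks genotyped on a dense bovine SNP chip: variant quality
control, a marker-derived relationship matrix, REML variance components
and heritability, GBLUP and four Bayesian marker-effect models, and
repeated five-fold cross-validation. This vignette is the package's own
account of the science: the models and their assumptions, the parameters
that matter and their defaults, what the synthetic-herd generator does and
does not emulate, and the numerical and design choices made where the
published description left the design open.

## The statistical models

All five predictors share one additive phenotype model. For animal $i$
with genotype codes $z_{ij} \in \{0,1,2\}$ at markers $j = 1,\dots,m$:

$$y_i = \mu + \sum_{j=1}^m z_{ij} g_j + e_i,
  \qquad e_i \sim N(0, \sigma_e^2).$$

Only an intercept is fitted — no other fixed effects — matching the
single-farm, single-birth-season design of the study herd.

**GBLUP.** The animal-level form $y = 1\mu + g + e$ with
$g \sim N(0, G\sigma_a^2)$ replaces the pedigree numerator relationship
matrix with the VanRaden (method 1) genomic relationship matrix

$$G = \frac{MM'}{2\sum_j p_j(1-p_j)},$$

where column $j$ of $M$ is $z_{\cdot j} - 2p_j$ and the $p_j$ are the
observed sample allele frequencies (the only frequencies available to a
study with no external reference panel). With observed frequencies the
columns of $M$ sum to zero, so the rows of $G$ sum to zero exactly and
its mean diagonal is close to 1 for a panel near Hardy–Weinberg
proportions — both properties are asserted in the test suite. GEBVs solve
Henderson's mixed-model equations with shrinkage ratio
$\lambda = \sigma_e^2/\sigma_a^2$; the implementation uses the equivalent
phenotypic-covariance form $\hat g = \sigma_a^2 G V^{-1}(y - 1\hat\mu)$,
$V = \sigma_a^2 G + \sigma_e^2 I$, which is algebraically identical and
lets masked-fold prediction and whole-data fitting share one code path.
GBLUP is exactly equivalent to ridge regression on centered marker codes
with per-marker variance $\sigma_a^2 / (2\sum_j p_j(1-p_j))$; the test
suite checks this equivalence to $10^{-6}$ on random instances, which
pins the scaling conventions.

**The Bayesian alphabet.** The four samplers differ only in the prior on
the marker effect variance:

| model | effect prior | variance prior | inclusion |
|---|---|---|---|
| Bayes A | $g_j \sim N(0, s_j^2)$ | $s_j^2 \sim$ scaled-inv-$\chi^2(\nu, S)$ | all markers |
| Bayes B | as A | as A | prob. $1-\pi$, $\pi$ fixed |
| Bayes C | $g_j \sim N(0, s^2)$ (common) | $s^2 \sim$ scaled-inv-$\chi^2(\nu, S)$ | prob. $1-\pi$, $\pi \sim U(0,1)$ |
| Bayesian Lasso | $g_j \sim N(0, s_j^2)$ | $s_j^2 \sim \mathrm{Exp}(\lambda^2/2)$, $\lambda^2 \sim \Gamma(a,b)$ | all markers |

Each is fitted by a single-site Gibbs sampler (C++): the intercept is
sampled (not profiled), marker effects are updated one at a time against
the running residual, and Bayes B/C use the standard joint
(indicator, effect) update in which the effect is integrated out of the
inclusion odds — this avoids the reducibility of updating the indicator
conditional on a sampled effect. The Lasso follows the
inverse-Gaussian data augmentation for $1/s_j^2$. Genotype codes enter on
the $\{0,1,2\}$ scale and are centered internally by twice the observed
allele frequency; those frequencies are stored with the posterior so that
animals unseen in training are scored consistently
(`gebvFromEffects()`).

**Evaluation.** Predictive ability is the Pearson correlation between
GEBV and phenotype in a validation fold whose phenotypes were masked
during fitting. Accuracy divides ability by $\sqrt{h^2}$. The square-root
denominator is a deliberate design decision: the published table of
ability/accuracy pairs reconciles cell by cell under
$r/\sqrt{h^2}$ (e.g. $0.164/\sqrt{0.35} = 0.277$,
$0.044/\sqrt{0.07} = 0.166$) and not under $r/h^2$, so the square root is
the convention the reported numbers were computed with. 39 of the 40
published cells reproduce at 3-decimal rounding; the one exception
(GBLUP, 12-month chest girth: printed 0.220 vs computed
$0.129/\sqrt{0.25} = 0.258$) is consistent with a table typo, since the
printed GBLUP column mean (0.253) reconciles with 0.258, not 0.220. No
check in this package depends on that cell.

## REML: algorithm and numerical choices

Variance components maximise the restricted likelihood of
$y = 1\mu + g + e$ by average-information (AI) REML. The relationship
matrix is eigen-decomposed once ($G = UDU'$), the model is rotated by
$U'$, and every iteration then works with a diagonal covariance
$\sigma_a^2 D + \sigma_e^2 I$ at $O(n)$ cost — an implementation choice
that makes the 200-fit recovery studies in the test suite cheap. Details
that matter:

* **Updates.** AI steps with an EM fallback whenever an AI update leaves
  the parameter space; if the EM step is also non-positive the component
  is floored at $10^{-8}\,\mathrm{var}(y)$ and iteration continues.
  Convergence is declared when the maximum relative parameter change
  drops below `tol = 1e-8`. Boundary estimates
  ($\sigma_a^2 \to 0$) are reported with the convergence flag, not as
  errors.
* **Standard errors.** $\mathrm{se}(h^2)$ comes from the inverse AI
  matrix at the optimum by the delta method. The published "±" values
  are far smaller than any sampling-theory standard error at $n = 354$
  and their method is unstated, so no check is tied to them.
* **Validation.** The REML solution is tested against a dense grid
  search of the restricted likelihood evaluated from first principles on
  full matrices (agreement to 3 decimals), plus exact scale-equivariance
  and shift-invariance properties.
* **Positive definiteness.** A non-PD $G$ (duplicate animals, more
  animals than informative markers) triggers an error that points to
  `blendGRM()`; the default blend $G^* = 0.95\,G + 0.05\,I$ bounds the
  smallest eigenvalue at 0.05 and is recorded in the GRM object. The
  weight is exposed because the study's software defaults in this respect
  are undocumented.

The heritability identity $h^2 = \sigma_a^2/(\sigma_a^2+\sigma_e^2)$
applied to the eight published variance-component pairs reproduces the
printed heritabilities within one unit of their 2-decimal precision; seven
of eight reproduce at exact rounding. The exception is the 12-month
withers height row, where the printed components give 0.2258 (rounds to
0.23) against a printed 0.22 — an artifact of the table's own rounding,
documented here rather than hidden.

## Bayesian hyperparameters and chains

Defaults, all exposed in `bayesHyperparams()` and recorded in the
returned object:

* $\nu = 4.2$, the conventional degrees of freedom for
  scaled-inv-$\chi^2$ marker-variance priors.
* $S$ solved at fit time so the prior mean marker variance matches
  $\hat\sigma_a^2 / ((1-\pi)\,2\sum_j p_j(1-p_j))$, with
  $\hat\sigma_a^2$ from a REML pre-fit on the same data — the standard
  way of putting the prior on the scale the data imply.
* Bayes B $\pi = 0.95$; Bayes C initialises $\pi$ at 0.5 under its
  uniform prior (supplying an explicit $\pi$ to Bayes C pins it, which
  the degenerate conjugate checks use). Lasso $a = b = 0.1$.
* Residual variance prior: scaled-inv-$\chi^2$ with 4 degrees of freedom
  and mode at half the phenotypic variance — weakly informative, it
  guards the first iterations without influencing the posterior
  noticeably at $n \geq 100$.
* Chains: 20,000 iterations, 5,000 burn-in, thinning 5 by default,
  chosen for a 354-animal, $10^4$-marker panel. The test suite and the
  acceptance script run reduced chains (2,000–5,000 iterations) after
  checking, via the stored split-chain means, that doubling the chain
  length moves posterior-mean GEBVs by less than twice the Monte Carlo
  standard error.

Correctness anchors: with both variances held fixed each sampler's
posterior mean matches the conjugate closed form on a one-marker model
(within 3 Monte Carlo standard errors over replicate chains); Bayes C
with $\pi$ pinned at 0 and a fixed common variance reproduces ridge
GEBVs; Bayes B's posterior inclusion probabilities rank true QTL above
null markers on herds simulated with known architecture. Chains are
bit-reproducible from the seed because all randomness flows through R's
RNG.

## Quality control

Thresholds follow the study protocol verbatim, including the direction of
each inequality: markers are removed when call rate $\leq 0.90$, when the
Hardy–Weinberg test gives $p < 10^{-6}$, or when MAF $< 0.01$; animals
are retained when their call rate $> 0.90$. The HWE statistic is the
1-df Pearson chi-square against expectations at the sample allele
frequency — the conventional chip-QC default at this threshold — with a
conditional exact test available behind `method = "exact"`; monomorphic
markers return $p = 1$ by convention. Missing calls are excluded from
MAF and HWE counts at QC time (they are mean-imputed only later, for the
GRM). Because the published description lists thresholds without an
order and order changes the per-filter counts, the order is fixed and
logged: SNP call rate, then HWE, then MAF, then sample call rate. Marker
density is summarised in half-open 1-Mb windows per chromosome.

## The synthetic herd: what it emulates, and what it does not

The generator's defaults are the study conditions: 354 animals; marker
allele frequencies drawn uniform on $[0.06, 0.5]$ (the post-QC MAF
spectrum reported for the yak panel); markers spread over 29 autosomes;
an architecture of 20 large-effect QTL carrying half the genetic
variance over a polygenic background (growth traits are typically
controlled by a few large QTL plus many small effects); heritability
targets spanning the published 0.07–0.57 range; phenotype scale set to
the 6-month body-weight summary (mean 84.18 kg, SD 10.31 kg). The SNP
count defaults to 10,000 — a desk-scale stand-in for the ~98.7k post-QC
panel that preserves the MAF spectrum, LD level and architecture the
methods are sensitive to.

Two parameters are genuine free choices, fixed once at design time:

* **LD (`ldDecay = 0.95`).** Adjacent-marker dependence uses first-order
  haplotype copying on the latent-quantile scale: each haplotype's
  allele at marker $j$ is the indicator $u < p_j$ of a uniform $u$ that
  with probability `ldDecay` is copied from the previous marker.
  Copying on the quantile scale keeps every marker's marginal frequency
  exactly at its drawn $p_j$ (so the MAF-spectrum tests stay exact)
  while inducing positive adjacent-marker correlation. The default 0.95
  emulates the strong local LD of a dense bovine chip segregating in a
  small closed herd; the study does not report its panel's LD, so this
  is a declared choice, not an inference.
* **Genetic correlation with the later age
  (`geneticCorrelationLater = 0.9`).** The later-age (30-month analog)
  genetic value is $\rho\,\tilde a_{early} + \sqrt{1-\rho^2}\,\tilde
  a_{indep}$ with an independent residual, both stages at the same
  heritability and scale. $\rho = 0.9$ sits at the upper range of
  reported weaning-to-adult weight genetic correlations in bovids and
  calibrates the pipeline so whole-herd early-age GEBVs correlate with
  later-age phenotypes at roughly 0.4, the regime the published
  correlation table reports (0.374–0.422). Under these defaults the
  correlation across seeds falls in about [0.30, 0.47].

Residual variance is scaled to the realized genetic variance so the
expected heritability equals `h2Target`; the realized $h^2$ recorded in
the truth object uses the realized variances of both components, and its
mean over replicates stays within ±0.03 of the target (a tested
invariant).

What the generator does **not** emulate — and therefore what passing
tests do and do not show: there is no pedigree or family structure (real
herds have half-sib families that raise GBLUP accuracy), no
coalescent-realistic LD beyond first-order copying, no dominance or
epistasis, no genotyping error, and both age stages share one phenotype
scale. Passing the recovery and cross-validation tests demonstrates that
the estimators are correct and internally consistent under the assumed
additive model, not that real-yak accuracies would match; the published
real-data abilities (0.039–0.295) are not reproducible quantities because
the animal data are not public. The printed-number identities among the
published summary tables are reproduced exactly from the tables
themselves, which ship with the package.

`corruptForQC()` completes the loop for the QC module: it injects
missing calls (call rate 0.85 against the 0.90 filter), markers forced
below MAF 0.01 (a single heterozygote), and heterozygote-free
half-and-half columns whose HWE chi-square equals $n$, driving
$p < 10^{-6}$ deterministically for $n \geq 25$. Injection sets are
disjoint (precedence missing > maf > hwe) and the returned manifest is
compared field by field against the QC report in the tests.

## Cross-validation design

`makeFolds()` re-randomises the partition for every repeat (the
published description does not say whether its ten repeats re-drew the
folds; re-drawing is assumed, as is standard). Fold sizes differ by at
most one — at $n = 354$, $k = 5$ that is 71/71/71/71/70. Fold
assignments are shared across methods so method comparisons see
identical partitions. Aggregation is the mean of per-fold correlations
over all repeat×fold cells ("mean of the correlation values"); pooling
predictions before correlating is deliberately not the default. Accuracy
uses the whole-data REML $\hat h^2$, not per-training-fold estimates —
this matches how the published accuracy table reconciles with the
published heritability table. GBLUP in CV re-solves the masked
mixed-model equations per fold with whole-data variance components (the
two prediction routes, joint MME and projection
$G_{vt}G_{tt}^{-1}\hat g_t$, are algebraically identical and both
implemented as a cross-check); Bayesian methods are refitted per
training set. Animals missing a trait are dropped per trait, mirroring
the varying per-trait record counts in the study herd.

## Problem sizes used by the tests and the acceptance script

All sizes are the package's own desk-scale choices, selected so the full
suite runs in a few minutes while keeping every statistical check
well-powered: REML recovery uses 25 replicate herds of 400 animals ×
2,000 markers per heritability target; the ability-on-heritability
regression uses 20 seeds × 4 heritability levels at 300 × 1,000 with
GBLUP (slope positive in ≥ 95% of seeds) plus a Bayes C run at 5,000
iterations; the acceptance script runs one 354 × 2,000 herd with 5×2-fold
GBLUP CV and a 5,000-iteration Bayes C CV. The methods' costs scale as
$O(n^3)$ (one eigendecomposition) for REML and
$O(\text{iterations} \times nm)$ for the samplers, so the defaults
extrapolate directly to chip-scale panels.

## Known limitations

Single-trait models only (the later-age analysis is a correlation test,
not a multi-trait REML); no dominance or epistasis; no LD pruning,
relatedness-based sample exclusion or sex checks in QC; text PLINK
(ped/map) is the interchange format — binary bed is out of scope; the
exact software options (G-matrix construction, blending, priors, chain
lengths) used by the original analysis are unreported, so this package's
defaults are declared and logged rather than inferred; and the
"±" standard errors printed alongside the published heritabilities
cannot be reproduced because their method is unstated.
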