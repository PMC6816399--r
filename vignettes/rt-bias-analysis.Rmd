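---
title: "Quantifying reverse-transcription GC bias in 16S rRNA amplicon surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying reverse-transcription GC bias in 16S rRNA amplicon surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtshift)
```

## The problem

Ribosome-based (RNA) 16S rRNA amplicon sequencing requires a reverse
transcription (RT) step before amplification. Different RT enzymes and
reaction temperatures capture templates with different efficiency, and that
efficiency plausibly depends on template GC content: GC-rich rRNA folds into
more stable secondary structure, which a low-temperature reaction resolves
poorly. The result is a systematic, condition-dependent distortion of the
community profile that can masquerade as biology.

`rtshift` implements the downstream statistical analysis of such an
experiment. Its input is what an amplicon pipeline produces — an OTU count
table, a taxonomy, representative sequences and sample metadata mapping
samples to (enzyme, temperature) conditions with replicates. Its outputs
are class-level abundance profiles per condition, a normalized
between-condition enrichment statistic with propagated uncertainty,
abundance-weighted class GC content, and per-condition-pair regressions of
enrichment on GC.

## The enrichment statistic and its uncertainty

For a taxonomic class with mean relative abundance $A$ in one condition and
$B$ in another (each a mean over that condition's replicates), the
normalized enrichment is

$$E = \frac{A - B}{A + B}.$$

$E$ is dimensionless and bounded: 0 when the class is equally proportional
in both conditions, $+1$ when it occurs only in the first, $-1$ when it
occurs only in the second. It is antisymmetric in the two conditions and
invariant to rescaling both abundances, which makes it comparable across
classes of very different absolute abundance. When $A + B = 0$ the
statistic is undefined; such records are flagged and excluded from
regression rather than imputed.

Uncertainty is propagated from the replicate standard deviations
$\delta A$ and $\delta B$ by a first-order Taylor (delta-method) expansion.
With $\partial E/\partial A = 2B/(A+B)^2$ and
$\partial E/\partial B = -2A/(A+B)^2$,

$$\delta E = \frac{2}{(A+B)^2}\sqrt{B^2\,\delta A^2 + A^2\,\delta B^2}.$$

The test suite verifies this against the symbolic gradient formula to
near machine precision and against Monte-Carlo perturbation with small
Gaussian noise.

Replicate dispersion enters as the sample standard deviation
(denominator $n-1$) by default; a standard-error mode
(`dispersion = "se"`) is available. The default matches the view of
$\delta A$, $\delta B$ as the spread of a condition's replicates, not the
uncertainty of their mean.

## Pipeline stages and their parameters

1. **Rarefaction** (`rarefy`, default `depth = 9000` reads/sample): a
   single without-replacement (multivariate hypergeometric) draw per
   sample, delegated to `vegan::rrarefy`. Samples shallower than the depth
   are dropped and listed. One draw — not an average over repeated
   rarefactions — so the preprocessed table is an integer count table with
   exactly equal totals.
2. **Outlier scoring** (`flag_outliers`, default `k = 3`): each sample is
   scored by its mean Bray–Curtis dissimilarity (on relative abundances) to
   the other replicates of its condition, and flagged when the score
   exceeds the within-condition median + $k\cdot$MAD. Manual outlier
   removal by eye is not reproducible, so the package offers this
   deterministic surrogate, *report-only* by default; removal requires
   `drop_flagged = TRUE` or an explicit `drop_samples` list.
3. **Replicate equalization** (`equalize_replicates`): uniformly random
   removal of excess samples down to a common replicate count (default the
   minimum across conditions), deterministic given its seed.
4. **Class aggregation and profiles**: counts are summed to taxonomic
   class (rank 3 of the lineage); OTUs without a class rank are pooled
   under the sentinel `"Unclassified"`. Per condition, mean and sd of
   relative abundance across replicates form the profile.
5. **Weighted class GC** (`class_weighted_gc`): per-OTU GC is the expected
   GC fraction of the representative amplicon sequence under the IUPAC
   alphabet (an ambiguity code contributes the fraction of its expansion
   that is G or C, so ambiguous positions neither bias nor shorten the
   sequence). Class GC is the abundance-weighted mean over member OTUs,
   with the grand-mean relative abundance across all retained samples as
   the default weight basis — one covariate per class, shared by every
   condition pair.
6. **Regression** (`fit_gc_regression`): ordinary least squares of
   enrichment on weighted GC per condition pair, with slope $t$ and
   two-sided $p$, adjusted $R^2$, significance codes (`*`, `**`, `***` at
   $p<0.05, 0.01, 0.001$), and assumption diagnostics — Shapiro–Wilk on
   residuals and Breusch–Pagan for homoscedasticity. Pairs failing either
   diagnostic (at 0.05) carry a bullet-style caveat flag in the output and
   should not be interpreted as significant regardless of their $p$.

Condition pairs are oriented by ordering conditions by enzyme label and
then temperature ascending; the orientation is reported in every output
row because the sign of $E$ depends on it. Raw $p$-values are reported by
default (six pairwise tests in a 4-condition design); Holm adjustment is
available via `holm = TRUE`.

## The synthetic-data generator

`simulate_experiment` draws complete experiments with the structure the
analysis assumes:

- A base community of `n_classes` classes (default 40) with log-normal
  (sdlog = 1) abundances, spanning a GC gradient (default evenly spaced on
  0.35–0.75, the range typical of bacterial 16S V3–V4 amplicons), a few
  OTUs per class with jittered GC, plus a small `"Unclassified"` component
  (default 2% of the community).
- A capture-efficiency model $e(g) = e_0\,\mathrm{e}^{-\lambda g}$ in GC
  fraction $g$: the simplest monotone one-parameter family expressing
  "low reaction temperature penalizes GC-rich templates". $\lambda = 0$
  recovers an unbiased reaction. The default condition set assigns
  $\lambda = 3$ to ImProm-II 42 °C, $\lambda = 1$ to ImProm-II 55 °C and
  $\lambda = 0.5$ to both SuperScript IV 55 °C and TGIRT 57 °C, so the two
  high-temperature enzymes are exchangeable while the low-temperature
  reaction is strongly biased. The exponential form is a declared modeling
  choice, not a mechanistic claim; an optional per-(condition, class)
  log-normal effect (`enzyme_effect_sd`) adds GC-*independent* enzyme bias
  of the processivity type, producing between-enzyme differences that GC
  cannot explain.
- Replicate noise is Dirichlet-multinomial: replicate class proportions
  are Dirichlet with concentration $\theta w$ around the biased expected
  profile $w$ (default $\theta = 200$, giving replicate coefficients of
  variation of a few tens of percent for mid-abundance classes, in line
  with biological replicates of amplicon data), then counts are
  multinomial at fixed depth (default 9000) distributed over member OTUs.
- Representative sequences are composition-exact random sequences at each
  OTU's assigned GC: GC is the only sequence property the pipeline
  consumes, so no phylogenetic realism is attempted.

What passing simulation-based tests shows — and what it does not: the
generator reproduces the *statistical* structure (compositionality, even
depth, replicate overdispersion, GC-linked and GC-independent bias), not
the upstream realities of real surveys (chimeras, primer mismatch,
clustering artifacts, taxonomy error, phylogenetically structured GC).
Results on simulated data validate the inference machinery, not any claim
about a particular environmental community.

## Calibration and power

`recovery_experiment` simulates many independent experiments — each with a
fresh community and GC assignment, because a type-I-error or power
statement is about repetitions of the whole study design — and summarizes
the GC regression of the first condition pair. With identical efficiency
parameters across conditions the rejection rate at $\alpha = 0.05$ is
nominal (the test suite checks 1,000 null datasets of 20 classes at depth
2,000 against the 95% binomial interval — sizes chosen to make thousands
of full pipeline runs cheap while keeping ≥ 18 regression points per
dataset). `power_curve` sets the first condition's $\lambda$ above the
second's by a grid of differences under common random numbers; power
increases monotonically in the injected bias and the fitted slope is
negative — high-GC classes depleted in the biased (low-temperature)
condition — matching the direction the enrichment analysis is designed to
detect (the suite uses 40 classes at depth 9,000 with 100 experiments per
grid point).

## Numerical and degenerate-input choices

- "Top 15% of the most abundant classes" (the stacked-bar summary) is
  interpreted as a *rank* fraction: classes are ranked by grand-mean
  relative abundance and the top $\lceil 0.15K \rceil$ of $K$
  non-"Unclassified" classes are kept, the rest merged into a
  "Low abundance groups" category (mean = sum of member means,
  sd = root-sum-square). Ties at the cutoff break lexicographically.
  `top_fraction` is configurable.
- Diversity indices (richness, Shannon in nats, Pielou $J = H/\ln S$) are
  computed at OTU level on the rarefied table; $J$ is reported missing
  when richness is 1. A Kruskal–Wallis screen per index is reported as a
  convenience, with no claim attached.
- Classes with $A + B = 0$ are excluded from regression (the statistic is
  undefined there), not set to 0.
- A perfect (zero-residual) fit leaves the normality and homoscedasticity
  diagnostics undefined; they are reported as `NA` and do not trip the
  caveat flag.
- Zero GC variance across classes is a hard "degenerate covariate" error;
  fewer than 3 usable classes is an error.
- All randomness flows through named seeds (rarefaction, equalization,
  simulation); every step is a pure function of inputs + seeds, and
  pipeline reruns are byte-identical.

## Known limitations

- The enrichment statistic operates on compositions; abundance changes in
  one class necessarily perturb others. Log-ratio alternatives are out of
  scope — the package implements this statistic, and the regression's
  mild inter-class dependence is the price of matching it.
- Class GC is computed from amplicon representative sequences (V3–V4
  region), a proxy for — not a measurement of — genomic or full-length
  rRNA GC.
- The OLS significance machinery assumes independent, homoscedastic
  Gaussian residuals across classes; the diagnostics flag but do not
  correct violations.
- Upstream processing (read merging, OTU clustering, taxonomy assignment)
  is consumed, not implemented; biases introduced there are invisible
  here.
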