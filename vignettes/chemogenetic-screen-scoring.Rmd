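---
title: "Scoring chemogenetic interactions in pooled CRISPR screens"
author: "drugzr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring chemogenetic interactions in pooled CRISPR screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drugzr)
```

## The problem

A pooled CRISPR knockout drug-modifier screen asks, for every gene at once:
does knocking this gene out make a drug work better (a synergistic or
synthetic-lethal interaction) or worse (a suppressor or resistance
interaction)? Cells transduced with a genome-scale guide library are split
into a drug-treated arm and an untreated control arm, grown for several
doublings under sub-lethal dosing, and sequenced. The readout is a table of
read counts per guide per sample; the signal is a *difference between arms*
in how a gene's guides change abundance. Counts are noisy and overdispersed,
per-guide effects vary within a gene, and most genes do nothing, so the
scoring problem is one of careful variance estimation followed by
aggregation.

## The model

### Fold changes

Each sample is scaled to a common depth of $10^7$ reads. For replicate $r$
and guide $i$,

$$\mathrm{fc}_{r,i} = \log_2
  \frac{\mathrm{norm}(T_{r,i}) + c}{\mathrm{norm}(C_{r,i}) + c},$$

with pseudocount $c = 5$ (in normalized read units) so the ratio is always
finite. The pseudocount is added *after* normalization; a consequence worth
knowing is that multiplying all raw counts by any constant changes nothing
at all, because normalization absorbs the scale before the pseudocount is
applied.

### Empirical-Bayes variance

A guide's fold-change variance depends strongly on its sequencing depth:
low-count guides are noisy. Rather than fitting a parametric mean–variance
curve, each guide borrows an empirical estimate from its depth
neighbourhood: guides are ranked by control read count (descending; ties
broken by guide identifier so results are machine-independent), and the
guide's $\mathrm{eb\_std}$ is the root mean square of the fold changes of
the $N = 1000$ guides nearest to it in rank,

$$\mathrm{eb\_std}_{r,i} = \sqrt{\tfrac{1}{N}\textstyle\sum_{j \in
  \mathcal{W}(i)} \mathrm{fc}_{r,j}^2}.$$

Two deliberate choices here:

* The RMS is taken about $\mu = 0$, not about the window mean. Most guides
  are null, so the window RMS about zero estimates the null spread; a
  window mean estimated from 1000 fold changes would differ negligibly, and
  zero is the model's null.
* Windows are *centered* on the guide's rank and clamped at both ends of
  the ranking (the first and last $\lfloor N/2\rfloor$ guides share the
  first or last full window). Centering borrows symmetrically from
  slightly-deeper and slightly-shallower guides; clamping keeps every
  window at full size $N$, so edge guides are not estimated from fewer
  observations. Samples with fewer than $N$ guides use a single global
  window.

With the **monotone filter** (on by default) a running maximum down the
ranking enforces that the estimated standard deviation never decreases as
read count decreases. Sampling noise in the windowed estimate can otherwise
produce dips that would inflate the Z-scores of poorly-measured guides. The
filter is kept as the default because its cost is at most a slight
conservatism for low-count guides.

Degenerate case: if every fold change in a window is zero the raw estimate
is zero; it is replaced by the smallest positive estimate in the sample. If
the *whole* sample is zero (a treated arm identical to its control), guide
Z-scores are set to zero — null data stays null rather than erroring.

### Gene scores

Guide Z-scores $Z_{r,i} = \mathrm{fc}_{r,i} / \mathrm{eb\_std}_{r,i}$ are
summed over all guides and replicates of a gene and divided by the square
root of the number of summed terms, so that under the null the aggregate is
variance-stabilized across genes with different guide numbers:

$$\mathrm{normZ}_g = \frac{\sum Z_{r,i_g}}{\sqrt{n_g}}.$$

### Calibration, p-values, FDR

The raw aggregate is *not* exactly standard normal under the null: a
guide's fold change and its control read count are anti-correlated (the
control draw appears in both the ratio's denominator and the ranking), and
the monotone filter shrinks the positive tail of low-count guides. Measured
on simulated null screens the raw scores run at mean $\approx -0.15$ and sd
$\approx 0.95$. Gene scores are therefore calibrated against the screen
itself before p-values are taken: centred on the median and scaled by the
normal-consistent MAD. Robust location/scale is used rather than mean/sd so
that a screen's genuine hits — which can be a sizeable minority of genes at
several sigma — do not inflate the scale and deflate their own
significance. The standardization is linear, so all rank-based and
correlation-based comparisons are unaffected; the raw aggregate remains
recoverable from the reported `sumZ` and `numObs` columns.

P-values come from the standard normal in both directions — lower tail for
synergy (guides depleted under drug), upper tail for suppression — and each
direction is independently Benjamini–Hochberg adjusted across all genes.
The two directions are reported as separate ranked lists because a screen's
consumers ask the two questions separately.

### Paired and unpaired designs

In the paired design (default) each replicate's treated sample is compared
to its own matched control, yielding one fold-change column per replicate;
the variance window is ranked by that replicate's own control reads. In the
unpaired design the mean of the normalized treated columns is compared to
the mean of the normalized control columns, yielding a single fold-change
column. Unpaired mode accepts asymmetric arm sizes; paired mode refuses
them. On simulated screens the two modes rank genes nearly identically
(Spearman $\rho \approx 0.96$), consistent with pairing's theoretical
advantage having little practical effect at this noise level.

## The Gibbs-sampling scorer

`druggs()` replaces the closed-form aggregation with per-gene Bayesian
inference. A gene's guide Z-scores are modelled as
$\mathcal{N}(\mu, 1/\tau)$ with a semi-conjugate prior
$\mu \sim \mathcal{N}(\mu_0, 1/\tau_0)$,
$\tau \sim \Gamma(a, b)$ (shape/rate). The sampler alternates the full
conditionals

$$\mu \mid \tau, z \sim \mathcal{N}\!\left(
  \frac{n \bar y \tau + \mu_0 \tau_0}{n\tau + \tau_0},
  \frac{1}{n\tau + \tau_0}\right), \qquad
  \tau \mid \mu, z \sim \Gamma\!\left(a + \tfrac{n}{2},\;
  b + \tfrac{1}{2}\textstyle\sum (z_i - \mu)^2\right)$$

for $S = 1000$ draws per gene, starting at the data
($\mu = \bar y$, $\tau = 1$). Numerical choices:

* **Rate update.** The conventional conjugate form carries the factor
  $\tfrac12$ on the sum of squares; only this form matches the analytic
  posterior, and it is the default. A `strict_update` flag drops the
  $\tfrac12$ (halving the inferred precision) for comparison.
* **Hyperparameters.** $\mu_0 = 0$, $\tau_0 = 10^{-3}$, $a = b = 0.5$:
  weakly informative, so with even a handful of guide scores the posterior
  mean essentially equals the shrunken data mean
  $(n\bar y + \tau_0\mu_0)/(n + \tau_0)$. All are exposed in
  `gibbs_config()`.
* **Burn-in.** The first 10% of draws are discarded before the posterior
  mean is taken (configurable, including 0). The chain mixes quickly —
  both conditionals are exact draws — so this is cheap insurance, not a
  convergence necessity.
* **Determinism.** A single seed on `gibbs_config()` seeds the run once;
  genes are sampled in alphabetical order, so identical inputs give
  bit-identical output.

The posterior means are then passed through exactly the same robust
standardization and two-directional p/FDR machinery as `drugz()`. On
simulated screens the two scorers correlate at Pearson $r > 0.99$; the
Gibbs route costs roughly two orders of magnitude more compute and exists
as a statistical cross-check, not a replacement.

## What the simulator emulates — and what it does not

`simulate_screen()` generates a paired screen with known truth. Defaults
(chosen once, as the package's study conditions): 1000 genes × 4 guides ×
3 paired replicates; 5% synergy and 5% suppressor genes at mean
$|\log_2|$ shift 2 (per-guide jitter $\mathcal{N}(e, |e|/4)$ so guides of
one gene are correlated but not identical); 10% fitness-only genes at mean
shift $-1$ applied to *both* arms; log-normal guide abundances (sdlog 1,
scaled to mean 1); negative-binomial counts with dispersion 0.25 around a
mean depth of 500 reads per guide. These mirror a genome-scale screen's
structure at desk scale: a real screen has ~70–90k guides and 17–18k genes
but the same guides-per-gene, replicate structure, abundance spread and
overdispersion regime; 500 reads/guide matches common coverage practice;
dispersion 0.25 is in the range fitted to published pooled screens.

Captured: depth-dependent fold-change variance, within-gene effect
correlation, paired count noise, arm-composition shifts caused by strong
planted effects (depth normalization redistributes reads). Not captured:
copy-number cutting toxicity, time-course trajectories, guide-efficiency
differences, bottlenecking/jackpot effects, CRISPRi/a modality differences.
Passing tests on these simulations therefore demonstrate statistical
correctness of the scoring machinery under a realistic noise model, not
robustness to every artifact of real screens.

The fitness-only genes encode a key design premise: a knockout with a
moderate drug-independent fitness cost drops out of *both* arms and must
not be called a drug interaction. Tests verify that fitness-only genes'
|normZ| distribution is indistinguishable from null genes'.

## Enrichment evaluation

`enrichment_curve()` benchmarks a hit list against an annotated gene set
(e.g. DNA damage response genes for a PARP-inhibitor screen): at each FDR
threshold it reports the number of hits, the number of annotated hits, and
the upper-tail hypergeometric probability ($P[X \ge k]$, the standard
over-representation convention) of the overlap. The universe is the set of
genes scored in the screen, not the genome: the question is whether the
screen's hits concentrate in the pathway relative to what the screen could
have returned. A threshold of exactly 1 is treated as the boundary case
returning every gene (BH-adjusted FDRs are capped at 1, so a strict
inequality would exclude them). The packaged
`extdata/ddr_geneset_synthetic.txt` is a hand-picked DDR-like symbol list
for examples; it is not a snapshot of any pathway database.

## Problem sizes and test design

The test suite and the acceptance script run entirely on simulated screens
at the 1000-gene scale (4000 guides), where a full drugZ pass takes well
under a second and a drugGS pass a few seconds; null-calibration checks
average over 20 independently seeded screens. Brute-force oracles — an
$O(m^2)$ Benjamini–Hochberg step-up, explicit-loop variance windows,
exhaustive hypergeometric enumeration, and numerical integration of the
single-observation posterior — are implemented independently in the test
helpers and never share code with the package.

## Known limitations

* No copy-number correction: amplified loci can in principle mask
  interactions (false negatives), though they should not create false
  positives in a treated-vs-control comparison.
* Each time point is an independent run; no joint time-course model.
* The empirical-Bayes window assumes fold-change variance varies smoothly
  with control read count; pathological libraries (e.g. bimodal abundance)
  would violate this.
* Replicate pairing is positional; there is no inference of pairing from
  sample names.
* Tumor-suppressor-like genes whose knockout speeds growth can recur as
  suppressor hits across unrelated drugs; the score reports them
  faithfully, and distinguishing drug-specific resistance from generic
  growth advantage requires an accompanying fitness screen.
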