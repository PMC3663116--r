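---
title: "Inferring transcriptional bursting kinetics from single-cell counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring transcriptional bursting kinetics from single-cell counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burstkin)
```

## The model

Most genes are not transcribed at a steady rate. A promoter switches
stochastically between an inactive and an active state; only the active
state produces mRNA, so transcripts appear in bursts. The standard
two-state ("telegraph") model has four rates: activation `k_on`,
inactivation `k_off`, transcription `s` (active state only), and mRNA
decay `d`. Dividing all rates by `d` expresses them per mean mRNA
lifetime, which is the same as fixing `d = 1`; `burstkin` works in these
units throughout. Estimates can be converted to absolute time only with
independently measured decay rates.

At stationarity the fraction of time spent active is
`k_on / (k_on + k_off)` (`active_fraction()`), and the mRNA copy number
follows the Poisson-beta distribution: the count is Poisson with rate
`s * p`, where the auxiliary variable `p ~ Beta(k_on, k_off)` is the
(random) activity level. Its closed-form moments (`pobe_moments()`) give a
Fano factor

    phi = 1 + s * k_off / ((k_on + k_off) * (k_on + k_off + 1))

which is always at least 1 — bursty transcription is at least
Poisson-dispersed — and tends to 1 as switching becomes fast, which is
precisely why fast-switching genes are statistically indistinguishable
from Poisson noise. Two derived quantities summarize bursting
(`burst_summaries()`): the burst size `s / k_off` (mean transcripts per
active period) and the burst frequency `k_on` (bursts per mRNA lifetime).

## Evaluating the Poisson-beta pmf

`dpobe()` integrates `dpois(x, s * p)` against the beta density over
`p` in (0, 1). Direct quadrature is delicate for two reasons: the beta
density has an integrable singularity at an endpoint whenever its shape
parameter is below 1, and the Poisson factor is sharply peaked in `p` for
large `s`. The integral is therefore split at `p = 1/2`; a half whose
shape parameter is below 1 is transformed by the exact power substitution
(`v = p^k_on` on the left, `w = (1 - p)^k_off` on the right), which
removes the singularity, while halves with shape at least 1 are left on
the natural scale, where the adaptive integrator resolves the Poisson
peak. Each piece is evaluated in log space after subtracting the analytic
maximum of its log integrand (the root of a quadratic), so no
intermediate value can overflow. The confluent-hypergeometric closed form
(`method = "hyp1f1"`, a positive-term Kummer series summed in log space)
serves as an independent cross-check; the two routes agree to better than
1e-11 in relative terms across `k_on, k_off` in [0.01, 100] and `s` in
[1, 500]. The quadrature is the default because no series acceleration is
needed for it to be stable over the whole parameter range.

Finite summation ranges come from `pobe_truncation()`. A moment rule of
the form mean + 12 sd fails in the heavy-tailed regime (tiny `k_on`,
large `k_off`), where rare near-full activations carry around 1e-3 of
mass far beyond it. Because the count given `p` is Poisson with rate at
most `s`, the count is stochastically dominated by Poisson(`s`); the
truncation therefore takes the larger of the moment rule and an extreme
Poisson(`s`) quantile, guaranteeing a truncated tail below 1e-9
everywhere.

## The hierarchical model and its sampler

Counts are modeled per gene i and cell j as
`x_ij ~ Poisson(t_i * t_j * s_i * p_ij)` with
`p_ij ~ Beta(k_on_i, k_off_i)`, where `t_j` is a per-cell scale factor
and `t_i` a gene-length offset. The per-gene rates get gamma priors in
the scale parameterization (density proportional to
`v^(alpha-1) * exp(-v / beta)`). Defaults (`hyper_params()`):

* `s_i ~ Gamma(1, max_j x_ij)` — an empirical-Bayes choice that is nearly
  flat over the realistic range of the transcription rate for each gene;
* `k_on_i, k_off_i ~ Gamma(1, 100)` — diffuse over the switching-rate
  range in which the parameters are identifiable at all. Rescaling these
  prior scales by two orders of magnitude moves posterior means of
  well-identified genes by under 20% (a test pins this), so conclusions
  are not prior-driven except where a deliberately concentrated prior
  penalizes very large rates.

`t_j` comes from `compute_norm_factors()`: library size times a
trimmed-mean-of-M-values factor (via edgeR, log-ratio trim 0.30,
intensity trim 0.05), rescaled to geometric mean 1 so the factors carry
no global scale. Factors are always computed on the full matrix before
any gene filtering: filtering removes mostly low-count genes that barely
influence the trimmed mean, and fixing the order makes filtering and
normalization commute. The expression filter (`filter_genes()`) drops
genes whose maximum normalized count across cells is below 50; such genes
are dominated by the technical noise of low-input protocols. The cutoff
is applied to `x_ij / t_j` without gene-length division — it is a
read-count magnitude criterion, not an expression-density one — and that
choice is deliberately conspicuous here because reasonable
implementations could differ. Inside the model, `t_i` is the transcript
length divided by the median length of retained genes
(`length_offsets()`): raw base pairs would push `s_i` onto a microscopic
scale and collide with the `max_j x_ij` prior scale, while median scaling
keeps `s_i` interpretable on the normalized-count scale.

`run_gibbs()` performs systematic-scan Gibbs sampling with univariate
slice updates (step-out and shrinkage) of every variable against its full
conditional: each `p_ij` on its natural (0, 1) scale with width 0.2, and
each rate on the log scale (with the Jacobian term) with width 1.0 —
posterior rate magnitudes span orders of magnitude, so log-scale widths
adapt naturally. Step-outs are capped at 50. Nothing is integrated out:
all four blocks of conditionals are sampled as written. Initialization is
moment-flavored — `p_ij` starts at a shrunken normalized count,
`s_i` at the gene's maximum normalized count, switching rates at 1 — and
the scan order is fixed (all of `p`, then per-gene `k_on`, `k_off`,
`s`). The default run is a single chain of 10,000 iterations with the
first half discarded; `point_estimates()` reports post-burn-in means with
batch-means Monte-Carlo standard errors. The compiled core makes a
50-gene, 100-cell, 2,000-iteration run take a few seconds, and chains are
bit-reproducible for a given seed.

The log posterior (`log_posterior()`) is evaluated in full, including all
gamma normalizing terms, and doubles as a convergence monitor; its value
on a one-gene, one-cell configuration is pinned in the tests against an
independent symbolic evaluation. One caveat on monitoring: for genes
whose `s_i` is weakly identified the joint posterior has a long ridge
(`s_i` up, `p_ij` down), the trace mixes slowly, and naive standard
errors on short windows overstate precision; the stationarity test in the
suite therefore uses a well-identified configuration.

## Goodness of fit and identifiability

Fast switching collapses the Poisson-beta law onto Poisson or negative
binomial shapes, and then the three parameters cannot be recovered no
matter how good the fit looks. `classify_identifiability()` makes this
operational: draw `n` samples from the fitted Poisson-beta distribution,
fit Poisson and negative binomial by maximum likelihood (the NB by
profile likelihood over the size parameter, checked in the tests against
an independent optimizer), and compute for each the Kolmogorov-Smirnov
statistic at the observed points. The null distribution of that statistic
with estimated parameters is supplied by a parametric bootstrap — B
rounds of simulate-from-fit, refit, recompute — not by an asymptotic
table, so the discreteness of count CDFs needs no correction. The P value
counts bootstrap statistics strictly exceeding the observed one, making
it a multiple of 1/B. A gene is declared identifiable when **both**
simpler families are rejected, `max(p_Poisson, p_NB) < 0.1`: rejecting
only Poisson still leaves the NB shape explaining the data without
separate switching rates. Underdispersed samples, where the NB likelihood
has no interior maximum, are flagged and treated as trivially
NB-consistent (P = 1). Defaults are `n = B = 1000`; a reduced `n = B =
200` mode is used in the test suite, where the slow-switching corner of
the (`k_on`, `k_off`) plane at `s = 100` classifies identifiable and the
fast corner does not. Identifiability is a power statement: with enough
samples even mild overdispersion (Fano 1.25 at `k_on = k_off = 100`)
becomes detectable, so the classification is meaningful only relative to
a stated `n`.

## What the synthetic data does and does not emulate

`simulate_dataset()` draws from exactly the generative model above, so
simulation-based checks validate inference, not biology: real single-cell
data additionally carry dropout, amplification noise and cell-size
effects that are deliberately not modeled (the filter is the only
concession to technical noise). Passing recovery tests therefore show
that the sampler recovers parameters *of its own model*, and nothing
stronger.

Two default designs are fixed once:

* **Identifiability landscape** — `sample_parameter_grid()` draws
  switching rates log-uniformly with `s = 100` fixed, the scheme used to
  map where identifiability holds.
* **Recovery experiment** — `recovery_experiment()` simulates 3, 6, 12,
  20 and 100 cells for 50 genes and default truth
  `k_on ~ logU[0.02, 1]`, `k_off ~ logU[1, 10]`, `s = 100`. This is the
  burst-like regime characteristic of fitted single-cell data —
  activation slower than decay, inactivation faster, few genes with very
  small `k_off` — rather than a symmetric box in the rate plane. The
  regime matters: rank correlation with truth improves with cell count
  (about 0.97 for `k_on` at 100 cells), and at 12 cells `s_i` is
  underestimated on average, because with few cells no cell catches a
  bursty gene near full activation and the empirical-Bayes prior scale
  `max_j x_ij` then sits below the true `s`. For truth distributions
  rich in genes with `k_on >= k_off` the same mechanism reverses into
  overestimation (the `s_i` posterior acquires a long right tail), so
  the reported bias direction is a property of the regime, not of the
  sampler. Chain length is 2,000 iterations in the shipped checks (the
  full default is 10,000); at these problem sizes the experiment runs in
  well under a minute.

## PolII pausing metrics

For GRO-seq-style data the package computes, per gene and strand-matched
(sense transcription only): gene-body activity — total reads from 1 kb
downstream of the TSS to the gene end, divided by the region length;
promoter activity — the maximum read count over all 50-bp windows
stepping by 1 bp fully contained in the TSS ± 1 kb region (full
containment avoids ambiguous edge windows); and the pause index —
promoter activity divided by 50, over body activity. Uniform coverage
gives a pause index of exactly 1, and the index is invariant to global
coverage scaling. Coordinates are BED-style 0-based half-open; the TSS is
the gene start on the plus strand and the final base on the minus strand.
Genes of 1 kb or less have no body region, and a zero-activity body makes
the index undefined; both report NA rather than infinity. Tracks are
per-base coverage; if 5'-end counts are supplied instead, the window
maxima are literal read counts.

## Numerical and design notes

* All sampling entry points take an explicit `seed` and run under a local
  RNG state, leaving the caller's stream untouched; no hidden state.
* Bootstrap ties (a bootstrap KS statistic exactly equal to the observed
  one) do not count as exceedances: the comparison is strict.
* The slice sampler refuses a start with non-finite log density rather
  than silently resetting; degenerate shrinkage (bracket below 1e-300)
  returns the current point.
* `dpobe()` falls back from the closed form to quadrature on non-finite
  values instead of returning NaN.
* Problem sizes in the shipped test suite (grid 5x5x3 for distribution
  checks with 1e6 draws per point, n = B = 200 for bootstrap checks,
  2,000-iteration chains) were chosen as the smallest designs at which
  the checked properties are statistically decidable.

## Limitations

Single rate-limiting steps for both transitions (no multi-state
promoters); no time-dependent solutions (steady state only); no
allele-specific resolution; no explicit technical-noise model; rates in
mRNA-lifetime units only. These mirror the scope of the underlying
two-state framework rather than implementation shortcuts.
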