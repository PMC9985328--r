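---
title: "Detecting positive selection from maximal perfect haplotype blocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting positive selection from maximal perfect haplotype blocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haploscan)
```

## The model in brief

A selective sweep drags a long stretch of the chromosome surrounding the
favoured allele to high frequency faster than recombination can break it
up. The footprint this leaves in a sample of phased haplotypes is a set of
sequences that are *identical* over a long interval — long relative to how
frequent they are, because frequent neutral haplotypes are old and old
haplotypes are short. `haploscan` turns this intuition into three phases:

1. **Enumeration.** A *maximal perfect haplotype block* is a set `K` of at
   least two haplotypes identical over a column interval `[i, j]` of the
   binary haplotype matrix, extensible neither left, nor right, nor by
   another haplotype. All blocks are enumerated in `O(nk + z)` time with
   the positional Burrows–Wheeler transform (pBWT): sorting prefixes
   colexicographically makes the haplotypes of every block contiguous, and
   blocks ending at a column are exactly the lcp-intervals of the
   divergence array, checked for right-maximality in `O(1)` via prefix
   sums over next-column changes.

2. **Estimation.** Treating a block's haplotypes as independent copies of
   a common ancestor (a star genealogy), the probability that one copy
   survives recombination across the block span `r` (recombination
   fraction, from centimorgans via Haldane's map function) during a sweep
   from frequency `y0 = 1/(2Ne)` to the observed `y` is
   `C(s, r, y) = (y0/y)^{r/s}`. Each haplotype additionally requires at
   least one recombination just outside each end of the block (at
   inter-SNP fraction `delta_r`), giving a per-block composite
   log-likelihood
   `ln L(s) = 2|K| ( (r/s) ln(y0/y) + ln(1 - (y0/y)^{delta_r/s}) )`,
   whose maximizer is available in closed form:
   `s_hat = delta_r / ln(r/(delta_r + r)) * ln(y0/y)`.
   Substituting `s_hat` back into the sweep trajectory dates the block:
   `t_hat1` with the single-copy convention `y0 = 1/(2Ne)` and `t_hat2`
   with the two-copy convention `y0 = 1/Ne`.

3. **Filtering.** Both filters are upper bounds on block age. The *drift
   filter* discards blocks old enough that genetic drift alone could have
   lifted them to their frequency: a block passes only while
   `t_hat1 < 2Ne * t1(q)`, where `t1(q)` is a quantile of the
   Wright–Fisher allele-age distribution at an adaptive level
   `q(s_min, Ne, p)` clamped to `[0.01%, 1%]`. The *common-ancestry
   filter* discards blocks whose implied age is compatible with neutral
   coalescence: for `|K|` lineages spanning fraction `r`, the neutral time
   to the most recent common ancestor is a sum of exponentials with rates
   `lambda_i = i(i - 1 + 2Ne r)/(2Ne)`, and a block passes only if
   `t_hat2` lies below the first percentile of that distribution —
   i.e. preserving the block requires an ancestry more recent than
   neutrality delivers outside its extreme left tail.

### Why the common-ancestry filter keeps the *young* blocks

The direction of this filter deserves a note, because the opposite
convention ("remove blocks younger than the percentile") looks superficially
plausible. Genuine sweep blocks are, by construction, very young: a strong
sweep at intermediate frequency implies ages of one or two hundred
generations, far below the neutral first percentile for the same block
geometry. Removing young blocks therefore removes every true positive and
the scan has no power at all — we verified this directly on simulated
sweeps. Keeping young blocks also explains the observed false-positive
mode: the rare survivors of both filters are large, rare haplotypes whose
inflated `s_hat` implies a very young age, which is exactly what slips
through an age *upper* bound.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `Ne` | 10,000 | diploid individuals | sets `y0`, filter stringency, TMRCA rates; choose the low end of the plausible range when demography is uncertain (lower `Ne` means lower estimates and stricter filters) |
| `delta_r` | derived | recombination fraction | Haldane-transformed mean map distance between consecutive retained SNPs; recomputed after any site filtering |
| `s_min` | 0.005 | per generation | smallest coefficient of interest; parametrizes the drift filter's adaptive quantile |
| `maf_min` | 0 (scan) | frequency | site filter for real data; 0.01 is sensible for error-prone sequencing data |

Blocks fixed in the sample (`y = 1`) are dated at `y = 1 - 1/(2k)`, one
sample chromosome short of fixation — the frequency resolution of the
sample — which keeps ages finite. Blocks with `r = 0` or `y <= y0` get
`s_hat = 0`, are flagged non-estimable, and can never pass the filters.

## Numerical choices

* All likelihood work is in log space with `log1p`/`expm1` guards;
  underflow yields `-Inf`, never `NaN`.
* The exact TMRCA distribution (a hypoexponential) is evaluated by
  uniformization of the underlying pure-death chain, which is backward
  stable where the classical alternating-sign mixture cancels
  catastrophically for large `|K|`; truncation error is held below 1e-10.
* The lookup table stores a *single-gamma approximation* of the TMRCA
  distribution per grid cell. The gamma conserves the exact mean; its
  scale is chosen within the bounds `mu/(k-1) <= beta <= max(beta_i)` by
  calibrating the gamma's first percentile against a saddlepoint
  (Lugannani–Rice) evaluation of the exact left tail. This costs `O(k)`
  per cell, keeps the filter threshold well within the 15% band the test
  suite asserts against the uniformization oracle (plain moment matching,
  the fallback when calibration cannot bracket, can err far more in the
  deep tail), and retains the `k = 2` case as an exact exponential.
* The table grid is geometric in `k` (ratio 1.4, capped at the sample
  size) and logarithmic in `r` (64 points from 1e-8 to 0.5, plus `r = 0`);
  off-grid queries interpolate bilinearly in `(log k, log r)`, which keeps
  interpolation error under 5%. First percentiles grow with `k` (more
  lineages coalesce later) and shrink with `r` (recombination truncates
  lineages), and both monotonicities are asserted on every built table.
* Hidden-block removal (a block fully contained in a block with at least
  its coefficient) breaks ties toward the longer block, then the earlier
  record, and is computed with a Fenwick prefix-maximum sweep in
  `O(z log z)`.

## What the simulators emulate — and what they do not

The package ships its own validation generators so that every claim above
is testable without external data.

* `simulate_neutral()` draws the sample under the sequentially Markov
  coalescent (SMC'): the genealogy at the left chromosome end is exact
  (structured, piecewise-constant demography with optional two demes and
  symmetric migration), and marginal trees along the sequence are updated
  at recombination breakpoints by detaching a lineage at a uniform point
  and re-coalescing it into the standing genealogy. Mutations are Poisson
  on branches under infinite sites. SMC' reproduces diversity, the site
  frequency spectrum and the decay of linkage to a very good
  approximation; it slightly thins long-range ancestral-recombination
  correlations, which matters little for block statistics.
* `simulate_sweep()` is a hybrid: the selected-allele trajectory is
  simulated forward under Wright–Fisher dynamics with genic selection and
  conditioned on reaching the target frequency; the beneficial-class
  genealogy is drawn backwards along the trajectory with coalescence
  inflated by `1/y(t)`; recombination events thinned by `1 - y(t)`
  truncate the ancestral haplotype along each branch; new mutations arise
  on the genealogy inside the surviving extent. Flanking diversity and
  non-carriers come from an SMC' panel under the same demography. This
  captures the length-vs-frequency signal and its fragmentation by young
  mutations, but idealizes two things: carriers are *exactly* identical to
  the origin haplotype inside their extents (no standing variation deep
  within the swept core), and escaped flanks recombine onto independent
  panel haplotypes. Both idealizations make block edges slightly crisper
  than forward-simulated data, so estimated/true coefficient ratios here
  centre near 1.0 where full forward simulations centre near 0.6–0.8;
  passing the accuracy floor of 0.6 therefore does, but matching the
  published point values does not, transfer verbatim to real data.
* No MAF filter is applied to simulated samples by default. Simulated
  data carry no genotyping error, and the rare variants are load-bearing:
  they fragment the long, rare neutral clades that would otherwise mimic
  sweeps. Filtering simulated data at 1% minor allele frequency hides
  every variant carried by fewer than 20 of 2,000 chromosomes, making
  such clades look like perfect mega-blocks and inflating the
  false-positive rate dramatically — an artifact of the filter, not of
  the scan. For real sequencing data the 1% preprocessing filter remains
  the recommendation; interpret low-`s_hat` blocks on sparse data with
  care.

### Validation scale

The shipped validation runs 1 Mb regions with 1,000 sampled diploids at
`Ne` = 10,000, recombination 1e-8 and mutation 2.5e-8 per bp per
generation: 50 neutral constant-size replicates, 20 each under the
bottleneck (chromosome count to 5% for 10 generations, 1,120 generations
before sampling) and migration (two demes, rate 3.11e-5, split 1,120
generations before sampling) models, and 20 sweep replicates per
coefficient in {0.01, 0.02, 0.05} conditioned on a selected-allele
frequency of 0.5, plus a near-fixation cell at 0.95. A 1 Mb window
comfortably contains the block geometry that drives estimates up to
`s ~ 0.05` at intermediate frequency; the out-of-Africa check collapses
the European lineage to its single-deme size history (growth discretized
into 16 steps, continental migration ignored) and is the one place where
the idealizations above visibly lift the accuracy ratio (about 1.0
against the published 0.6).

## Known limitations

* Additive (genic) selection only; dominant and recessive trajectories
  are not sigmoidal and are outside the model.
* Perfect matching: sequencing errors and recent mutations break blocks
  and bias `s_hat` downward; filter genotypes by quality first.
* A single compound `Ne` stands in for demography; for structured or
  growing populations use a conservative (low) value, or the geometric
  mean of sizes over time.
* The composite likelihood ignores the correlation between haplotypes of
  a block, so likelihood ratios between blocks are not calibrated
  statistics; the filters, not the likelihood, control error rates.
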