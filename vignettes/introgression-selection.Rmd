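---
title: "Quantifying genome-wide selection against archaic introgression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying genome-wide selection against archaic introgression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(introgsel)
```

## The problem

After a pulse of admixture between an archaic donor population (such as
Neanderthals) and a much larger recipient population (modern humans),
purifying selection gradually removes introgressed alleles that are
deleterious in the recipient. Because selection at an exonic site also
drags down linked neutral variants, present-day frequencies of
introgressed alleles dip near genes, and the depth and width of those
dips carry information about three genome-wide quantities:

* `s` — the average selection coefficient against a heterozygous (or, on
  the X, hemizygous) carrier of a deleterious introgressed allele;
* `mu` — the probability that any given exonic base pair harbors such an
  allele (the "density" of selected sites);
* `p0` — the effective initial admixture proportion, i.e. the admixture
  fraction left after the very rapid early purging driven by unlinked
  deleterious alleles, which acts uniformly along the genome.

`introgsel` estimates these from three inputs: a per-SNP table of
observed introgressed-allele frequencies `pn`, an exon annotation (BED)
and a genetic map.

## The model

For a neutral introgressed allele at recombination fraction `r` from a
single selected site with heterozygote fitness `1 - s`, introduced on
the same haplotype at frequency `p0`, the expected frequency after `t`
generations is `p0 * f(r, s, t)`. On autosomes

$$f_a(r,s,t) = \frac{[(1-s)(1-r)]^t\,[1 - r - (1-s)(1-r)] + r}{1-(1-s)(1-r)},$$

which interpolates between `(1-s)^t` at complete linkage and 1 at free
recombination, and converges for large `t` to the classical gene flow
factor `r / (1 - (1-s)(1-r))` of a single barrier locus. The non-PAR X
chromosome does not recombine in males and spends 2/3 of its time in
females, so recombination enters at the effective rate `(2/3) r` while
selection acts every generation (`f_xchr()`). Homozygous carriers of the
introgressed selected allele are ignored throughout: at the admixture
proportions relevant here they are vanishingly rare, and the resulting
recursion is linear, which is also why `f` does not depend on `p0`.

The deleterious sites themselves are unobserved. The package therefore
averages over their locations: each exon of length `l` in a window
(default 1 cM) around a focal SNP carries a selected site with
probability `mu * l`, and only the *nearest* selected exon matters (for
small `mu` the nearest site dominates all others). This yields the
per-SNP mixture factor

$$g_\ell = \sum_i \mu l_i \prod_{j<i}(1-\mu l_j)\, f(r_i, s, t)
  + \prod_j (1-\mu l_j),$$

with exons ordered by genetic distance from the SNP and `r_i` the
recombination fraction to the midpoint of exon `i` (the selected site,
when present, is placed at the exon midpoint). `E[p_n] = p0 * g_l`.

Two oracles guard these closed forms. `haplotype_recursion()` iterates
the underlying two-locus haplotype recursion generation by generation
(recombination onto the resident background, then selection); the
closed forms agree with it to better than 1e-8 across a 26 x 26 grid of
`(r, s)` at `t = 2000`. For the X, the recursion iterated is the
sex-averaged one that the closed form solves exactly; an explicit
two-sex recursion (female and male haplotype pools, recombination in
females only) is also provided and agrees to about 1e-4 — the 2/3
weighting is the first-order reduction of the two-sex system, and the
residual difference is far below anything the data can resolve.

## Inference

`fit_introgression()` minimizes the residual sum of squares
`sum_l (pn_l - p0 * g_l)^2` over a logarithmic grid of `(s, mu)`. For
each cell the optimal `p0` is available analytically as
`sum(pn*g)/sum(g^2)` (clamped to [0, 1]), so the search is effectively
two-dimensional: a coarse 13 x 13 pass over `s` in [1e-5, 4e-3] and
`mu` in [1e-6, 1e-3], then a fine 26 x 26 grid spanning two coarse
cells on either side of the coarse optimum. The two-cell span is
deliberate: with a one-cell span, bootstrap replicate estimates pile up
on the fine-grid boundary and the resulting confidence intervals are
truncated. Ties are broken toward smaller `s`, then smaller `mu`, so
that degenerate fits (e.g. constant `pn` explained by `mu = 0`) are
deterministic. Window geometry is computed once and cached; the grid
pass recomputes the `f`-vector once per distinct `s` and sweeps all
`mu` cells in a single pass over the cached windows (compiled code).

`s` and `mu` are individually confounded along a ridge of nearly
constant `mu*s` — raising the density while weakening selection leaves
the predicted dips nearly unchanged — so the compound parameter `mu*s`,
the average selection coefficient per exonic base pair, is the
best-constrained quantity and is reported alongside the marginals.

### Uncertainty

`bootstrap_fit()` implements a blockwise bootstrap: SNPs are tiled into
non-overlapping 5-cM blocks (tiling starts at each chromosome's first
SNP; terminal partial blocks are kept), and for every fine-grid cell the
numerator and denominator of the analytic `p0`, together with the block
sums of `pn^2`, are precomputed per block. A bootstrap genome resamples
blocks with replacement chromosome by chromosome (preserving each
chromosome's block count), and the whole objective is reassembled from
the block sums — no SNP-level computation is repeated — before
re-optimizing `(s, mu, p0)`. Confidence intervals are 2.5/97.5
percentiles across replicates (default 1000).

### Diagnostics

`exon_density_diagnostic()` reproduces the binned goodness-of-fit view:
1-cM segments ranked by exonic content, ten equal-count bins, mean
observed vs mean predicted frequency per bin, plus the segment-level
Pearson correlation. Bins consisting entirely of zero-exon segments are
collapsed (ties carry no rank information); segment sizes of 0.5-2 cM
are supported. An optional variance-weighted RSS surface
(`weighted = TRUE`; residuals weighted by `1/(phat(1-phat))`) is
available as a robustness check.

## Wright-Fisher split simulations

Why would an archaic donor carry so many weakly deleterious alleles in
the first place? `simulate_split()` tests the nearly-neutral
explanation: in a donor population of diploid size 1000, alleles with
`s` below about `1/(2*1000)` drift almost freely and can fix, while the
same alleles are still purged in a recipient of size 10000. Each exonic
site is simulated independently: gamma-distributed selection
coefficients (shape 0.184, mean 0.03, additive, no dominance — the
commonly used point estimate for new deleterious mutations, both
configurable), irreversible mutation at `u = 1e-8` per copy per
generation, deterministic selection followed by binomial resampling,
a burn-in of `10 * Ne_ancestral` generations for standing variation,
20000 generations of divergence, and an optional recipient bottleneck
(10-1000 generations) before contact. Two absorbing-boundary shortcuts
(geometric waiting times while a site has zero copies; permanence of
fixation under irreversible mutation) make hundreds of thousands of
sites tractable in seconds without changing the process law.
`classify_fixed_differences()` then bins sites by `s` and reports
donor- and recipient-specific fixed-difference fractions with all
simulated sites in the denominator. In the band
`1/(2*10^4) < s < 1/(2*10^3)` the donor-specific fraction exceeds the
recipient-specific one robustly, including under recipient bottlenecks
— the pattern that motivates treating deleterious introgressed alleles
as fixed in the donor.

The default of
2e5 sites (5e5 in the acceptance script) was chosen once so that the
nearly-neutral band holds on the order of ten donor-specific fixed
differences, enough for the qualitative contrast to be stable across
seeds.

## Synthetic data

`synthetic_genome()` and `synthetic_calls()` generate complete inputs
with the statistical structure the inference assumes, used for all
tests and demonstrations:

* 22 chromosomes of 150 cM / 150 Mb; piecewise-linear genetic map with
  lognormal rate heterogeneity (sdlog 0.3 over 5-Mb segments);
* exons from a renewal process, exponential lengths (mean 1200 bp,
  truncated to 50-6000 bp) and gaps (mean 36 kb), ~3.2% exonic —
  emulating merged exon clusters rather than individual UCSC exon
  records;
* ~50,000 SNPs on a jittered 0.066-cM grid;
* observed frequencies with mean `p0 * g_l` at a truth near the
  genome-wide autosomal estimates (`p0` 0.0338, `s` 4.12e-4, `mu`
  8.1e-5) and, by default, Balding-Nichols Beta drift noise with
  variance `m(1-m) * (1 - (1 - 1/(2*10^4))^2000)`.

The Beta noise model deserves a note: at these parameter values the
neutral drift standard deviation exceeds the mean frequency, so a
clipped Gaussian would inflate the observed mean by roughly a quarter
and bias `p0` upward. The Beta keeps the exact mean and the prescribed
drift variance while respecting the [0, 1] support, matching the
treatment of drift as mean-zero deviation around the deterministic
expectation. A `mechanistic = TRUE` mode instead places actual selected
sites exon by exon and applies the single-site reduction factor of the
nearest one — slower, but it verifies that the mixture expectation is
the average of the mechanism it summarizes.

What the generator does *not* emulate: linkage disequilibrium between
nearby SNPs (drift noise is drawn independently per SNP, whereas real
drift deviations are locally correlated — the 5-cM block bootstrap is
therefore conservative rather than necessary on synthetic data), call
uncertainty from the underlying hidden-Markov ancestry inference,
realistic exon catalogs, and selection's second-order effect on the
drift variance. Passing the recovery tests therefore shows the
estimator is consistent and approximately calibrated under its own
model assumptions, not that those assumptions hold for any particular
real dataset.

## Numerical choices

* Powers `(1-x)^t` are evaluated as `exp(t*log1p(-x))`; equilibrium
  checks run to `t = 1e7` without underflow, and `t = Inf` routes to
  the equilibrium closed forms.
* `mu * l >= 1` (outside the model's regime) is clamped to 1 with a
  warning rather than an error, so that wide grid searches remain
  defined.
* Genetic distance converts to recombination fraction linearly
  (`min(d/100, 0.5)`); at window scales of at most 10 cM a Haldane or
  Kosambi correction would change `r` by less than a part in a
  thousand.
* Map queries outside the mapped range clamp to the boundary cM value.
* Equidistant exons are ordered by physical coordinate; overlapping
  exon records are merged before midpoints are computed, so each merged
  exon is one opportunity for a selected site.
* Calls are 1-based on disk and 0-based internally; BED is 0-based
  half-open throughout.

## Problem sizes used by the test suite

Parameter-recovery properties run on 20 genomes at the full synthetic
scale (~50k SNPs); bootstrap coverage of `mu*s` uses 50 genomes with
200 bootstrap replicates each (the reduced replicate count widens the
percentile grid slightly but leaves coverage essentially unchanged);
the split simulations in the acceptance checks use 5e5 sites. These
sizes were chosen so each check has clear statistical resolution for
the property it asserts.

## Limitations

* Only the nearest selected exon is modeled; multiple simultaneously
  linked selected sites (and their multiplicative interaction) are not.
  This matters most for very high `mu`, where the nearest-site
  approximation undercounts the aggregate effect.
* A single pulse of admixture and a single shared `s` are assumed;
  continuous migration histories can mimic a pulse and are not
  identifiable from present-day frequencies alone.
* The deleterious allele is assumed fixed in the donor (the simulations
  support this as the typical case, not a law).
* `p0` is an *effective* quantity: genome-wide effects of unlinked
  deleterious alleles are absorbed into it, so it underestimates the
  true initial admixture fraction.
* On the X, a single `s` averages over heterozygous females and
  hemizygous males; sex-specific coefficients are not separable with
  realistic data and are not offered.
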