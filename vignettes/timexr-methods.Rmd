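---
title: "Methods: allele-specific replication timing with timexr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-specific replication timing with timexr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(timexr)
```

## The S/G1 model of replication timing

Cells in G1 carry two copies of every locus; cells in S carry between two
and four, and the expected copy number of a locus in an unsynchronized
S-phase population is a decreasing function of its replication time. The
normalized ratio of S-phase to G1-phase read depth is therefore a
surrogate for replication timing, spanning a theoretical range of 1
(replicating at the very end of S) to 2 (at the very start). With a phased
genome, restricting to reads that overlap heterozygous SNPs splits the
signal by homolog, so maternal and paternal timing profiles can be
compared locus by locus.

The profile pipeline (`build_profile()`) follows the standard form of this
analysis:

1. per-SNP allele depths are summed into 500 bp bins (half-open, 0-based);
2. each track (homolog × fraction) is normalized to its total, removing
   library-size differences;
3. tracks are smoothed with a Gaussian kernel, σ = 100 kb, truncated at
   4σ. SNP density in a family-phased genome varies between roughly one
   SNP per 500 bp and one per 5 kb, with genuine deserts; the kernel
   weights are therefore renormalized over *covered* bins only, so gaps
   neither leak zeros into the estimate nor block information flow across
   short deserts. Bins with no SNP stay uncovered.
4. the per-bin S/G1 ratio is scaled by 1.4, a constant chosen so observed
   values land near the theoretical 1–2 range (empirically most covered
   values fall in 0.9–2.1). The scale factor is configurable; because the
   ratio and the scaling commute with smoothing only the order
   "smooth, then ratio, then scale" is implemented.

The high-resolution, non-allele-specific variant (`hires_profile()`) bins
all reads at 1 kb, removes outlier bins with raw ratio above 2.4, smooths
lightly (σ = 20 kb), and affinely indexes the result so the covered
minimum maps to 1 and the maximum to 2 (a robust 0.1/99.9-percentile
indexing is available behind a flag; the strict min/max is the default).

## Detecting asynchronously replicated domains

The difference of the two homolog profiles is scanned with a SICER-style,
gap-tolerant island finder (`find_islands()`): maximal runs of bins at or
beyond ±0.02 timing-ratio units, merged across gaps of up to 250 kb, kept
at a minimum span of 50 kb. Islands are sign-specific — a maternal-earlier
island is never merged with a paternal-earlier one; opposite-sign bins act
as gap content. These parameters (0.02 / 250 kb / 50 kb), historically tuned by trial
and error to maximize recovery of simulated regions, are the package
defaults; cores — the sub-intervals where the difference is
strongest, whose delays better approximate the true asynchrony — use
0.1 / 50 kb / 50 kb.

A threshold of 0.02 sits well inside the smoothed noise band, so the
island stage deliberately over-generates candidates; statistical control
comes from the second stage. For each candidate island the *raw*
(unsmoothed, unnormalized) allele-depth counts are summed into a 2×2
table — maternal/paternal × S/G1 — and tested with Pearson's chi-square
(1 df, no continuity correction; counts are in the 10³–10⁵ range where the
correction is immaterial). Benjamini–Hochberg adjustment is applied
genome-wide across all candidates of both signs in one batch, and domains
with q < 0.05 are reported (`call_ards()`).

Delays are reported in minutes via `delay_minutes()`: the mean profile
difference over the domain × 480 (an 8 h S phase) / 1.2. The 1.2 corrects
for the observed value range (≈0.9–2.1) being 1.2× the theoretical 1–2
range; because raw differences overstate the S-phase fraction, the factor
is applied as a division (a multiplication is available via
`range_action`, since the opposite reading of the correction is
defensible). `excess_to_minutes()` implements the companion nominal
conversion for spike-in excesses (10% → 48 min).

## What the synthetic-data generator emulates

`synth_genome_spec()` fixes the study conditions: SNP positions laid out
in piecewise-constant density blocks of 100 kb–1 Mb with spacing drawn
uniformly between 500 bp and 5 kb per block (so local density always
respects the bounds while deserts exist); a timing landscape obtained by
Gaussian-filtering white noise so its autocorrelation length equals the
1 Mb domain scale, mapped onto [1, 2]; and per-SNP depths that are
independent Poisson draws per homolog and fraction — G1 at the mean depth
(25 reads per SNP per fraction per homolog), S at the mean depth scaled by
the local timing value relative to its genome average. Poisson noise is
the generator's own choice of sequencing-noise model; it matches shotgun-coverage behaviour and makes the
binomial resampler well defined.

What the generator does *not* emulate: mappability and GC bias, phasing
errors, alignment artifacts, depth overdispersion, and real biological
asynchrony in the background. Passing tests therefore demonstrate the
correctness and calibration of the *procedure* under its stated
assumptions, not performance on real libraries.

For benchmarking, both homolog "controls" are imputed from a single
source homolog (`make_control_pair()` then `spike_regions()`): each SNP's
observed (S, S+G1) pair is fed to a binomial resampler independently for
the two homologs, so homolog differences under the null are purely
binomial — this resampling scheme is what makes the chi-square stage exactly calibrated (unspiked
runs yield a median of zero significant domains). Spikes inflate each
in-region SNP's total by `round(total × (1 + excess))` with all extra
reads assigned to S before resampling; rounding on the total, and leaving
the pre-spike S count untouched before the draw, are the package's own
resolutions of details the percentage-inflation rule leaves open.

## The power study and its honest discrepancies

`run_power_study()` scores each (size, excess) cell by simulating 200 Mb
genomes carrying randomly placed, non-overlapping spiked regions —
occupancy is capped at ~25% of each replicate genome and regions
accumulate across replicates to ~150 per condition, keeping spike density
comparable to a ~1000-region study on a full-size genome — then rebuilding profiles,
calling ARDs at 5% FDR, and computing: detection rate (truth regions
overlapped ≥1 bp by a significant domain), empirical FDR (both the
conventional false/detected and the false/true-overlapping ratio variant),
and size/delay distortion of matched detections (detected span over truth
span, and mean profile difference over the detected span relative to the
truth span — smoothing makes detected domains wider and their mean
differential shallower, strongly so below 500 kb).

Two benchmark results differ from what the method's characterization on
real sequencing libraries would suggest, and the package reports them as
computed rather than adjusting the conditions:

- **Sensitivity is higher.** At 25 reads per SNP per fraction per homolog
  and the stated SNP spacing, a 1 Mb spike at 5% excess already shifts the
  island's count balance by ~5–7 standard errors, so ≥90% detection is
  reached at smaller excesses than real-library benchmarks report for
  1 Mb and 500 kb regions. The synthetic data — homogeneous depth, no mappability
  or phasing noise — is simply more informative than real resampled
  libraries.
- **Empirical FDR on spiked runs exceeds the nominal 5%** even though the
  null is exactly calibrated. Two mechanisms, both inherent to the
  procedure itself at ~25% spike occupancy: normalizing the spiked S track to its
  inflated total depresses the difference baseline outside spikes, so the
  positive-sign noise islands that still clear +0.02 correspond to ~2 SD
  count fluctuations with genuinely small chi-squares; and the many
  overwhelming true discoveries loosen the BH step-up cutoff, admitting
  them.

A related internal tension is documented rather than resolved: the spike
adds `excess × (S+G1)` reads to S, which (with S ≈ G1) inflates the S/G1
ratio by about twice the excess, while the nominal minutes equivalence
(`excess_to_minutes()`) treats the excess itself as the S-phase fraction
shift. Observed delays on spiked data therefore run ≈2× the nominal
conversion; the distortion metric avoids the issue by comparing profile
differentials over detected versus true spans.

## Ripples, fractions, and interval statistics

Sub-domain timing ripples and nascent-strand clusters are exposed by
subtracting a 100 kb smooth from a 20 kb smooth of the same track
(`dual_smooth_residual()`); candidate peaks are maximal positive runs of
the residual (chosen because peak callers assuming a flat background fail
on the strongly varying timing baseline), ranked by area (sum of residual
over the run), with the top 10% kept by default. `partition_s_fractions()`
orders covered bins by timing value and splits them into five equal-count
fractions S1 (earliest) to S5, with ties broken stably by genomic
position.

Association statistics follow the 1 bp-overlap rule throughout. The
closed-form chance expectation `expected_overlap()` is
`cov_a × 3 × cov_b`, the factor 3 accounting for partial overlaps (with
two-decimal coverages like 0.219 and 0.184 the product, 12.09%, can
differ in its second decimal from a value computed on unrounded
coverages). Empirical baselines come
from `randomize_intervals()`, which re-places intervals uniformly within a
stated territory, width-preserved and never straddling territory segment
ends; `bootstrap_enrichment()` reports observed/expected folds against
100 such randomizations by default. The structural-variant test
(`sv_randomization_test()`) averages inverted allelic ratios (≥1 by
construction) in 500 kb windows stepped every 100 kb, classes windows by
the largest overlapping SV, and attaches an add-one-corrected empirical
p-value over (configurably) 1000+ randomizations; a window "contains" an
SV on ≥1 bp overlap, the package's resolution of an ambiguity between
containment and overlap.

## Numerical choices and problem sizes

- Gaussian smoothing is computed by FFT convolution of the value and
  coverage-indicator grids; it matches a direct O(nk) convolution oracle
  to 1e-9 relative error in the tests.
- Division by a zero G1 bin masks the bin (with a warning) rather than
  erroring; SNP deserts make such bins routine.
- All coordinates are 0-based half-open internally; only the TSV/VCF
  boundary is 1-based.
- Every stochastic function takes a seed; a single global seed expands to
  per-stage seeds via `derive_seed()`, so any stage can be reproduced in
  isolation. Arguments are forced before seeding so lazy evaluation cannot
  perturb the stream.
- Test and benchmark problem sizes — 200 Mb genomes with ~150 regions per
  condition for the power study, 20–50 Mb genomes for calibration and
  recovery checks — are the package's chosen desk scale; per-cell
  Monte-Carlo error at these sizes is a few percentage points on a
  detection rate, which the tests' tolerances reflect.

## Known limitations

Beyond the generator's idealizations listed above: the island finder's
opposite-sign-as-gap rule can nest a small opposite-sign island inside a
larger one (kept, since both pass their own tests); the chi-square stage
tests count imbalance, not timing per se, so systematic allelic coverage
bias in real data (e.g. reference-allele mapping bias) would masquerade as
asynchrony and should be handled upstream; and the BH batch treats islands
as independent units although long-range smoothing correlates adjacent
candidates.
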