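# timexr

Allele-specific replication-timing analysis from S/G1 read-depth ratios:
profile construction, detection of asynchronously replicated domains
(ARDs), and a spike-in simulation benchmark, with tidy (tibble in,
tibble out) interfaces throughout.

## The problem

During S phase, a locus that replicates early is present in more copies in
S-phase cells than one that replicates late: sequencing DNA from sorted S
and G1 cell populations and forming the per-locus **S/G1 read-depth ratio**
gives a surrogate for replication time on a theoretical 1 (latest) to 2
(earliest) scale — the TimEX approach. With a *phased* genome, reads
overlapping heterozygous SNPs can be assigned to the maternal or paternal
homolog, yielding one timing profile per homolog and making **replication
asynchrony** — regions where the two homologs replicate at different times,
as at imprinted loci and on the inactive X — directly measurable.

`timexr` implements this analysis for people who have phased per-SNP
allele-depth tables (or binned read-depth tracks) and want:

- per-homolog timing profiles: 500 bp binning, library-size normalization,
  gap-aware Gaussian smoothing (σ = 100 kb), scaled S/G1 ratios
  (`build_profile()`, `hires_profile()` for non-allele-specific 1 kb
  tracks);
- ARD calls: a SICER-style gap-tolerant island finder on the profile
  difference (threshold 0.02, max gap 250 kb, min size 50 kb), a χ² test on
  the 2×2 table of raw S/G1 read counts per homolog summed over each
  island, Benjamini–Hochberg FDR at 5%, core sub-domains at stricter
  parameters, and delay estimates in minutes
  (`call_ards()`, `delay_minutes()`: Δ(S/G1) × 480 / 1.2);
- a simulation benchmark reproducing the method's power study: binomial
  resampling of observed counts into matched homolog controls, spike-in of
  asynchronous regions (125 kb–2 Mb, 5–50% S-phase read excess), and
  detection-rate / empirical-FDR / distortion scoring
  (`run_power_study()`, `spike_regions()`);
- sub-domain structure and origin statistics: timing "ripples" by
  dual-scale smoothing residuals (20 kb − 100 kb), S1–S5 timing quintiles,
  interval randomization and bootstrap enrichment, nascent-strand peak
  association with G-quadruplex/TSS/CpG/DNase windows, and a randomization
  test for structural-variant effects on allelic timing
  (`dual_smooth_residual()`, `partition_s_fractions()`,
  `bootstrap_enrichment()`, `sv_randomization_test()`).

## Worked example

Simulate a 30 Mb phased genome, spike one 2 Mb region on the maternal
homolog with a 50% S-phase read excess, and call ARDs:

```r
library(timexr)

spec  <- synth_genome_spec(c(chr1 = 3e7), seed = 31)
sim   <- simulate_allele_depths(spec)
truth <- tibble::tibble(chrom = "chr1", start = 1e7, end = 1.2e7)
spiked <- spike_regions(make_control_pair(sim$depths), truth,
                        excess_fraction = 0.5, seed = 77)

mat <- build_profile(spiked, "maternal")   # 500 bp bins, sigma 100 kb, x1.4
pat <- build_profile(spiked, "paternal")
ards <- call_ards(mat, pat, spiked)        # islands + chi-square + BH 5%
tidy(ards)
#> # A tibble: 2 x 15
#>   chrom    start      end  length sign             mat_s mat_g1 pat_s pat_g1
#>   <chr>    <dbl>    <dbl>   <dbl> <chr>            <dbl>  <dbl> <dbl>  <dbl>
#> 1 chr1   9880000 12181500 2301500 paternal-delayed 72810  44214 38397  44285
#> 2 chr1  29675000 29999500  324500 paternal-delayed  1842   2566  1692   2716
#>   p_value q_value coverage mean_diff delay_minutes n_cores
#>     <dbl>   <dbl>    <dbl>     <dbl>         <dbl>   <int>
#> 1 0       0          0.386    0.870          348.        1
#> 2 0.00111 0.00223    0.162    0.0250          10.0       0
glance(ards)
#> # A tibble: 1 x 6
#>   n_ards n_candidate_islands   fdr total_span_bp mean_abs_delay_min max_abs_delay_min
#>    <int>               <int> <dbl>         <dbl>              <dbl>             <dbl>
#> 1      2                   4  0.05       2626000               179.              348.
```

The first domain recovers the spiked region (slightly widened by the
smoothing): the maternal homolog received the extra S reads, so it
replicates earlier and the domain is `paternal-delayed` with a large
positive delay and a called core. The second, small low-delay domain is a
read-count fluctuation that clears the 5% FDR — the methods vignette
discusses why such calls appear alongside strong spikes. `autoplot(mat)`,
`plot_homolog_profiles(mat, pat, ards)` and `autoplot()` on a power grid
give the standard figures.

A thin command-line front end wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli","timexr.R",package="timexr"))') \
    simulate --genome-length 2000000 --n-regions 1 --sizes 500000 \
    --excess 0.5 --seed 11 --out-prefix sim
```

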