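---
title: "Composite selection signals: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite selection signals: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Artificial and natural selection leave two linked footprints around a
favoured variant: the allele-frequency spectrum diverges between
populations that were and were not selected for the trait, and
hitchhiking sweeps a long, common haplotype to high frequency in the
selected population.  No single statistic captures both footprints well,
and popular statistics (the fixation index in particular) have no usable
null distribution on real multi-breed panels.  `csscan` implements a
composite, rank-based genome scan for exactly this setting: two groups of
phased diploid samples -- a putatively *selected* group and a *reference*
group, each typically pooled from several breeds sharing the contrasting
phenotype -- genotyped on a common SNP map.

## The composite score

Three constituent statistics are computed per SNP:

* **Fixation index** `fst_per_snp()`.  With ALT frequencies $f_1, f_2$
  in the two groups and $\bar p = (f_1+f_2)/2$:
  $F_{ST} = (H_T - H_S)/H_T$ where $H_T = 2\bar p(1-\bar p)$ and
  $H_S = [2f_1(1-f_1) + 2f_2(1-f_2)]/2$; defined as 0 when $H_T = 0$.
  Unsigned: large values mean strong differentiation in either direction.
* **Derived-allele frequency contrast** `delta_daf()`: derived frequency
  in the selected group minus the reference group, where the derived
  allele is the non-ancestral one per the map annotation.  Where the
  ancestral state is unknown, `delta_saf()` substitutes the frequency
  contrast of the *selected group's major allele* -- an ancestral-free
  surrogate that coincides with the derived contrast whenever selection
  has made the derived allele major.  The combined per-SNP statistic is
  standardized genome-wide to zero mean and unit variance.
* **Cross-population extended haplotype homozygosity** `xpehh_scan()`.
  EHH at a boundary SNP is the probability that two haplotypes drawn
  without replacement are identical over the whole closed interval from
  the core.  Each side of the core is extended SNP by SNP; the decay is
  integrated against physical distance by the trapezoid rule, and the
  statistic is $\ln(I_{sel}/I_{ref})$, standardized genome-wide.
  Positive values mean longer homozygosity in the selected group.

Each statistic is oriented so large = evidence of selection in the
selected group, converted to fractional ranks $R'_{ij} = R_{ij}/(n+1)$
(ascending, average ranks on ties), mapped through the standard-normal
quantile $Z_{ij} = \Phi^{-1}(R'_{ij})$, and averaged over the $m$ tests.
Under the idealization that the tests are independent,
$\bar Z_j \sim N(0, 1/m)$, so the composite p-value is
$p_j = 1 - \Phi(\sqrt{m}\,\bar Z_j)$ and the reported score is
$\mathrm{CSS}_j = -\log_{10} p_j$.  Because only ranks enter, the
composite is invariant to any strictly monotone transform of any
constituent -- the scale, skew, or lack of a null distribution of the
inputs is irrelevant.

## From scores to regions

Per-SNP scores are noisy, and true sweeps affect runs of linked SNPs, so
the CSS values (on the $-\log_{10}$ scale, never on the p scale) and each
constituent statistic are smoothed: the window of SNP $j$ holds every
same-chromosome SNP within 500 kb (closed interval, centre included) and
the smoothed value is the window mean.  Windows with fewer than 5 SNPs
are discarded outright.  The top 0.1% of retained smoothed values
(exactly $\lceil 0.001\,n_{retained}\rceil$ SNPs; cutoff ties broken by
genome order) are significant.  Clusters are seeded greedily from the
most extreme smoothed SNP, capturing significant SNPs within 500 kb of
the core; same-chromosome clusters separated by less than 1 Mb merge;
clusters with fewer than 3 members are dropped; and each cluster is
padded by 0.5 Mb per side to form the candidate region reported for gene
mining.  Per-test concordance counts (how many significant SNPs of each
constituent's own smoothed scan fall inside each region) accompany every
region.

## FDR on calibrated p-values

Rank-based composite p-values are *empirical*: their null distribution is
only approximately uniform, so tail-area FDR is computed on recalibrated
values.  `calibrate_p()` projects the empirical CDF onto the class of
ideal empirical p-value distributions (non-decreasing, concave, anchored
at (0,0) and (1,1)) via its least concave majorant and transports each
p-value onto the projection.  The construction is deliberately simple --
it is not a port of the published constrained-regression recalibration,
and is flagged as a fidelity deviation -- but it has the properties the
q-value step needs, each of which is asserted in the test suite: exactly
uniform input passes through unchanged; rank order is always preserved
(ties stay tied); the uniform null component of a valid
signal-plus-uniform mixture stays uniform; conservative (super-uniform)
inputs are pulled back to uniformity; the map is approximately
idempotent.  `q_values()` then estimates the null proportion
$\eta_0$ from the p-values above their 75th percentile (observed over
expected uniform mass) and applies the step-up tail-area rule
$q(p_{(k)}) = \min_{j \ge k} \eta_0\, n\, p_{(j)}/j$; with $\eta_0 = 1$
this is exactly Benjamini--Hochberg, which the tests verify against
`p.adjust()`.  FDR always runs on the non-smoothed composite p-values.

### Why the composite null is not exactly uniform

The independence idealization behind $\bar Z \sim N(0,1/m)$ fails in one
specific, structural way: the fixation index is an unsigned function of
the same per-SNP frequency contrast whose signed version feeds the
derived-allele test.  The two are uncorrelated globally (the sign is
symmetric under the null) but tail-dependent: a SNP with an extreme
frequency contrast is extreme in $F_{ST}$ and, with probability one
half, simultaneously extreme-high in the signed contrast.  These
co-extremes skew $\bar Z$, producing an excess of very small composite
p-values on perfectly null panels -- this package's null simulations
show a Kolmogorov--Smirnov distance of roughly 0.06 from uniformity and
a cluster of spuriously small q-values.  No order-preserving calibration
can remove the excess, because by construction it is indistinguishable
from genuine signal.  The practical consequences, visible in the test
suite: composite p is exactly uniform when the constituents are
independent (asserted), but on two-population panels the absolute FDR
level is optimistic and q-values should be read *comparatively* --
regions against genome background -- which is how the region summary
presents them.  Window smoothing has an analogous caveat: smoothed
values of neighbouring SNPs share most of their window, so even null
panels produce occasional clusters of top-ranked smoothed SNPs;
region calls on real data should always be weighed against the
constituent-test concordance counts reported with each region.

## Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| `min_maf` | 0.01 | frequency | pooled MAF retention threshold |
| `half_width_bp` | 500,000 | bp | smoothing window half-width (1 Mb window) |
| `min_snps` | 5 | SNPs | minimum window occupancy; sparser windows pruned |
| `top_fraction` | 0.001 | fraction | significant share of smoothed scores |
| `cluster_merge_gap_bp` | 1,000,000 | bp | merge clusters closer than this |
| `min_cluster_snps` | 3 | SNPs | minimum cluster membership |
| `region_pad_bp` | 500,000 | bp | flank added to clusters for regions |
| `truncation` | 0.05 | EHH | stop extending a side below this EHH |
| `max_extension_bp` | 1,000,000 | bp | maximum EHH extension per side |
| `alpha` | 0.05 | q-value | region FDR summary threshold |

The MAF filter is pooled across groups deliberately: a SNP monomorphic
in one group but segregating in the other is precisely the
differentiation signal sought, and per-group filtering would delete it.
The EHH truncation and maximum extension are the community's usual
defaults; they bound runtime and have little effect on the integrated
log-ratio because the integrand is near zero beyond the truncation
point.  Physical distance is used throughout (no genetic map input).

## Design decisions in ambiguous corners

* **$F_{ST}$ estimator.**  The unweighted Wright/Nei frequency form is
  the default because it matches the definition of differentiation
  against within-population polymorphism and stays a pure frequency
  contrast under the very unbalanced group sizes typical of multi-breed
  panels (e.g. 149 vs 2,654 animals).  The sample-size-weighted
  Weir--Cockerham estimator is available via `fst_estimator = "wc"`.
* **EHH conditioning.**  The cross-population statistic compares the
  same core site across populations, so the decay is computed over *all*
  haplotypes of a population (allele-agnostic core), not conditioned on
  the ancestral/derived core allele as in within-population tests.  The
  shared integration extent for the two groups is fixed once on the
  pooled panel, which keeps the log-ratio a comparison of identical
  intervals.
* **Undefined scores.**  SNPs whose XP-EHH log-ratio is undefined (zero
  integral, e.g. single-SNP chromosomes) receive the median fractional
  rank 0.5, keeping $n$ identical across tests; they are excluded from
  the genome-wide standardization.
* **Ties.**  Average ranks keep the fractional-rank multiset symmetric,
  and the cutoff tie-break by genome order keeps the significant count
  exact.  The $\Delta$SAF major-allele tie at frequency 0.5 resolves to
  ALT, arbitrarily but deterministically.
* **Order of region operations.**  Clusters merge first, then the
  3-member minimum applies; this lets two nearby 2-SNP clusters survive
  as one merged cluster, which matches the biological reading that they
  are one signal.
* **Positions.**  1-based inclusive coordinates everywhere; all window
  arithmetic uses closed intervals; the BED-like region output converts
  to 0-based starts only at the writer.

## The synthetic benchmark

`simulate_sweep_panel()` emulates the contrast the scan targets without
claiming to be a population-genetics simulator of record.  Ancestral
derived-allele frequencies are Beta(0.5, 0.5); each population jitters
them independently (truncated Normal, sd 0.05), mimicking neutral
divergence; haplotypes are independent Bernoulli draws, i.e. the neutral
background is in linkage equilibrium; derived/ancestral polarity is
random per SNP.  The sweep is structural rather than forward-simulated:
one fixed haplotype spanning ±300 kb of the sweep locus, carrying the
derived allele at the locus itself, is assigned to each selected
haplotype with probability 0.9.  This creates exactly the two signals
the constituents detect -- locally elevated derived-allele frequency and
one long, high-frequency haplotype -- at desk scale and bit-identically
for a fixed seed.  Default sizes (20,000 SNPs on five 200 Mb
chromosomes, 100 + 100 samples) give about 20 SNPs per 1 Mb window,
matching the density of the 50K bovine/ovine genotyping chips this kind
of scan is usually run on; the faster unit tests use a 2,500-SNP,
two-chromosome version of the same scenario.

What the background's linkage equilibrium buys and costs: EHH decays
within a few SNPs outside the sweep, so the XP-EHH null is clean and the
sweep's haplotype signal is isolated -- but real genomes have background
LD, so passing tests here demonstrate correctness of the machinery and
power against a clean sweep, not calibration on real LD structure.

```{r}
library(csscan)
sim <- simulate_sweep_panel(sweep_scenario(seed = 1))
scan <- css_scan(sim$panel, sim$map, sim$groups)
scan
scan$regions[, c("chrom", "cluster_start_bp", "cluster_end_bp",
                 "core_snp_id", "n_members")]
```

## Known limitations

Biallelic autosomal SNPs only; phasing and imputation are upstream
(strict mode rejects any unphased genotype).  Two groups only -- no
hierarchical or $k$-population $F_{ST}$.  No genetic-map distances, no
within-population haplotype tests (iHS, Rsb), no gene annotation.  The
recalibration is a simplified stand-in for the published
constrained-regression method, matching its contract rather than its
fitting details.  Absolute FDR levels inherit the optimism described
above; comparative use is recommended.
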