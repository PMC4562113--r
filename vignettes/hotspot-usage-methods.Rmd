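---
title: "Methods: relating in vitro binding-site catalogs to in vivo hotspot usage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: relating in vitro binding-site catalogs to in vivo hotspot usage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Meiotic recombination in most mammals initiates at hotspots positioned by the
zinc-finger protein PRDM9. An in vitro affinity assay can catalog essentially
every genomic sequence the protein is able to bind, together with a
quantitative affinity (reads normalized to parts per million, ppm). In vivo,
however, only a fraction of these sites ever acquire the hallmarks of an
active hotspot (PRDM9-dependent H3K4me3, DMC1-marked double-strand breaks).
The analytical questions this package addresses are:

1. **Which catalog sites are used in vivo?** Overlap-based classification of
   sites against in vivo mark peak sets, with a rule for removing ambiguous,
   promoter-like signals.
2. **Where along the chromosomes does usage fail wholesale?** r-scan span
   statistics detect megabase-scale regions depleted of active hotspots, and
   a cross-reference against the in vitro catalog distinguishes regions where
   binding is possible but activation fails from regions that are merely
   unmappable.
3. **What suppresses usage?** Usage fractions by chromatin category
   (H3K9me2/H3K9me3 heterochromatin domains, lamina-associated domains, gene
   bodies and expression quartiles) with Poisson errors, and the interaction
   of binding affinity with chromatin state via affinity-quintile usage
   ratios in closed versus open chromatin.
4. **Positional structure.** Composite coverage around sites, per-position
   nucleotide frequencies along oriented motifs, and SNP-density ratio
   profiles that reveal the evolutionary erosion of historically active
   motifs by biased gene conversion.

All real inputs are BED-family text files; a synthetic-data generator
produces the same data classes with known ground truth so that every
estimator is testable end to end without sequencing data.

## Coordinate conventions and overlap

Intervals are 0-based half-open `[start, end)` throughout (the BED
convention); any 1-based dialect must be converted at the reader boundary.
"Overlap" always means at least one shared base pair: a site belongs to a
category if it crosses into or is encapsulated within the category's
borders. No fractional-overlap thresholds are used anywhere. Interval
queries and merging are delegated to IRanges behind the package's own
data-frame-based interval sets.

## Site classification

A site overlapping the primary strain's H3K4me3 peaks or the DMC1 peaks is a
candidate in vivo hotspot. Among candidates, sites that coincide with
H3K4me3 peaks from *both* strains but carry no DMC1 peak are promoter-like
(H3K4me3 at promoters is PRDM9-independent and strain-shared) and are
classified `ambiguous`; they are removed from every usage numerator and
denominator. The remaining candidates are `in_vivo`; non-candidates are
`in_vitro_only`. A site overlapping DMC1 is never ambiguous, regardless of
its H3K4me3 pattern — the ambiguity rule requires the *absence* of a DSB
mark. The partition is exhaustive and exclusive and is asserted on every
run.

## r-scan detection of hotspot-deficient regions

For the `n_c` hotspots of a chromosome there are `n_c - 1` inter-hotspot
distances `U_i`. The order-`r` scan length at hotspot `i` is the span
covering `r` consecutive distances,

$$R_i^{(r)} = \sum_{j=i}^{i+r-1} U_j = \mathrm{pos}_{i+r} - \mathrm{pos}_i,
\qquad i = 1, \ldots, n_c - r,$$

the standard Karlin–Macken form. Long spans indicate dispersion
(depletion); the package scans `r = 1..24` by default, pools spans across
chromosomes, and retains the `k = 1..10` largest per order.

Significance is empirical: `n_null` random hotspot sets are drawn matching
the per-chromosome counts of the test set — either without replacement from
a background catalog (e.g. all in vitro sites) or as uniform positions along
each chromosome — and the distribution of each extreme statistic
`m_k^{(r)}` is recorded. The p-value uses the permutation-safe estimator
`p = (1 + #{null >= observed}) / (n_null + 1)`, so no p-value is ever zero.
Benjamini–Hochberg adjustment is applied across the whole `r x k` family by
default (`bh_family = "per_r"` adjusts within each order instead). Spans
with adjusted `p < 0.05` are dispersed.

**Localisation rule.** A long gap is contained in significant spans of
*every* order: the order-1 span is the gap itself, while the order-24 span
adds ~23 ordinary neighbours on its flanks. Merging all significant spans
therefore pads every anomaly with ordinary hotspots, inflating a single gap
by up to `r_max - 1` inter-hotspot distances per side. The package instead
builds deficient regions from **minimal significant spans** — significant
spans that contain no shorter significant span — and merges those with gap
0. A solitary gap is then localised exactly to its bounding hotspots, while
a broad sparse region whose evidence only accumulates at larger `r` (no
significant sub-span) keeps its full extent. `extent = "all"` restores the
merge-everything behaviour. Regions overlapping supplied assembly-gap or
low-mappability annotations are removed.

Finally, each called region's in vitro site density is compared with the
genome-wide average ([cross_reference_deficiency()]): regions at or above
half the average density (configurable) are *truly* hotspot-deficient —
binding is possible there, activation is not — rather than artifacts of
read mapping.

## Usage statistics

Usage fractions are `n_used / n_total` over non-ambiguous sites, with the
numerator treated as a Poisson count: `se = sqrt(n_used) / n_total`. This
matches error bars computed "from the Poisson distribution" on category
counts; a binomial alternative is reported alongside. Affinity quintiles
are equal-count bins over all sites genome-wide *before* stratifying by
chromatin, so a quintile's closed- and open-chromatin subsets share the same
affinity range; the reported ratio `(used/total)_closed / (used/total)_open`
equals 1 when heterochromatin has no effect, and its delta-method standard
error is included. Distribution comparisons (e.g. affinities of
ChIP-detected versus all sites) use the Mann–Whitney test: exact enumeration
for `n_a * n_b <= 400` without ties, otherwise the tie-corrected normal
approximation.

## Positional profiles

* **Composite coverage** ([composite_profile()]): mean coverage per offset in
  a symmetric odd window around the site center (or motif start),
  minus-strand sites reversed; sites truncated by chromosome ends are
  excluded and counted.
* **Nucleotide frequencies** ([nucleotide_frequency_profile()]): sites
  aligned on the motif start, minus-strand windows reverse-complemented;
  channels sum to 1 at every offset.
* **SNP-density ratio** ([snp_density_profile()]): 2-kb windows
  `[-1000, +1000)` centered and oriented on sites; per-offset SNP frequency
  divided by its window mean, so the profile mean is exactly 1. Smoothing is
  off by default; when enabled it is an odd-width moving average.
* **Binned log2 enrichment** ([binned_log2_enrichment()]): 2-kb bins,
  library-size scaling to equal totals (the choice of scaling before the
  ratio is ours; the pseudocount, default 1 per bin, keeps empty bins at 0).

## The synthetic-data generator

`simulate_dataset()` emulates the data classes of such a study on a toy
genome (default 2 chromosomes x 10 Mb, 2,000 sites — minutes on one CPU):

* **Sites** are placed uniformly outside any implanted site-free gaps with a
  minimum spacing (200 bp) and exact total count; affinities are log-normal
  (`meanlog = 1.5`, `sdlog = 1` on the ppm scale). A site's peak interval
  spans `2L - m` bp (`L` = fragment length 177, `m` = motif length 31), the
  footprint of fragments that must fully contain the motif.
* **Chromatin domains** (H3K9me2, H3K9me3, cLAD) and **gene bodies** are
  independent alternating-exponential mosaics with target genome fractions
  0.35/0.15/0.30/0.35 and mean segment lengths 300/200/500/30 kb — broad
  domains scaled to the toy chromosomes. Genes carry log-normal FPKM.
* **Activation** is logistic:
  `P(activate) = plogis(b0 + a * log(affinity) - sum(penalty_d * in_d) +
  c_e * log1p(FPKM))`. The field's account of activation is a qualitative
  energy barrier; the logistic in log-affinity is the minimal monotone model
  that reproduces the observed interaction (strong binding overcomes
  heterochromatin). The expression covariate is continuous
  (`log1p(FPKM)` of the containing gene) so that usage rises smoothly
  across expression quartiles. Barrier penalties (1.5/2.0/1.0 for
  H3K9me2/H3K9me3/cLAD) are arbitrary magnitudes — the real ones are not
  quantified — and the baseline `b0 = -0.95` was calibrated once so that
  roughly half (~48 %) of sites activate, matching the study-scale headline;
  these defaults are fixed and are not tuned per analysis.
* **In vivo marks**: activated sites emit 1-kb H3K4me3 peaks in both
  "strains" and a DMC1 peak; DMC1 peaks are wider (1.4 kb) so that the DSB
  evidence of an activated site always covers its H3K4me3 footprint —
  without this, peak bleed between close neighbours would manufacture
  spurious ambiguous calls. The top affinity decile of activated sites also
  emits a PRDM9 ChIP peak, mirroring the low sensitivity of direct PRDM9
  ChIP. A configurable ~4 % of sites get promoter-like both-strain H3K4me3
  with no DMC1 (the ambiguous class).
* **SNPs** are a Poisson process (5 per kb background, roughly the
  divergence of a distant subspecies) whose rate is multiplied by `e`
  (default 3) within the central motif of *historically active* sites;
  the generator collapses evolutionary history to the current activation
  flag, which is sufficient to exercise the profile estimator. The central
  ratio of the SNP profile then has the closed form `e / (1 + (e-1) m / W)`
  for window `W`.
* **Sequence** (`simulate_genome_sequence()`): uniform background with motif
  instances sampled from a position-weight model whose invariant positions
  (8, 11, 13, 15, 16) carry their major base at weight 0.9 and all other
  positions at 0.55.

Deterministic given the seed: reruns are byte-identical, which the pipeline
manifest (MD5 per file) makes checkable.

### What the generator does *not* emulate

Sequence composition beyond the implanted motif; read-level noise, mapping
artifacts and assembly gaps (assembly-gap filtering is exercised with
explicit annotations instead); correlated domain placement (real LOCKs and
LADs overlap strongly; the generator draws them independently);
evolutionary history beyond the single historically-active flag; and
crossover interference. Tests passing on this generator therefore validate
the estimators' logic and calibration, not robustness to alignment
artifacts in real sequencing data.

## Numerical choices and degenerate inputs

* Tie-breaks: extreme spans are ordered by (length desc, chrom, start);
  expression quartiles and affinity quintiles use stable equal-count
  binning (bin sizes differ by at most 1; ties keep input order).
* Chromosomes with fewer than two test hotspots are skipped with a warning;
  `r > length(U)` yields no spans; an empty test set returns an empty,
  well-formed result.
* A quintile with no closed- or open-chromatin sites reports a missing
  ratio rather than dividing by zero; `percent`/density/rate helpers refuse
  zero denominators.
* Problem sizes in the test suite: the r-scan null uses 1,000 replicates
  (the analysis default is 10,000); type-I behaviour is checked over 20
  simulations of 2,000 uniform sites on 10 Mb; generator/estimator closure
  checks run at the default 2,000-site scale, except the quintile-ratio
  checks which use 20,000 sites because adjacent-quintile ratio differences
  at 2,000 sites are comparable to their sampling error.

## Worked example

```{r, eval = FALSE}
library(hotspotUsage)

tr <- simulate_dataset(synth_config(seed = 1))
cls <- classify_sites(tr$sites, tr$peaks$h3k4me3_a,
                      tr$peaks$h3k4me3_b, tr$peaks$dmc1)
print(cls)

res <- rscan(cls$sites[cls$sites$status == "in_vivo", ], tr$genome,
             background = tr$sites,
             config = rscan_config(n_null = 1000))
summary(res)

run_pipeline(pipeline_config(seed = 1), "pipeline_out")
```

## Known limitations

The minimal-span localisation is a deliberate design choice: it trades a
small loss of extent for broad, weakly-deficient regions against exact
localisation of sharp gaps. The empirical null inherits the granularity of
`n_null` (the smallest attainable raw p is `1/(n_null + 1)`), so with few
significant spans and small `n_null` the BH threshold can be unreachable —
use 10,000 replicates for production scans. Usage fractions treat sites as
independent; closely spaced sites sharing one peak are counted separately.
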