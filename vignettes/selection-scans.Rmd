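---
title: "Haplotype-based selection scans over a pangenome-genotyped cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-based selection scans over a pangenome-genotyped cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pansweep)
library(dplyr)
```

`pansweep` re-implements, as tested tidyverse-style functions, the
downstream analysis that sits behind a multi-assembly livestock
pangenome: haplotype-based selection scans (iHS and nSL) with a windowed
hysteresis peak caller, structural-variant set accounting over assembly
support vectors, kinship-based cohort pruning, karyotype fusion-point
detection, and impact-class enrichment of variants in sweep regions.
This vignette explains the models and conventions, the parameters that
matter, what the synthetic-data generators emulate, and the package's
known limitations.

## The haplotype statistics

Water buffalo cohorts genotyped against a pangenome yield phased,
biallelic variant panels. The substrate of all haplotype statistics here
is a `hap_matrix`: haplotypes in rows, sites in columns, entries 0
(ancestral) / 1 (derived), strictly increasing bp positions.

**EHH.** For a core site and allele, the extended haplotype homozygosity
at extension site $t$ is the probability that two random carriers of the
core allele are identical over every site from the core to $t$:

$$\mathrm{EHH}(t) = \sum_h \binom{c_h}{2} \Big/ \binom{n}{2},$$

over the distinct extended haplotypes $h$ with multiplicities $c_h$
among the $n$ carriers. EHH is 1 at the core and non-increasing
outwards.

**iHH and iHS.** iHH is the trapezoidal integral of the EHH decay curve
against physical distance in bp, summed over both arms. The
unstandardized score at a site is
$\ln(\mathrm{iHH}_\mathrm{ancestral}/\mathrm{iHH}_\mathrm{derived})$;
a strongly negative value marks unusually long homozygosity around the
derived allele — the signature of a recent hard sweep. No genetic map is
used: integration is over physical distance, as in the scan tools this
mirrors.

**nSL.** The same ratio with iHH replaced by the mean pairwise
shared-segment length measured in *sites*: for every pair of carriers,
the count of consecutive sites (core inclusive, so $L \ge 1$) over which
the pair is identical, stopping at the first mismatch or the chromosome
edge. Measuring in segregating sites rather than bp makes nSL robust to
recombination-rate variation.

Numerical conventions, fixed and tested:

* The EHH curve is truncated after the *first* extension site whose EHH
  drops below the cutoff (default 0.05); that site is kept as the
  curve's edge and contributes its trapezoid to iHH. A curve that
  reaches EHH = 0 stops there — it cannot recover.
* Under the default `truncation = "skip"`, a site is invalid when any of
  its four arms fails to decay below the cutoff before the chromosome
  end, or when either iHH is 0. `truncation = "clip"` integrates to the
  edge instead, appropriate for short synthetic chromosomes.
* Sites with derived-allele frequency outside
  `(maf_floor, 1 - maf_floor)` (default floor 0.05, matching the cohort
  variant filter) are reported but flagged invalid.
* The inner loops are compiled (Rcpp); the test suite holds them to
  *exact* equality with exhaustive pair-enumeration oracles on hundreds
  of random small panels.

**Standardization.** Unstandardized scores depend strongly on allele
frequency, so valid scores are z-standardized within derived-allele
frequency bins: 50 equal-width bins on (0, 1) by default, bins holding
fewer than 20 scores merged with their nearest (smaller) neighbour
until every bin meets the floor, and the population (divide-by-$n$)
standard deviation in the denominator, so that within-bin moments are
exactly 0/1 — a property the tests assert to 1e-9. Both bin count and
floor are exposed because scan tools differ here and the upstream
pipelines leave them at tool defaults.

## Windowed hysteresis peak calling

Standardized scores are averaged (sign retained) over consecutive,
non-overlapping windows of exactly 100 valid variants per chromosome;
the trailing partial window is dropped so window means stay comparable.
A window whose $|\text{mean } z|$ reaches 1.5 seeds a peak, which
extends over consecutive windows in both directions while
$|\text{mean } z| \ge 0.5$; overlapping spans merge. The two-threshold
rule keeps one broad signal from fragmenting into many calls, and using
absolute values makes calls invariant to a global sign flip (tested).
Extension is bidirectional from the seed — this makes the call
symmetric and independent of scan order, which a forward-only reading
would not be. Peak bp coordinates run from the first to the last variant
of the member windows. Peaks are unioned per chromosome into disjoint
"selection regions" (`merge_peak_regions()`), written as 0-based BED,
and intersected with gene models under closed 1-based semantics
(touching intervals do not overlap).

```{r pipeline, eval = FALSE}
run <- run_selection_pipeline(
  list(seed = 1,
       simulate = list(n_hap = 100, n_site = 2000, seed = 1,
                       sweep = list(core_index = 1000, halfwidth = 150,
                                    seed = 2)),
       scan = list(metric = "ihs")),
  out_dir = "sweep_run")
glance(run)
autoplot(run$windows, peaks = run$peaks)
```

## Cohort QC

* `mask_low_gq()` sets genotypes with GQ strictly below 25 to missing;
  GQ 25 survives, records without GQ pass through.
* `filter_variants()` keeps a variant iff its missing-genotype fraction
  is $\le$ 0.2 **and** its minor allele frequency over non-missing
  alleles is strictly $>$ 0.05 (a variant at exactly MAF 0.05 is
  excluded, the usual `MAF>0.05` filter-expression reading). Missing
  genotypes never enter allele-frequency denominators.
* `prune_related()` removes close kin: pairs with KING kinship
  strictly above 0.0625 (third degree) are edges of a relatedness
  graph, and within each connected component a greedy maximum-coverage
  independent set is kept — samples visited by mean coverage
  descending (ties by sample id for determinism), each kept iff no
  already-kept neighbour. This keeps *every* mutually unrelated member
  of a family cluster rather than one representative: it maximizes the
  retained cohort while guaranteeing no kept pair is related, and
  it provably keeps each cluster's highest-coverage member. Whether the
  original cohort analysis kept one or several members per component is
  not recoverable from its description; this choice reproduces both its
  "prioritize higher coverage" rule and its no-related-pair guarantee.
* `titv_ratio()` is the usual transition/transversion count ratio over
  SNVs (~2.1–2.2 indicates a clean mammalian WGS call set).

## Pangenome set accounting

A multi-assembly graph VCF records, per variant, which assemblies carry
the alternative allele. `compute_support_vectors()` writes this as a
`SUPP_VEC` bit-string (missing genotype = 0: in an assembly VCF,
missingness means the path is absent). On top of it:

* `upset_counts()` tallies presence patterns over variants with
  $|\Delta\ell| \ge 50$ bp — the numbers behind an SV upset plot. The
  50 bp threshold is the community SV convention; the source material
  uses "over 50 bp" in one place and "$\ge$ 50 bp" in another, and the
  package adopts $\ge$ 50 everywhere.
* `nonreference_lengths()` sums inserted bp per assembly group: `total`
  counts a record once when any group member carries it, `exclusive`
  only when every carrier is inside the group. Each variant counts
  once per group, not once per carrier — inserted sequence is a
  property of the variant path, not of how many samples walk it.
  Deletions contribute nothing.
* `classify_caller_overlap()` compares two call sets by exact
  `(chrom, pos, ref, alt)` key, an explicit simplification of
  haplotype-aware (vcfeval-style) matching: a variant represented
  differently by two callers counts as two caller-specific keys.

## Karyotype fusion point

Swamp buffalo (2n = 48) carry a chromosome 1 formed by the fusion of
river buffalo (2n = 50) chromosomes 4 and 9. `find_fusion_point()`
recovers the junction from PAF alignments of the fused chromosome
against the two river targets: alignments shorter than 10 kb are
dropped as spurious, records are clustered per target, the cluster
with the smaller maximum query end is upstream, and the fusion point is
the floor midpoint of the gap between the clusters. Ragged alignments
may overlap slightly near the junction: overlaps up to 1% of the query
length produce a warning (the midpoint is still returned), larger
interleaving is an error. `split_chromosome()` and `lift_coordinate()`
then define the two segments and map coordinates across the split,
composing to the identity (tested exhaustively).

## Impact enrichment in sweep regions

`impact_enrichment()` asks whether HIGH/MODERATE/LOW/MODIFIER variants
(SnpEff-style annotations, most severe retained when several are
present) are over-represented inside selection regions, separately for
SNVs, indels and SVs. The 2x2 table per (variant class, impact) is
[in-region impact X, in-region other; out-of-region X, out-of-region
other]: the background is the variants *outside* the regions, which
keeps the table cells disjoint and the exact test well-formed — a
"genome-wide" background including the region variants would count
them twice. The two-sided Fisher p is computed by point-probability
summation of the hypergeometric distribution (the convention of
standard exact-test implementations; held to 1e-12 against exhaustive
enumeration over all tables with $N \le 40$), odds ratios get a 0.5
continuity correction when a cell is zero, and Benjamini–Hochberg
adjusted p-values are reported alongside the raw ones across the
impact-by-class grid. `population_aaf()` reports per-population
alternate allele frequencies (over non-missing alleles) for variants
inside the regions.

## What the synthetic data emulate

Every input is generated in code, so the whole pipeline runs and is
tested without any download.

* **Founder-mosaic panels** (`simulate_panel()`): `n_founders = 8`
  founder haplotypes i.i.d. Bernoulli(0.5) per site; each sampled
  haplotype copies one founder and switches with probability 0.01 per
  site, then flips alleles with probability 0.002; site spacing is
  geometric with mean 1000 bp (minimum 1, so positions strictly
  increase). This creates linkage blocks and realistic allele-frequency
  spread without a coalescent simulation — a deliberately stylized
  stand-in. All generators are bit-reproducible given their seed.
* **Implanted sweeps** (`implant_sweep()`): `round(0.8 n)` carriers
  (first indices of a seeded shuffle) have their alleles on
  core $\pm$ 150 sites replaced by founder 1's alleles with a 0.01
  per-site flip, and the core column is forced so the core DAF is
  exact. Carriers therefore share one long haplotype — the signal iHS
  and nSL respond to at the core.
* **Toy pangenomes** (`simulate_toy_pangenome()`): presence patterns
  over assemblies (60% singletons, otherwise uniform over non-empty
  patterns), hom-alt genotypes for presence (assembly-haplotype
  semantics), log-uniform allele-length differences with 30% forced
  into the SV range, and insertions outnumbering deletions 7:3 —
  roughly the insertion-heavy balance assembly-based SV sets show. The
  generator returns its truth table, and the set-accounting module is
  required to reproduce it exactly.
* **Kin cohorts** (`simulate_kin_cohort()`): family clusters whose
  within-cluster kinship (0.07–0.25) sits strictly above the 0.0625
  third-degree threshold and cross-cluster kinship (0–0.05) at or
  below it, with uniform 5–40x coverage — so the correct pruning
  behaviour is known by construction.
* **Fused-chromosome alignments** (`simulate_fusion_paf()`): two query
  blocks aligned to the two river targets with a known midpoint truth;
  blocks can be cut into sub-alignments (evenly spaced cuts with
  bounded jitter, so no sub-alignment falls under the caller's 10 kb
  filter) to exercise the clustering.

## Problem sizes and reproducibility

The default test-suite and acceptance-script experiments use panels of
100 haplotypes by 2000 sites (20 sweep + 20 neutral replicates),
toy pangenomes of 400 variants over 4–5 assemblies, 100 seeded kin
cohorts, 1000 random window tracks for the peak caller, and all 2x2
tables with total $N \le 40$ for the exact test — sizes chosen so the
full suite runs in a couple of minutes on one core while still
exercising every code path. All randomness flows from explicit seeds;
the pipeline writes its config hash and seed to the run log, and two
runs with the same config are byte-identical.

## Known limitations

* **Windowed recovery of stylized sweeps.** The founder-template sweep
  implants hitchhiking alleles whose derived/ancestral label is random
  with respect to the swept haplotype: roughly half the swept-window
  sites score strongly negative and half strongly positive. The
  100-variant *signed* window means used by the peak caller therefore
  cancel near zero (|mean| ~ 0.2 at best), and the 1.5 seed threshold —
  calibrated for real cohorts, where linkage makes window means both
  more dispersed and more sign-coherent — is never reached on these
  panels. The sweep is nevertheless plainly visible at the site level
  (core raw iHS ~ -2 to -3.6, z ~ -4 across replicates; both are
  asserted by the tests and reported by the acceptance script).
  Passing the windowed caller on synthetic panels would require either
  a sign-coherent (all-derived) sweep template or re-calibrated
  thresholds; both would change the study conditions, so the package
  documents the discrepancy instead. By the same mechanism, the mean
  |z| inside the swept window does not exceed the genome background on
  these panels: standardization pins the genome-wide mean |z| near 0.8
  and sweep sites partly dominate their own DAF bins.
* The generators make no attempt at realistic recombination maps,
  coalescent genealogies, or sequencing error; passing tests show the
  *algorithms* are correct under known structure, not that thresholds
  are optimal for any real cohort.
* Variant normalization is trim-only (no left-alignment against a
  reference sequence), symbolic ALT alleles are rejected, and caller
  comparison is exact-key, not haplotype-aware.
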