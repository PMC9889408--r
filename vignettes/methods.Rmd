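---
title: "Methods: cistrome integration, motif enrichment, and the synthetic truth generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(eracr)
```

# Scope and model

`eracr` integrates *peak-level* ATAC-seq and ChIP-seq data for an
inducible-ERα experiment laid out on a clone × Dox × E2 grid. It starts
from called peaks, not reads: alignment, peak calling and quantitative
(read-count) differential testing are upstream of, and outside, this
package. Every analysis below is a deterministic function of the input
peak files, the genome FASTA, the motif library and the thresholds;
randomness exists only in the synthetic generator and is fully governed
by its seed.

## Interval conventions

All coordinates are 0-based half-open (BED convention); narrowPeak
summit offsets are converted to absolute positions on ingestion.
"Overlap" means ≥ `min_bp` shared bases (default 1). Chromosome names
are compared by exact string equality. Intervals with identical
coordinates within one file are deduplicated with a warning. Interval
algebra is delegated to `GenomicRanges`/`IRanges` behind the package's
own operation surface; the test suite checks those operations against
independent brute-force per-pair and per-base oracles, so the
delegation is itself under test.

## Condition groups

For one clone and assay, consensus regions are the merged union of the
four condition peak sets, re-scored for binary presence per condition.
A region present in exactly one condition is `<condition>_specific`. A
region absent from both Dox− conditions and present under Dox is
ERα-dependent: only Dox+/E2− (`E2minus_ERa`), only Dox+/E2+
(`E2plus_ERa`), or both (`E2ind_ERa`). Regions touching any Dox−
condition are labelled `unclassified` rather than discarded so totals
remain auditable. Presence is binary (overlap), not count-based: the
occupancy criterion used by the original analysis workflow is not
recoverable from peak files alone, so stringency is exposed as the
`min_bp` knob instead of hard-coding a count threshold.

## ERα-ACR

An ERα-ACR is a ChIP peak overlapping an ATAC peak of the same clone
and condition. The reported coordinates are the ChIP peak's: ChIP
defines "ERα-bound", ATAC only gates "active". Across the three
ERα-expressing clones a region is `common` (overlaps all three clones'
ACR), `<clone>_specific` (overlaps neither other clone), or
`shared_subset` (exactly two clones). The two-clone case is kept as an
explicit label — silently folding it into either published category
would make the partition counts non-additive. Cross-clone identity is
overlap-based because clones have independent peak calls; synthetic
data places loci disjointly so identity is unambiguous there.

## Motif scanning and ERE classification

Motifs are probability PWMs with per-base pseudocount (default 0.25)
and a background distribution (default uniform). A window scores
`sum_j log2(p_j(b_j) / bg(b_j))` bits; both strands are scanned and a
hit requires `score ≥ threshold_fraction × max score` with
`threshold_fraction = 0.8` by default. Windows containing `N` score
−Inf. With the bundled sharp toy PWMs (85:5:5:5 columns), the 0.8
threshold admits exactly the consensus string and nothing with a
mismatch — a property the synthetic round trip relies on (see below).

ERE classification: a *full* site is a forward half-site hit and a
reverse-complement half-site hit separated by exactly `spacer` (default
3) intervening bases — the palindromic `AGGTCAnnnTGACCT` arrangement.
Everted or differently spaced pairs do not count. Any half-site hit
without such a pair is *half*; otherwise *none*. Reported "half-site
rates" therefore mean *half-site-only* (full sites are counted
separately, not double-counted as halves).

## Enrichment

Motif enrichment of a region group against a background set containing
it is the exact upper-tail hypergeometric probability
`P(X ≥ k | N, K, n)`, reported as `score = −log10 p` (computed on the
log scale, so extreme enrichments do not underflow). The background for
a clone's condition groups defaults to that clone's full consensus set.
Benjamini–Hochberg adjusted p-values are reported alongside but the
selection filters operate on the raw score, mirroring how the
enrichment scores are used as descriptive statistics rather than as a
multiplicity-controlled decision procedure. Differential enrichment
between a mutant and the WT clone is the per-motif score difference;
"remarkably enriched" has no published numeric definition, so the flag
threshold defaults to `delta_min = 10` on the −log10 scale and raw
deltas are always reported so any cutoff can be re-applied. The
high-enrichment selection threshold is `p ≤ 1e-20`: the printed filter
"−Log(p-value) ≤ 10^−20" taken literally would select p ≈ 1, so it is
read as a bound on the p-value itself; the argument `p_max` makes the
choice explicit and reversible.

## Fox co-occurrence statistics

For a clone pair (canonically WT vs K303R, Dox+/E2+): the Fox fraction
is the share of ChIP peaks with ≥ 1 Fox-motif hit; the ERE-free
fraction is the share of those Fox+ peaks classified `none`; sharing is
directional (a WT Fox+ peak is shared iff it overlaps any K303R Fox+
peak, and vice versa) and the single headline number is the larger
direction; the opening rate is the fraction of Fox+ peaks overlapping
the same clone's ATAC peaks, stratified by the two-clone partition
(shared / clone-specific) and by ERE label. "Open" uses raw ATAC peaks
(not the ACR subset) by default; both interpretations are available.

# The synthetic generator: a stated world

`plant_scenario()` draws non-overlapping fixed-width loci (200 bp,
summit at centre) on an i.i.d. random genome (GC 0.41, human-like),
writes motif instances into the sequence, and emits narrowPeak files
per clone × Dox × E2 × assay plus a manifest of every draw. The default
`fig4c` configuration plants, per clone, `n = 4000` ChIP peaks under
each Dox+ condition, composed of:

- 1200 tri-clone *common* active regions per E2 condition (always open
  in all clones), with ERE labels drawn at half/full = 11%/5% (E2−) and
  25%/15% (E2+) — the condition-specific region sets differ because an
  ERE is a sequence property and cannot appear with E2 treatment at a
  fixed locus;
- Fox+ peaks at the published per-clone fractions (WT 16.5%, K303R
  18.5%; Y537S set to 10%, a value chosen once for plausibility, not a
  published number), with WT→K303R locus sharing at 80%;
- ERE-free fractions among Fox+ peaks of 63.6% (WT) and 68.1% (K303R).
  Shared loci carry a single sequence read by both clones, so they are
  drawn at the WT rate and the K303R-only rate is adjusted so the K303R
  *marginal* matches its configured value (the adjustment is computed,
  not tuned);
- chromatin opening per stratum: WT-specific 8.5%, K303R-specific
  45.2%; the shared-stratum rates (WT 20%, K303R 35%) and the 60%
  baseline for non-Fox ChIP peaks are unpublished and were fixed once
  as scientifically plausible values consistent with the direction of
  the published contrast;
- 1000 constitutively open background loci present in every sample's
  ATAC (and only there), which exercise the `unclassified` path of the
  condition-group classifier; Dox− ChIP files are empty (no ectopic
  receptor), and among ERE-carrying Fox+ peaks one third are full
  sites.

**Scrubbing.** A 200 bp random sequence contains a chance `AGGTCA` with
probability ≈ 9% per strand pair, which would visibly bias every
planted rate. The generator therefore removes unintended exact
occurrences of the tracked Fox/ERE consensus strings (both strands)
from every analysed locus by point mutation, never touching planted
bases. Combined with the sharp PWMs at threshold 0.8 (consensus-only
hits), scanning the emitted files recovers *exactly* the planted flags
— the recovery tests assert equality with the manifest, and the
acceptance statistics inherit only the binomial sampling noise of the
draws themselves.

**What a green round trip does and does not establish.** It
establishes that the analysis code measures what the generator planted
— classification, set algebra, scanning and counting are correct end to
end. It does not establish robustness to properties of real data the
generator omits: variable peak widths, overlapping/nested peaks,
degenerate real-world motifs hitting below consensus, read-depth
effects on peak calling, or count-based presence criteria.

## Sample similarity ("DBA-lite") and reporter assays

True differential-binding-affinity analysis re-counts reads under
consensus regions; without raw reads the package builds a binary (or
peak-score) occupancy matrix over the global consensus and projects
samples by column-centred PCA (`prcomp`). Coordinates are deterministic
up to per-component sign. Dual-luciferase fold changes normalise
firefly by Renilla *per well* and divide condition means by the
reference-condition mean; per-well normalisation is the standard
convention and is replicate-robust (the alternative, ratio of means,
is not exposed because it changes results only under pathological
imbalance).

# Numerical choices and degenerate inputs

- Hypergeometric p-values are computed with `phyper(log.p = TRUE)`;
  scores are exact even when `p < 1e-300`.
- Empty strata report `rate = NA` with `n = 0`, never 0; empty region
  sets are errors for rate operations (an undefined rate is not a zero
  rate).
- `select_variable_motifs` guards zero minima with
  `eps = 1/group_size` so a motif absent from one cell can still be
  selected without dividing by zero.
- Ties in top-k and differential tables break lexicographically by
  motif id, making outputs reproducible.
- Summit windows clip to `[0, chromosome length)` and may therefore be
  narrower than `2 × flank` near edges.

# Default thresholds

| Parameter | Default | Meaning |
|---|---|---|
| `min_bp` | 1 bp | minimal overlap for presence/ACR/sharing |
| `threshold_fraction` | 0.8 | PWM hit cutoff as fraction of max score |
| `pseudocount` | 0.25 | per-base PWM regularisation |
| `spacer` | 3 bp | ERE full-site arm separation |
| `flank` | 3000 bp | summit window half-width |
| `delta_min` | 10 | differential-enrichment flag (−log10 scale) |
| `ratio_min`, `rate_min` | 3, 15% | variable-motif rate filter |
| `p_max` | 1e-20 | high-enrichment motif selection |

# Known limitations

Peak-level input only; binary presence (no affinity re-counting); exact
chromosome-name matching; the generator's fixed-width disjoint loci are
deliberately simpler than real peak landscapes; FoxM1/FoxK2-style
analyses are supported generically through the motif library but ship
no calibrated defaults.
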