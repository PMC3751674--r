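---
title: "Detecting conserved microRNA target sites in lncRNAs: methods and design"
author: "lncmir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting conserved microRNA target sites in lncRNAs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis

`lncmir` asks whether a set of transcripts — typically long non-coding
RNAs — carries evolutionarily conserved microRNA seed matches more
often than expected by chance. The analysis has five stages, each an
exported function, orchestrated by `runPipeline()`.

## Seed matches and site types

A microRNA family is represented by its 7-nt seed (miRNA positions
2–8, 5'→3', RNA alphabet). Target sites are exact matches in the
*sense* transcript sequence to one of three patterns, derived at
pattern-build time in DNA space (U→T):

* **7mer-m8** — reverse complement of the full seed;
* **8mer** — the 7mer-m8 followed by an `A` (the position opposite
  miRNA position 1);
* **7mer-A1** — reverse complement of seed positions 1–6 (miRNA 2–7)
  followed by an `A`.

All exact occurrences are found (Biostrings `PDict`/`matchPDict` over
an N-joined concatenation of the spliced transcripts; an 8-nt pattern
cannot cross the 10-N spacer). Overlapping occurrences are all kept,
but a locus is assigned its *best* site type: an 8mer match suppresses
the 7mer-m8 at the same start and the 7mer-A1 one base downstream, so
the three strata are disjoint and counts are additive. We do not
require the unpaired position-1 `A` to be conserved separately: the
full site string is the unit of conservation.

Sites are mapped from transcript to genome coordinates through the
exon structure, strand-aware. A site spanning a splice junction
yields several genomic pieces and is reported at the genomic position
of its 5'-most base in transcript orientation. Internally all
coordinates are 0-based half-open; GTF input and report output are
1-based.

## Conservation tiers

Conservation is read from a MAF multiple alignment anchored on the
reference species. A species is **intact** at a site iff its aligned
characters over the site's reference columns equal the site string
exactly, with no gap in either row — the strictest defensible reading
of "perfectly aligned", and deliberately insensitive to alignment
quality scores we do not model.

Species are grouped into three disjoint clade groups: non-reference
primates, non-primate placental mammals, and non-mammal vertebrates.
For each group we compute the fraction of *aligned* group members that
are intact (species absent from the covering alignment block are
excluded from the denominator by default; `absentCountsAgainst` flips
this). The site's tier is the deepest *nested* tier whose own group
and all shallower groups reach `minFraction` (default 0.5):

| tier | requires |
|------|----------|
| primate | primates ≥ 0.5 |
| mammal | primates ≥ 0.5 AND other mammals ≥ 0.5 |
| vertebrate | … AND non-mammal vertebrates ≥ 0.5 |

The reference species must itself carry the match
(`requireReference`, default on). Fractions are computed over
disjoint groups — not cumulative pools — because pooling would let a
site intact in all mammals clear a 50% threshold over the full
species set and be mislabelled vertebrate-conserved; scoring presence
separately in primates, mammals and non-mammal vertebrates keeps the
tiers meaningful. Stratum *counts* are nevertheless cumulative: a
mammal-tier site contributes to the primate and mammal strata, making
counts monotone non-increasing with stringency.

The per-clade criterion is a fractional threshold rather than an
all-species requirement because alignment dropout in large multiple
alignments makes all-species intactness unrealistically strict; the
threshold is configurable and recorded in run metadata.

## The dinucleotide null

Expected counts come from random seeds that preserve the composition
of the real seed pool. We fit a first-order Markov model: the initial
distribution is the empirical distribution of position-1 nucleotides
(unsmoothed — position-1 composition is preserved exactly), and the
4×4 transition matrix pools all seed dinucleotides with add-one
smoothing (a pool of ~87 seeds contributes only ~520 transitions, so
rare dinucleotides can be absent; a zero row would make sampling
undefined). We *generate* from a fitted model rather than shuffling
each seed because 7-mers admit very few distinct
dinucleotide-preserving shuffles — too few to build 20 diverse sets.

Each of 20 random sets has exactly the size of the real family set.
A sampled seed identical to any real seed is rejected and redrawn
(it would absorb true signal into the null); duplicates within a set
are allowed, since real families can share composition. Sampling is
reproducible given `rngSeed`, and a rejection budget (`maxDraws`,
default 10^6) turns a degenerate model into an explicit error.

Random sets are mapped by the *same* code path as the real seeds —
`expectedCounts()` calls the same scan and conservation internals —
so feeding the real set through the null path reproduces the observed
counts exactly (this pipeline identity is asserted in the tests).

## Enrichment statistics

For each stratum (tier × site type × transcript subset × family
class):

* expected = arithmetic mean of the 20 per-set counts. The
  alternative — mean of per-set ratios — is unstable when per-set
  counts are small, so the ratio-to-mean is primary and the mean of
  per-set ratios is reported alongside (`mean_of_ratios`).
* ratio = observed / expected; 0 when nothing is observed; undefined
  (NA) when the expectation is 0 with a positive observation.
* empirical *P* = fraction of random sets with count ≥ observed.
  Ties count as exceeding — the conservative choice. With 20 sets the
  *P* scale is quantized in steps of 1/20, and the labels follow the
  19/20 and 18/20 rules: `P<=0.05` when at most one set reaches the
  observed count, `P=0.10` when exactly two do.
* FDR = expected/observed capped at 1 — the estimated fraction of
  reported sites attributable to chance, the reciprocal of the
  ratio. No multiple-testing correction is applied across the
  stringency grid: the strata are nested views of the same signal,
  not independent hypotheses.
* a stratum with expected < 1 is flagged unreliable (`reliable =
  FALSE`): a ratio estimated from sub-unit expectations is noise.

## Localization

Genes are classified from a nuclear/cytoplasmic fraction count matrix
(`SummarizedExperiment`, one column per cell line × fraction). Each
library is scaled to counts per million by its library size (column
sums by default); the normalized ratio is the pooled cytoplasmic CPM
plus a 0.5-CPM pseudocount over the pooled nuclear CPM plus the same
pseudocount. Pooling across cell lines is robust to zero counts in
individual lines; a per-line-median variant is available
(`perLineMedian`). The depth filter — at least 20 *raw* mapped reads
over all libraries — guards against unreliable ratios in the
low-abundance range and deliberately operates on raw counts, not CPM.
A gene is cytoplasmic iff it passes the depth filter and its ratio
exceeds 1.

# The synthetic-data generator

`generateDataset()` emulates every input of a real study: a
single-chromosome genome for a primate reference; star-topology
species within three clades (independent per-site substitutions from
the reference at clade-specific rates — adequate because conservation
calls here are presence/absence per species, not phylogeny-aware); a
GENCODE-dialect GTF with coding genes (5'UTR+CDS+3'UTR over three
exons) and lncRNA genes (one or two exons); seed families; a gapless
MAF with one block per gene locus; and negative binomial fraction
counts (dispersion 0.1, a standard over-dispersed RNA-seq model).

Key default conditions: 87 conserved and 87 non-conserved families
and 20 random sets of matching size; seven cell lines of fraction
counts; background GC 0.41 (human-like, i.i.d. — the simplest
background under which the dinucleotide null is still non-trivially
exercised through seed composition); clade divergence 0.02 / 0.08 /
0.30 substitutions per site for primates / mammals / vertebrates
(monotone by construction); intergenic gap 12 kb so that clean genes
pass the 10 kb filter; a fixed set of decoy genes exercising every
exclusion rule (a pseudogene, a <200 nt isoform, a mixed-biotype
gene, a coding-symbol collision, and a pair of genes 3 kb apart).

## Planting a known enrichment

For a target enrichment *e* at the planted stratum, the generator
inserts `round((e − 1) · E)` extra 8mer sites, where *E* is the
*analytic* expected count of clade-conserved background matches for
the emitted conserved families: per-pattern match probabilities under
the realized base composition, times the number of scan positions,
times the probability that a background match passes the planted
tier's clade thresholds (binomial over group sizes with per-species
intact probability `(1 − d)^8`). This makes the recovery target
well-defined: the observed count is background-plus-planted while the
null estimates the background, so the realized ratio concentrates
around *e*. Planted sites are copied verbatim into all species of the
planted tier's clades and forced to carry ≥ 2 mismatches within the
seed-pairing positions in deeper clades; `plantedEnrichment = 1`
plants nothing. Insertion positions are uniform over single-exon
windows, non-overlapping; an enrichment that exceeds sequence
capacity fails loudly rather than silently saturating.

What the generator does *not* emulate — and what passing tests
therefore do not show about real data: indels and alignment gaps
(the emitted MAF is gapless, though the parser and conservation
caller handle gaps and are tested on gapped fixtures), phylogenetic
correlation between species, local conservation patches, splice
isoform complexity beyond two exons, composition heterogeneity along
transcripts, and read-level sequencing artifacts. Byte-identical
output for identical configurations is guaranteed and tested.

# Numerical choices and degenerate inputs

* Site-type ties at one locus resolve 8mer > 7mer-m8 > 7mer-A1; if a
  family's 7mer-A1 string happens to equal its 7mer-m8 string, the
  locus is counted once as 7mer-m8.
* The clade threshold is `count ≥ ceiling(f · n)` over `n` aligned
  group members; a group with no aligned members fails the threshold
  (NaN fraction) rather than passing vacuously.
* Score-based gene subsetting breaks ties lexicographically by gene
  id; unscored genes are skipped with a warning.
* The intergenic gap is measured between gene spans (outermost
  transcript bounds), strand-ignored, with overlap counting as gap
  0 — the most conservative reading of "genomic separation".
* Pseudogene detection is substring matching on "pseudogene" across
  transcript biotypes.
* Symbol matching against the coding list is case-insensitive exact
  match, since symbol lists mix cases across sources.
* Empty transcript sets, empty site tables, all-zero count matrices
  and unalignable sites (no covering MAF block → tier `none`) are all
  defined, tested paths, not errors.

# Problem sizes used by the test suite

The suite's simulation scales are chosen so the full run completes in
a few minutes while keeping Monte-Carlo noise well inside the asserted
bands: planted-enrichment recovery averages 10 replicates of 800
lncRNA transcripts × 20 conserved families (per-replicate ratio SD
≈ 0.1, so the 10-replicate mean is within ±0.2 of the 1.8 target
with large margin); null calibration averages 50 replicates of 250
transcripts × 10 families (per-replicate SD ≈ 0.19, 50-replicate
standard error ≈ 0.03 against a ±0.1 band). The acceptance script
runs 10 replicates at 2,000 transcripts × 20 families. Scanner
correctness is checked against a position-by-position brute-force
oracle on 1,000 random sequences.

# Known limitations

* No context scores, 3'-supplementary pairing, free-energy models,
  wobble pairing or 6mer sites: site definition is exact seed
  complementarity only.
* Conservation is binary per species; branch lengths and ancestral
  states are out of scope (no PhyloP/PhastCons analogue).
* The MAF reader requires the reference row first in each block on
  the + strand, and indexes blocks by reference interval only; sites
  spanning two blocks are treated as unalignable rather than
  stitched.
* The empirical *P* resolution is 1/20 with the default 20 sets; a
  finer scale needs more sets, at proportional cost.
* Localization is gene-level; isoform-level localization is not
  attempted.
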