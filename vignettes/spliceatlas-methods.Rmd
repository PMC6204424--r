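---
title: "Methods: event classification, stratification and dating in spliceatlas"
author: "spliceatlas authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: event classification, stratification and dating in spliceatlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceatlas)
```

# Scope

`spliceatlas` rebuilds, as a tested R pipeline, the analytical core of a
genome-wide alternative-splicing (AS) atlas of the kind constructed for moso
bamboo (*Phyllostachys edulis*): AS events are extracted and classified from
transcript isoforms, splice-site dinucleotides are typed against the genome,
tissue specificity is quantified with the fractional statistic maxTs, genes
are stratified by evolutionary age against a dated eight-species tree, and
gene families are screened by homology filters and dated through synonymous
divergence. Dataset-scale results of the original atlas (hundreds of
thousands of events from ~600 Gb of reads) are not reproducible at desk
scale; what this package makes reproducible is the *method*, exercised on a
synthetic-data generator with planted, machine-readable ground truth.

# The event model

## Coordinates

All internal coordinates are 0-based half-open `[start, end)`; GTF/GFF3
(1-based inclusive) and BED (0-based half-open) are converted exactly once at
the I/O boundary. Adjacent exons in input (zero-length introns) are merged
with a warning, and introns shorter than a configurable minimum (default
20 bp, matching common transcript-assembler settings) are rejected.

## Extraction and delimitation

An AS event is a variation between the intron chains of two isoforms of one
gene. Within the genomic span shared by both isoforms, the splice sites
present in *both* chains partition the span into regions; every region where
the chains differ is one event. This nearest-common-flank delimitation makes
signatures well defined and therefore deduplicable: two events are equal iff
their (gene, type, signature) triples are equal, where the signature records
the region bounds and both intron chains inside it, canonically ordered so
that `pairwise_events(a, b)` and `pairwise_events(b, a)` agree.

Because an interior splice site shared by both chains always splits regions,
a pattern such as chains `[(100,200)]` versus `[(90,200),(220,260)]`
produces *two* events (an alternative-donor pair sharing the acceptor at
200, plus a retained intron at `(220,260)`), not one composite event.

## Classification

Each differing region is classified from the intron content of its two
sides:

* **IR** (intron retention): one side has exactly one intron, the other is
  contiguous exon.
* **A3SS** (alternative acceptor): one intron per side sharing the donor
  boundary and differing at the acceptor.
* **A5SS** (alternative donor): the symmetric case, shared acceptor.
* **ES** (exon skipping): one side has `k >= 1` complete exon(s) flanked by
  introns whose outer boundaries match the single spanning intron of the
  other side. Multi-cassette skipping is deliberately typed ES, keeping the
  coarse four-type scheme.
* **OTHER**: every remaining pattern — e.g. a skip combined with a shifted
  donor in one region, or an exon versus two retained introns.

Donor and acceptor are defined in transcription orientation, so the genomic
comparison is strand-flipped for minus-strand genes: the same coordinates
that classify A3SS on the plus strand classify A5SS on the minus strand.
Genes with unknown strand (`.`) still yield events, but one-boundary-shared
patterns cannot be oriented into A3SS versus A5SS and fall into OTHER; IR
and ES are orientation-free and keep their labels.

Two further conventions close the definition. Isoform pairs whose intron
chains are identical inside the shared span but whose terminal exons extend
differently yield *no* events — alternative transcription start/polyA sites
are not splicing events in the four-type scheme. And regions that touch a
truncated intron at the shared-span edge (an intron continuing past the
other isoform's terminus) carry incomplete evidence and are typed OTHER.

The implementation is verified in two independent ways: against a
brute-force enumerator that re-derives events from per-position
intron-membership vectors and run-length encodings, on thousands of random
small loci; and against the generator's planted events, which must be
recovered at 100% with exact types.

## Catalogs, tissue support and platform overlap

A catalog deduplicates events over all distinct isoform structures of all
genes. When per-tissue annotations are supplied, each event records its
*support*: the tissues in which some witness isoform pair co-occurs (if any
pair does), otherwise the union of the witness isoforms' tissues. From this,
two partitions are reported separately: `tissue_specific` (support size 1)
versus shared, and `within_tissue` (derivable inside at least one single
tissue's annotation) versus `among_tissue` (only derivable by comparing
isoforms across tissues). Both notions appear in atlas reports and they are
not the same thing; keeping them separate avoids forcing either number.

`catalog_overlap(a, b)` reports |A∩B|/|A| on events and on AS-gene sets,
with the first argument as the denominator — pass the smaller platform
(e.g. a long-read catalog) first, which is the direction such comparisons
are usually quoted in.

# Splice-site typing

The donor is the first two intronic bases and the acceptor the last two, in
transcription orientation (reverse-complemented on the minus strand).
Classes are GT-AG, GC-AG and AT-AC (canonical), GT-AT (tracked as its own
noncanonical class, as splice-site surveys commonly do) and `other`;
dinucleotides containing N fall into `other`, since ambiguity codes cannot
support a canonical call. Classification is a pure function of the two
dinucleotides and is property-tested against a literal 256-entry table.
Tallies are reported per unique intron and, optionally, per AS event (every
intron of an event's variable region counted once per event) — published
usage percentages are sometimes quoted against either denominator, so both
are emitted.

# Tissue specificity (maxTs)

For a gene with non-negative expression `x_1..x_n` over `n` tissues,
`Ts_i = x_i / sum(x)` and `maxTs = max_i Ts_i`, so `maxTs` ranges from `1/n`
(perfectly uniform) to 1 (all expression in one tissue). Under this
fractional definition, *high* maxTs means *more* tissue-specific. Some
reports verbally attach the opposite orientation to the same statistic; the
implementation follows the fractional definition and provides an
`orientation` switch that only relabels, never changes the numbers. All-zero
rows are flagged unexpressed and excluded downstream. Label thresholds
(maxTs ≥ 0.8 tissue-specific, ≤ 2/n constitutive) are configurable
conveniences, not part of the statistic. The statistic is scale-invariant by
construction, which the suite checks by property.

# Phylostratigraphy

Given a rooted ultrametric species tree with node ages and an ortholog
copy-number table, each focal-species gene is dated by a Dollo-style rule:
the deepest node on the root-to-focal path whose off-path clade contains at
least one carrier marks the origination; losses are not modelled. With 7
internal nodes on the focal path of the default eight-species tree this
yields strata D8 (evidence at the root — shared by all species) down to D2,
plus D1 for focal-lineage-specific genes.

Origination windows are half-open `(age of evidence node, age of next
deeper node]`: with the default tree, the second-oldest stratum D7 spans
(164.9, 213.6] Mya — the published window for that stratum — and D8 is
open-ended above the root age. The windows of D1..D7 tile `(0, root age]`
exactly.

The default tree places the eight species on a ladder with focal-path ages
213.6, 164.9, 131, 104, 96, 53 and 46 Mya. The two oldest ages reproduce the
published D7 window; the remaining five are round figures consistent with
angiosperm phylogeny (monocot orders branching before the grasses; the
PACMAD/BEP split preceding the within-BEP splits). Only the *order* of ages
affects stratum assignment; the absolute values only parameterise the
reported windows.

Single-copy subsets (D8s–D1s) keep genes whose ortholog group has exactly
one copy in every species where present. Stratified summaries aggregate AS
burden, type proportions, gene features, TE-gene fraction and mean maxTs per
stratum, with monotone-trend flags; trend statistics are computed as stratum
index (or age) versus the stratum-level summary, and the raw per-stratum
table is emitted so users can correlate differently. Mann-Whitney U,
chi-square and correlation statistics are delegated to R's `wilcox.test`,
`chisq.test` and `cor.test` (exact U enumeration for both samples ≤ 20,
normal approximation with tie/continuity correction otherwise).

# Gene families and Ks dating

Family candidates survive three strict homology cutoffs — E-value < 1e-10,
identity > 40%, query coverage > 95% — followed by a required-domain check
on externally produced domain-scan tables (running the scans themselves is
out of scope). Coverage is taken per best HSP, with a summed-HSP option,
since tabular homology output does not fix that convention.

Synonymous divergence is estimated with the Nei–Gojobori (1986) counting
method: per-codon synonymous site fractions averaged over both sequences
(mutations creating stop codons count as nonsynonymous), per-codon-pair
difference counts averaged over all mutation orderings that avoid stop
codons (with the standard fallback to unrestricted averaging when every
path is blocked), and the Jukes–Cantor correction
`K = -(3/4) log(1 - (4/3) p)`, flagged saturated at `p >= 3/4`. The
implementation is checked to 9 decimals against an independent reference
implementation on fixed codon pairs, and for symmetry and estimator
consistency by property. A full codon-model estimator (transition/
transversion and codon-frequency machinery) is deliberately not implemented;
the module accepts precomputed Ks columns for users who ran one. Divergence
times follow `T = Ks / (2 r)` with `r = 6.5e-9` substitutions/site/year by
default.

# The synthetic-data generator

The generator is the package's study-conditions definition, not a tuning
knob. Defaults emulate the published atlas conditions:

* 26 tissues; AS-gene fraction 0.4939.
* Event-type mix IR/A3SS/A5SS/ES/OTHER = 38.22/20.20/10.48/2.92/28.18 (%).
* Splice-site class mix GT-AG/GC-AG/GT-AT = 97.31/2.33/0.32 (%), with the
  unprinted remainder split 0.035% AT-AC and 0.005% other.
* Among-tissue fraction of planted events 0.6757.
* Exons uniform 50–500 bp, introns uniform 60–2000 bp — inside the
  pipeline's 20/4000 intron bounds, so nothing planted is ever filtered.

Where the emulated study states no value, one realistic choice was fixed
once: tissue-specific gene fraction 0.3 with ±20% uniform noise on
constitutive expression; stratum proportions weighted towards the oldest
and youngest strata (D8 = 0.40, D1 = 0.15); 50% single-copy ortholog
groups; off-path carrier probability 0.7; inter-gene spacers of 200–500 bp
on a single synthetic chromosome with no overlapping genes.

Genes are simulated independently: a reference isoform with 2–5 introns,
plus, for AS genes, one alternative isoform realising the drawn event type
(IR merges two exons; A3SS/A5SS shift one boundary by 10–150 bp in
transcription orientation; ES removes an internal exon; OTHER combines a
skip with a shifted donor so the composite bucket is genuinely exercised).
Boundary dinucleotides of every planted intron are written into the genome
per the class mix, strand-aware, so splice-site extraction recovers the
planted classes exactly. Within-tissue events place both witnesses in one
tissue; among-tissue events place the alternative isoform only in a tissue
lacking the reference.

Codon pairs with known synonymous divergence are produced by
Poisson-distributed substitution events at 4-fold degenerate third
positions (which can never create a stop codon), with the per-site
intensity calibrated against the sequence's NG86 synonymous site count so
that the NG86 + Jukes–Cantor estimate is centred on the target to first
order. Targets beyond the configurable saturation bound (default 3.0), or
beyond what a particular sequence's 4-fold sites can express, are rejected.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: assembly noise and fragmentary isoforms (recall on
real transcript assemblies would not be 100%), overlapping or nested gene
loci, more than one alternative isoform per gene, terminal-extent isoform
variation, expression-coupled isoform detectability, ortholog-table errors
from real clustering pipelines, gene loss (which the Dollo dating rule does
not model), nonsynonymous divergence, and any biological placement of TE
intervals (the pipeline's TE track is uniform random). The generator
validates the *implementation* of the methods, not the biology.

# Numerical choices and degenerate inputs

* Percentages printed to two decimals use half-up rounding
  (`as_fraction(25225, 51074)` is exactly 49.39), since half-even rounding
  would disagree with figures as usually printed.
* N50/N90 follow the cumulative-length rule (sorting descending, the first
  length at which the running total reaches 50%/90% of the sum), checked
  against a subtraction-style oracle; permutation invariance is asserted.
* Zero-variance trend inputs give NA correlations; a flat specificity trend
  reports R² = 0 (an undefined slope treated as "no trend").
* Empty catalogs, header-only TSVs, all-zero expression rows, empty strata
  and empty families are all defined, tested cases rather than errors.
* Every pipeline output carries a `#`-prefixed metadata header (tool
  version, seed, preset, sizes) and all randomness derives from the single
  configured seed, so reruns are byte-identical — asserted by test.

# Problem sizes used by the test suite

The suite exercises the implementation at sizes chosen to make the
properties sharp while keeping a full run in the low minutes on one CPU:
500-gene / 26-tissue annotations for planted-event recall, 1000 random
small loci for brute-force equivalence, 10,000 random introns for strand
antisymmetry, 200 simulated 300-codon pairs for NG86 recovery at Ks = 0.1
(mean within 10% of target), 1000 random length lists for the N50/N90
oracle, and two full pipeline runs for byte determinism.

# Known limitations

Transcript-to-gene assignment is taken from the input annotation
(`gene_id`/`Parent`); clustering gene_id-less transcripts by exon overlap is
not implemented, so inputs must be gene-resolved. PSI-style quantitative
splicing ratios, differential splicing, read-level evidence, GO enrichment
and phylogeny reconstruction are out of scope. The NG86 estimator ignores
transition/transversion bias and codon usage, which biases Ks slightly
downward at higher divergences relative to richer codon models — acceptable
here because dating uses modest Ks values, and documented rather than
hidden.
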