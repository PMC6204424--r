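# spliceatlas

Alternative-splicing (AS) atlas construction with evolutionary
stratification, in R.

Genome-wide AS surveys — such as the multi-tissue atlas built for moso
bamboo (*Phyllostachys edulis*) — all rest on the same computational core:
compare the transcript isoforms of each gene, extract and classify the
splicing variations between them, type the splice-site dinucleotides
against the genome, quantify how tissue-restricted each gene's expression
is, and relate AS burden to gene age and family evolution. `spliceatlas`
implements that core as a reusable, tested package for computational
biologists who want the method itself — runnable end to end on synthetic
data with planted ground truth, and applicable to any genome + transcript
models they supply.

## What it computes

* **AS events** (`pairwise_events`, `build_catalog`): within the genomic
  span shared by two isoforms, splice sites common to both intron chains
  partition the span into regions; every differing region is one event,
  classified IR / A3SS / A5SS / ES / OTHER (donor/acceptor in transcription
  orientation; strand-aware). Events deduplicate by (gene, type, coordinate
  signature); per-tissue support yields the tissue-specific/shared and
  within-/among-tissue partitions.
* **Splice sites** (`extract_splice_sites`, `splice_site_tally`): donor =
  first two intronic bases, acceptor = last two; classes GT-AG, GC-AG,
  AT-AC (canonical), GT-AT, other.
* **Tissue specificity** (`ts_profile`): Ts\_i = x\_i / Σ x, maxTs = max Ts;
  maxTs ∈ [1/n, 1], higher = more tissue-specific.
* **Phylostrata** (`assign_stratum`, `stratified_summary`): genes dated by
  the deepest dated-tree split with ortholog evidence (D8 = shared by all
  eight species … D1 = lineage-specific), single-copy subsets (D8s–D1s),
  per-stratum AS/feature/TE/maxTs summaries and trend statistics.
* **Gene families and dating** (`filter_hits`, `domain_filter`, `ng86_ks`,
  `ks_to_time`): homology screening at E < 1e-10, identity > 40%,
  coverage > 95% plus required-domain checks; Nei–Gojobori (1986)
  synonymous-rate estimation with Jukes–Cantor correction; divergence time
  T = Ks / (2r), r = 6.5e-9 substitutions/site/year.
* **Synthetic data** (`sim_config`, `simulate_annotation`,
  `simulate_expression`, `simulate_orthologs`, `simulate_codon_pairs`):
  deterministic generators with planted events, splice-site classes,
  specificity labels, origination nodes and true Ks, emulating the
  published study conditions (26 tissues, published type and splice-site
  mixes).

## Worked example

```r
library(spliceatlas)

cfg <- sim_config(seed = 1, n_genes = 500)   # 26 tissues, published mixes
sim <- simulate_annotation(cfg)
catalog <- build_catalog(sim$tissues)
catalog
#> event_catalog: 252 unique events in 252 AS genes (of 500 genes)
#>    IR  A3SS  A5SS    ES OTHER
#>   102    50    21     3    76

as_fraction(length(catalog$as_genes), catalog$n_genes)
#> [1] 50.4      # percent of genes with at least one AS event

truth <- sim$truth$events
mean(paste(truth$gene_id, truth$type) %in%
     paste(catalog$events$gene_id, catalog$events$type))
#> [1] 1         # every planted event recovered with its exact type

tally <- splice_site_tally(extract_splice_sites(sim$genome, sim$union)$class)
round(100 * tally$fractions, 2)
#> GT-AG GC-AG AT-AC GT-AT other
#> 96.93  2.91  0.00  0.16  0.00

r <- ng86_ks(strrep("GGT", 100), paste0("GGC", strrep("GGT", 99)))
c(S = r$S, Ks = round(r$Ks, 5))
#>       S      Ks
#> 100.0000 0.01007   # one synonymous change at a 4-fold site, JC-corrected
ks_to_time(0.13)
#> [1] 10            # Mya at r = 6.5e-9
```

The interpretation: of 500 simulated genes, the 252 carrying a planted
splicing variation are all rediscovered from the per-tissue transcript
models alone, with the correct type label; splice-site usage reflects the
planted class mix (GT-AG dominant); and the synonymous-rate machinery turns
codon alignments into divergence times on the published clock.

## The analysis workflow

`analysis/01_simulate.R` … `analysis/07_report.R` run the whole study
sequence as numbered, narrative drivers over the package functions:
simulate → detect events → splice sites → tissue specificity →
phylostrata/TE → family filter + Ks dating → report. Each stage writes its
tables under `results/` and prints the numbers it found:

```sh
for s in analysis/0*.R; do Rscript "$s"; done
```

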