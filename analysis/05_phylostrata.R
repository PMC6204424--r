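#!/usr/bin/env Rscript
# Stage 5: evolutionary stratification.
#
# Genes are dated by the deepest species-tree split with ortholog evidence
# (D8 = shared by all eight species ... D1 = focal-lineage-specific), the
# single-copy subsets are extracted, and AS burden, gene features, TE
# insertion and maxTs are summarised per stratum, with trend statistics
# along the age gradient.

suppressPackageStartupMessages(library(spliceatlas))

data_dir <- "results/data"
tree <- read_dated_tree(file.path(data_dir, "species_tree.nwk"))
orth <- spliceatlas:::read_tsv_with_header(file.path(data_dir,
                                                     "orthologs.tsv"))
assignment <- assign_stratum(orth, tree, "Phyllostachys_edulis")
spliceatlas:::write_tsv_with_header(assignment, "results/strata.tsv")

truth <- spliceatlas:::read_tsv_with_header(file.path(data_dir,
                                                      "ortholog_truth.tsv"))
recovery <- 100 * mean(assignment$stratum ==
                         truth$stratum[match(assignment$gene_id,
                                             truth$gene_id)])
sc <- single_copy_subset(assignment)

ann <- read_transcripts(file.path(data_dir, "transcripts_union.gtf"))
feats <- gene_features(ann)
ev <- read_events_tsv("results/events.tsv")
catalog <- structure(list(events = ev,
                          as_genes = sort(unique(ev$gene_id)),
                          n_genes = nrow(feats)),
                     class = "event_catalog")
tsp <- spliceatlas:::read_tsv_with_header("results/ts_profiles.tsv")

# seed-derived TE intervals over the simulated chromosome
set.seed(5L)
glen <- max(feats$end) + 100L
te <- data.frame(chrom = "chr1",
                 start = sort(sample.int(glen - 3000L, nrow(feats))))
te$end <- pmin(te$start + sample(100:3000, nrow(te), replace = TRUE), glen)
teov <- te_gene_overlap(feats, te)

summ <- stratified_summary(assignment, catalog, features = feats,
                           tsp = tsp, te_flags = teov$gene_flags)
spliceatlas:::write_tsv_with_header(summ$table, "results/strata_summary.tsv")

tab <- summ$table
tr_as <- trend_stats(tab$stratum_index, tab$as_percent)
tr_ts <- trend_stats(tab$stratum_index, tab$mean_maxTs)

jsonlite::write_json(
  list(stratum_recovery_percent = recovery,
       n_single_copy = nrow(sc),
       monotone = summ$monotone,
       as_percent_vs_stratum = tr_as,
       mean_maxTs_vs_stratum = tr_ts,
       te_genes = sum(teov$gene_flags$te),
       te_total_length = teov$total_te_length),
  "results/strata_trends.json", auto_unbox = TRUE, pretty = TRUE,
  digits = 6)

cat(sprintf("stratum recovery: %.1f%%; %d single-copy genes (D8s-D1s)\n",
            recovery, nrow(sc)))
print(tab[, c("stratum", "n_genes", "n_as_genes", "as_percent",
              "prop_IR", "mean_maxTs", "te_fraction")])
cat(sprintf("AS%% vs stratum index: r=%.3f (R2=%.3f, p=%.3g)\n",
            tr_as$pearson_r, tr_as$r_squared, tr_as$pearson_p))
cat(sprintf("mean maxTs vs stratum index: r=%.3f (R2=%.3f)\n",
            tr_ts$pearson_r, tr_ts$r_squared))
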