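#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study dataset.
#
# One synthetic chromosome, 500 genes, 26 tissues; roughly half the genes
# carry one planted AS event drawn from the published type mix, splice-site
# dinucleotides follow the published class mix, and tissue membership of the
# alternative isoforms realises the among-/within-tissue split. Everything
# downstream (02-07) reads only the files written here.

suppressPackageStartupMessages(library(spliceatlas))

seed <- 1L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = seed, n_genes = 500L)
sim <- simulate_annotation(cfg)

write_fasta(sim$genome, file.path(out, "genome.fa"))
write_transcripts(sim$union, file.path(out, "transcripts_union.gtf"))
dir.create(file.path(out, "tissues"), showWarnings = FALSE)
for (tn in names(sim$tissues)) {
  write_transcripts(sim$tissues[[tn]], file.path(out, "tissues",
                                                 paste0(tn, ".gtf")))
}
jsonlite::write_json(sim$truth[c("events", "genes", "introns")],
                     file.path(out, "ground_truth.json"),
                     dataframe = "rows", auto_unbox = TRUE, digits = NA)

expr <- simulate_expression(cfg, sim$truth$genes$gene_id)
spliceatlas:::write_tsv_with_header(
  data.frame(gene_id = rownames(expr$expression), expr$expression,
             check.names = FALSE),
  file.path(out, "expression.tsv"), meta = c(seed = seed))

tree <- default_dated_tree()
ape::write.tree(tree, file.path(out, "species_tree.nwk"))
orth <- simulate_orthologs(cfg, tree)
spliceatlas:::write_tsv_with_header(orth$table,
                                    file.path(out, "orthologs.tsv"),
                                    meta = c(seed = seed))
spliceatlas:::write_tsv_with_header(orth$truth,
                                    file.path(out, "ortholog_truth.tsv"),
                                    meta = c(seed = seed))

pairs <- simulate_codon_pairs(sim_config(seed = seed, ks_grid = c(0.05, 0.1,
                                                                  0.13, 0.2),
                                         pairs_per_target = 50L))
spliceatlas:::write_tsv_with_header(pairs, file.path(out, "codon_pairs.tsv"),
                                    meta = c(seed = seed))

cat(sprintf("simulated %d genes (%d with a planted AS event) across %d tissues\n",
            cfg$n_genes, nrow(sim$truth$events), cfg$n_tissues))
cat(sprintf("genome: %d bp; planted introns: %d; ortholog genes: %d; codon pairs: %d\n",
            nchar(sim$genome[["chr1"]]), nrow(sim$truth$introns),
            nrow(orth$table), nrow(pairs)))
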