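# End-to-end orchestration over the synthetic study conditions, plus the
# assembly-style length statistics. Every output file carries a '#'-prefixed
# metadata header (tool version, seed, preset) so a rerun with the same
# configuration reproduces identical bytes.

#' Assembly-style length statistics (N50/N90)
#'
#' N50 is the length L such that, summing lengths in descending order, the
#' cumulative total first reaches >= 50% of the overall total at a piece of
#' length L; N90 is the 90% analogue.
#'
#' @param lengths Vector of positive lengths.
#' @return List with `count`, `total`, `mean`, `n50`, `n90`, `max`, `min`.
#' @export
length_stats <- function(lengths) {
  if (!length(lengths)) stop("empty length list")
  if (any(lengths <= 0)) stop("lengths must be positive")
  s <- sort(lengths, decreasing = TRUE)
  cum <- cumsum(s)
  total <- cum[length(cum)]
  n50 <- s[which(cum >= 0.5 * total)[1L]]
  n90 <- s[which(cum >= 0.9 * total)[1L]]
  list(count = length(s), total = total, mean = mean(s),
       n50 = n50, n90 = n90, max = s[1L], min = s[length(s)])
}

#' Fold change between two values
#'
#' @param new_value,old_value Values with `old_value > 0`.
#' @param mode `"ratio_round"` (rounded ratio, e.g. an ~89-fold N50 increase)
#'   or `"percent_increase"` (`100 * (new - old) / old`).
#' @return A number.
#' @export
fold_change <- function(new_value, old_value,
                        mode = c("ratio_round", "percent_increase")) {
  mode <- match.arg(mode)
  if (old_value <= 0) stop("old_value must be positive")
  switch(mode,
         ratio_round = round(new_value / old_value),
         percent_increase = 100 * (new_value - old_value) / old_value)
}

.pipeline_meta <- function(config, preset) {
  c(tool = paste0("spliceatlas ",
                  as.character(utils::packageVersion("spliceatlas"))),
    seed = as.character(config$seed),
    preset = preset,
    n_genes = as.character(config$n_genes),
    n_tissues = as.character(config$n_tissues))
}

# Seed-derived TE intervals on the simulated chromosome (the annotation
# generator itself stays TE-agnostic).
.simulate_te <- function(config, genome_length) {
  set.seed(config$seed + 4L)
  n <- config$n_genes
  start <- sort(sample.int(max(genome_length - 3000L, 1L), n))
  len <- sample(100:3000, n, replace = TRUE)
  data.frame(chrom = "chr1", start = start,
             end = pmin(start + len, genome_length),
             name = sprintf("TE%05d", seq_len(n)), strand = "+",
             stringsAsFactors = FALSE)
}

#' Run the full synthetic-atlas pipeline
#'
#' Stages: simulate genome/annotations -> detect and classify AS events ->
#' type splice sites -> tissue specificity -> phylostrata and stratified
#' summary -> TE overlap -> codon-pair Ks estimation and dating -> report.
#' All randomness derives from `seed`; rerunning with identical arguments
#' reproduces byte-identical files.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param preset `"small"` (quick desk-scale run) or `"paperlike"`
#'   (500 genes, 26 tissues).
#' @param config Optional `sim_config` overriding the preset.
#' @return Invisibly, the report list (also written as `report.json`).
#' @export
run_pipeline <- function(out_dir, seed = 1L,
                         preset = c("small", "paperlike"), config = NULL) {
  preset <- match.arg(preset)
  if (is.null(config)) {
    config <- switch(preset,
      small = sim_config(seed = seed, n_genes = 60L, n_tissues = 6L,
                         pairs_per_target = 5L, n_codons = 150L,
                         ks_grid = c(0.1, 0.5)),
      paperlike = sim_config(seed = seed, n_genes = 500L))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- .pipeline_meta(config, preset)

  # --- simulate ----------------------------------------------------------
  sim <- simulate_annotation(config)
  write_fasta(sim$genome, file.path(out_dir, "genome.fa"))
  write_transcripts(sim$union, file.path(out_dir, "transcripts_union.gtf"))
  tdir <- file.path(out_dir, "tissues")
  dir.create(tdir, showWarnings = FALSE)
  for (tn in names(sim$tissues)) {
    write_transcripts(sim$tissues[[tn]], file.path(tdir, paste0(tn, ".gtf")))
  }
  truth <- sim$truth
  jsonlite::write_json(
    list(events = truth$events, genes = truth$genes,
         introns = truth$introns),
    file.path(out_dir, "ground_truth.json"),
    dataframe = "rows", auto_unbox = TRUE, pretty = TRUE, digits = NA)

  # --- AS events ---------------------------------------------------------
  catalog <- build_catalog(sim$tissues)
  write_events_tsv(catalog, file.path(out_dir, "events.tsv"), meta = meta)
  part <- partition_by_tissue(catalog)

  planted <- truth$events
  main <- planted[planted$type != "OTHER", , drop = FALSE]
  detected_keys <- paste(catalog$events$gene_id, catalog$events$type)
  recall <- if (nrow(main)) {
    mean(paste(main$gene_id, main$type) %in% detected_keys)
  } else NA_real_

  # --- splice sites ------------------------------------------------------
  sites <- extract_splice_sites(sim$genome, sim$union)
  write_tsv_with_header(sites, file.path(out_dir, "splice_sites.tsv"),
                        meta = meta)
  tally <- splice_site_tally(sites$class)

  # --- tissue specificity ------------------------------------------------
  gene_ids <- truth$genes$gene_id
  exprsim <- simulate_expression(config, gene_ids)
  expr_df <- data.frame(gene_id = rownames(exprsim$expression),
                        exprsim$expression, check.names = FALSE)
  write_tsv_with_header(expr_df, file.path(out_dir, "expression.tsv"),
                        meta = meta)
  tsp <- ts_profile(exprsim$expression)

  # --- phylostrata -------------------------------------------------------
  tree <- default_dated_tree()
  ape::write.tree(tree, file.path(out_dir, "species_tree.nwk"))
  orth <- simulate_orthologs(config, tree)
  write_tsv_with_header(orth$table, file.path(out_dir, "orthologs.tsv"),
                        meta = meta)
  assignment <- assign_stratum(orth$table, tree, "Phyllostachys_edulis")
  stratum_recovery <- mean(assignment$stratum == orth$truth$stratum)

  te <- .simulate_te(config, nchar(sim$genome[["chr1"]]))
  write_tsv_with_header(te, file.path(out_dir, "te.bed.tsv"), meta = meta)
  feats <- gene_features(sim$union)
  tx <- transcript_models(sim$union)
  intr_rows <- lapply(tx, function(t) {
    ic <- intron_chain(t)
    if (!nrow(ic)) return(NULL)
    data.frame(gene_id = t$gene_id, chrom = t$chrom,
               start = ic[, 1L], end = ic[, 2L], stringsAsFactors = FALSE)
  })
  gene_introns <- unique(do.call(rbind, intr_rows))
  teov <- te_gene_overlap(truth$genes, te, introns = gene_introns)
  summ <- stratified_summary(assignment, catalog, features = feats,
                             tsp = tsp, te_flags = teov$gene_flags)
  write_tsv_with_header(summ$table, file.path(out_dir, "strata_summary.tsv"),
                        meta = meta)

  # --- Ks dating ---------------------------------------------------------
  pairs <- simulate_codon_pairs(config)
  ks <- vapply(seq_len(nrow(pairs)), function(i) {
    ng86_ks(pairs$seq_a[i], pairs$seq_b[i])$Ks
  }, numeric(1))
  ks_df <- data.frame(pair_id = pairs$pair_id, target_ks = pairs$target_ks,
                      ks = ks, t_mya = ks_to_time(pmax(ks, 0)),
                      stringsAsFactors = FALSE)
  write_tsv_with_header(ks_df, file.path(out_dir, "ks_estimates.tsv"),
                        meta = meta)

  # --- report ------------------------------------------------------------
  report <- list(
    meta = as.list(meta),
    events = list(n_unique = nrow(catalog$events),
                  n_as_genes = length(catalog$as_genes),
                  n_genes = catalog$n_genes,
                  as_gene_percent = as_fraction(length(catalog$as_genes),
                                                catalog$n_genes),
                  counts_by_type = as.list(catalog$counts)),
    planted_vs_recovered = list(
      planted_main_type_events = nrow(main),
      recall_percent = 100 * recall),
    tissue_partition = list(
      tissue_specific = part$tissue_specific,
      among_tissue = part$among_tissue,
      within_tissue = part$within_tissue,
      among_fraction = part$among_fraction),
    splice_sites = list(counts = as.list(tally$counts),
                        canonical_fraction = tally$canonical_fraction,
                        noncanonical = tally$noncanonical),
    strata = list(recovery_fraction = stratum_recovery,
                  as_percent_by_stratum = stats::setNames(
                    summ$table$as_percent, summ$table$stratum),
                  monotone = summ$monotone),
    te = list(genes_flagged = sum(teov$gene_flags$te),
              total_te_length = teov$total_te_length),
    ks = list(mean_by_target = lapply(split(ks_df$ks, ks_df$target_ks),
                                      mean, na.rm = TRUE)))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 10)
  invisible(report)
}

#' Rebuild the summary report from a pipeline output directory
#'
#' Re-derives the headline numbers from the intermediate TSVs without
#' recomputation (cheap iteration on presentation).
#'
#' @param out_dir Directory previously written by [run_pipeline()].
#' @return The report list.
#' @export
report_from_dir <- function(out_dir) {
  ev <- read_events_tsv(file.path(out_dir, "events.tsv"))
  sites <- read_tsv_with_header(file.path(out_dir, "splice_sites.tsv"))
  ks <- read_tsv_with_header(file.path(out_dir, "ks_estimates.tsv"))
  list(events = list(n_unique = nrow(ev),
                     counts_by_type = as.list(table(ev$type))),
       splice_sites = splice_site_tally(sites$class)[c("counts", "total",
                                                       "noncanonical")],
       ks = lapply(split(as.numeric(ks$ks), ks$target_ks), mean,
                   na.rm = TRUE))
}
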