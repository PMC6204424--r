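species8 <- c("Amborella_trichopoda", "Arabidopsis_thaliana",
              "Spirodela_polyrhiza", "Elaeis_guineensis", "Sorghum_bicolor",
              "Brachypodium_distachyon", "Oryza_sativa",
              "Phyllostachys_edulis")

ortho_row <- function(gene, present, copies = 1L) {
  counts <- stats::setNames(rep(0L, length(species8)), species8)
  counts[present] <- copies
  cbind(data.frame(gene_id = gene, stringsAsFactors = FALSE),
        as.data.frame(as.list(counts), check.names = FALSE))
}

test_that("presence in all species maps to the oldest stratum, focal-only to D1", {
  tree <- default_dated_tree()
  tab <- rbind(ortho_row("g_all", species8),
               ortho_row("g_focal", "Phyllostachys_edulis"),
               ortho_row("g_d7", setdiff(species8, "Amborella_trichopoda")))
  a <- assign_stratum(tab, tree, "Phyllostachys_edulis")
  expect_equal(a$stratum, c("D8", "D1", "D7"))
  # published-style D7 window: between the two oldest splits
  expect_equal(a$age_lower[3], 164.9)
  expect_equal(a$age_upper[3], 213.6)
  expect_equal(a$age_upper[1], Inf)
  expect_equal(a$age_lower[2], 0)

  expect_error(assign_stratum(tab[, -2], tree, "Phyllostachys_edulis"),
               "match")
  bad <- tab; bad$Phyllostachys_edulis[1] <- 0L
  expect_error(assign_stratum(bad, tree, "Phyllostachys_edulis"),
               "absent from focal")
})

test_that("stratum windows tile the root-to-tip age range without overlap", {
  tree <- default_dated_tree()
  tab <- do.call(rbind, c(
    list(ortho_row("gAll", species8),
         ortho_row("gFoc", "Phyllostachys_edulis")),
    lapply(2:7, function(k) {
      # evidence exactly at path node k (root-first)
      keep <- switch(k - 1L,
                     "Arabidopsis_thaliana", "Spirodela_polyrhiza",
                     "Elaeis_guineensis", "Sorghum_bicolor",
                     "Brachypodium_distachyon", "Oryza_sativa")
      ortho_row(paste0("gk", k), c("Phyllostachys_edulis", keep))
    })))
  a <- assign_stratum(tab, tree, "Phyllostachys_edulis")
  a <- a[order(-a$stratum_index), ]
  expect_equal(a$stratum, paste0("D", 8:1))
  # consecutive windows abut exactly: lower bound of one = upper of the next
  expect_equal(a$age_lower[-nrow(a)], a$age_upper[-1])
  expect_equal(a$age_lower[nrow(a)], 0)
})

test_that("planted origination nodes are recovered exactly, at scale", {
  cfg <- sim_config(seed = 99, n_genes = 300)
  o <- simulate_orthologs(cfg)
  a <- assign_stratum(o$table, default_dated_tree(), "Phyllostachys_edulis")
  expect_equal(mean(a$stratum == o$truth$stratum), 1.0)
  expect_equal(a$single_copy, o$truth$single_copy)
})

test_that("single-copy subset keeps exactly the all-single groups", {
  tree <- default_dated_tree()
  tab <- rbind(ortho_row("g1", species8, 1L),
               ortho_row("g2", species8, 2L),
               ortho_row("g3", c("Phyllostachys_edulis", "Oryza_sativa"), 1L))
  a <- assign_stratum(tab, tree, "Phyllostachys_edulis")
  s <- single_copy_subset(a)
  expect_setequal(s$gene_id, c("g1", "g3"))
  expect_true(all(grepl("s$", s$stratum)))

  all_single <- assign_stratum(rbind(ortho_row("x", species8, 1L)),
                               tree, "Phyllostachys_edulis")
  expect_equal(nrow(single_copy_subset(all_single)), 1L)
})

test_that("stratified summary aggregates genes, events and proportions", {
  cfg <- sim_config(seed = 55, n_genes = 150, n_tissues = 4)
  sim <- simulate_annotation(cfg)
  ctl <- build_catalog(sim$tissues)
  o <- simulate_orthologs(cfg)
  a <- assign_stratum(o$table, default_dated_tree(), "Phyllostachys_edulis")
  s <- stratified_summary(a, ctl)
  tab <- s$table
  expect_equal(sum(tab$n_genes), cfg$n_genes)
  expect_equal(sum(tab$n_events), nrow(ctl$events))
  props <- tab[tab$n_events > 0, grepl("^prop_", names(tab))]
  expect_true(all(abs(rowSums(props) - 1) < 1e-9))
  expect_true(all(tab$as_percent >= 0 & tab$as_percent <= 100, na.rm = TRUE))

  # one-stratum degenerate case collapses to global stats
  one <- a; one$stratum <- "D8"; one$stratum_index <- 8L
  s1 <- stratified_summary(one, ctl)
  expect_equal(nrow(s1$table), 1L)
  expect_equal(s1$table$n_as_genes, length(ctl$as_genes))
})

test_that("proportion folds reproduce the printed IR contrast", {
  expect_equal(proportion_fold(57.76, 16.95), 3.4)
  expect_equal(proportion_fold(1, 1), 1)
  expect_error(proportion_fold(1, 0))
})

test_that("TE overlap equals a quadratic interval-intersection oracle", {
  set.seed(66)
  genes <- data.frame(gene_id = paste0("g", 1:20), chrom = "chr1",
                      strand = sample(c("+", "-"), 20, TRUE),
                      start = seq(0, 19000, by = 1000))
  genes$end <- genes$start + sample(300:900, 20, TRUE)
  te <- data.frame(chrom = "chr1", start = sample(0:19500, 15))
  te$end <- te$start + sample(50:800, 15, TRUE)

  got <- te_gene_overlap(genes, te)
  # brute force: merge TEs, intersect each gene with each merged block
  ir <- IRanges::reduce(IRanges::IRanges(te$start + 1L, te$end))
  blocks <- cbind(IRanges::start(ir) - 1L, IRanges::end(ir))
  brute <- vapply(seq_len(nrow(genes)), function(i) {
    tot <- 0
    for (b in seq_len(nrow(blocks))) {
      tot <- tot + max(0, min(genes$end[i], blocks[b, 2]) -
                          max(genes$start[i], blocks[b, 1]))
    }
    tot
  }, numeric(1))
  expect_equal(got$gene_flags$te_length, brute)
  expect_equal(got$gene_flags$te, brute > 0)

  none <- te_gene_overlap(genes, data.frame(chrom = "chr2", start = 1,
                                            end = 100))
  expect_equal(sum(none$gene_flags$te), 0L)

  # a TE inside intron 1 flags the gene and lands in an early bin (+ strand)
  g1 <- data.frame(gene_id = "g", chrom = "chr1", strand = "+",
                   start = 0, end = 1000)
  introns <- data.frame(gene_id = "g", chrom = "chr1",
                        start = c(100, 400, 700), end = c(150, 450, 750))
  tiny <- te_gene_overlap(g1, data.frame(chrom = "chr1", start = 110,
                                         end = 140), introns = introns)
  expect_true(tiny$gene_flags$te)
  expect_equal(sum(tiny$intron_hist), 30)
  expect_equal(unname(tiny$intron_hist[["bin02"]]), 30)
})

test_that("trend and rank statistics behave on canonical cases", {
  x <- 1:8
  tr <- trend_stats(x, 2 * x)
  expect_equal(tr$r_squared, 1.0)
  expect_true(is.na(trend_stats(x, rep(1, 8))$r_squared))

  u <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(u$U, 0)
  # exact two-sided p for complete separation at n = m = 3: 2/20
  expect_equal(u$p_value, 0.1)
  # large-sample path agrees with the exact path on moderate samples
  set.seed(9)
  a <- stats::rnorm(18); b <- stats::rnorm(18, 0.5)
  pe <- mann_whitney_u(a, b, exact = TRUE)$p_value
  pa <- mann_whitney_u(a, b, exact = FALSE)$p_value
  expect_lt(abs(pe - pa), 0.05)

  gof <- chi_square_gof(c(10, 20, 30), c(10, 20, 30))
  expect_equal(gof$statistic, 0)
  expect_equal(gof$p_value, 1)

  hom <- chi_square_homogeneity(rbind(c(50, 30, 20), c(48, 33, 19)))
  expect_gt(hom$p_value, 0.5)
})
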