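test_that("intron_chain derives gaps between consecutive exons", {
  expect_equal(unname(intron_chain(make_tx("t", list(c(0, 100), c(200, 300))))),
               cbind(100, 200))
  expect_equal(nrow(intron_chain(make_tx("t", list(c(0, 100))))), 0L)
  expect_equal(unname(intron_chain(
    make_tx("t", list(c(0, 50), c(60, 70), c(90, 120))))),
    cbind(c(50, 70), c(60, 90)))
})

test_that("the four main patterns classify by definition, strand-aware", {
  ir <- pairwise_events(make_tx("a", list(c(0, 100), c(200, 300))),
                        make_tx("b", list(c(0, 300))))
  expect_equal(ir$type, "IR")

  # shared donor at 100 on plus strand: alternative acceptor
  a3 <- pairwise_events(make_tx("a", list(c(0, 100), c(200, 300))),
                        make_tx("b", list(c(0, 100), c(240, 300))))
  expect_equal(a3$type, "A3SS")
  # the same coordinates on the minus strand share the acceptor instead
  a5 <- pairwise_events(
    make_tx("a", list(c(0, 100), c(200, 300)), strand = "-"),
    make_tx("b", list(c(0, 100), c(240, 300)), strand = "-"))
  expect_equal(a5$type, "A5SS")

  es <- pairwise_events(
    make_tx("a", list(c(0, 100), c(150, 180), c(250, 350))),
    make_tx("b", list(c(0, 100), c(250, 350))))
  expect_equal(es$type, "ES")
  expect_equal(es$region_start, 100)
  expect_equal(es$region_end, 250)

  # double-cassette skipping is still ES, not OTHER
  es2 <- pairwise_events(
    make_tx("a", list(c(0, 100), c(150, 180), c(220, 240), c(300, 400))),
    make_tx("b", list(c(0, 100), c(300, 400))))
  expect_equal(es2$type, "ES")
})

test_that("one-boundary-shared events on unknown strand fall back to OTHER", {
  ev <- pairwise_events(
    make_tx("a", list(c(0, 100), c(200, 300)), strand = "."),
    make_tx("b", list(c(0, 100), c(240, 300)), strand = "."))
  expect_equal(ev$type, "OTHER")
  # IR needs no orientation and keeps its label
  ir <- pairwise_events(make_tx("a", list(c(0, 100), c(200, 300)),
                                strand = "."),
                        make_tx("b", list(c(0, 300)), strand = "."))
  expect_equal(ir$type, "IR")
})

test_that("a combined shift+skip pattern with a shared interior site splits at it", {
  # chains [(100,200)] vs [(90,200),(220,260)]: 200 is a common splice site,
  # so two events emerge: an alternative-donor pair and a retained intron
  ev <- pairwise_events(make_tx("a", list(c(0, 100), c(200, 400))),
                        make_tx("b", list(c(0, 90), c(200, 220), c(260, 400))))
  expect_setequal(ev$type, c("A5SS", "IR"))
  orc <- oracle_pairwise(make_tx("a", list(c(0, 100), c(200, 400))),
                         make_tx("b", list(c(0, 90), c(200, 220), c(260, 400))))
  expect_setequal(ev$signature, orc$signature)
})

test_that("a genuinely composite region classifies OTHER", {
  # skip plus shifted donor in one region (no shared interior site)
  ev <- pairwise_events(
    make_tx("a", list(c(0, 100), c(150, 180), c(250, 350))),
    make_tx("b", list(c(0, 90), c(250, 350))))
  expect_equal(ev$type, "OTHER")
})

test_that("identical chains with different terminal extents yield no events", {
  ev <- pairwise_events(make_tx("a", list(c(0, 100), c(200, 300))),
                        make_tx("b", list(c(20, 100), c(200, 280))))
  expect_equal(nrow(ev), 0L)
})

test_that("pairwise_events is symmetric and rejects mismatched inputs", {
  a <- make_tx("a", list(c(0, 100), c(150, 180), c(250, 350)))
  b <- make_tx("b", list(c(0, 100), c(250, 350)))
  e1 <- pairwise_events(a, b); e2 <- pairwise_events(b, a)
  expect_equal(sort(e1$signature), sort(e2$signature))
  expect_equal(e1$type[order(e1$signature)], e2$type[order(e2$signature)])
  expect_error(pairwise_events(a, make_tx("c", list(c(0, 300)), gene = "g2")),
               "different genes")
  expect_error(pairwise_events(a, make_tx("c", list(c(0, 300)), strand = "-")),
               "strands")
})

test_that("pairwise_events equals the brute-force enumerator on random loci", {
  set.seed(202)
  for (rep in 1:200) {
    locus <- random_locus()
    for (i in seq_len(length(locus) - 1L)) {
      for (j in seq(i + 1L, length(locus))) {
        got <- pairwise_events(locus[[i]], locus[[j]])
        want <- oracle_pairwise(locus[[i]], locus[[j]])
        expect_equal(sort(got$signature), sort(want$signature))
        expect_equal(got$type[order(got$signature)],
                     want$type[order(want$signature)],
                     info = paste("rep", rep))
      }
    }
  }
})

test_that("gene_events deduplicates identical signatures across pairs", {
  ref <- make_tx("r", list(c(0, 100), c(200, 300), c(400, 500)))
  alt1 <- make_tx("x", list(c(0, 300), c(400, 500)))   # IR of intron 1
  alt2 <- make_tx("y", list(c(0, 300), c(400, 500)))   # same structure again
  alt2$transcript_id <- "y"
  ev <- gene_events(list(ref, alt1, alt2))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$type, "IR")
  expect_equal(nrow(gene_events(list(ref))), 0L)
})

test_that("catalog counts conserve and overlap report behaves on subsets", {
  cfg <- sim_config(seed = 21, n_genes = 80, n_tissues = 4)
  sim <- simulate_annotation(cfg)
  ctl <- build_catalog(sim$tissues)
  expect_equal(sum(ctl$counts), nrow(ctl$events))
  expect_false(anyDuplicated(ctl$events$signature) > 0)
  expect_setequal(ctl$as_genes, unique(ctl$events$gene_id))

  expect_equal(catalog_overlap(ctl, ctl)$event_overlap, 1.0)
  expect_equal(catalog_overlap(ctl, ctl)$gene_overlap, 1.0)
  # subset catalog: pick half the tissues
  sub <- build_catalog(sim$tissues[1:2])
  ov <- catalog_overlap(sub, ctl)
  expect_equal(ov$event_overlap, 1.0)  # subset platform fully contained
  expect_equal(ov$gene_overlap, 1.0)
  # disjoint catalogs
  empty_ctl <- build_catalog(sim$tissues[1][0])
  expect_true(is.na(catalog_overlap(empty_ctl, ctl)$event_overlap))
})

test_that("tissue partition recovers the planted among/within mix", {
  cfg <- sim_config(seed = 31, n_genes = 400, n_tissues = 8)
  sim <- simulate_annotation(cfg)
  ctl <- build_catalog(sim$tissues)
  part <- partition_by_tissue(ctl)
  truth <- sim$truth$events
  expect_equal(part$n_events, nrow(truth))
  # per-event among labels must match the plant exactly
  lab <- part$labels
  m <- match(lab$gene_id, truth$gene_id)
  expect_equal(lab$derivation == "among_tissue", truth$among[m])
  # and the realised fraction sits within 3 binomial SE of the mix parameter
  p <- cfg$among_fraction
  se <- sqrt(p * (1 - p) / nrow(truth))
  expect_lt(abs(part$among_fraction - p), 3 * se + 1e-12)
  # within-tissue events supported by their single co-occurrence tissue
  expect_true(all(lab$n_support[lab$derivation == "within_tissue"] == 1L))
})

test_that("worked arithmetic: isoform ceiling, AS percentage, novel split", {
  expect_equal(max_isoform_count(c(12, 48, 33, 2)), 38016)
  expect_equal(max_isoform_count(c(1)), 1)
  expect_equal(max_isoform_count(c(2, 3)), 6)
  expect_error(max_isoform_count(numeric(0)), "empty")

  expect_equal(as_fraction(25225, 51074), 49.39)
  expect_equal(as_fraction(0, 10), 0)
  expect_equal(as_fraction(26366, 51074), 51.62)
  expect_error(as_fraction(5, 0))

  expect_equal(novel_gene_partition(25225, 12653)[["n_novel"]], 12572)
  expect_equal(novel_gene_partition(c("a", "b"), c("a", "b"))[["n_novel"]], 0)
  expect_equal(novel_gene_partition(c("a", "b"), c("x"))[["n_novel"]], 2)
})
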