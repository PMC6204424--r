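test_that("hit filtering applies the three strict cutoffs", {
  hits <- data.frame(
    query = "q", subject = paste0("s", 1:6),
    evalue = c(1e-12, 1e-12, 1e-12, 1e-9, 1e-20, 0),
    identity = c(55, 40.0, 85, 70, 41, 99),
    coverage = c(98, 98, 95.0, 99, 96, 100))
  f <- filter_hits(hits)
  # row 1 passes; row 2 fails identity (not > 40); row 3 fails coverage
  # (not > 95); row 4 fails E-value; rows 5-6 pass
  expect_setequal(f$subjects, c("s1", "s5", "s6"))

  # monotonicity: relaxing any threshold never shrinks the surviving set
  set.seed(12)
  rnd <- data.frame(query = "q", subject = paste0("r", 1:200),
                    evalue = 10^stats::runif(200, -30, 0),
                    identity = stats::runif(200, 0, 100),
                    coverage = stats::runif(200, 0, 100))
  base <- filter_hits(rnd)$subjects
  expect_true(all(base %in% filter_hits(rnd, e_max = 1e-5)$subjects))
  expect_true(all(base %in% filter_hits(rnd, id_min = 20)$subjects))
  expect_true(all(base %in% filter_hits(rnd, cov_min = 80)$subjects))
})

test_that("outfmt-6 tables parse and coverage derives from qlen when present", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(c("q1", "s1", "97.5", "480", "12", "0", "1", "480", "3",
                     "482", "1e-50", "900", "500"), collapse = "\t"), f)
  h <- read_hits(f)
  expect_equal(h$coverage, 96)
  expect_equal(h$identity, 97.5)
  expect_equal(h$evalue, 1e-50)
  # summed-HSP mode pools coverage of repeated query-subject pairs
  two <- rbind(h, h)
  expect_equal(nrow(filter_hits(two, coverage = "best_hsp")$hits), 2L)
  expect_equal(filter_hits(two, coverage = "summed")$subjects, "s1")
})

test_that("domain filter keeps candidates covering the required set", {
  obs <- data.frame(candidate = c("a", "a", "b", "c"),
                    domain = c("PF1", "PF2", "PF1", "PF2"))
  expect_equal(domain_filter(c("a", "b", "c"), c("PF1", "PF2"), obs), "a")
  expect_equal(domain_filter(c("a", "b"), "PF1", obs), c("a", "b"))
  expect_equal(domain_filter(character(0), "PF1", obs), character(0))
  expect_error(domain_filter("a", character(0), obs), "empty")
})

test_that("NG86 agrees with an independent reference implementation", {
  # expected values computed once with Biopython's cal_dn_ds (NG86) and frozen
  r1 <- ng86_ks("ATGGGTGCTTTAACCGGT", "ATGGGCGCTTTGACCGGA")
  expect_equal(r1$Ks, 1.4594326118, tolerance = 1e-9)
  expect_equal(r1$Ka, 0, tolerance = 1e-12)
  r2 <- ng86_ks("AAATTTCCC", "AGATTCCCC")
  expect_equal(r2$Ka, 0.1543890407, tolerance = 1e-9)
  expect_equal(r2$Ks, 0.9744622381, tolerance = 1e-9)
})

test_that("NG86 site/difference counting matches hand computation", {
  id <- strrep("GGT", 100)
  r0 <- ng86_ks(id, id)
  expect_equal(r0$Ks, 0); expect_equal(r0$Ka, 0)

  # one change at a 4-fold degenerate third position across 100 GGT codons:
  # every third position is fully synonymous (S = 100), one synonymous
  # difference, Jukes-Cantor correction of pS = 0.01
  b <- paste0("GGC", strrep("GGT", 99))
  r <- ng86_ks(id, b)
  expect_equal(r$S, 100)
  expect_equal(r$N, 200)
  expect_equal(r$Sd, 1)
  expect_equal(r$Ks, -3 / 4 * log(1 - 4 / 3 * 0.01), tolerance = 1e-12)
  expect_equal(r$Ka, 0)

  expect_error(ng86_ks("ATG", "ATGAAA"), "mismatch")
  expect_error(ng86_ks("ATGA", "ATGA"), "multiple of 3")
  expect_error(ng86_ks("TAAGGG", "TAAGGG"), "stop")
  # gapped codons are masked pairwise
  g <- ng86_ks("ATG---GGT", "ATGAAAGGC")
  expect_equal(g$n_codons, 2L)
})

test_that("NG86 is symmetric and flags saturation", {
  set.seed(23)
  cfg <- sim_config(seed = 23, ks_grid = 0.3, pairs_per_target = 5L,
                    n_codons = 120L)
  pp <- simulate_codon_pairs(cfg)
  for (i in seq_len(nrow(pp))) {
    a <- ng86_ks(pp$seq_a[i], pp$seq_b[i])
    b <- ng86_ks(pp$seq_b[i], pp$seq_a[i])
    expect_equal(a, b)
  }
  sat <- ng86_ks(strrep("GGT", 4), strrep("GGA", 4))  # pS = 1 > 3/4
  expect_true(sat$saturated)
  expect_true(is.na(sat$Ks))
})

test_that("simulated synonymous-only pairs recover the target and keep Ka near 0", {
  cfg <- sim_config(seed = 31, ks_grid = 0.1, pairs_per_target = 60L,
                    n_codons = 300L)
  pp <- simulate_codon_pairs(cfg)
  est <- vapply(seq_len(nrow(pp)), function(i) {
    r <- ng86_ks(pp$seq_a[i], pp$seq_b[i])
    c(r$Ks, r$Ka)
  }, numeric(2))
  expect_lt(abs(mean(est[1, ]) - 0.1), 0.01)
  expect_lt(mean(est[2, ]), 1e-6)  # no nonsynonymous signal
})

test_that("Ks-to-time conversion is the linear dating formula", {
  expect_equal(ks_to_time(0.13), 10)
  expect_equal(ks_to_time(0), 0)
  expect_equal(ks_to_time(0.156), 12)
  expect_error(ks_to_time(-0.1), "negative")
  # linearity and round trip through the rate
  t <- c(1, 7, 12, 300)
  expect_equal(ks_to_time(2 * 6.5e-9 * t * 1e6), t)
})

test_that("family copy summaries report means and extrema", {
  members <- data.frame(
    family = c(rep("POD", 5), rep("C3H", 1), rep("CAD", 3)),
    species = "Ph_edulis",
    gene_id = paste0("m", 1:9))
  s <- family_copy_summary(members)
  expect_equal(unname(s$mean_copies), 3)
  expect_equal(s$largest, "POD")
  expect_equal(s$smallest, "C3H")
  one <- family_copy_summary(data.frame(family = "PAL", species = "x",
                                        gene_id = paste0("p", 1:5)))
  expect_equal(unname(one$mean_copies), 5)
  expect_equal(one$largest, one$smallest)
})
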