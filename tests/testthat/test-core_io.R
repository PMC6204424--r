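test_that("FASTA reading normalises case, enforces the alphabet and rejects duplicates", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1 descriptive text", "acgt", ">chr2", "NNACGT"), f)
  g <- read_fasta(f)
  expect_equal(unclass(g), c(chr1 = "ACGT", chr2 = "NNACGT"))

  writeLines(c(">chr1", "ACGT", ">chr1", "GGGG"), f)
  expect_error(read_fasta(f), "duplicate")

  writeLines(c(">chr1", "ACXT"), f)
  expect_error(read_fasta(f), "alphabet")
})

test_that("FASTA write/read round trip preserves the genome", {
  g <- random_genome(500)
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(g, f)
  expect_equal(unclass(read_fasta(f)), unclass(g))
})

test_that("genome_interval enforces chromosome bounds", {
  g <- structure(c(chr1 = "ACGTACGT"), class = "genome_seq")
  expect_equal(genome_interval(g, "chr1", 0, 4), "ACGT")
  expect_equal(genome_interval(g, "chr1", 6, 8), "GT")
  expect_error(genome_interval(g, "chr1", 5, 9), "out of bounds")
  expect_error(genome_interval(g, "chrX", 0, 2), "unknown chromosome")
})

test_that("GTF exons convert from 1-based inclusive to 0-based half-open", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t1\t100\t.\t+\t.\tgene_id "g1"; transcript_id "tx1";',
    'chr1\tsrc\texon\t201\t300\t.\t+\t.\tgene_id "g1"; transcript_id "tx1";'),
    f)
  ann <- read_transcripts(f, dialect = "gtf")
  tx <- transcript_models(ann)[["tx1"]]
  expect_equal(unname(tx$exons), cbind(c(0, 200), c(100, 300)))
  expect_equal(tx$gene_id, "g1")
})

test_that("GFF3 input yields the same annotation as equivalent GTF", {
  fg <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1\t300\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t1\t300\t.\t+\t.\tID=tx1;Parent=g1",
    "chr1\tsrc\texon\t1\t100\t.\t+\t.\tParent=tx1",
    "chr1\tsrc\texon\t201\t300\t.\t+\t.\tParent=tx1"), fg)
  ft <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t1\t100\t.\t+\t.\tgene_id "g1"; transcript_id "tx1";',
    'chr1\tsrc\texon\t201\t300\t.\t+\t.\tgene_id "g1"; transcript_id "tx1";'),
    ft)
  a <- read_transcripts(fg, dialect = "gff3")
  b <- read_transcripts(ft, dialect = "gtf")
  expect_equal(a$exons, b$exons)
})

test_that("annotation invariants: strand mixing rejected, adjacent exons merged", {
  bad <- data.frame(transcript_id = "t1", gene_id = "g1", chrom = "chr1",
                    strand = c("+", "-"), start = c(0, 200), end = c(100, 300))
  expect_error(annotation_set(bad), "mixes strands")

  adj <- data.frame(transcript_id = "t1", gene_id = "g1", chrom = "chr1",
                    strand = "+", start = c(0, 100), end = c(100, 300))
  expect_warning(ann <- annotation_set(adj), "merged")
  expect_equal(unname(transcript_models(ann)[["t1"]]$exons),
               cbind(0, 300))

  short <- data.frame(transcript_id = "t1", gene_id = "g1", chrom = "chr1",
                      strand = "+", start = c(0, 105), end = c(100, 300))
  expect_error(annotation_set(short), "intron shorter")
  expect_silent(annotation_set(short, min_intron = 5))
})

test_that("annotation write/read round trip re-parses to an equal set", {
  cfg <- sim_config(seed = 3, n_genes = 15, n_tissues = 3)
  sim <- simulate_annotation(cfg)
  f <- withr::local_tempfile(fileext = ".gtf")
  write_transcripts(sim$union, f)
  back <- read_transcripts(f, dialect = "gtf")
  a <- sim$union$exons[order(sim$union$exons$transcript_id,
                             sim$union$exons$start), ]
  b <- back$exons[order(back$exons$transcript_id, back$exons$start), ]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("GTF coordinate conversion round-trips through write/read exactly", {
  set.seed(11)
  n <- 40L
  start0 <- sort(sample.int(100000, n)) + c(0L, cumsum(rep(400L, n - 1L)))
  end0 <- start0 + sample(50:300, n, replace = TRUE)
  ex <- data.frame(transcript_id = sprintf("t%02d", seq_len(n)),
                   gene_id = sprintf("g%02d", seq_len(n)), chrom = "chr1",
                   strand = "+", start = start0, end = end0)
  ann <- annotation_set(ex)
  f <- withr::local_tempfile(fileext = ".gtf")
  write_transcripts(ann, f)
  back <- read_transcripts(f, dialect = "gtf")
  b <- back$exons[order(back$exons$transcript_id), ]
  expect_equal(b$start, ex$start)
  expect_equal(b$end, ex$end)
})

test_that("events TSV output is sorted, headered and byte-reproducible", {
  ev <- data.frame(
    gene_id = c("g2", "g1"), chrom = "chr1", strand = "+",
    type = c("IR", "ES"), signature = c("s2", "s1"),
    region_start = c(500L, 10L), region_end = c(600L, 90L),
    support = c("t1", "t1,t2"), within_tissue = c(TRUE, FALSE))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_events_tsv(ev, f1)
  write_events_tsv(ev[2:1, ], f2)  # permuted input, identical bytes out
  expect_identical(readLines(f1), readLines(f2))
  back <- read_events_tsv(f1)
  expect_equal(back$region_start, c(10L, 500L))  # sorted by position

  f3 <- withr::local_tempfile(fileext = ".tsv")
  write_events_tsv(ev[0, ], f3)
  expect_equal(nrow(read_events_tsv(f3)), 0L)
})
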