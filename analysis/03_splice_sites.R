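#!/usr/bin/env Rscript
# Stage 3: type splice-site dinucleotides.
#
# Every unique intron of the union annotation is typed against the genome
# (donor = first two intronic bases, acceptor = last two, transcription
# orientation); the tally is reported per unique intron and per AS event —
# the two denominators a splice-site usage figure can be quoted in.

suppressPackageStartupMessages(library(spliceatlas))

data_dir <- "results/data"
genome <- read_fasta(file.path(data_dir, "genome.fa"))
ann <- read_transcripts(file.path(data_dir, "transcripts_union.gtf"))

sites <- extract_splice_sites(genome, ann)
spliceatlas:::write_tsv_with_header(sites, "results/splice_sites.tsv")
tally <- splice_site_tally(sites$class)

ev <- read_events_tsv("results/events.tsv")
ctl <- structure(list(events = ev), class = "event_catalog")
ev_classes <- event_splice_classes(genome, ctl)
ev_tally <- splice_site_tally(ev_classes)

jsonlite::write_json(
  list(per_intron = list(counts = as.list(tally$counts),
                         percent = as.list(round(100 * tally$fractions, 2)),
                         canonical_percent = 100 * tally$canonical_fraction,
                         noncanonical = tally$noncanonical),
       per_event = list(counts = as.list(ev_tally$counts),
                        percent = as.list(round(100 * ev_tally$fractions, 2)),
                        noncanonical = ev_tally$noncanonical)),
  "results/splice_sites_summary.json", auto_unbox = TRUE, pretty = TRUE,
  digits = 6)

cat(sprintf("%d unique introns typed\n", tally$total))
cat("per-intron class percentages:\n")
print(round(100 * tally$fractions, 2))
cat(sprintf("canonical: %.2f%%; noncanonical sites: %d (GT-AT %d + other %d)\n",
            100 * tally$canonical_fraction, tally$noncanonical,
            tally$counts[["GT-AT"]], tally$counts[["other"]]))
cat(sprintf("event-level denominator: %d intron observations\n",
            ev_tally$total))
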