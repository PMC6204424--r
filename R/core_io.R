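# Coordinate convention: all internal coordinates are 0-based half-open
# [start, end). GTF/GFF3 (1-based inclusive) and BED (0-based half-open) are
# converted at the I/O boundary, nowhere else.

#' Read a multi-record FASTA file into a genome object
#'
#' Sequences are uppercased on load and restricted to the A/C/G/T/N alphabet.
#' Record ids are taken as the first whitespace-delimited token of each header.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector (one element per chromosome/record) of
#'   class `genome_seq`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- Biostrings::readBStringSet(path)  # no silent letter filtering
  if (length(seqs) == 0L) stop("empty FASTA: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  x <- toupper(as.character(seqs))
  names(x) <- ids
  if (any(grepl("[^ACGTN]", x))) {
    stop("sequence alphabet must be restricted to A/C/G/T/N")
  }
  structure(x, class = "genome_seq")
}

#' Write a genome object to FASTA
#'
#' @param genome Named character vector of sequences (`genome_seq` or plain).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  dss <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(dss, filepath = path, width = 70L)
  invisible(path)
}

#' Extract a genomic interval (0-based half-open) from a genome
#'
#' @param genome A `genome_seq` object (named character vector).
#' @param chrom Chromosome id.
#' @param start,end 0-based half-open interval bounds.
#' @return The interval sequence as a character scalar.
#' @export
genome_interval <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  len <- nchar(genome[[chrom]])
  if (start < 0 || end > len || end <= start) {
    stop(sprintf("interval [%d,%d) out of bounds for %s (length %d)",
                 start, end, chrom, len))
  }
  substr(genome[[chrom]], start + 1L, end)
}

#' Construct an annotation set from an exon table
#'
#' The exon table carries one row per exon with 0-based half-open coordinates.
#' Per transcript, exons are sorted, must not overlap, and adjacent exons
#' (zero-length introns) are merged with a warning. Transcript ids must be
#' unique within the set, and each transcript must sit on a single chromosome
#' and strand.
#'
#' @param exons data.frame with columns `transcript_id`, `gene_id`, `chrom`,
#'   `strand` (one of `"+"`, `"-"`, `"."`), `start`, `end`.
#' @param provenance Optional sample/tissue/platform label.
#' @param min_intron Minimum allowed intron length (default 20); a shorter gap
#'   between consecutive exons is an error.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(exons, provenance = NA_character_, min_intron = 20L) {
  need <- c("transcript_id", "gene_id", "chrom", "strand", "start", "end")
  if (!all(need %in% names(exons))) {
    stop("exon table must have columns: ", paste(need, collapse = ", "))
  }
  exons <- as.data.frame(exons)[need]
  if (any(exons$end <= exons$start)) stop("exon with end <= start")
  if (!all(exons$strand %in% c("+", "-", "."))) stop("strand must be +, - or .")

  exons <- exons[order(exons$transcript_id, exons$start, exons$end), ,
                 drop = FALSE]
  pieces <- split(exons, exons$transcript_id)
  merged_any <- FALSE
  pieces <- lapply(pieces, function(df) {
    if (length(unique(df$strand)) != 1L) {
      stop("transcript ", df$transcript_id[1], " mixes strands")
    }
    if (length(unique(df$chrom)) != 1L) {
      stop("transcript ", df$transcript_id[1], " spans chromosomes")
    }
    if (length(unique(df$gene_id)) != 1L) {
      stop("transcript ", df$transcript_id[1], " assigned to several genes")
    }
    if (nrow(df) > 1L) {
      # merge exons that abut exactly (zero-length intron)
      keep <- df[1, , drop = FALSE]
      for (i in seq_len(nrow(df))[-1]) {
        last <- nrow(keep)
        if (df$start[i] < keep$end[last]) {
          stop("overlapping exons in transcript ", df$transcript_id[1])
        }
        if (df$start[i] == keep$end[last]) {
          keep$end[last] <- df$end[i]
          merged_any <<- TRUE
        } else {
          if (df$start[i] - keep$end[last] < min_intron) {
            stop("intron shorter than ", min_intron, " in transcript ",
                 df$transcript_id[1])
          }
          keep <- rbind(keep, df[i, , drop = FALSE])
        }
      }
      keep
    } else df
  })
  if (merged_any) warning("adjacent exons merged (zero-length introns)")
  exons <- do.call(rbind, c(pieces, list(make.row.names = FALSE)))
  structure(list(exons = exons, provenance = provenance), class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set: %d exons, %d transcripts, %d genes%s\n",
              nrow(x$exons), length(unique(x$exons$transcript_id)),
              length(unique(x$exons$gene_id)),
              if (is.na(x$provenance)) "" else paste0(" [", x$provenance, "]")))
  invisible(x)
}

#' List the transcript models of an annotation set
#'
#' @param ann An `annotation_set`.
#' @return Named list of transcript records, each a list with fields
#'   `transcript_id`, `gene_id`, `chrom`, `strand` and `exons` (a two-column
#'   matrix of 0-based half-open intervals, sorted ascending).
#' @export
transcript_models <- function(ann) {
  stopifnot(inherits(ann, "annotation_set"))
  ex <- ann$exons
  idx <- split(seq_len(nrow(ex)), ex$transcript_id)
  lapply(idx, function(i) {
    list(transcript_id = ex$transcript_id[i[1]],
         gene_id = ex$gene_id[i[1]],
         chrom = ex$chrom[i[1]],
         strand = ex$strand[i[1]],
         exons = cbind(start = ex$start[i], end = ex$end[i]))
  })
}

#' Group transcript models into gene loci
#'
#' @param ann An `annotation_set`.
#' @return Named list (by gene id) of lists of transcript records.
#' @export
gene_loci <- function(ann) {
  tx <- transcript_models(ann)
  split(tx, vapply(tx, `[[`, "", "gene_id"))
}

# Walk GFF3 Parent attributes: exon -> mRNA/transcript -> gene.
.gff3_exon_table <- function(gr) {
  type <- as.character(gr$type)
  is_tx <- type %in% c("mRNA", "transcript")
  tx_gene <- character(0)
  if (any(is_tx)) {
    ids <- as.character(gr$ID[is_tx])
    par <- vapply(gr$Parent[is_tx],
                  function(p) if (length(p)) as.character(p)[1] else NA_character_,
                  character(1))
    tx_gene <- stats::setNames(par, ids)
  }
  ex <- gr[type == "exon"]
  if (length(ex) == 0L) stop("no exon features in GFF3 input")
  tid <- vapply(ex$Parent,
                function(p) if (length(p)) as.character(p)[1] else NA_character_,
                character(1))
  if (anyNA(tid)) stop("GFF3 exon without Parent attribute")
  gid <- unname(tx_gene[tid])
  gid[is.na(gid)] <- tid[is.na(gid)]  # orphan transcripts: gene = transcript
  data.frame(transcript_id = tid, gene_id = gid,
             chrom = as.character(GenomicRanges::seqnames(ex)),
             strand = as.character(GenomicRanges::strand(ex)),
             start = GenomicRanges::start(ex) - 1L,
             end = GenomicRanges::end(ex),
             stringsAsFactors = FALSE)
}

#' Read transcript models from GTF or GFF3
#'
#' Exon features are grouped by transcript and gene; file coordinates
#' (1-based inclusive) are converted to the internal 0-based half-open
#' convention. GTF inputs must carry `gene_id`/`transcript_id` attributes;
#' GFF3 inputs use `ID`/`Parent` chains.
#'
#' @param path Input path.
#' @param dialect `"gtf"`, `"gff3"`, or `"auto"` (by file extension).
#' @param provenance Optional provenance tag stored in the result.
#' @return An `annotation_set`.
#' @export
read_transcripts <- function(path, dialect = c("auto", "gtf", "gff3"),
                             provenance = NA_character_) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.(gff3?|gff)$", path, ignore.case = TRUE)) "gff3" else "gtf"
  }
  gr <- rtracklayer::import(path, format = if (dialect == "gtf") "gtf" else "gff3")
  ex <- if (dialect == "gtf") {
    e <- gr[as.character(gr$type) == "exon"]
    if (length(e) == 0L) stop("no exon features in GTF input")
    data.frame(transcript_id = as.character(e$transcript_id),
               gene_id = as.character(e$gene_id),
               chrom = as.character(GenomicRanges::seqnames(e)),
               strand = as.character(GenomicRanges::strand(e)),
               start = GenomicRanges::start(e) - 1L,
               end = GenomicRanges::end(e),
               stringsAsFactors = FALSE)
  } else {
    .gff3_exon_table(gr)
  }
  ex$strand[!ex$strand %in% c("+", "-")] <- "."
  annotation_set(ex, provenance = provenance)
}

#' Write an annotation set as GTF
#'
#' Inverse of [read_transcripts()]: internal 0-based half-open exons are
#' written as 1-based inclusive GTF exon features.
#'
#' @param ann An `annotation_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcripts <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_set"))
  ex <- ann$exons
  gr <- GenomicRanges::GRanges(
    seqnames = ex$chrom,
    ranges = IRanges::IRanges(start = ex$start + 1L, end = ex$end),
    strand = ifelse(ex$strand %in% c("+", "-"), ex$strand, "*"))
  gr$type <- "exon"
  gr$source <- "spliceatlas"
  gr$gene_id <- ex$gene_id
  gr$transcript_id <- ex$transcript_id
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read TE (or other) intervals from BED
#'
#' @param path BED file (0-based half-open, as BED is defined).
#' @return data.frame with columns `chrom`, `start`, `end`, `name`, `strand`
#'   (0-based half-open coordinates).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             name = if (!is.null(gr$name)) as.character(gr$name) else NA_character_,
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

# Shared writer for '#'-headed TSV outputs; `meta` is a named character vector
# echoed as "# key=value" lines so reruns are byte-reproducible and auditable.
write_tsv_with_header <- function(df, path, meta = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(meta)) {
    writeLines(paste0("# ", names(meta), "=", unname(meta)), con)
  }
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  if (nrow(df)) {
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

read_tsv_with_header <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr_i <- max(grep("^#", lines[seq_len(min(length(lines), 50L))]))
  cols <- strsplit(sub("^#", "", lines[hdr_i]), "\t")[[1]]
  body <- lines[-seq_len(hdr_i)]
  if (!length(body)) {
    df <- as.data.frame(stats::setNames(replicate(length(cols), character(0),
                                                  simplify = FALSE), cols))
    return(df)
  }
  utils::read.table(text = body, sep = "\t", col.names = cols,
                    stringsAsFactors = FALSE, quote = "")
}

#' Write an event catalog (or plain event table) to TSV
#'
#' One row per unique event, ordered by (chromosome, region start, type,
#' signature) so repeated runs over the same input produce identical bytes.
#'
#' @param events An `event_catalog` or its `events` data.frame.
#' @param path Output path.
#' @param meta Optional named character vector written as `# key=value` lines.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(events, path, meta = NULL) {
  df <- if (inherits(events, "event_catalog")) events$events else events
  cols <- c("gene_id", "chrom", "strand", "type", "signature",
            "region_start", "region_end", "support", "within_tissue")
  for (cc in setdiff(cols, names(df))) df[[cc]] <- NA
  df <- df[cols]
  if (nrow(df)) {
    df <- df[order(df$chrom, df$region_start, df$type, df$signature), ,
             drop = FALSE]
  }
  write_tsv_with_header(df, path, meta = meta)
}

#' Read back an events TSV written by [write_events_tsv()]
#'
#' @param path Input path.
#' @return data.frame of events.
#' @export
read_events_tsv <- function(path) {
  read_tsv_with_header(path)
}
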