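# Splice-site dinucleotide typing. The donor is the first two intronic bases
# and the acceptor the last two, both read in transcription orientation, so
# minus-strand introns are reverse-complemented. Canonical classes are GT-AG,
# GC-AG and AT-AC; GT-AT is tracked as its own noncanonical class and
# everything else (including any N) falls into "other".

.SPLICE_CLASSES <- c("GT-AG", "GC-AG", "AT-AC", "GT-AT", "other")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Classify donor/acceptor dinucleotide pairs
#'
#' Pure function of the two dinucleotides (vectorised).
#'
#' @param donor,acceptor Character vectors of 2-letter dinucleotides
#'   (A/C/G/T/N alphabet).
#' @return Character vector over
#'   `c("GT-AG", "GC-AG", "AT-AC", "GT-AT", "other")`.
#' @export
classify_splice_pair <- function(donor, acceptor) {
  key <- paste(donor, acceptor, sep = "-")
  out <- rep("other", length(key))
  for (cls in c("GT-AG", "GC-AG", "AT-AC", "GT-AT")) out[key == cls] <- cls
  out
}

#' Is a splice-site class canonical?
#'
#' @param class Character vector of splice-site classes.
#' @return Logical vector; canonical means GT-AG, GC-AG or AT-AC.
#' @export
is_canonical_class <- function(class) {
  class %in% c("GT-AG", "GC-AG", "AT-AC")
}

#' Extract the donor/acceptor pair of one intron
#'
#' @param genome A `genome_seq` object.
#' @param chrom Chromosome id.
#' @param start,end Intron interval, 0-based half-open, length >= 4.
#' @param strand `"+"` or `"-"`.
#' @return List with `donor`, `acceptor` (transcription orientation) and
#'   `class`.
#' @export
extract_pair <- function(genome, chrom, start, end, strand) {
  if (!strand %in% c("+", "-")) stop("unknown strand: ", strand)
  if (end - start < 4L) stop("intron shorter than 4 bases")
  left <- genome_interval(genome, chrom, start, start + 2L)
  right <- genome_interval(genome, chrom, end - 2L, end)
  if (strand == "+") {
    donor <- left; acceptor <- right
  } else {
    donor <- revcomp(right); acceptor <- revcomp(left)
  }
  list(donor = donor, acceptor = acceptor,
       class = classify_splice_pair(donor, acceptor))
}

#' Unique introns of an annotation set
#'
#' @param ann An `annotation_set`.
#' @param drop_unstranded Exclude introns of strand-"." transcripts (the
#'   default: donor/acceptor orientation is undefined for them).
#' @return data.frame with `chrom`, `start`, `end`, `strand`, one row per
#'   distinct intron.
#' @export
unique_introns <- function(ann, drop_unstranded = TRUE) {
  txs <- transcript_models(ann)
  parts <- lapply(txs, function(tx) {
    ic <- intron_chain(tx)
    if (!nrow(ic)) return(NULL)
    data.frame(chrom = tx$chrom, start = ic[, 1L], end = ic[, 2L],
               strand = tx$strand, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, parts)
  if (is.null(df)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  }
  if (drop_unstranded) df <- df[df$strand %in% c("+", "-"), , drop = FALSE]
  df <- unique(df)
  df[order(df$chrom, df$start, df$end, df$strand), , drop = FALSE]
}

#' Type all introns of an annotation against the genome
#'
#' @param genome A `genome_seq`.
#' @param ann An `annotation_set` (or a data.frame as from
#'   [unique_introns()]).
#' @return data.frame with intron coordinates, `donor`, `acceptor`, `class`,
#'   `canonical`.
#' @export
extract_splice_sites <- function(genome, ann) {
  introns <- if (inherits(ann, "annotation_set")) unique_introns(ann) else ann
  n <- nrow(introns)
  if (!n) {
    return(cbind(introns, data.frame(donor = character(0),
                                     acceptor = character(0),
                                     class = character(0),
                                     canonical = logical(0))))
  }
  seqs <- unclass(genome)[introns$chrom]
  left <- substr(seqs, introns$start + 1L, introns$start + 2L)
  right <- substr(seqs, introns$end - 1L, introns$end)
  minus <- introns$strand == "-"
  donor <- ifelse(minus, revcomp(right), left)
  acceptor <- ifelse(minus, revcomp(left), right)
  cls <- classify_splice_pair(donor, acceptor)
  cbind(introns,
        data.frame(donor = donor, acceptor = acceptor, class = cls,
                   canonical = is_canonical_class(cls),
                   stringsAsFactors = FALSE))
}

#' Tally splice-site classes
#'
#' @param classes Character vector of splice-site classes (e.g. the `class`
#'   column of [extract_splice_sites()], taken per unique intron or repeated
#'   per AS event for event-level counting).
#' @return List with per-class `counts`, `total`, per-class `fractions`,
#'   `canonical_fraction` and `noncanonical` count (GT-AT + other).
#' @export
splice_site_tally <- function(classes) {
  counts <- table(factor(classes, levels = .SPLICE_CLASSES))
  counts <- stats::setNames(as.integer(counts), .SPLICE_CLASSES)
  total <- sum(counts)
  fractions <- if (total > 0) counts / total else counts * NA_real_
  list(counts = counts, total = total, fractions = fractions,
       canonical_fraction = if (total > 0) {
         sum(counts[c("GT-AG", "GC-AG", "AT-AC")]) / total
       } else NA_real_,
       noncanonical = counts[["GT-AT"]] + counts[["other"]])
}

# Introns referenced by an event signature, e.g. "100:300[100-200|=]".
.signature_introns <- function(signature) {
  inner <- sub("^[0-9]+:[0-9]+\\[(.*)\\]$", "\\1", signature)
  chains <- strsplit(inner, "|", fixed = TRUE)[[1]]
  parts <- unlist(strsplit(chains[chains != "="], ",", fixed = TRUE))
  if (!length(parts)) {
    return(cbind(start = integer(0), end = integer(0)))
  }
  se <- do.call(rbind, strsplit(parts, "-", fixed = TRUE))
  cbind(start = as.integer(se[, 1L]), end = as.integer(se[, 2L]))
}

#' Splice-site classes counted per AS event
#'
#' Every intron taking part in an event's variable region contributes one
#' observation per event (the event-level denominator, as opposed to the
#' per-unique-intron denominator of [unique_introns()] + [splice_site_tally()]).
#'
#' @param genome A `genome_seq`.
#' @param catalog An `event_catalog`.
#' @return Character vector of classes, one per (event, intron) occurrence;
#'   introns of unknown-strand genes are skipped.
#' @export
event_splice_classes <- function(genome, catalog) {
  ev <- catalog$events
  out <- character(0)
  for (i in seq_len(nrow(ev))) {
    if (!ev$strand[i] %in% c("+", "-")) next
    m <- .signature_introns(ev$signature[i])
    for (j in seq_len(nrow(m))) {
      if (m[j, 2L] - m[j, 1L] < 4L) next
      p <- extract_pair(genome, ev$chrom[i], m[j, 1L], m[j, 2L], ev$strand[i])
      out <- c(out, p$class)
    }
  }
  out
}
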