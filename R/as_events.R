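# Alternative-splicing event extraction and classification.
#
# Events are variations between the intron chains of two isoforms of the same
# gene. Within the genomic span shared by both isoforms, splice sites present
# in both chains partition the span into regions (the AStalavista convention);
# every region in which the two chains differ is one event, classified from
# the intron content of each side:
#   IR    one side has exactly one intron, the other is contiguous exon
#   A3SS  one intron each, shared donor, different acceptor
#   A5SS  one intron each, shared acceptor, different donor
#   ES    k>=1 complete exon(s) on one side vs a single spanning intron
#   OTHER any remaining pattern (including everything on unknown strand that
#         would need donor/acceptor orientation to name)
# Donor/acceptor are taken in transcription orientation, so the genomic
# comparison is strand-flipped on minus-strand genes.

.EVENT_TYPES <- c("IR", "A3SS", "A5SS", "ES", "OTHER")

empty_events <- function() {
  data.frame(gene_id = character(0), chrom = character(0),
             strand = character(0), type = character(0),
             signature = character(0), region_start = integer(0),
             region_end = integer(0), tx_a = character(0), tx_b = character(0),
             stringsAsFactors = FALSE)
}

#' Derive the intron chain of a transcript model
#'
#' @param tx A transcript record (as from [transcript_models()]) or a
#'   two-column exon matrix of 0-based half-open intervals sorted ascending.
#' @return Two-column matrix (`start`, `end`) of introns; zero rows for a
#'   single-exon transcript.
#' @export
intron_chain <- function(tx) {
  exons <- if (is.list(tx) && !is.null(tx$exons)) tx$exons else tx
  n <- nrow(exons)
  if (is.null(n) || n < 2L) {
    return(cbind(start = integer(0), end = integer(0)))
  }
  cbind(start = exons[-n, 2L], end = exons[-1L, 1L])
}

.chain_string <- function(m) {
  if (nrow(m) == 0L) return("=")
  paste(paste0(m[, 1L], "-", m[, 2L]), collapse = ",")
}

# Classify the intron content (a, b: intron matrices restricted to one
# region). `clipped` marks regions touching a truncated intron at the shared
# span edge: incomplete evidence, typed OTHER.
.classify_region <- function(a, b, strand, clipped = FALSE) {
  na <- nrow(a); nb <- nrow(b)
  if (clipped) return("OTHER")
  if ((na == 1L && nb == 0L) || (na == 0L && nb == 1L)) return("IR")
  if (na == 1L && nb == 1L) {
    same_start <- a[1L, 1L] == b[1L, 1L]
    same_end <- a[1L, 2L] == b[1L, 2L]
    if (same_start && !same_end) {
      # shared left boundary: donor on '+', acceptor on '-'
      return(switch(strand, "+" = "A3SS", "-" = "A5SS", "OTHER"))
    }
    if (same_end && !same_start) {
      return(switch(strand, "+" = "A5SS", "-" = "A3SS", "OTHER"))
    }
    return("OTHER")
  }
  multi <- NULL; single <- NULL
  if (na >= 2L && nb == 1L) { multi <- a; single <- b }
  if (nb >= 2L && na == 1L) { multi <- b; single <- a }
  if (!is.null(multi)) {
    if (multi[1L, 1L] == single[1L, 1L] &&
        multi[nrow(multi), 2L] == single[1L, 2L]) {
      return("ES")
    }
  }
  "OTHER"
}

#' Extract AS events between two isoforms of one gene
#'
#' @param tx_a,tx_b Transcript records (see [transcript_models()]) of the same
#'   gene, chromosome and strand.
#' @return data.frame of events with columns `gene_id`, `chrom`, `strand`,
#'   `type`, `signature`, `region_start`, `region_end`, `tx_a`, `tx_b`.
#'   Symmetric in its arguments (the signature canonicalises chain order).
#' @export
pairwise_events <- function(tx_a, tx_b) {
  if (tx_a$gene_id != tx_b$gene_id) stop("isoforms from different genes")
  if (tx_a$chrom != tx_b$chrom || tx_a$strand != tx_b$strand) {
    stop("isoforms from different chromosomes or strands")
  }
  span_l <- max(tx_a$exons[1L, 1L], tx_b$exons[1L, 1L])
  span_r <- min(tx_a$exons[nrow(tx_a$exons), 2L],
                tx_b$exons[nrow(tx_b$exons), 2L])
  if (span_r <= span_l) return(empty_events())

  clip <- function(m) {
    if (nrow(m) == 0L) {
      return(list(introns = m, clipped = logical(0)))
    }
    keep <- m[, 2L] > span_l & m[, 1L] < span_r
    m <- m[keep, , drop = FALSE]
    clipped <- m[, 1L] < span_l | m[, 2L] > span_r
    m[, 1L] <- pmax(m[, 1L], span_l)
    m[, 2L] <- pmin(m[, 2L], span_r)
    list(introns = m, clipped = clipped)
  }
  ca <- clip(intron_chain(tx_a))
  cb <- clip(intron_chain(tx_b))
  ia <- ca$introns; ib <- cb$introns

  # splice sites common to both chains partition the shared span
  sites_a <- as.vector(ia[!ca$clipped, , drop = FALSE])
  sites_b <- as.vector(ib[!cb$clipped, , drop = FALSE])
  cuts <- sort(unique(c(span_l, span_r, intersect(sites_a, sites_b))))

  out <- empty_events()
  for (k in seq_len(length(cuts) - 1L)) {
    l <- cuts[k]; r <- cuts[k + 1L]
    sel_a <- ia[, 1L] >= l & ia[, 2L] <= r
    sel_b <- ib[, 1L] >= l & ib[, 2L] <= r
    a <- ia[sel_a, , drop = FALSE]
    b <- ib[sel_b, , drop = FALSE]
    if (nrow(a) == nrow(b) && identical(unname(a), unname(b))) next
    clipped <- any(ca$clipped[sel_a]) || any(cb$clipped[sel_b])
    type <- .classify_region(a, b, tx_a$strand, clipped = clipped)
    sig <- paste0(l, ":", r, "[",
                  paste(sort(c(.chain_string(a), .chain_string(b))),
                        collapse = "|"), "]")
    out <- rbind(out, data.frame(
      gene_id = tx_a$gene_id, chrom = tx_a$chrom, strand = tx_a$strand,
      type = type, signature = sig, region_start = l, region_end = r,
      tx_a = tx_a$transcript_id, tx_b = tx_b$transcript_id,
      stringsAsFactors = FALSE))
  }
  out
}

#' All unique AS events of one gene locus
#'
#' Union of [pairwise_events()] over all isoform pairs, deduplicated by
#' (gene, type, signature). A gene is an AS gene iff the catalog is non-empty.
#'
#' @param locus List of transcript records of one gene.
#' @return data.frame of unique events (first witness pair kept per event).
#' @export
gene_events <- function(locus) {
  n <- length(locus)
  if (n < 2L) return(empty_events())
  parts <- list()
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      parts[[length(parts) + 1L]] <- pairwise_events(locus[[i]], locus[[j]])
    }
  }
  ev <- do.call(rbind, parts)
  ev[!duplicated(paste(ev$gene_id, ev$type, ev$signature, sep = "\r")), ,
     drop = FALSE]
}

# Deduplicate isoform structures across tissues; returns per gene a list of
# distinct structures, each carrying the set of provenance tags it appears in.
.distinct_structures <- function(annotations) {
  if (inherits(annotations, "annotation_set")) {
    annotations <- list(annotations)
  }
  tags <- names(annotations)
  if (is.null(tags)) {
    tags <- vapply(annotations, function(a) {
      if (is.na(a$provenance)) NA_character_ else a$provenance
    }, character(1))
    tags[is.na(tags)] <- paste0("sample", seq_along(annotations))[is.na(tags)]
  }
  pool <- new.env(parent = emptyenv())
  for (s in seq_along(annotations)) {
    txs <- transcript_models(annotations[[s]])
    for (tx in txs) {
      key <- paste(tx$gene_id, tx$chrom, tx$strand,
                   .chain_string(tx$exons), sep = "\r")
      rec <- if (!is.null(pool[[key]])) pool[[key]] else {
        tx$tissues <- character(0)
        tx
      }
      rec$tissues <- union(rec$tissues, tags[s])
      pool[[key]] <- rec
    }
  }
  keys <- sort(ls(pool, all.names = TRUE))  # deterministic catalog order
  structs <- mget(keys, envir = pool)
  split(structs, vapply(structs, `[[`, "", "gene_id"))
}

#' Build an AS event catalog from one or several annotation sets
#'
#' Given a single (e.g. merged) annotation the catalog is the union of
#' [gene_events()] over its loci. Given a named list of per-tissue
#' annotations, isoform structures are deduplicated across tissues first
#' (union mode) and each event records its tissue support: the set of tissues
#' contributing a witness isoform, plus whether some single tissue contains a
#' complete witness pair (`within_tissue`).
#'
#' @param annotations An `annotation_set` or a named list of them.
#' @return Object of class `event_catalog`: list with `events` (data.frame),
#'   `n_genes` (genes inspected), `as_genes` (character vector of AS genes)
#'   and `counts` (events per type).
#' @export
build_catalog <- function(annotations) {
  genes <- .distinct_structures(annotations)
  rows <- list()
  for (g in names(genes)) {
    structs <- genes[[g]]
    n <- length(structs)
    if (n < 2L) next
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        ev <- pairwise_events(structs[[i]], structs[[j]])
        if (!nrow(ev)) next
        ti <- structs[[i]]$tissues; tj <- structs[[j]]$tissues
        co <- intersect(ti, tj)
        # support = tissues where this witness pair makes the event
        # derivable: the co-occurrence tissues if any, otherwise the
        # cross-tissue union
        ev$support_set <- paste(sort(if (length(co)) co else union(ti, tj)),
                                collapse = ",")
        ev$within_tissue <- length(co) > 0L
        rows[[length(rows) + 1L]] <- ev
      }
    }
  }
  ev <- if (length(rows)) do.call(rbind, rows) else {
    e <- empty_events(); e$support_set <- character(0)
    e$within_tissue <- logical(0); e
  }
  # merge witness pairs of identical events: union supports, any-within
  key <- paste(ev$gene_id, ev$type, ev$signature, sep = "\r")
  first <- !duplicated(key)
  uniq <- ev[first, , drop = FALSE]
  if (any(!first)) {
    supp <- tapply(ev$support_set, key, function(s) {
      paste(sort(unique(unlist(strsplit(s, ",", fixed = TRUE)))), collapse = ",")
    })
    within <- tapply(ev$within_tissue, key, any)
    uniq$support_set <- unname(supp[key[first]])
    uniq$within_tissue <- unname(within[key[first]])
  }
  uniq$support <- uniq$support_set
  uniq$support_set <- NULL
  uniq$n_support <- vapply(strsplit(uniq$support, ",", fixed = TRUE),
                           length, integer(1))
  counts <- table(factor(uniq$type, levels = .EVENT_TYPES))
  structure(list(events = uniq,
                 n_genes = length(genes),
                 as_genes = sort(unique(uniq$gene_id)),
                 counts = as.integer(counts) |>
                   stats::setNames(.EVENT_TYPES)),
            class = "event_catalog")
}

#' @export
print.event_catalog <- function(x, ...) {
  cat(sprintf("event_catalog: %d unique events in %d AS genes (of %d genes)\n",
              nrow(x$events), length(x$as_genes), x$n_genes))
  print(x$counts)
  invisible(x)
}

#' Overlap of two event catalogs
#'
#' Event overlap is |A intersect B| / |A| with A the *first* catalog (pass the
#' smaller platform, e.g. long-read, first to mirror the usual reporting
#' direction); gene overlap is analogous on the AS-gene sets. A per-type
#' breakdown is included.
#'
#' @param a,b `event_catalog` objects built against the same annotation space.
#' @return List with `event_overlap`, `gene_overlap`, `by_type`.
#' @export
catalog_overlap <- function(a, b) {
  ka <- paste(a$events$gene_id, a$events$type, a$events$signature, sep = "\r")
  kb <- paste(b$events$gene_id, b$events$type, b$events$signature, sep = "\r")
  ev <- if (length(ka)) mean(ka %in% kb) else NA_real_
  gn <- if (length(a$as_genes)) mean(a$as_genes %in% b$as_genes) else NA_real_
  by_type <- vapply(.EVENT_TYPES, function(tp) {
    sel <- a$events$type == tp
    if (!any(sel)) return(NA_real_)
    mean(ka[sel] %in% kb)
  }, numeric(1))
  list(event_overlap = ev, gene_overlap = gn, by_type = by_type)
}

#' Partition catalog events by tissue support
#'
#' `tissue_specific` events are supported by exactly one tissue; the
#' within/among partition separates events derivable from isoform pairs
#' co-occurring in a single tissue (`within_tissue`) from those only seen by
#' comparing isoforms across tissues (`among_tissue`).
#'
#' @param catalog An `event_catalog` built from per-tissue annotations.
#' @return List with counts and fractions of both partitions plus the
#'   per-event labels.
#' @export
partition_by_tissue <- function(catalog) {
  ev <- catalog$events
  if (!nrow(ev)) {
    return(list(n_events = 0L, tissue_specific = 0L, shared = 0L,
                within_tissue = 0L, among_tissue = 0L,
                tissue_specific_fraction = NA_real_,
                among_fraction = NA_real_, labels = ev))
  }
  specific <- ev$n_support == 1L
  within <- ev$within_tissue
  ev$tissue_class <- ifelse(specific, "tissue_specific", "shared")
  ev$derivation <- ifelse(within, "within_tissue", "among_tissue")
  list(n_events = nrow(ev),
       tissue_specific = sum(specific), shared = sum(!specific),
       within_tissue = sum(within), among_tissue = sum(!within),
       tissue_specific_fraction = mean(specific),
       among_fraction = mean(!within),
       labels = ev)
}

#' Maximum number of distinct isoforms from independent alternative regions
#'
#' With `k` mutually exclusive alternatives in each of several independently
#' spliced regions, the combinatorial ceiling is the product of the counts
#' (e.g. `c(12, 48, 33, 2)` gives 38,016).
#'
#' @param alternatives_per_region Vector of positive integers.
#' @return The product, as a double.
#' @export
max_isoform_count <- function(alternatives_per_region) {
  if (length(alternatives_per_region) == 0L) stop("empty region list")
  if (any(alternatives_per_region < 1)) stop("all entries must be >= 1")
  prod(as.numeric(alternatives_per_region))
}

#' Percentage of AS genes among annotated genes
#'
#' @param n_as_genes,n_total_genes Counts with
#'   `0 <= n_as_genes <= n_total_genes`, `n_total_genes > 0`.
#' @return `100 * n_as_genes / n_total_genes`, half-up rounded to 2 decimals.
#' @export
as_fraction <- function(n_as_genes, n_total_genes) {
  if (n_total_genes <= 0) stop("n_total_genes must be positive")
  if (n_as_genes < 0 || n_as_genes > n_total_genes) stop("invalid AS gene count")
  x <- 100 * n_as_genes / n_total_genes
  floor(x * 100 + 0.5) / 100  # half-up, unlike round()'s round-half-even
}

#' Split AS genes into previously annotated and novel
#'
#' @param as_genes Character vector (or count) of AS genes.
#' @param annotated_as_genes Character vector of AS genes already present in
#'   the reference annotation; when counts are given the known count must not
#'   exceed the AS count.
#' @return Named integer vector `c(n_known, n_novel)`.
#' @export
novel_gene_partition <- function(as_genes, annotated_as_genes) {
  if (is.numeric(as_genes)) {
    n_as <- as_genes; n_known <- annotated_as_genes
    if (n_known > n_as) stop("known AS genes exceed AS genes")
  } else {
    n_as <- length(unique(as_genes))
    n_known <- length(intersect(unique(as_genes), annotated_as_genes))
  }
  c(n_known = as.integer(n_known), n_novel = as.integer(n_as - n_known))
}
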