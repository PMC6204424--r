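# Shared fixtures and independent oracles for the test suite.

# Minimal transcript record constructor.
make_tx <- function(id, exons, strand = "+", gene = "g1", chrom = "chr1") {
  list(transcript_id = id, gene_id = gene, chrom = chrom, strand = strand,
       exons = matrix(unlist(exons), ncol = 2, byrow = TRUE,
                      dimnames = list(NULL, c("start", "end"))))
}

# Brute-force event enumerator, independent of the interval arithmetic in
# pairwise_events(): works on per-position intron-membership vectors over the
# shared span, partitions at splice sites common to both chains, and tests
# each differing region against the type definitions via run-length encoding.
oracle_pairwise <- function(tx_a, tx_b) {
  gaps <- function(ex) {
    n <- nrow(ex)
    if (n < 2L) return(cbind(numeric(0), numeric(0)))
    cbind(ex[-n, 2L], ex[-1L, 1L])
  }
  L <- max(tx_a$exons[1L, 1L], tx_b$exons[1L, 1L])
  R <- min(tx_a$exons[nrow(tx_a$exons), 2L], tx_b$exons[nrow(tx_b$exons), 2L])
  none <- data.frame(type = character(0), region_start = numeric(0),
                     region_end = numeric(0), signature = character(0))
  if (R <= L) return(none)
  memb <- function(ex) {
    v <- rep(FALSE, R - L)
    g <- gaps(ex)
    for (k in seq_len(nrow(g))) {
      a <- max(g[k, 1L], L); b <- min(g[k, 2L], R)
      if (b > a) v[(a - L + 1L):(b - L)] <- TRUE
    }
    v
  }
  va <- memb(tx_a$exons); vb <- memb(tx_b$exons)
  inner <- function(ex) {
    g <- gaps(ex)
    g[g[, 1L] >= L & g[, 2L] <= R, , drop = FALSE]  # unclipped only
  }
  ga <- inner(tx_a$exons); gb <- inner(tx_b$exons)
  cuts <- sort(unique(c(L, R, intersect(as.vector(ga), as.vector(gb)))))
  crosses_span <- function(ex, l, r) {
    g <- gaps(ex)
    any(g[, 2L] > l & g[, 1L] < r & (g[, 1L] < L | g[, 2L] > R))
  }
  runs <- function(v, off) {
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- c(0L, utils::head(ends, -1L))
    cbind(off + starts[r$values], off + ends[r$values])
  }
  chain_str <- function(m) {
    if (nrow(m) == 0L) return("=")
    paste(paste0(m[, 1L], "-", m[, 2L]), collapse = ",")
  }
  out <- none
  for (k in seq_len(length(cuts) - 1L)) {
    l <- cuts[k]; r <- cuts[k + 1L]
    sa <- va[(l - L + 1L):(r - L)]; sb <- vb[(l - L + 1L):(r - L)]
    if (all(sa == sb)) next
    a <- runs(sa, l); b <- runs(sb, l)
    clipped <- crosses_span(tx_a$exons, l, r) || crosses_span(tx_b$exons, l, r)
    na <- nrow(a); nb <- nrow(b)
    type <- if (clipped) {
      "OTHER"
    } else if ((na == 1L && nb == 0L) || (na == 0L && nb == 1L)) {
      "IR"
    } else if (na == 1L && nb == 1L) {
      if (a[1L, 1L] == b[1L, 1L] && a[1L, 2L] != b[1L, 2L]) {
        if (tx_a$strand == "+") "A3SS" else if (tx_a$strand == "-") "A5SS" else "OTHER"
      } else if (a[1L, 2L] == b[1L, 2L] && a[1L, 1L] != b[1L, 1L]) {
        if (tx_a$strand == "+") "A5SS" else if (tx_a$strand == "-") "A3SS" else "OTHER"
      } else "OTHER"
    } else if ((na >= 2L && nb == 1L && a[1L, 1L] == b[1L, 1L] &&
                a[na, 2L] == b[1L, 2L]) ||
               (nb >= 2L && na == 1L && b[1L, 1L] == a[1L, 1L] &&
                b[nb, 2L] == a[1L, 2L])) {
      "ES"
    } else "OTHER"
    sig <- paste0(l, ":", r, "[",
                  paste(sort(c(chain_str(a), chain_str(b))), collapse = "|"),
                  "]")
    out <- rbind(out, data.frame(type = type, region_start = l,
                                 region_end = r, signature = sig))
  }
  out
}

# Random multi-isoform locus: up to `max_tx` isoforms, each with at most 6
# introns, over a ~300 bp window; exon and intron pieces are kept >= 3 bp.
random_locus <- function(max_tx = 4L, span = 300L) {
  strand <- sample(c("+", "-"), 1L)
  n_tx <- sample(2:max_tx, 1L)
  txs <- vector("list", n_tx)
  for (i in seq_len(n_tx)) {
    repeat {
      s <- sample(0:40, 1L)
      e <- sample((span - 40L):span, 1L)
      n_introns <- sample(0:6, 1L)
      if (n_introns == 0L) {
        ex <- cbind(s, e)
      } else {
        b <- sort(sample((s + 5L):(e - 5L), 2L * n_introns))
        if (any(diff(c(s, b, e)) < 3L)) next
        ex <- cbind(c(s, b[seq(2L, 2L * n_introns, 2L)]),
                    c(b[seq(1L, 2L * n_introns, 2L)], e))
      }
      txs[[i]] <- list(transcript_id = paste0("t", i), gene_id = "g1",
                       chrom = "chr1", strand = strand,
                       exons = matrix(ex, ncol = 2,
                                      dimnames = list(NULL,
                                                      c("start", "end"))))
      break
    }
  }
  txs
}

# Cumulative-subtraction N50/N90 oracle, distinct from the cumsum route in
# length_stats().
oracle_nxx <- function(lengths, frac) {
  s <- sort(lengths, decreasing = TRUE)
  need <- frac * sum(s)
  for (x in s) {
    need <- need - x
    if (need <= 0) return(x)
  }
  s[length(s)]
}

# Random A/C/G/T genome of the given length as a genome_seq.
random_genome <- function(len, name = "chr1") {
  structure(stats::setNames(
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    name), class = "genome_seq")
}

rc_string <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(strsplit(x, ""), function(ch) paste(rev(comp[ch]), collapse = ""), "")
}
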