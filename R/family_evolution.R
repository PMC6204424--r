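# Gene-family identification filters and synonymous-rate dating.
#
# Candidate family members are homology hits surviving the three strict
# cutoffs (E-value < 1e-10, identity > 40, query coverage > 95) followed by a
# required-domain check on externally computed domain tables. Synonymous
# divergence is estimated with the Nei-Gojobori (1986) counting method:
# degeneracy-averaged site counts over both sequences, per-codon difference
# counts averaged over all mutation pathways that avoid stop codons, and a
# Jukes-Cantor multiple-hit correction K = -(3/4) log(1 - (4/3) p). Divergence
# time follows T = Ks / (2 r) with r in substitutions/site/year.

#' Read a BLAST outfmt-6-style hit table
#'
#' Standard 12 columns (`qseqid sseqid pident length mismatch gapopen qstart
#' qend sstart send evalue bitscore`), optionally followed by `qlen` as a 13th
#' column, from which query coverage is computed as `100 * length / qlen`
#' (per best HSP). A pre-aggregated table with columns
#' `query, subject, evalue, identity, coverage` is also accepted.
#'
#' @param path Tab-separated hit table, '#' comments allowed.
#' @return data.frame with columns `query`, `subject`, `evalue`, `identity`,
#'   `coverage` (percent), `align_length`.
#' @export
read_hits <- function(path) {
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          header = FALSE, stringsAsFactors = FALSE)
  first <- df[1, , drop = FALSE]
  if (is.character(first[[3]]) || ncol(df) == 5L) {
    names(df) <- c("query", "subject", "evalue", "identity", "coverage")[
      seq_len(ncol(df))]
    df$align_length <- NA_integer_
    return(df)
  }
  if (ncol(df) < 12L) stop("expected >= 12 outfmt-6 columns")
  names(df)[1:12] <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                       "gapopen", "qstart", "qend", "sstart", "send",
                       "evalue", "bitscore")
  cov <- if (ncol(df) >= 13L) 100 * df$length / df[[13L]] else NA_real_
  data.frame(query = df$qseqid, subject = df$sseqid, evalue = df$evalue,
             identity = df$pident, coverage = cov, align_length = df$length,
             stringsAsFactors = FALSE)
}

#' Filter homology hits by E-value, identity and coverage
#'
#' All three cutoffs are strict inequalities: keep hits with
#' `evalue < e_max`, `identity > id_min` and `coverage > cov_min`.
#' Relaxing any threshold can only grow the surviving set.
#'
#' @param hits data.frame as from [read_hits()].
#' @param e_max,id_min,cov_min Cutoffs (defaults 1e-10, 40, 95).
#' @param coverage `"best_hsp"` (default: each row judged on its own
#'   coverage) or `"summed"` (coverage summed over HSPs of the same
#'   query-subject pair before filtering; needs `align_length` and a `qlen`
#'   attribute or `coverage` values to reconstruct).
#' @return List with `hits` (surviving rows) and `subjects` (deduplicated
#'   subject ids).
#' @export
filter_hits <- function(hits, e_max = 1e-10, id_min = 40, cov_min = 95,
                        coverage = c("best_hsp", "summed")) {
  coverage <- match.arg(coverage)
  if (any(c(e_max, id_min, cov_min) <= 0)) stop("thresholds must be positive")
  cov <- hits$coverage
  if (coverage == "summed") {
    key <- paste(hits$query, hits$subject, sep = "\r")
    cov <- stats::ave(hits$coverage, key, FUN = sum)
  }
  keep <- hits$evalue < e_max & hits$identity > id_min & cov > cov_min
  keep[is.na(keep)] <- FALSE
  list(hits = hits[keep, , drop = FALSE],
       subjects = sort(unique(hits$subject[keep])))
}

#' Keep candidates carrying all required protein domains
#'
#' Consumes tabular domain-scan output (e.g. hmmsearch --tblout distilled to
#' candidate/domain pairs); candidates whose observed domain set does not
#' cover the required set are discarded.
#'
#' @param candidates Character vector of candidate ids.
#' @param required Character vector of required domain ids (non-empty).
#' @param observed data.frame with columns `candidate`, `domain`.
#' @return Character vector: the confirmed candidates, input order preserved.
#' @export
domain_filter <- function(candidates, required, observed) {
  if (!length(required)) stop("required domain set is empty")
  doms <- split(observed$domain, observed$candidate)
  keep <- vapply(candidates, function(cand) {
    all(required %in% doms[[cand]])
  }, logical(1))
  candidates[keep]
}

# --- NG86 machinery -------------------------------------------------------

.CODON_TABLE <- NULL

.codon_env <- new.env(parent = emptyenv())

.genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

.all_codons <- function() {
  nts <- c("A", "C", "G", "T")
  as.vector(outer(outer(nts, nts, paste0), nts, paste0))
}

# Per-codon synonymous site count: at each position, the fraction of the 3
# single-nucleotide changes that preserve the amino acid; changes to stop
# codons count as nonsynonymous.
.syn_sites_table <- function() {
  if (!is.null(.codon_env$syn_sites)) return(.codon_env$syn_sites)
  code <- .genetic_code()
  nts <- c("A", "C", "G", "T")
  codons <- .all_codons()
  s <- stats::setNames(numeric(length(codons)), codons)
  for (cd in codons) {
    if (code[cd] == "*") { s[cd] <- NA_real_; next }
    tot <- 0
    for (pos in 1:3) {
      for (nt in setdiff(nts, substr(cd, pos, pos))) {
        mut <- cd
        substr(mut, pos, pos) <- nt
        if (code[mut] != "*" && code[mut] == code[cd]) tot <- tot + 1 / 3
      }
    }
    s[cd] <- tot
  }
  .codon_env$syn_sites <- s
  s
}

# Pathway-averaged synonymous/nonsynonymous difference counts for one codon
# pair; paths through stop codons are excluded (all-blocked pairs fall back
# to unrestricted averaging).
.codon_diffs <- function(c1, c2) {
  key <- paste0(c1, c2)
  if (is.null(.codon_env$diffs)) .codon_env$diffs <- list()
  cached <- .codon_env$diffs[[key]]
  if (!is.null(cached)) return(cached)
  if (is.null(.codon_env$code)) .codon_env$code <- .genetic_code()
  code <- .codon_env$code
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  out <- c(sd = 0, nd = 0)
  if (length(pos)) {
    perms <- if (length(pos) == 1L) list(pos) else {
      # all orderings of the changed positions
      pp <- list()
      gen <- function(prefix, rest) {
        if (!length(rest)) { pp[[length(pp) + 1L]] <<- prefix; return() }
        for (i in seq_along(rest)) gen(c(prefix, rest[i]), rest[-i])
      }
      gen(integer(0), pos)
      pp
    }
    walk <- function(order) {
      cur <- c1; sd <- 0; nd <- 0
      for (p in order) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (code[nxt] == "*") return(NULL)
        if (code[nxt] == code[cur]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd = sd, nd = nd)
    }
    res <- Filter(Negate(is.null), lapply(perms, walk))
    if (!length(res)) {
      # every path crosses a stop; average without the stop restriction
      res <- lapply(perms, function(order) {
        cur <- c1; sd <- 0; nd <- 0
        for (p in order) {
          nxt <- cur
          substr(nxt, p, p) <- substr(c2, p, p)
          if (code[nxt] != "*" && code[nxt] == code[cur]) sd <- sd + 1 else nd <- nd + 1
          cur <- nxt
        }
        c(sd = sd, nd = nd)
      })
    }
    out <- colMeans(do.call(rbind, res))
  }
  .codon_env$diffs[[key]] <- out
  out
}

.split_codons <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

#' Nei-Gojobori (1986) synonymous and nonsynonymous rate estimate
#'
#' @param seq_a,seq_b Codon-aligned nucleotide sequences (equal length,
#'   multiple of 3, no internal stop codons). Codons containing gaps or
#'   ambiguous bases are masked out pairwise.
#' @return List with site counts `S`, `N`, difference counts `Sd`, `Nd`,
#'   proportions `pS`, `pN`, Jukes-Cantor-corrected `Ks`, `Ka`, the number of
#'   compared codons `n_codons`, and a `saturated` flag (`pS >= 3/4` or
#'   `pN >= 3/4`; the corresponding estimate is NA).
#' @export
ng86_ks <- function(seq_a, seq_b) {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b)) stop("sequence length mismatch")
  if (nchar(seq_a) %% 3L != 0L) stop("length not a multiple of 3")
  ca <- .split_codons(seq_a); cb <- .split_codons(seq_b)
  clean <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  ca <- ca[clean]; cb <- cb[clean]
  if (!length(ca)) stop("no comparable codons after masking")
  code <- .genetic_code()
  internal <- seq_len(length(ca))
  if (any(code[ca[internal]] == "*") || any(code[cb[internal]] == "*")) {
    stop("internal stop codon")
  }
  syn <- .syn_sites_table()
  s_a <- sum(syn[ca]); s_b <- sum(syn[cb])
  S <- (s_a + s_b) / 2
  N <- 3 * length(ca) - S
  diffs <- mapply(function(x, y) .codon_diffs(x, y), ca, cb)
  Sd <- sum(diffs["sd", ]); Nd <- sum(diffs["nd", ])
  pS <- Sd / S; pN <- Nd / N
  jc <- function(p) {
    if (p >= 3 / 4) return(NA_real_)
    -3 / 4 * log(1 - 4 / 3 * p)
  }
  list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
       Ks = jc(pS), Ka = jc(pN), n_codons = length(ca),
       saturated = pS >= 3 / 4 || pN >= 3 / 4)
}

#' Convert a synonymous rate to a divergence time
#'
#' `T = Ks / (2 r)`, reported in Mya.
#'
#' @param ks Synonymous substitutions per synonymous site (>= 0).
#' @param r Substitution rate per site per year (default 6.5e-9).
#' @return Divergence time in Mya.
#' @export
ks_to_time <- function(ks, r = 6.5e-9) {
  if (any(ks < 0)) stop("negative Ks")
  if (r <= 0) stop("rate must be positive")
  ks / (2 * r) / 1e6
}

#' Copy-number summary across gene families
#'
#' @param members data.frame with columns `family`, `species`, `gene_id`
#'   (one row per member gene).
#' @param species Optional species to compute extrema for (default: totals
#'   over all species).
#' @return List with `counts` (family x species matrix), `family_totals`,
#'   `mean_copies` (mean family size in the chosen species/overall),
#'   `largest`, `smallest` (family names).
#' @export
family_copy_summary <- function(members, species = NULL) {
  if (!nrow(members)) stop("need >= 1 family member")
  counts <- table(members$family, members$species)
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  sel <- if (is.null(species)) rowSums(counts) else counts[, species]
  fam_order <- order(-sel, rownames(counts))
  list(counts = counts,
       family_totals = sel,
       mean_copies = mean(sel),
       largest = rownames(counts)[fam_order[1L]],
       smallest = rownames(counts)[fam_order[length(fam_order)]])
}
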