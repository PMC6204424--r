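# Phylostratigraphic gene-age assignment. Given a rooted, dated species tree
# and an ortholog presence/copy-number table for a focal species, each focal
# gene is dated by a Dollo-style rule: the deepest node on the root-to-focal
# path whose "other side" clade contains at least one species with the gene
# marks the origination; losses are not modelled. With m internal nodes on
# the focal path the strata are D(m+1) (evidence at the root; shared by all
# species) down to D2, plus D1 for focal-lineage-specific genes. Origination
# windows are half-open (age of the evidence node, age of the next deeper
# node], with the root stratum open-ended above.

#' Read a dated species tree from Newick
#'
#' @param path Newick file with branch lengths (an ultrametric, dated tree;
#'   node ages are recovered from the root-to-tip depths).
#' @return An `ape` `phylo` object.
#' @export
read_dated_tree <- function(path) {
  ape::read.tree(path)
}

.tree_node_ages <- function(tree) {
  depths <- ape::node.depth.edgelength(tree)
  max(depths) - depths
}

# Internal nodes on the root-to-focal-tip path, ordered root first.
.focal_path <- function(tree, focal) {
  tip <- match(focal, tree$tip.label)
  if (is.na(tip)) stop("focal species not in tree: ", focal)
  root <- length(tree$tip.label) + 1L
  path <- integer(0)
  node <- tip
  while (node != root) {
    node <- tree$edge[match(node, tree$edge[, 2L]), 1L]
    path <- c(node, path)
  }
  path
}

.clade_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  ape::extract.clade(tree, node)$tip.label
}

# Per focal-path node, the species in the clade splitting off at that node
# (i.e. not on the focal path).
.offpath_species <- function(tree, focal) {
  path <- .focal_path(tree, focal)
  tip <- match(focal, tree$tip.label)
  on_path <- c(path, tip)
  lapply(seq_along(path), function(j) {
    kids <- tree$edge[tree$edge[, 1L] == path[j], 2L]
    off <- kids[!kids %in% on_path]
    unlist(lapply(off, .clade_tips, tree = tree))
  })
}

#' Assign genes to phylostrata from an ortholog table and a dated tree
#'
#' @param table data.frame with a `gene_id` column and one copy-count column
#'   per species in the tree (0 = absent); the focal species count must be
#'   >= 1 for every gene.
#' @param tree Dated `phylo` tree covering exactly the table's species.
#' @param focal Focal species tip label.
#' @return data.frame with `gene_id`, `stratum` (`"D1"`..), `stratum_index`,
#'   `age_lower`, `age_upper` (Mya, window `(age_lower, age_upper]`; `Inf`
#'   upper for the root stratum), `single_copy`.
#' @export
assign_stratum <- function(table, tree, focal) {
  species <- setdiff(names(table), "gene_id")
  if (!setequal(species, tree$tip.label)) {
    stop("table species do not match tree tips")
  }
  counts <- as.matrix(table[, species, drop = FALSE])
  rownames(counts) <- table$gene_id
  if (any(counts[, focal] < 1)) stop("gene absent from focal species")

  ages <- .tree_node_ages(tree)
  path <- .focal_path(tree, focal)
  m <- length(path)
  offpath <- .offpath_species(tree, focal)
  node_ages <- ages[path]  # strictly decreasing root -> tip for a dated tree
  if (is.unsorted(rev(node_ages), strictly = TRUE)) {
    stop("focal-path node ages must strictly decrease from root to tip")
  }

  evidence <- vapply(seq_len(m), function(j) {
    rowSums(counts[, offpath[[j]], drop = FALSE] > 0) > 0
  }, logical(nrow(counts)))
  evidence <- matrix(evidence, nrow = nrow(counts))
  deepest <- apply(evidence, 1L, function(r) {
    w <- which(r)
    if (length(w)) w[1L] else NA_integer_
  })

  # evidence at path node j (root-first) -> stratum D(m+2-j); none -> D1
  idx <- ifelse(is.na(deepest), 1L, m + 2L - deepest)
  age_lower <- ifelse(is.na(deepest), 0, node_ages[deepest])
  age_upper <- ifelse(is.na(deepest), node_ages[m],
                      ifelse(deepest == 1L, Inf, node_ages[pmax(deepest - 1L, 1L)]))
  single <- apply(counts, 1L, function(r) all(r[r > 0] == 1))

  data.frame(gene_id = table$gene_id,
             stratum = paste0("D", idx),
             stratum_index = as.integer(idx),
             age_lower = unname(age_lower),
             age_upper = unname(age_upper),
             single_copy = unname(single),
             stringsAsFactors = FALSE)
}

#' Restrict a stratum assignment to single-copy ortholog groups
#'
#' Keeps genes whose ortholog group has exactly one copy in every species
#' where it is present (the D8s-D1s style subsets).
#'
#' @param assignment Output of [assign_stratum()].
#' @return The single-copy subset, with strata relabelled `"D1s"`, `"D2s"`, ...
#' @export
single_copy_subset <- function(assignment) {
  out <- assignment[assignment$single_copy, , drop = FALSE]
  out$stratum <- paste0(out$stratum, "s")
  out
}

#' Stratified AS / feature / expression summary
#'
#' Aggregates, per stratum: gene and AS-gene counts, AS percentage, events
#' per gene, AS-type proportions, means of any supplied per-gene features,
#' TE-gene fraction and mean maxTs. Also flags whether AS fraction and mean
#' maxTs change monotonically from the oldest to the youngest stratum.
#'
#' @param assignment Output of [assign_stratum()].
#' @param catalog An `event_catalog` (or NULL).
#' @param features Optional data.frame `gene_id` + numeric feature columns.
#' @param tsp Optional output of [ts_profile()].
#' @param te_flags Optional data.frame `gene_id`, `te` (logical).
#' @return List with `table` (one row per stratum, oldest first) and
#'   `monotone` (logical flags).
#' @export
stratified_summary <- function(assignment, catalog = NULL, features = NULL,
                               tsp = NULL, te_flags = NULL) {
  strata <- sort(unique(assignment$stratum_index), decreasing = TRUE)
  ev <- if (!is.null(catalog)) catalog$events else empty_events()
  ev_stratum <- assignment$stratum_index[match(ev$gene_id, assignment$gene_id)]
  rows <- lapply(strata, function(s) {
    genes <- assignment$gene_id[assignment$stratum_index == s]
    n <- length(genes)
    sev <- ev[!is.na(ev_stratum) & ev_stratum == s, , drop = FALSE]
    n_as <- length(unique(sev$gene_id))
    props <- if (nrow(sev)) {
      as.numeric(table(factor(sev$type, levels = .EVENT_TYPES))) / nrow(sev)
    } else rep(NA_real_, length(.EVENT_TYPES))
    row <- data.frame(stratum = paste0("D", s), stratum_index = s,
                      n_genes = n, n_as_genes = n_as,
                      as_percent = if (n) 100 * n_as / n else NA_real_,
                      n_events = nrow(sev),
                      events_per_gene = if (n) nrow(sev) / n else NA_real_,
                      stringsAsFactors = FALSE)
    names(props) <- paste0("prop_", .EVENT_TYPES)
    row <- cbind(row, as.data.frame(as.list(props)))
    if (!is.null(features)) {
      fsel <- features[features$gene_id %in% genes, , drop = FALSE]
      numcols <- names(features)[vapply(features, is.numeric, logical(1))]
      for (cc in setdiff(numcols, "gene_id")) {
        row[[paste0("mean_", cc)]] <- if (nrow(fsel)) {
          mean(fsel[[cc]], na.rm = TRUE)
        } else NA_real_
      }
    }
    if (!is.null(te_flags)) {
      tsel <- te_flags$te[te_flags$gene_id %in% genes]
      row$te_fraction <- if (length(tsel)) mean(tsel) else NA_real_
    }
    if (!is.null(tsp)) {
      msel <- tsp$maxTs[tsp$gene_id %in% genes]
      row$mean_maxTs <- if (any(!is.na(msel))) mean(msel, na.rm = TRUE) else NA_real_
    }
    row
  })
  tab <- do.call(rbind, rows)
  mono_dec <- function(x) {
    x <- x[!is.na(x)]
    length(x) >= 2L && !is.unsorted(rev(x))
  }
  mono_inc <- function(x) {
    x <- x[!is.na(x)]
    length(x) >= 2L && !is.unsorted(x)
  }
  monotone <- list(
    as_percent_nonincreasing_old_to_young = mono_dec(tab$as_percent),
    mean_maxTs_monotone = if (!is.null(tsp)) {
      mono_dec(tab$mean_maxTs) || mono_inc(tab$mean_maxTs)
    } else NA)
  list(table = tab, monotone = monotone)
}

#' Fold ratio between two proportions
#'
#' @param p_a,p_b Proportions or percentages on the same scale (`p_b > 0`).
#' @param digits Decimal places for the ratio (default 1).
#' @return `round(p_a / p_b, digits)`.
#' @export
proportion_fold <- function(p_a, p_b, digits = 1) {
  if (p_b <= 0) stop("denominator proportion must be positive")
  round(p_a / p_b, digits)
}

#' TE insertion versus genes: flags, lengths and intron-position profile
#'
#' A gene is TE-flagged if any TE interval intersects its span. Per-intron
#' TE overlap is binned along the normalised gene body (5' to 3'; positions
#' are flipped on minus-strand genes).
#'
#' @param genes data.frame `gene_id`, `chrom`, `strand`, `start`, `end`
#'   (0-based half-open).
#' @param te data.frame `chrom`, `start`, `end` (0-based half-open), as from
#'   [read_bed()].
#' @param introns Optional data.frame `gene_id`, `chrom`, `start`, `end` for
#'   the positional histogram.
#' @param n_bins Number of gene-body bins (default 10).
#' @return List with `gene_flags` (`gene_id`, `te`, `te_length`),
#'   `total_te_length` (summed per-gene inserted length) and `intron_hist`
#'   (per-bin TE-overlap length; NULL without `introns`).
#' @export
te_gene_overlap <- function(genes, te, introns = NULL, n_bins = 10L) {
  gr_g <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end))
  gr_t <- GenomicRanges::reduce(GenomicRanges::GRanges(
    te$chrom, IRanges::IRanges(te$start + 1L, te$end)))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gr_g, gr_t))
  w <- suppressWarnings(IRanges::width(IRanges::pintersect(
    gr_g[S4Vectors::queryHits(hits)], gr_t[S4Vectors::subjectHits(hits)])))
  len <- rep(0, nrow(genes))
  if (length(w)) {
    agg <- tapply(w, S4Vectors::queryHits(hits), sum)
    len[as.integer(names(agg))] <- as.numeric(agg)
  }
  flags <- data.frame(gene_id = genes$gene_id, te = len > 0, te_length = len,
                      stringsAsFactors = FALSE)
  hist <- NULL
  if (!is.null(introns) && nrow(introns)) {
    gr_i <- GenomicRanges::GRanges(
      introns$chrom, IRanges::IRanges(introns$start + 1L, introns$end))
    ih <- GenomicRanges::findOverlaps(gr_i, gr_t)
    iw <- IRanges::width(IRanges::pintersect(
      gr_i[S4Vectors::queryHits(ih)], gr_t[S4Vectors::subjectHits(ih)]))
    ov <- rep(0, nrow(introns))
    if (length(iw)) {
      agg <- tapply(iw, S4Vectors::queryHits(ih), sum)
      ov[as.integer(names(agg))] <- as.numeric(agg)
    }
    gi <- match(introns$gene_id, genes$gene_id)
    mid <- (introns$start + introns$end) / 2
    rel <- (mid - genes$start[gi]) / (genes$end[gi] - genes$start[gi])
    minus <- genes$strand[gi] == "-"
    rel[minus] <- 1 - rel[minus]
    bin <- pmin(pmax(ceiling(rel * n_bins), 1L), n_bins)
    hist <- vapply(seq_len(n_bins), function(b) sum(ov[bin == b]), numeric(1))
    names(hist) <- sprintf("bin%02d", seq_len(n_bins))
  }
  list(gene_flags = flags, total_te_length = sum(len), intron_hist = hist)
}

#' Per-gene structural features of an annotation
#'
#' @param ann An `annotation_set`.
#' @return data.frame with `gene_id`, `chrom`, `strand`, `start`, `end`,
#'   `gene_length`, `n_transcripts`, `mean_exons` (exons per isoform),
#'   `mean_exon_length`, `mean_intron_length`.
#' @export
gene_features <- function(ann) {
  loci <- gene_loci(ann)
  rows <- lapply(names(loci), function(g) {
    txs <- loci[[g]]
    ex_n <- vapply(txs, function(t) nrow(t$exons), integer(1))
    ex_len <- unlist(lapply(txs, function(t) t$exons[, 2L] - t$exons[, 1L]))
    introns <- lapply(txs, intron_chain)
    in_len <- unlist(lapply(introns, function(m) m[, 2L] - m[, 1L]))
    start <- min(vapply(txs, function(t) t$exons[1L, 1L], numeric(1)))
    end <- max(vapply(txs, function(t) t$exons[nrow(t$exons), 2L], numeric(1)))
    data.frame(gene_id = g, chrom = txs[[1L]]$chrom, strand = txs[[1L]]$strand,
               start = start, end = end, gene_length = end - start,
               n_transcripts = length(txs), mean_exons = mean(ex_n),
               mean_exon_length = mean(ex_len),
               mean_intron_length = if (length(in_len)) mean(in_len) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Correlation statistics for stratified trends
#'
#' @param x,y Numeric vectors (>= 3 points), e.g. stratum index or age versus
#'   a stratum-mean feature.
#' @return List with `pearson_r`, `r_squared`, `pearson_p`, `spearman_rho`,
#'   `spearman_p`; all NA (R squared included) when either input has zero
#'   variance.
#' @export
trend_stats <- function(x, y) {
  if (length(x) < 3L || length(x) != length(y)) stop("need >= 3 paired points")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    return(list(pearson_r = NA_real_, r_squared = NA_real_,
                pearson_p = NA_real_, spearman_rho = NA_real_,
                spearman_p = NA_real_))
  }
  pe <- suppressWarnings(stats::cor.test(x, y, method = "pearson"))
  sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(pearson_r = unname(pe$estimate), r_squared = unname(pe$estimate)^2,
       pearson_p = pe$p.value, spearman_rho = unname(sp$estimate),
       spearman_p = sp$p.value)
}

#' Mann-Whitney U test
#'
#' Exact enumeration for small samples (both n <= 20 by default), normal
#' approximation with continuity and tie correction otherwise; U is reported
#' for the first sample.
#'
#' @param a,b Numeric samples.
#' @param exact Force exact (TRUE) or approximate (FALSE); default chooses by
#'   sample size.
#' @return List with `U` and `p_value`.
#' @export
mann_whitney_u <- function(a, b, exact = NULL) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  if (is.null(exact)) exact <- length(a) <= 20L && length(b) <= 20L
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  list(U = unname(wt$statistic), p_value = wt$p.value)
}

#' Chi-square goodness-of-fit test
#'
#' @param observed Observed counts.
#' @param expected Expected counts (rescaled to probabilities internally).
#' @return List with `statistic`, `df`, `p_value`.
#' @export
chi_square_gof <- function(observed, expected) {
  ct <- suppressWarnings(stats::chisq.test(observed,
                                           p = expected / sum(expected)))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value)
}

#' Chi-square homogeneity test over a contingency matrix
#'
#' E.g. AS-type counts (columns) across strata (rows).
#'
#' @param counts Matrix of counts.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
chi_square_homogeneity <- function(counts) {
  ct <- suppressWarnings(stats::chisq.test(counts))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value)
}
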