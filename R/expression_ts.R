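# Fractional tissue specificity. For a gene with expression x_1..x_n over n
# tissues, Ts_i = x_i / sum(x) and maxTs = max_i Ts_i. maxTs = 1 means all
# expression in one tissue (maximal specificity); maxTs = 1/n means perfectly
# uniform (constitutive) expression. The `orientation` switch only relabels:
# some reports use the opposite verbal convention.

#' Read a gene x tissue expression matrix from TSV
#'
#' First column = gene ids, remaining columns = tissues; '#' comment lines
#' are skipped.
#'
#' @param path Input path.
#' @return Numeric matrix with gene rownames and tissue colnames.
#' @export
read_expression <- function(path) {
  first <- readLines(path, n = 1L)
  df <- if (startsWith(first, "#")) {
    read_tsv_with_header(path)
  } else {
    utils::read.table(path, header = TRUE, sep = "\t",
                      check.names = FALSE, stringsAsFactors = FALSE)
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}

#' Per-gene tissue-specificity profiles (Ts and maxTs)
#'
#' @param expr Non-negative numeric matrix, genes x tissues (>= 2 tissues).
#' @param specific_min maxTs at or above which a gene is labelled
#'   `tissue_specific` (default 0.8).
#' @param constitutive_max maxTs at or below which a gene is labelled
#'   `constitutive`; default `2/n_tissues`.
#' @param min_total Minimum row sum for a gene to count as expressed
#'   (default 0, i.e. any positive expression).
#' @param orientation `"specific_high"` (fractional definition: maxTs = 1 is
#'   tissue-specific; the default) or `"specific_low"` to swap the
#'   tissue_specific/constitutive label names for comparability with reports
#'   using the opposite verbal convention.
#' @return data.frame with `gene_id`, `total`, `expressed`, `maxTs`,
#'   `top_tissue`, `label`; the full Ts matrix is attached as attribute
#'   `"ts"` (rows of unexpressed genes are NA).
#' @export
ts_profile <- function(expr, specific_min = 0.8, constitutive_max = NULL,
                       min_total = 0, orientation = c("specific_high",
                                                      "specific_low")) {
  orientation <- match.arg(orientation)
  expr <- as.matrix(expr)
  if (ncol(expr) < 2L) stop("need >= 2 tissues")
  if (any(expr < 0)) stop("negative expression value")
  if (is.null(constitutive_max)) constitutive_max <- 2 / ncol(expr)
  totals <- rowSums(expr)
  expressed <- totals > min_total & totals > 0
  ts <- expr / totals  # rows with total 0 become NaN
  ts[!expressed, ] <- NA_real_
  maxts <- apply(ts, 1L, function(r) if (all(is.na(r))) NA_real_ else max(r))
  top <- colnames(expr)[apply(expr, 1L, which.max)]
  top[!expressed] <- NA_character_
  label <- ifelse(!expressed, NA_character_,
                  ifelse(maxts >= specific_min, "tissue_specific",
                         ifelse(maxts <= constitutive_max, "constitutive",
                                "intermediate")))
  if (orientation == "specific_low") {
    label <- c(tissue_specific = "constitutive",
               constitutive = "tissue_specific",
               intermediate = "intermediate")[label]
  }
  out <- data.frame(gene_id = rownames(expr), total = totals,
                    expressed = expressed, maxTs = maxts, top_tissue = top,
                    label = unname(label), stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "ts") <- ts
  attr(out, "orientation") <- orientation
  out
}

#' Specificity trend across age strata
#'
#' Summarises maxTs per stratum and correlates stratum age with mean maxTs
#' (Pearson r, R squared, Spearman rho). Strata without expressed genes are
#' dropped with a warning; a flat trend (zero variance in the means) is
#' reported as R squared 0 with NA correlation.
#'
#' @param maxts Numeric vector of per-gene maxTs (NA = unexpressed).
#' @param stratum Stratum label per gene.
#' @param stratum_ages Named numeric vector: representative age per stratum
#'   (e.g. the origination-window midpoint or upper bound, in Mya).
#' @return List with `per_stratum` (data.frame) and `trend`
#'   (pearson_r/r_squared/p values, spearman_rho).
#' @export
specificity_trend <- function(maxts, stratum, stratum_ages) {
  keep <- !is.na(maxts)
  if (!all(keep)) { maxts <- maxts[keep]; stratum <- stratum[keep] }
  means <- tapply(maxts, stratum, mean)
  n <- tapply(maxts, stratum, length)
  missing_strata <- setdiff(names(stratum_ages), names(means))
  if (length(missing_strata)) {
    warning("strata without expressed genes dropped: ",
            paste(missing_strata, collapse = ", "))
  }
  strata <- intersect(names(stratum_ages), names(means))
  if (length(strata) < 2L) stop("need >= 2 strata with expressed genes")
  per <- data.frame(stratum = strata, age = unname(stratum_ages[strata]),
                    n = as.integer(n[strata]), mean_maxTs = unname(means[strata]),
                    stringsAsFactors = FALSE)
  x <- per$age; y <- per$mean_maxTs
  if (stats::var(y) == 0 || stats::var(x) == 0) {
    trend <- list(pearson_r = NA_real_, r_squared = 0, pearson_p = NA_real_,
                  spearman_rho = NA_real_, spearman_p = NA_real_)
  } else if (length(strata) == 2L) {
    # two points define a perfect line; correlation magnitude is 1 and no
    # p-value is meaningful
    slope <- sign(diff(y)) * sign(diff(x))
    trend <- list(pearson_r = slope, r_squared = 1, pearson_p = NA_real_,
                  spearman_rho = slope, spearman_p = NA_real_)
  } else {
    pe <- suppressWarnings(stats::cor.test(x, y, method = "pearson"))
    sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    trend <- list(pearson_r = unname(pe$estimate),
                  r_squared = unname(pe$estimate)^2,
                  pearson_p = pe$p.value,
                  spearman_rho = unname(sp$estimate),
                  spearman_p = sp$p.value)
  }
  list(per_stratum = per, trend = trend)
}
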