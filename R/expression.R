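## ---------------------------------------------------------------------------
## Expression integration: TPM/FPKM normalization, expression filters
## (TPM > 100 embryo stages, FPKM > 1 tissues), specificity and overlap,
## virus-responsive calls, and cis (<= 10 kb) / trans (|R| > 0.85,
## p < 0.01) association.
## ---------------------------------------------------------------------------

#' Normalize a count matrix to TPM or FPKM
#'
#' FPKM = count x 1e9 / (length x library_size);
#' TPM_i = rate_i x 1e6 / sum(rates) with rate_i = count_i / length_i.
#' TPM columns sum to 1e6.
#'
#' @param counts Numeric matrix, features x samples.
#' @param lengths Feature lengths in bp (named or in row order; > 0).
#' @param mode "TPM" or "FPKM".
#' @param library_sizes Optional per-sample library sizes for FPKM;
#'   default `colSums(counts)` (> 0 required).
#' @return Normalized matrix with the same dimnames.
#' @export
normalize_counts <- function(counts, lengths, mode = c("TPM", "FPKM"),
                             library_sizes = NULL) {
  mode <- match.arg(mode)
  counts <- as.matrix(counts)
  if (!is.null(names(lengths)) && !is.null(rownames(counts))) {
    lengths <- lengths[rownames(counts)]
  }
  if (any(is.na(lengths)) || any(lengths <= 0)) {
    stop("feature lengths must be > 0 for all features")
  }
  if (mode == "FPKM") {
    if (is.null(library_sizes)) library_sizes <- colSums(counts)
    if (any(library_sizes <= 0)) stop("library size must be > 0 per sample")
    sweep(counts / lengths, 2, library_sizes, "/") * 1e9
  } else {
    rates <- counts / lengths
    sums <- colSums(rates)
    if (any(sums <= 0)) stop("library size must be > 0 per sample")
    sweep(rates, 2, sums, "/") * 1e6
  }
}

## Mean per condition over replicate columns.
condition_means <- function(mat, conditions) {
  stopifnot(ncol(mat) == length(conditions))
  conds <- unique(conditions)
  out <- sapply(conds, function(cn) {
    rowMeans(mat[, conditions == cn, drop = FALSE])
  })
  colnames(out) <- conds
  out
}

#' Per-condition expressed feature sets
#'
#' A feature belongs to a condition's set when its replicate-mean
#' normalized value exceeds the threshold in that condition.
#'
#' @param mat Normalized matrix (features x samples).
#' @param conditions Condition label per sample column.
#' @param threshold Expression threshold (strictly greater-than).
#' @return Named list of feature-id character vectors, one per condition.
#' @export
expressed_set <- function(mat, conditions, threshold) {
  means <- condition_means(mat, conditions)
  out <- lapply(colnames(means), function(cn) {
    rownames(means)[means[, cn] > threshold]
  })
  names(out) <- colnames(means)
  out
}

#' Condition-specific features and overlap counts
#'
#' `specific[[c]]` holds the features expressed in condition c and no
#' other; `overlaps` is the full intersection table over all non-empty
#' condition combinations.
#'
#' @param sets Named list of feature sets (>= 2 conditions).
#' @return List with `specific` (named list), `overlaps` (data.frame:
#'   combination, size) and `union_size`.
#' @export
specificity_and_overlap <- function(sets) {
  if (length(sets) < 2) stop("need at least 2 conditions")
  conds <- names(sets)
  specific <- lapply(conds, function(cn) {
    setdiff(sets[[cn]], unique(unlist(sets[setdiff(conds, cn)])))
  })
  names(specific) <- conds
  combos <- list()
  for (k in seq_along(conds)) {
    cmb <- utils::combn(conds, k, simplify = FALSE)
    for (cc in cmb) {
      inter <- Reduce(intersect, sets[cc])
      combos[[length(combos) + 1L]] <- data.frame(
        combination = paste(cc, collapse = "&"),
        k = k, size = length(inter), stringsAsFactors = FALSE)
    }
  }
  list(specific = specific, overlaps = do.call(rbind, combos),
       union_size = length(unique(unlist(sets))))
}

#' Call virus-responsive (upregulated) features
#'
#' A feature is flagged when its infected replicate-mean exceeds
#' `min_expr` and log2((infected + pseudocount) / (control + pseudocount))
#' is at least `min_log2fc`. An explicit threshold rule stands in for
#' model-based differential testing; all parameters are exposed.
#'
#' @param control,infected Normalized matrices (features x replicates)
#'   with matching rownames.
#' @param min_expr Minimum infected mean (same units as the matrices).
#' @param min_log2fc Minimum log2 fold change (default 1).
#' @param pseudocount Added to both means (default 1).
#' @return data.frame per feature: control_mean, infected_mean, log2fc,
#'   responsive.
#' @export
virus_responsive <- function(control, infected, min_expr = 1,
                             min_log2fc = 1, pseudocount = 1) {
  if (ncol(control) == 0 || ncol(infected) == 0) stop("condition size 0")
  stopifnot(identical(rownames(control), rownames(infected)))
  cm <- rowMeans(control); im <- rowMeans(infected)
  lfc <- log2((im + pseudocount) / (cm + pseudocount))
  data.frame(feature = rownames(control), control_mean = cm,
             infected_mean = im, log2fc = lfc,
             responsive = im > min_expr & lfc >= min_log2fc,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Find genes adjacent to elements (cis candidates)
#'
#' Reports every (element, gene) pair on the same chromosome whose
#' interval gap is at most `window` bp (overlapping intervals have
#' distance 0).
#'
#' @param elements data.frame with element_id, chrom, start, end
#'   (0-based half-open).
#' @param genes data.frame with gene_id, chrom, start, end.
#' @param window Maximum gap in bp (default 10000).
#' @return data.frame: element_id, gene_id, distance.
#' @export
cis_neighbors <- function(elements, genes, window = 10000) {
  empty <- data.frame(element_id = character(0), gene_id = character(0),
                      distance = numeric(0), stringsAsFactors = FALSE)
  if (nrow(elements) == 0 || nrow(genes) == 0) return(empty)
  rows <- list()
  for (cn in intersect(unique(elements$chrom), unique(genes$chrom))) {
    e <- elements[elements$chrom == cn, ]
    g <- genes[genes$chrom == cn, ]
    ir_e <- IRanges::IRanges(start = e$start + 1L, end = e$end)
    ir_g <- IRanges::IRanges(start = g$start + 1L, end = g$end)
    hits <- IRanges::findOverlaps(ir_e, ir_g, maxgap = window)
    if (length(hits) == 0) next
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    d <- IRanges::distance(ir_e[qi], ir_g[si])
    rows[[length(rows) + 1L]] <- data.frame(
      element_id = e$element_id[qi], gene_id = g$gene_id[si],
      distance = as.numeric(d), stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out <- out[out$distance <= window, , drop = FALSE]
  out <- out[order(out$element_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Trans-acting association by expression correlation
#'
#' Tests every (element, gene) pair across shared samples; a pair is
#' retained when |Pearson R| exceeds `r_min` and the two-sided correlation
#' t-test p-value is below `p_max`. Zero-variance features are skipped
#' with a warning. A Benjamini-Hochberg column is reported alongside the
#' raw p-values.
#'
#' @param erv_expr,gene_expr Normalized matrices (features x samples,
#'   same sample columns, >= 3 samples).
#' @param r_min Absolute correlation floor (default 0.85).
#' @param p_max Raw p-value ceiling (default 0.01).
#' @return data.frame of retained pairs: element_id, gene_id, R, p,
#'   p_bh (BH across all tested pairs).
#' @export
trans_partners <- function(erv_expr, gene_expr, r_min = 0.85, p_max = 0.01) {
  if (ncol(erv_expr) != ncol(gene_expr)) stop("sample columns must match")
  if (ncol(erv_expr) < 3) stop("need >= 3 shared samples")
  ok_e <- apply(erv_expr, 1, stats::sd) > 0
  ok_g <- apply(gene_expr, 1, stats::sd) > 0
  if (any(!ok_e) || any(!ok_g)) {
    warning("skipping ", sum(!ok_e) + sum(!ok_g), " zero-variance feature(s)")
  }
  e <- erv_expr[ok_e, , drop = FALSE]; g <- gene_expr[ok_g, , drop = FALSE]
  if (nrow(e) == 0 || nrow(g) == 0) {
    return(data.frame(element_id = character(0), gene_id = character(0),
                      R = numeric(0), p = numeric(0), p_bh = numeric(0),
                      stringsAsFactors = FALSE))
  }
  n <- ncol(e)
  R <- stats::cor(t(e), t(g))                 # elements x genes
  tstat <- R * sqrt((n - 2) / pmax(1e-300, 1 - R^2))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[abs(R) >= 1] <- 0
  p_bh <- matrix(stats::p.adjust(p, method = "BH"), nrow = nrow(p))
  sel <- which(abs(R) > r_min & p < p_max, arr.ind = TRUE)
  out <- data.frame(element_id = rownames(e)[sel[, 1]],
                    gene_id = rownames(g)[sel[, 2]],
                    R = R[sel], p = p[sel], p_bh = p_bh[sel],
                    stringsAsFactors = FALSE)
  out[order(out$element_id, out$gene_id), , drop = FALSE]
}
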