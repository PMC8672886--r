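## ---------------------------------------------------------------------------
## Chromosomal distribution statistics: densities, expected counts under a
## uniform genome-wide density, two-cell chi-square enrichment per
## chromosome, count-length / count-GC correlations, and windowed density
## tracks.
## ---------------------------------------------------------------------------

#' Per-chromosome element density
#'
#' @param detected Integer vector of element counts.
#' @param lengths Chromosome lengths in Mb (> 0).
#' @return Densities in elements/Mb (full precision; round only for
#'   presentation).
#' @export
chromosome_density <- function(detected, lengths) {
  if (any(lengths <= 0)) stop("lengths must be > 0")
  detected / lengths
}

#' Expected element counts under uniform density
#'
#' expected_i = length_i x genome-wide density.
#'
#' @param lengths Chromosome lengths (Mb).
#' @param genomewide_density Genome-wide density (elements/Mb, >= 0).
#' @return Expected counts (real).
#' @export
expected_counts <- function(lengths, genomewide_density) {
  if (genomewide_density < 0) stop("density must be >= 0")
  lengths * genomewide_density
}

#' Two-cell chi-square enrichment test for one chromosome
#'
#' Goodness-of-fit on the cells (on-chromosome, off-chromosome):
#' chi2 = (O-E)^2/E + ((T-O)-(T-E))^2/(T-E), 1 df, where T is the
#' genome-wide element total.
#'
#' @param observed Observed count on the chromosome.
#' @param expected Expected count (0 < expected < total).
#' @param total Genome-wide total count.
#' @param alpha Significance level for the direction call (default 0.01).
#' @return List with `chi2`, `p`, `direction`
#'   ("enriched"/"depleted"/"none").
#' @export
chisq_enrichment <- function(observed, expected, total, alpha = 0.01) {
  if (expected <= 0) stop("expected must be > 0")
  if (expected >= total) stop("expected must be < total")
  if (observed > total) stop("observed cannot exceed total")
  chi2 <- (observed - expected)^2 / expected +
    ((total - observed) - (total - expected))^2 / (total - expected)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  direction <- if (p < alpha) {
    if (observed > expected) "enriched" else "depleted"
  } else "none"
  list(chi2 = chi2, p = p, direction = direction)
}

#' Full per-chromosome distribution table
#'
#' Computes density, expected count, chi-square, p-value (raw plus a
#' Bonferroni column for transparency) and enrichment direction for every
#' chromosome.
#'
#' @param chrom Chromosome names.
#' @param lengths Lengths (Mb).
#' @param detected Detected counts.
#' @param gc GC percentages (optional, carried through).
#' @param total Genome-wide element total; default `sum(detected)`. The
#'   published total may exceed the per-chromosome sum when some elements
#'   sit on unplaced scaffolds.
#' @param genomewide_density Genome-wide density (elements/Mb); default
#'   `total / sum(lengths)`.
#' @param expected Optional externally supplied expected counts (e.g. the
#'   printed values of a published table); overrides the density product.
#' @param alpha Significance level for direction calls.
#' @return data.frame, one row per chromosome.
#' @export
chromosome_stats <- function(chrom, lengths, detected, gc = NA,
                             total = sum(detected),
                             genomewide_density = total / sum(lengths),
                             expected = NULL, alpha = 0.01) {
  dens <- chromosome_density(detected, lengths)
  if (is.null(expected)) {
    expected <- expected_counts(lengths, genomewide_density)
  }
  tests <- lapply(seq_along(chrom), function(i) {
    ## degenerate two-cell table (e.g. a single-chromosome genome where
    ## expected == total): no off-chromosome cell, test undefined
    if (expected[i] <= 0 || expected[i] >= total) {
      list(chi2 = NA_real_, p = NA_real_, direction = "none")
    } else {
      chisq_enrichment(detected[i], expected[i], total, alpha)
    }
  })
  p <- vapply(tests, `[[`, numeric(1), "p")
  data.frame(chrom = chrom, length_mb = lengths, gc_percent = gc,
             detected = detected, expected = expected, density = dens,
             chi2 = vapply(tests, `[[`, numeric(1), "chi2"),
             p = p, p_bonferroni = pmin(1, p * length(chrom)),
             direction = vapply(tests, `[[`, character(1), "direction"),
             stringsAsFactors = FALSE)
}

#' Correlation of element counts with chromosome length and GC
#'
#' Pearson product-moment correlations with two-sided t-test p-values.
#'
#' @param stats data.frame with `detected`, `length_mb` and optionally
#'   `gc_percent` columns (>= 3 rows).
#' @return List with `length` and `gc` components, each `(R, p)`.
#' @export
count_length_gc_correlation <- function(stats) {
  if (nrow(stats) < 3) stop("need at least 3 chromosomes")
  corr <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero-variance column")
    ct <- stats::cor.test(x, y, method = "pearson")
    list(R = unname(ct$estimate), p = ct$p.value)
  }
  out <- list(length = corr(stats$detected, stats$length_mb))
  if ("gc_percent" %in% names(stats) && !all(is.na(stats$gc_percent))) {
    out$gc <- corr(stats$detected, stats$gc_percent)
  }
  out
}

#' Windowed feature density track
#'
#' Counts features per fixed-size window; a feature is counted in every
#' window it overlaps.
#'
#' @param starts,ends Feature intervals (0-based half-open).
#' @param chrom_length Chromosome length (bp).
#' @param window Window size (bp, > 0).
#' @return data.frame with `window_start`, `window_end`, `count`; track
#'   length is `ceiling(chrom_length / window)`.
#' @export
windowed_feature_density <- function(starts, ends, chrom_length, window) {
  if (window <= 0) stop("window must be > 0")
  n_win <- ceiling(chrom_length / window)
  counts <- integer(n_win)
  if (length(starts) > 0) {
    first <- pmax(0L, floor(starts / window)) + 1L
    last <- pmin(n_win - 1L, floor((ends - 1L) / window)) + 1L
    for (i in seq_along(starts)) {
      if (last[i] >= first[i]) {
        idx <- first[i]:last[i]
        counts[idx] <- counts[idx] + 1L
      }
    }
  }
  data.frame(window_start = (seq_len(n_win) - 1L) * window,
             window_end = pmin(seq_len(n_win) * window, chrom_length),
             count = counts)
}

#' Read the packaged chromosome statistics fixture
#'
#' A published 25-chromosome survey table (length, GC, detected and
#' expected counts per chromosome) shipped as TSV for regression tests.
#' The genome-wide totals are carried in attributes `total` and
#' `genomewide_density`.
#'
#' @param path TSV path; default the packaged fixture.
#' @return data.frame with columns chrom, length_mb, gc_percent, detected,
#'   expected.
#' @export
read_chrom_stats_fixture <- function(path = system.file(
  "extdata", "chrom_survey_table.tsv", package = "ervatlas")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character"))
  attr(df, "total") <- 3315L
  attr(df, "genomewide_density") <- 2.31
  df
}
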