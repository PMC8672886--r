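## ---------------------------------------------------------------------------
## Molecular dating from 5'/3' LTR divergence: T = D / (2R), with D the
## per-site divergence of the two LTRs (p-distance by default, Jukes-Cantor
## optionally) and R the neutral substitution rate per site per year.
## ---------------------------------------------------------------------------

#' Globally align two LTR sequences
#'
#' Needleman-Wunsch global alignment with affine gaps. Default scoring:
#' match +1, mismatch -1, gap of length L costs 5 + L (opening 5,
#' extension 1 per base).
#'
#' @param a,b Nucleotide strings (non-empty).
#' @param match,mismatch,gap_opening,gap_extension Scoring parameters.
#' @return List with aligned strings `a`, `b` (equal length, `-` for gaps)
#'   and the alignment `score`.
#' @export
align_ltr_pair <- function(a, b, match = 1, mismatch = -1,
                           gap_opening = 5, gap_extension = 1) {
  if (is.null(a) || is.null(b) || nchar(a) == 0 || nchar(b) == 0) {
    stop("empty sequence")
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = mat, gapOpening = gap_opening,
    gapExtension = gap_extension)
  list(a = as.character(Biostrings::alignedPattern(aln)[[1]]),
       b = as.character(Biostrings::alignedSubject(aln)[[1]]),
       score = Biostrings::score(aln))
}

#' Per-site divergence of an aligned LTR pair
#'
#' Gapped columns are excluded from both numerator and denominator.
#' `model = "p"` gives the proportion of differing ungapped columns;
#' `model = "JC"` applies the Jukes-Cantor correction
#' `-(3/4) log(1 - 4p/3)`.
#'
#' @param alignment List as returned by [align_ltr_pair()].
#' @param model "p" or "JC".
#' @return Divergence D (substitutions/site). Under JC, `NaN` with a
#'   warning when p >= 0.75 (saturation).
#' @export
ltr_divergence <- function(alignment, model = c("p", "JC")) {
  model <- match.arg(model)
  xa <- seq_to_chars(alignment$a); xb <- seq_to_chars(alignment$b)
  ungapped <- xa != "-" & xb != "-"
  n <- sum(ungapped)
  if (n < 1) stop("alignment has no ungapped columns")
  p <- sum(xa[ungapped] != xb[ungapped]) / n
  if (model == "p") return(p)
  if (p >= 0.75) {
    warning("p >= 0.75: Jukes-Cantor distance undefined (saturated)")
    return(NaN)
  }
  -0.75 * log(1 - 4 * p / 3)
}

#' Insertion time from divergence
#'
#' T = D / (2R), expressed in millions of years: each LTR accumulates
#' divergence independently after integration, so the pair diverges at 2R.
#'
#' @param D Divergence (substitutions/site, >= 0).
#' @param rate Substitution rate per site per year (default 1.46e-8).
#' @return Insertion time in Mya.
#' @export
insertion_time <- function(D, rate = DEFAULT_RATE) {
  if (any(D < 0, na.rm = TRUE)) stop("D must be >= 0")
  if (rate <= 0) stop("rate must be > 0")
  D / (2 * rate) / 1e6
}

#' Date a cohort of elements from their LTR pairs
#'
#' Computes per-element divergence and insertion time, flags eligibility
#' (score and LTR-length filters; the length filter applies to the shorter
#' of the two LTRs), and summarizes eligible elements: fraction with
#' identical LTRs, medians per LTR-length bin, per structure category and
#' per class, and counts per age bin.
#'
#' @param elements Element table with LTR interval columns, `score`,
#'   and optionally `structure_category` / `class_label`.
#' @param genome Named character vector of chromosome sequences (LTR
#'   sequences are extracted from it), or NULL if `ltr5_seq` / `ltr3_seq`
#'   columns are present.
#' @param rate Substitution rate (subs/site/year).
#' @param model Divergence model, "p" (default) or "JC".
#' @param min_score Eligibility: score must exceed this (default 300).
#' @param min_ltr Eligibility: shorter LTR must exceed this length in bp
#'   (default 100).
#' @param ltr_bins Breaks (bp) for LTR-length binning.
#' @param age_bin_width Width of age bins in Mya (default 1).
#' @return List with `results` (per-element table: element_id, D, T_mya,
#'   ltr_length, model, eligible), `identical_fraction`, `by_ltr_bin`,
#'   `by_structure`, `by_class`, `age_histogram`.
#' @export
dating_cohort <- function(elements, genome = NULL, rate = DEFAULT_RATE,
                          model = c("p", "JC"), min_score = 300,
                          min_ltr = 100,
                          ltr_bins = c(100, 200, 400, 600, 800, Inf),
                          age_bin_width = 1) {
  model <- match.arg(model)
  n <- nrow(elements)
  D <- rep(NA_real_, n); Lmin <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    el <- elements[i, ]
    if (is.na(el$ltr5_start) || is.na(el$ltr3_start)) next
    if (!is.null(genome)) {
      s <- genome[[el$chrom]]
      a <- substr(s, el$ltr5_start + 1L, el$ltr5_end)
      b <- substr(s, el$ltr3_start + 1L, el$ltr3_end)
    } else {
      a <- el$ltr5_seq; b <- el$ltr3_seq
    }
    Lmin[i] <- min(nchar(a), nchar(b))
    aln <- if (nchar(a) == nchar(b)) {
      list(a = a, b = b)  # equal length: column-wise comparison
    } else {
      align_ltr_pair(a, b)
    }
    D[i] <- ltr_divergence(aln, model)
  }
  T_mya <- ifelse(is.na(D), NA_real_, D / (2 * rate) / 1e6)
  score <- if ("score" %in% names(elements)) elements$score else rep(Inf, n)
  eligible <- !is.na(D) & score > min_score & Lmin > min_ltr
  res <- data.frame(element_id = elements$element_id, D = D, T_mya = T_mya,
                    ltr_length = Lmin, model = model, eligible = eligible,
                    stringsAsFactors = FALSE)
  el_res <- res[res$eligible, , drop = FALSE]
  summarize_by <- function(groups) {
    if (is.null(groups) || nrow(el_res) == 0) return(NULL)
    agg <- stats::aggregate(el_res$T_mya, by = list(group = groups),
                            FUN = stats::median)
    names(agg) <- c("group", "median_T_mya")
    agg$n <- as.integer(table(groups)[as.character(agg$group)])
    agg
  }
  by_ltr <- summarize_by(if (nrow(el_res)) {
    cut(el_res$ltr_length, breaks = ltr_bins, right = FALSE)
  } else NULL)
  by_struct <- if ("structure_category" %in% names(elements) && nrow(el_res)) {
    summarize_by(elements$structure_category[res$eligible])
  } else NULL
  by_class <- if ("class_label" %in% names(elements) && nrow(el_res)) {
    summarize_by(elements$class_label[res$eligible])
  } else NULL
  age_hist <- if (nrow(el_res)) {
    brk <- seq(0, ceiling(max(el_res$T_mya) / age_bin_width + 1) * age_bin_width,
               by = age_bin_width)
    h <- hist(el_res$T_mya, breaks = brk, plot = FALSE, right = FALSE)
    data.frame(bin_start = h$breaks[-length(h$breaks)],
               bin_end = h$breaks[-1], count = h$counts)
  } else NULL
  list(results = res,
       identical_fraction = if (nrow(el_res)) mean(el_res$D == 0) else NA_real_,
       by_ltr_bin = by_ltr, by_structure = by_struct, by_class = by_class,
       age_histogram = age_hist)
}
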