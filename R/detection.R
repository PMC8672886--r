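## ---------------------------------------------------------------------------
## Simplified LTR-retroelement detector: shared k-mer seeding of candidate
## LTR pairs, ungapped x-drop extension, then a composite evidence score
## (LTR identity, TSD, internal ORF/motif evidence, spacing plausibility)
## on the 250/300 reporting scale.
## ---------------------------------------------------------------------------

#' Default detector parameters
#'
#' LTR length bounds follow the observed concentration of LTRs near 500 bp
#' (floor 100 bp, cap 2 kb); spacing bounds keep the element span in the
#' 1.5-15 kb range typical of proviruses.
#'
#' @param k Seed k-mer length (>= 8).
#' @param min_ltr,max_ltr LTR length bounds (bp).
#' @param min_spacing,max_spacing Bounds on the distance between LTR starts.
#' @param min_identity Minimum ungapped LTR pair identity.
#' @param xdrop X-drop threshold for seed extension.
#' @param max_kmer_occ K-mers occurring more often than this are skipped
#'   (high-copy repeat guard).
#' @return A parameter list.
#' @export
detector_params <- function(k = 15, min_ltr = 100, max_ltr = 2000,
                            min_spacing = 1000, max_spacing = 15000,
                            min_identity = 0.85, xdrop = 12,
                            max_kmer_occ = 8) {
  if (k < 8) stop("k must be >= 8")
  if (min_ltr > max_ltr) stop("min_ltr > max_ltr")
  if (min_spacing > max_spacing) stop("min_spacing > max_spacing")
  list(k = k, min_ltr = min_ltr, max_ltr = max_ltr,
       min_spacing = min_spacing, max_spacing = max_spacing,
       min_identity = min_identity, xdrop = xdrop,
       max_kmer_occ = max_kmer_occ)
}

#' Segment a chromosome into overlapping fragments
#'
#' Fragment i (0-based) is
#' `[i*(fragment_size-overlap), min(i*(fragment_size-overlap)+fragment_size, length))`;
#' fragments cover the chromosome and consecutive fragments overlap by
#' exactly `overlap` bp (except possibly the last).
#'
#' @param length Chromosome length (bp, > 0).
#' @param fragment_size Fragment size (default 9 Mb).
#' @param overlap Overlap between consecutive fragments (default 2 kb).
#' @return data.frame with columns `fragment` (1-based), `start`, `end`
#'   (0-based half-open).
#' @export
segment_chromosome <- function(length, fragment_size = 9e6, overlap = 2e3) {
  if (length <= 0) stop("length must be > 0")
  if (!(fragment_size > overlap && overlap >= 0)) {
    stop("need fragment_size > overlap >= 0")
  }
  step <- fragment_size - overlap
  ## Fragment i exists while fragment i-1 did not already reach the end.
  n_frag <- 1L
  while ((n_frag - 1L) * step + fragment_size < length) n_frag <- n_frag + 1L
  starts <- (seq_len(n_frag) - 1L) * step
  ends <- pmin(starts + fragment_size, length)
  data.frame(fragment = seq_len(n_frag), start = starts, end = ends)
}

## Map a 0-based position to the earliest fragment (1-based) containing it.
fragment_of_position <- function(pos, fragment_size = 9e6, overlap = 2e3) {
  step <- fragment_size - overlap
  j <- floor((pos - fragment_size) / step) + 1
  as.integer(pmax(0, j)) + 1L
}

## Encode sequence as 0..3 (NA for non-ACGT).
encode_dna <- function(seq) {
  code <- rep(NA_integer_, 256)
  code[utf8ToInt("A") + 1L] <- 0L; code[utf8ToInt("C") + 1L] <- 1L
  code[utf8ToInt("G") + 1L] <- 2L; code[utf8ToInt("T") + 1L] <- 3L
  code[utf8ToInt(seq) + 1L]
}

## Rolling k-mer hash vector (base-4); NA where the window has non-ACGT.
kmer_hashes <- function(codes, k) {
  n <- length(codes)
  if (n < k) return(numeric(0))
  m <- n - k + 1L
  h <- numeric(m)
  for (j in 0:(k - 1)) h <- h * 4 + codes[(1L + j):(m + j)]
  h
}

#' Find candidate LTR pairs by shared k-mer seeding
#'
#' Pairs of positions sharing a k-mer at a spacing within bounds are
#' clustered by diagonal, extended in both directions by ungapped x-drop
#' extension, and reported when the extended repeat pair satisfies the LTR
#' length and identity constraints. Overlapping candidates are reduced to
#' the best-scoring (identity x length) per locus.
#'
#' @param seq Chromosome sequence (character).
#' @param params A [detector_params()] list.
#' @param chrom Chromosome name recorded in the output.
#' @return data.frame of candidate pairs: `ltr5_start`, `ltr5_end`,
#'   `ltr3_start`, `ltr3_end` (0-based half-open), `pair_identity`,
#'   `spacing` (between LTR starts), `tsd` (duplicated flank or NA).
#' @export
find_candidate_ltr_pairs <- function(seq, params = detector_params(),
                                     chrom = "chr") {
  n <- nchar(seq)
  empty <- data.frame(chrom = character(0), ltr5_start = integer(0),
                      ltr5_end = integer(0), ltr3_start = integer(0),
                      ltr3_end = integer(0), pair_identity = numeric(0),
                      spacing = integer(0), tsd = character(0),
                      stringsAsFactors = FALSE)
  if (n < 2 * params$min_ltr + params$min_spacing - params$max_ltr) return(empty)
  codes <- encode_dna(seq)
  h <- kmer_hashes(codes, params$k)
  valid <- which(!is.na(h))
  if (length(valid) == 0) return(empty)
  o <- valid[order(h[valid])]
  hv <- h[o]
  grp_start <- c(TRUE, hv[-1] != hv[-length(hv)])
  gid <- cumsum(grp_start)
  sizes <- tabulate(gid)
  keep_g <- which(sizes >= 2 & sizes <= params$max_kmer_occ)
  if (length(keep_g) == 0) return(empty)
  pair_p1 <- integer(0); pair_p2 <- integer(0)
  idx_by_g <- split(o[gid %in% keep_g], gid[gid %in% keep_g])
  for (ps in idx_by_g) {
    ps <- sort(ps)
    cmb <- utils::combn(ps, 2)
    d <- cmb[2, ] - cmb[1, ]
    sel <- d >= params$min_spacing & d <= params$max_spacing
    pair_p1 <- c(pair_p1, cmb[1, sel])
    pair_p2 <- c(pair_p2, cmb[2, sel])
  }
  if (length(pair_p1) == 0) return(empty)
  d <- pair_p2 - pair_p1
  ord <- order(d, pair_p1)
  p1 <- pair_p1[ord]; dd <- d[ord]

  ## Cluster seeds sharing a diagonal (within a small band) and locus.
  band <- 20L
  cl <- integer(length(p1)); cur <- 0L
  last_d <- -Inf; last_p <- -Inf
  for (i in seq_along(p1)) {
    if (abs(dd[i] - last_d) > band || abs(p1[i] - last_p) > params$max_ltr) {
      cur <- cur + 1L
    }
    cl[i] <- cur
    last_d <- dd[i]; last_p <- p1[i]
  }

  x <- seq_to_chars(seq)
  cands <- list()
  for (ci in unique(cl)) {
    sel <- cl == ci
    diag0 <- as.integer(stats::median(dd[sel]))
    s1 <- min(p1[sel]); e1 <- max(p1[sel]) + params$k - 1L  # 1-based inclusive
    ext <- extend_repeat(x, s1, e1, diag0, n, params)
    if (is.null(ext)) next
    cands[[length(cands) + 1L]] <- ext
  }
  if (length(cands) == 0) return(empty)
  df <- do.call(rbind, cands)
  df <- cbind(chrom = chrom, df, stringsAsFactors = FALSE)

  ## Non-redundancy: among candidates whose 5' LTRs overlap, keep the best.
  df <- df[order(-(df$pair_identity * (df$ltr5_end - df$ltr5_start))), ]
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!keep[i]) next
    if (i < nrow(df)) {
      for (j in (i + 1):nrow(df)) {
        if (!keep[j]) next
        if (intervals_overlap(df$ltr5_start[i], df$ltr3_end[i],
                              df$ltr5_start[j], df$ltr3_end[j])) {
          keep[j] <- FALSE
        }
      }
    }
  }
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$ltr5_start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

intervals_overlap <- function(s1, e1, s2, e2) s1 < e2 && s2 < e1

## Ungapped two-sided x-drop extension of a seeded repeat pair.
## s1, e1 are 1-based inclusive bounds of the seed block in the 5' copy;
## diag0 is the offset to the 3' copy. Returns a one-row data.frame or NULL.
extend_repeat <- function(x, s1, e1, diag0, n, params) {
  match_score <- 1; mismatch_score <- -2
  ## extend left
  best <- 0; run <- 0; left <- s1
  i <- s1 - 1L
  while (i >= 1L && i + diag0 >= 1L) {
    run <- run + (if (x[i] == x[i + diag0]) match_score else mismatch_score)
    if (run > best) { best <- run; left <- i }
    if (best - run >= params$xdrop) break
    i <- i - 1L
  }
  ## extend right (5' copy must stop before the 3' copy starts)
  best <- 0; run <- 0; right <- e1
  i <- e1 + 1L
  while (i + diag0 <= n && i < left + diag0) {
    run <- run + (if (x[i] == x[i + diag0]) match_score else mismatch_score)
    if (run > best) { best <- run; right <- i }
    if (best - run >= params$xdrop) break
    i <- i + 1L
  }
  len <- right - left + 1L
  if (len > params$max_ltr) {  # clip symmetrically around the seed
    over <- len - params$max_ltr
    left <- left + ceiling(over / 2); right <- right - floor(over / 2)
    len <- right - left + 1L
  }
  if (len < params$min_ltr) return(NULL)
  idx <- left:right
  ident <- mean(x[idx] == x[idx + diag0])
  if (ident < params$min_identity) return(NULL)
  ltr5_start <- left - 1L           # 0-based half-open
  ltr5_end <- right
  ltr3_start <- ltr5_start + diag0
  ltr3_end <- ltr5_end + diag0
  tsd <- find_tsd(x, ltr5_start, ltr3_end, n)
  data.frame(ltr5_start = ltr5_start, ltr5_end = ltr5_end,
             ltr3_start = ltr3_start, ltr3_end = ltr3_end,
             pair_identity = ident, spacing = diag0,
             tsd = if (is.null(tsd)) NA_character_ else tsd,
             stringsAsFactors = FALSE)
}

## Look for a duplicated flank (TSD) of length 4-6 just outside the element.
find_tsd <- function(x, start0, end0, n, lengths = 6:4) {
  for (L in lengths) {
    if (start0 - L >= 1L - 1L && end0 + L <= n && start0 - L + 1L >= 1L) {
      left <- x[(start0 - L + 1L):start0]
      right <- x[(end0 + 1L):(end0 + L)]
      if (all(left == right)) return(paste(left, collapse = ""))
    }
  }
  NULL
}

#' Default evidence weights for the composite element score
#'
#' Calibrated so that a complete planted provirus scores above 300 (the
#' high-confidence flag) and random-sequence candidates stay below the 250
#' reporting floor.
#' @export
score_weights <- function(identity = 300, tsd = 30, spacing = 20,
                          orf = 120, motif = 15) {
  list(identity = identity, tsd = tsd, spacing = spacing, orf = orf,
       motif = motif)
}

#' Score a candidate LTR pair
#'
#' The score is a weighted sum of: an LTR-identity term (scaled from an 0.70
#' identity floor), a TSD bonus, internal ORF evidence (up to three long
#' ORFs, tentatively labelled gag/pol/env by position), internal motif hits,
#' and a spacing-plausibility term.
#'
#' @param cand One-row candidate (as from [find_candidate_ltr_pairs()]).
#' @param seq The chromosome sequence.
#' @param weights A [score_weights()] list.
#' @param params Detector parameters (for spacing bounds).
#' @return List with `score` and a named `components` breakdown, plus the
#'   internal ORF table used as gene evidence.
#' @export
score_candidate <- function(cand, seq, weights = score_weights(),
                            params = detector_params()) {
  n <- nchar(seq)
  if (cand$ltr5_start < 0 || cand$ltr3_end > n) stop("candidate out of range")
  identity_term <- weights$identity *
    max(0, min(1, (cand$pair_identity - 0.70) / 0.30))
  tsd_term <- if (!is.na(cand$tsd)) weights$tsd else 0
  spacing_term <- if (cand$spacing >= params$min_spacing &&
                        cand$spacing <= params$max_spacing) {
    weights$spacing
  } else 0

  internal <- substr(seq, cand$ltr5_end + 1L, cand$ltr3_start)
  orf_term <- 0; motif_term <- 0
  genes <- data.frame(gene = character(0), start = integer(0),
                      end = integer(0), strand = character(0), aa = integer(0),
                      stringsAsFactors = FALSE)
  if (nchar(internal) >= 300) {
    orfs <- find_orfs(internal, min_len_aa = 200)
    if (nrow(orfs) > 0) {
      top <- utils::head(orfs, 3)
      orf_term <- sum(pmin(top$length_aa, 400) / 400 * weights$orf)
      ilen <- nchar(internal)
      mid <- (top$start + top$end) / 2
      tentative <- c("gag", "pol", "env")[pmin(3, 1 + floor(3 * mid / ilen))]
      ## de-duplicate tentative labels, keep longest per label
      keep <- !duplicated(tentative)
      genes <- data.frame(gene = tentative[keep],
                          start = cand$ltr5_end + top$start[keep],
                          end = cand$ltr5_end + top$end[keep],
                          strand = top$strand[keep],
                          aa = top$length_aa[keep],
                          stringsAsFactors = FALSE)
      hits <- unique(unlist(lapply(top$protein, function(p) {
        unique(scan_simple_motifs(p)$motif)
      })))
      motif_term <- min(3, length(hits)) * weights$motif
    }
  }
  score <- identity_term + tsd_term + spacing_term + orf_term + motif_term
  list(score = score,
       components = c(identity = identity_term, tsd = tsd_term,
                      spacing = spacing_term, orf = orf_term,
                      motif = motif_term),
       genes = genes)
}

#' Call elements from scored candidates
#'
#' Candidates scoring at or above `report_threshold` become elements;
#' overlapping calls are resolved in favour of the higher score. Element
#' boundaries are the outer LTR boundaries; `high_confidence` flags scores
#' above 300. Strand is taken from the orientation of the best internal ORF
#' (LTR-LTR elements default to "+").
#'
#' @param candidates data.frame from [find_candidate_ltr_pairs()].
#' @param seq Chromosome sequence.
#' @param report_threshold Reporting floor (default 250).
#' @param weights,params Passed to [score_candidate()].
#' @return data.frame of elements sorted by chromosome then start.
#' @export
call_elements <- function(candidates, seq, report_threshold = 250,
                          weights = score_weights(),
                          params = detector_params()) {
  empty <- data.frame(element_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0),
                      ltr5_start = integer(0), ltr5_end = integer(0),
                      ltr3_start = integer(0), ltr3_end = integer(0),
                      gag_start = integer(0), gag_end = integer(0),
                      pol_start = integer(0), pol_end = integer(0),
                      env_start = integer(0), env_end = integer(0),
                      score = numeric(0), high_confidence = logical(0),
                      pair_identity = numeric(0), tsd = character(0),
                      stringsAsFactors = FALSE)
  if (is.null(candidates) || nrow(candidates) == 0) return(empty)
  rows <- list()
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates[i, ]
    sc <- score_candidate(cand, seq, weights, params)
    if (sc$score < report_threshold) next
    g <- sc$genes
    gene_iv <- function(name) {
      j <- which(g$gene == name)
      if (length(j) == 0) c(NA_integer_, NA_integer_) else c(g$start[j[1]], g$end[j[1]])
    }
    strand <- if (nrow(g) > 0) g$strand[which.max(g$aa)] else "+"
    gag <- gene_iv("gag"); pol <- gene_iv("pol"); env <- gene_iv("env")
    rows[[length(rows) + 1L]] <- data.frame(
      element_id = NA_character_, chrom = cand$chrom,
      start = cand$ltr5_start, end = cand$ltr3_end, strand = strand,
      ltr5_start = cand$ltr5_start, ltr5_end = cand$ltr5_end,
      ltr3_start = cand$ltr3_start, ltr3_end = cand$ltr3_end,
      gag_start = gag[1], gag_end = gag[2],
      pol_start = pol[1], pol_end = pol[2],
      env_start = env[1], env_end = env[2],
      score = sc$score, high_confidence = sc$score > 300,
      pair_identity = cand$pair_identity, tsd = cand$tsd,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(empty)
  df <- do.call(rbind, rows)
  ## Resolve overlaps: higher score wins.
  df <- df[order(-df$score), ]
  keep <- rep(TRUE, nrow(df))
  if (nrow(df) > 1) {
    for (i in seq_len(nrow(df) - 1)) {
      if (!keep[i]) next
      for (j in (i + 1):nrow(df)) {
        if (!keep[j]) next
        if (df$chrom[i] == df$chrom[j] &&
              intervals_overlap(df$start[i], df$end[i],
                                df$start[j], df$end[j])) keep[j] <- FALSE
      }
    }
  }
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  df$element_id <- sprintf("erv%04d", seq_len(nrow(df)))
  rownames(df) <- NULL
  df
}

#' Detect elements across a genome
#'
#' Runs [find_candidate_ltr_pairs()] and [call_elements()] per chromosome.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param params,weights,report_threshold See [call_elements()].
#' @return data.frame of detected elements.
#' @export
detect_elements <- function(genome, params = detector_params(),
                            weights = score_weights(),
                            report_threshold = 250) {
  if (length(genome) == 0 || sum(nchar(genome)) == 0) {
    stop("empty genome")
  }
  res <- lapply(names(genome), function(cn) {
    cands <- find_candidate_ltr_pairs(genome[[cn]], params, chrom = cn)
    call_elements(cands, genome[[cn]], report_threshold, weights, params)
  })
  df <- do.call(rbind, res)
  if (nrow(df) > 0) df$element_id <- sprintf("erv%04d", seq_len(nrow(df)))
  rownames(df) <- NULL
  df
}

#' Compare detections with a simulator truth table
#'
#' A detection matches a truth element when their spans overlap with a
#' Jaccard index of at least `min_jaccard` on the same chromosome.
#'
#' @param calls data.frame from [detect_elements()].
#' @param truth Truth table from [plant_elements()].
#' @param min_jaccard Overlap requirement (default 0.5).
#' @return List with `recall`, `precision`, `n_matched`, and the matched
#'   pairs table.
#' @export
evaluate_detection <- function(calls, truth, min_jaccard = 0.5) {
  if (nrow(truth) == 0) {
    return(list(recall = NA_real_, precision = if (nrow(calls)) 0 else NA_real_,
                n_matched = 0L, pairs = NULL))
  }
  matched_truth <- logical(nrow(truth))
  matched_call <- logical(nrow(calls))
  pairs <- list()
  for (i in seq_len(nrow(calls))) {
    for (j in seq_len(nrow(truth))) {
      if (calls$chrom[i] != truth$chrom[j]) next
      inter <- min(calls$end[i], truth$end[j]) - max(calls$start[i], truth$start[j])
      if (inter <= 0) next
      uni <- max(calls$end[i], truth$end[j]) - min(calls$start[i], truth$start[j])
      if (inter / uni >= min_jaccard) {
        matched_truth[j] <- TRUE
        matched_call[i] <- TRUE
        pairs[[length(pairs) + 1L]] <- data.frame(
          call = calls$element_id[i], truth = truth$element_id[j],
          jaccard = inter / uni, stringsAsFactors = FALSE)
      }
    }
  }
  list(recall = mean(matched_truth),
       precision = if (nrow(calls) > 0) mean(matched_call) else NA_real_,
       n_matched = sum(matched_truth),
       pairs = if (length(pairs)) do.call(rbind, pairs) else NULL)
}
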