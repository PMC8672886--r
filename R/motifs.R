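## ---------------------------------------------------------------------------
## ORF finding and the Gag/Env protein feature grammar: furin cleavage site
## (R/K-X-R/K-R), the 17-aa immunosuppressive domain with the position-14
## Q (on) vs R/K (off) rule, C-X-X-C and C-X{5,6,7}-CC cysteine motifs, and
## Kyte-Doolittle transmembrane prediction, with an Env architecture check.
## ---------------------------------------------------------------------------

## Residues that may match a motif wildcard: the 20 standard amino acids.
## "X" is tolerated in input but never matches.
AA20 <- "ACDEFGHIKLMNPQRSTVWY"

#' Find open reading frames in all six frames
#'
#' An ORF runs from a start codon (unless `require_start = FALSE`, in which
#' case from the first in-frame position after a stop) to the next stop
#' codon or the end of the frame. Coordinates are 0-based half-open on the
#' input (forward) sequence, for both strands.
#'
#' @param nt_seq Nucleotide string.
#' @param min_len_aa Minimum protein length (>= 1; the stop codon is not
#'   counted).
#' @param both_strands Scan the reverse complement too (default TRUE).
#' @param require_start Require an ATG (default TRUE).
#' @return data.frame sorted longest-first: `start`, `end`, `strand`,
#'   `frame` (0/1/2 on its strand), `length_aa`, `protein`.
#' @export
find_orfs <- function(nt_seq, min_len_aa = 100, both_strands = TRUE,
                      require_start = TRUE) {
  if (min_len_aa < 1) stop("min_len_aa must be >= 1")
  if (nchar(nt_seq) < 3) stop("sequence shorter than one codon")
  scan_strand <- function(s, strand) {
    n <- nchar(s)
    out <- list()
    for (frame in 0:2) {
      m <- (n - frame) %/% 3
      if (m < 1) next
      codons <- substring(s, frame + 1 + 3 * (0:(m - 1)),
                          frame + 3 + 3 * (0:(m - 1)))
      aa <- unname(Biostrings::GENETIC_CODE[codons])
      aa[is.na(aa)] <- "X"
      ## segment between stops
      is_stop <- aa == "*"
      seg_id <- cumsum(c(TRUE, is_stop[-m]))
      for (sg in split(seq_len(m), seg_id)) {
        idx <- sg[!is_stop[sg]]
        if (length(idx) == 0) next
        if (require_start) {
          st <- which(aa[idx] == "M")
          if (length(st) == 0) next
          idx <- idx[st[1]:length(idx)]
        }
        if (length(idx) < min_len_aa) next
        prot <- paste(aa[idx], collapse = "")
        c0 <- frame + 3 * (idx[1] - 1)            # 0-based on this strand
        c1 <- frame + 3 * idx[length(idx)]
        if (strand == "+") {
          start <- c0; end <- c1
        } else {
          start <- n - c1; end <- n - c0
        }
        out[[length(out) + 1L]] <- data.frame(
          start = start, end = end, strand = strand, frame = frame,
          length_aa = length(idx), protein = prot, stringsAsFactors = FALSE)
      }
    }
    out
  }
  res <- scan_strand(nt_seq, "+")
  if (both_strands) res <- c(res, scan_strand(revcomp(nt_seq), "-"))
  if (length(res) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), frame = integer(0),
                      length_aa = integer(0), protein = character(0),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, res)
  df <- df[order(-df$length_aa, df$start), ]
  rownames(df) <- NULL
  df
}

## Overlap-tolerant regex scan; positions 0-based.
scan_pattern <- function(protein, pattern) {
  m <- gregexpr(paste0("(?=(", pattern, "))"), protein, perl = TRUE)[[1]]
  if (m[1] == -1) return(integer(0))
  as.integer(m) - 1L
}

#' Scan a protein for the simple retroviral Env motifs
#'
#' Motifs (all overlapping matches reported, 0-based positions):
#' furin cleavage site `[RK]-X-[RK]-R`; `C-X-X-C`; `C-X{n}-CC` for
#' n in \{5, 6, 7\}. Wildcard positions match any of the 20 standard amino
#' acids; an `X` in the input never matches.
#'
#' @param protein Amino-acid string.
#' @return data.frame with `motif`, `start`, `end` (0-based half-open).
#' @export
scan_simple_motifs <- function(protein) {
  any1 <- paste0("[", AA20, "]")
  defs <- list(
    furin = list(pat = paste0("[RK]", any1, "[RK]R"), len = 4L),
    cxxc  = list(pat = paste0("C", any1, "{2}C"), len = 4L),
    cx5cc = list(pat = paste0("C", any1, "{5}CC"), len = 8L),
    cx6cc = list(pat = paste0("C", any1, "{6}CC"), len = 9L),
    cx7cc = list(pat = paste0("C", any1, "{7}CC"), len = 10L)
  )
  rows <- lapply(names(defs), function(nm) {
    pos <- scan_pattern(protein, defs[[nm]]$pat)
    if (length(pos) == 0) return(NULL)
    data.frame(motif = nm, start = pos, end = pos + defs[[nm]]$len,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(data.frame(motif = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$motif), , drop = FALSE]
}

#' Locate the 17-aa immunosuppressive domain (ISD)
#'
#' Scores every 17-aa window against each reference profile (one point per
#' identical column) and reports the best window. The 14th residue
#' (1-based within the window) switches immunosuppressive activity:
#' Q = suppressive ("on"), R/K = "off", anything else undetermined (NA).
#'
#' @param protein Amino-acid string (>= 17 residues).
#' @param isd_reference_profiles Character vector of 17-aa profiles (one
#'   per Env group); default [default_isd_profiles()].
#' @return List with `start` (0-based), `window` (17-aa string), `score`,
#'   `residue14`, `suppressive` (TRUE/FALSE/NA).
#' @export
locate_isd <- function(protein, isd_reference_profiles = default_isd_profiles()) {
  if (nchar(protein) < 17) stop("protein shorter than the 17-aa ISD window")
  if (length(isd_reference_profiles) < 1) stop("need at least one profile")
  if (any(nchar(isd_reference_profiles) != 17)) {
    stop("ISD profiles must be exactly 17 aa")
  }
  x <- seq_to_chars(protein)
  n_win <- length(x) - 16L
  best <- list(score = -Inf, start = NA_integer_)
  profs <- lapply(isd_reference_profiles, seq_to_chars)
  for (w in seq_len(n_win)) {
    win <- x[w:(w + 16L)]
    for (pr in profs) {
      sc <- sum(win == pr)
      if (sc > best$score) best <- list(score = sc, start = w - 1L)
    }
  }
  win <- substr(protein, best$start + 1L, best$start + 17L)
  r14 <- substr(win, 14, 14)
  suppressive <- if (r14 == "Q") TRUE else if (r14 %in% c("R", "K")) FALSE else NA
  list(start = best$start, window = win, score = best$score,
       residue14 = r14, suppressive = suppressive)
}

#' Default ISD reference profiles
#'
#' Synthetic 17-aa consensi matching the simulator's planted payloads (one
#' "on" variant with Q14, one "off" with K14). Real analyses should supply
#' per-group consensi observed in their own Env alignments.
#' @export
default_isd_profiles <- function() {
  unname(MOTIF_PEPTIDES[c("isd_on", "isd_off")])
}

## Kyte-Doolittle hydropathy scale.
KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2)

#' Predict transmembrane segments by sliding-window hydropathy
#'
#' Maximal runs of positions whose `window`-length mean Kyte-Doolittle
#' hydropathy reaches `threshold`; runs separated by fewer than `merge_gap`
#' positions are merged. A reported segment spans from the first window's
#' start to the last window's end (0-based half-open, aa coordinates).
#'
#' @param protein Amino-acid string (length >= `window`).
#' @param window Window size (default 19).
#' @param threshold Mean hydropathy threshold (default 1.6).
#' @param merge_gap Merge runs closer than this many positions (default 5).
#' @return data.frame with `start`, `end`, `max_hydropathy`.
#' @export
predict_tm <- function(protein, window = 19, threshold = 1.6, merge_gap = 5) {
  n <- nchar(protein)
  if (n < window) stop("protein shorter than the window")
  h <- KD_SCALE[seq_to_chars(protein)]
  h[is.na(h)] <- 0  # X and unknowns are neutral
  cs <- c(0, cumsum(h))
  means <- (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
  above <- means >= threshold
  if (!any(above)) {
    return(data.frame(start = integer(0), end = integer(0),
                      max_hydropathy = numeric(0)))
  }
  r <- rle(above)
  ends_i <- cumsum(r$lengths); starts_i <- ends_i - r$lengths + 1L
  seg <- data.frame(start = starts_i[r$values], end = ends_i[r$values])
  ## merge close runs
  if (nrow(seg) > 1) {
    merged <- seg[1, , drop = FALSE]
    for (i in 2:nrow(seg)) {
      if (seg$start[i] - merged$end[nrow(merged)] < merge_gap) {
        merged$end[nrow(merged)] <- seg$end[i]
      } else {
        merged <- rbind(merged, seg[i, ])
      }
    }
    seg <- merged
  }
  data.frame(start = seg$start - 1L,                # window start, 0-based
             end = seg$end - 1L + window,           # last window's end
             max_hydropathy = vapply(seq_len(nrow(seg)), function(i) {
               max(means[seg$start[i]:seg$end[i]])
             }, numeric(1)))
}

#' Annotate an Env protein with the full feature grammar
#'
#' Runs the furin/cysteine scanners, ISD location and TM prediction, and
#' validates the canonical Env architecture: among the features present,
#' positions must be ordered furin < ISD < C-Xn-CC < TM (missing features
#' are skipped; an empty feature set is vacuously valid and flagged).
#'
#' @param protein Amino-acid string.
#' @param profiles ISD reference profiles (default
#'   [default_isd_profiles()]).
#' @param isd_min_score Minimum ISD window score to accept the hit
#'   (default 12 of 17 matching columns).
#' @return List: `furin_site`, `isd`, `cxxc`, `cxncc` (data.frame with the
#'   spacer length n), `tm_segment`, `architecture_valid`, `no_features`.
#' @export
annotate_env <- function(protein, profiles = default_isd_profiles(),
                         isd_min_score = 12) {
  motifs <- scan_simple_motifs(protein)
  furin <- motifs[motifs$motif == "furin", , drop = FALSE]
  cxxc <- motifs[motifs$motif == "cxxc", , drop = FALSE]
  cxn <- motifs[motifs$motif %in% c("cx5cc", "cx6cc", "cx7cc"), , drop = FALSE]
  if (nrow(cxn) > 0) cxn$n <- as.integer(sub("^cx([0-9])cc$", "\\1", cxn$motif))
  isd <- if (nchar(protein) >= 17) {
    hit <- locate_isd(protein, profiles)
    if (hit$score >= isd_min_score) hit else NULL
  } else NULL
  tm <- if (nchar(protein) >= 19) predict_tm(protein) else
    data.frame(start = integer(0), end = integer(0))

  present <- c(
    furin = if (nrow(furin) > 0) furin$start[1] else NA,
    isd = if (!is.null(isd)) isd$start else NA,
    cxncc = if (nrow(cxn) > 0) cxn$start[1] else NA,
    tm = if (nrow(tm) > 0) tm$start[nrow(tm)] else NA
  )
  pos <- present[!is.na(present)]
  no_features <- length(pos) == 0
  architecture_valid <- all(diff(pos) > 0) || no_features
  list(furin_site = if (nrow(furin) > 0) furin$start[1] else NULL,
       isd = isd,
       cxxc = cxxc$start,
       cxncc = if (nrow(cxn) > 0) cxn[, c("n", "start", "end")] else NULL,
       tm_segment = if (nrow(tm) > 0) tm else NULL,
       architecture_valid = architecture_valid,
       no_features = no_features)
}
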