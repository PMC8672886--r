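# Independent reference implementations used only to check package output.

# Gotoh global alignment score with affine gaps (a gap of length L costs
# opening + L * extension), matching the package's stated scoring.
oracle_global_score <- function(a, b, match = 1, mismatch = -1,
                                opening = 5, extension = 1) {
  xa <- strsplit(a, "")[[1]]; xb <- strsplit(b, "")[[1]]
  n <- length(xa); m <- length(xb)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # ends in match/mismatch
  X <- matrix(NEG, n + 1, m + 1)   # ends in gap in b (consumes a)
  Y <- matrix(NEG, n + 1, m + 1)   # ends in gap in a (consumes b)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(opening + extension * i)
  for (j in seq_len(m)) Y[1, j + 1] <- -(opening + extension * j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (xa[i] == xb[j]) match else mismatch
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - opening - extension,
                             X[i, j + 1] - extension)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - opening - extension,
                             Y[i + 1, j] - extension)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Plain nested-loop motif scanner: returns 0-based start positions.
oracle_motif_positions <- function(protein, motif) {
  x <- strsplit(protein, "")[[1]]
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  spec <- switch(motif,
    furin = list(c("R", "K"), aa20, c("R", "K"), "R"),
    cxxc = list("C", aa20, aa20, "C"),
    cx5cc = c(list("C"), rep(list(aa20), 5), list("C"), list("C")),
    cx6cc = c(list("C"), rep(list(aa20), 6), list("C"), list("C")),
    cx7cc = c(list("C"), rep(list(aa20), 7), list("C"), list("C")))
  L <- length(spec)
  out <- integer(0)
  if (length(x) < L) return(out)
  for (s in 0:(length(x) - L)) {
    ok <- TRUE
    for (k in seq_len(L)) {
      if (!(x[s + k] %in% spec[[k]])) { ok <- FALSE; break }
    }
    if (ok) out <- c(out, s)
  }
  out
}

# Per-frame regex ORF finder on one strand (start-required), for
# comparison with find_orfs. Returns protein strings only.
oracle_orf_proteins <- function(nt, min_len_aa) {
  gc <- Biostrings::GENETIC_CODE
  prots <- character(0)
  for (s in c(nt, as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(nt))))) {
    n <- nchar(s)
    for (frame in 0:2) {
      m <- (n - frame) %/% 3
      if (m < 1) next
      codons <- substring(s, frame + 1 + 3 * (0:(m - 1)),
                          frame + 3 + 3 * (0:(m - 1)))
      aa <- paste(ifelse(is.na(gc[codons]), "X", gc[codons]), collapse = "")
      for (seg in strsplit(aa, "*", fixed = TRUE)[[1]]) {
        mpos <- regexpr("M", seg, fixed = TRUE)
        if (mpos == -1) next
        orf <- substring(seg, mpos)
        if (nchar(orf) >= min_len_aa) prots <- c(prots, orf)
      }
    }
  }
  sort(prots)
}

random_protein_string <- function(n, alphabet = c(strsplit(
    "ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_dna_string <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_valid_name_fields <- function() {
  prefix <- sample(c("ERV", "ERVL"), 1)
  class_letter <- if (prefix == "ERV") sample(c("E", "AB", "S", ""), 1) else ""
  erv_name(prefix = prefix, class_letter = class_letter,
           chrom_token = as.character(sample(1:25, 1)),
           fragment_index = sample(1:9, 1), ordinal = sample(1:400, 1),
           out_of_bound_suffix = sample(c("G", "P", "E", ""), 1),
           species_token = sample(c("DanRer", "HomSap", "XenTro"), 1))
}
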