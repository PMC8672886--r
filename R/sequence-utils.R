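DNA_BASES <- c("A", "C", "G", "T")

#' Generate an i.i.d. random nucleotide sequence
#'
#' Draws bases independently so that the expected GC fraction equals
#' `gc_fraction` (G and C equiprobable, likewise A and T).
#'
#' @param length Sequence length in bp (>= 1).
#' @param gc_fraction Target GC fraction in \[0, 1\].
#' @param seed Optional integer seed; when supplied the draw is reproducible.
#' @return A single character string of `length` bases.
#' @export
generate_background <- function(length, gc_fraction = 0.366, seed = NULL) {
  if (length < 1) stop("length must be >= 1")
  if (gc_fraction < 0 || gc_fraction > 1) stop("gc_fraction must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  p <- c((1 - gc_fraction) / 2, gc_fraction / 2, gc_fraction / 2,
         (1 - gc_fraction) / 2)
  paste(sample(DNA_BASES, length, replace = TRUE, prob = p), collapse = "")
}

## Fast character <-> vector helpers; sequences are plain strings throughout.
seq_to_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]
chars_to_seq <- function(x) paste(x, collapse = "")

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Apply a Poisson number of point substitutions to a sequence
#'
#' Models a Jukes-Cantor-style neutral substitution process: the number of
#' events is Poisson(`rate * years * nchar(seq)`), event sites are uniform
#' (a site may be hit more than once), and each event replaces the current
#' base with one of the other three, uniformly.
#'
#' @param seq Nucleotide string.
#' @param rate Substitution rate per site per year.
#' @param years Elapsed time in years.
#' @return Mutated sequence (same length; no indels).
#' @keywords internal
mutate_sequence <- function(seq, rate, years) {
  n <- nchar(seq)
  n_events <- stats::rpois(1, rate * years * n)
  if (n_events == 0) return(seq)
  x <- seq_to_chars(seq)
  sites <- sample.int(n, n_events, replace = TRUE)
  for (i in sites) {
    x[i] <- sample(setdiff(DNA_BASES, x[i]), 1)
  }
  chars_to_seq(x)
}

## Inverted genetic code: amino acid -> codons (standard code, no ambiguity).
codons_by_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

#' Reverse-translate a peptide with uniform codon choice
#'
#' @param peptide Amino-acid string (standard 20 letters; `*` allowed for a
#'   stop codon).
#' @return In-frame nucleotide string, 3x the peptide length.
#' @keywords internal
reverse_translate <- function(peptide) {
  tab <- codons_by_aa()
  aas <- seq_to_chars(peptide)
  bad <- setdiff(unique(aas), names(tab))
  if (length(bad) > 0) stop("no codon for residue(s): ", paste(bad, collapse = ", "))
  paste(vapply(aas, function(a) {
    cods <- tab[[a]]
    cods[sample.int(length(cods), 1)]
  }, character(1)), collapse = "")
}

#' Random protein sequence without stops
#' @keywords internal
random_protein <- function(n_aa, exclude = c("C", "M", "*", "X")) {
  aa <- setdiff(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                  "M", "F", "P", "S", "T", "W", "Y", "V"), exclude)
  paste(sample(aa, n_aa, replace = TRUE), collapse = "")
}

## Hamming identity of two equal-length strings.
ungapped_identity <- function(a, b) {
  xa <- seq_to_chars(a); xb <- seq_to_chars(b)
  stopifnot(length(xa) == length(xb))
  mean(xa == xb)
}
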