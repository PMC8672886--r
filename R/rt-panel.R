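## Retroviral class labels used throughout: three LTR-retrotransposon
## superfamilies plus the three retroviral classes.
ERV_CLASSES <- c("Gypsy", "Bel", "Copia", "classI", "classII", "classIII")

#' Synthetic reverse-transcriptase reference panel
#'
#' The panel maps the most conserved region of pol (the RT region) to one of
#' the six element classes by nearest-reference identity. Real surveys build
#' this panel from an RT phylogeny; here a synthetic panel is generated
#' deterministically: one stop-free 220-aa protein per class, reverse
#' translated under a fixed internal seed, so that simulated elements can
#' carry a mutated copy and classification can be checked against truth.
#'
#' @param n_per_class References per class (default 1).
#' @return Named character vector of nucleotide sequences; names are
#'   `label|accession` tokens (accessions are synthetic).
#' @export
default_rt_panel <- function(n_per_class = 1) {
  res <- character(0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(900001L)
  for (cls in ERV_CLASSES) {
    for (i in seq_len(n_per_class)) {
      prot <- random_protein(220)
      nt <- reverse_translate(prot)
      res[paste0(cls, "|SYN", sprintf("%02d", match(cls, ERV_CLASSES)), i)] <- nt
    }
  }
  res
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Read a labelled reference panel from FASTA
#'
#' Headers must follow `>label|accession`; the label is one of the six class
#' labels (Gypsy, Bel, Copia, classI, classII, classIII).
#'
#' @param path FASTA file.
#' @return Named character vector (full header as name).
#' @export
read_rt_panel <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- as.character(ss)
  names(out) <- names(ss)
  labels <- panel_labels(out)
  bad <- setdiff(unique(labels), ERV_CLASSES)
  if (length(bad) > 0) {
    stop("unknown panel label(s): ", paste(bad, collapse = ", "))
  }
  out
}

#' Write a reference panel to FASTA
#' @param panel Named nucleotide vector as from [default_rt_panel()].
#' @param path Output file.
#' @export
write_rt_panel <- function(panel, path) {
  ss <- Biostrings::DNAStringSet(unname(panel))
  names(ss) <- names(panel)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

panel_labels <- function(panel) {
  vapply(strsplit(names(panel), "|", fixed = TRUE), `[[`, character(1), 1L)
}
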