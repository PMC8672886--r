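## ---------------------------------------------------------------------------
## Plain-text interchange: FASTA genomes, BED6/GFF3 element annotations,
## TSV truth and results tables.
## ---------------------------------------------------------------------------

#' Write a genome to FASTA
#' @param genome Named character vector of chromosome sequences.
#' @param path Output file.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(unname(unlist(genome)))
  names(ss) <- names(genome)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a genome from FASTA
#' @param path FASTA file.
#' @return Named character vector.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write elements (or truth records) as BED6
#'
#' Scores are clipped to 1000 per the BED convention; for truth tables the
#' score column carries age in Mya x 100, rounded. Raw scores belong in
#' the TSV written by [write_elements_tsv()].
#'
#' @param df Element or truth table with chrom/start/end/strand and either
#'   `score` or `age_mya`.
#' @param path Output file.
#' @param name_col Column used for the BED name field (default `name` if
#'   present, else `element_id`).
#' @export
write_elements_bed <- function(df, path, name_col = NULL) {
  if (is.null(name_col)) {
    name_col <- if ("name" %in% names(df)) "name" else "element_id"
  }
  score <- if ("score" %in% names(df)) {
    pmin(1000, round(df$score))
  } else if ("age_mya" %in% names(df)) {
    round(df$age_mya * 100)
  } else rep(0L, nrow(df))
  bed <- data.frame(df$chrom, df$start, df$end, df[[name_col]], score,
                    if ("strand" %in% names(df)) df$strand else ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file written by [write_elements_bed()]
#' @param path BED file.
#' @return data.frame with chrom, start, end, name, score, strand.
#' @export
read_elements_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = c(V1 = "character"))
  names(df)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  df
}

#' Write elements as GFF3 with LTR and gene child features
#'
#' @param df Element table (detections with interval columns).
#' @param path Output file.
#' @export
write_elements_gff3 <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(df))) {
    el <- df[i, ]
    id <- if ("name" %in% names(df) && !is.na(el$name)) el$name else el$element_id
    lines <- sprintf("%s\tervatlas\tmobile_genetic_element\t%d\t%d\t%.1f\t%s\t.\tID=%s",
                     el$chrom, el$start + 1L, el$end,
                     if ("score" %in% names(df)) el$score else 0,
                     el$strand, id)
    child <- function(type, s, e) {
      if (is.na(s)) return(NULL)
      sprintf("%s\tervatlas\t%s\t%d\t%d\t.\t%s\t.\tParent=%s",
              el$chrom, type, s + 1L, e, el$strand, id)
    }
    lines <- c(lines,
               child("long_terminal_repeat", el$ltr5_start, el$ltr5_end),
               child("long_terminal_repeat", el$ltr3_start, el$ltr3_end),
               child("gag_gene", el$gag_start, el$gag_end),
               child("pol_gene", el$pol_start, el$pol_end),
               child("env_gene", el$env_start, el$env_end))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write any results table as TSV
#' @param df data.frame.
#' @param path Output file.
#' @export
write_elements_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a counts matrix with a feature-length sidecar
#' @param counts Features x samples matrix.
#' @param lengths Named length vector.
#' @param path Counts TSV path; lengths go to `<path>.lengths.tsv`.
#' @export
write_counts_tsv <- function(counts, lengths, path) {
  utils::write.table(data.frame(feature = rownames(counts), counts,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(feature = names(lengths), length = lengths),
                     paste0(path, ".lengths.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
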