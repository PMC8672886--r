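## ---------------------------------------------------------------------------
## Structural classification, reference-panel class assignment, and the
## reversible locus-based nomenclature
## (e.g. "ERV-E5.1.38-DanRer", "ERV-21.2.63E-DanRer", "ERVL-7.1.12-DanRer").
## ---------------------------------------------------------------------------

#' Classify element structure into a category token
#'
#' The token lists the parts present, 5' to 3': an "LTR" at each end when
#' both LTRs are present, "(LTR)" when a single LTR exists at one end only,
#' and the gene tokens gag/pol/env in genomic order. A complete provirus is
#' `LTR-gag-pol-env-LTR`.
#'
#' @param element One row of an element table (needs `ltr5_start`,
#'   `ltr3_start`, `gag_start`, `pol_start`, `env_start`; NA = absent).
#' @return The structure token (character scalar).
#' @export
classify_structure <- function(element) {
  has5 <- !is.na(element$ltr5_start); has3 <- !is.na(element$ltr3_start)
  genes <- c("gag", "pol", "env")[!is.na(c(element$gag_start,
                                           element$pol_start,
                                           element$env_start))]
  if (!has5 && !has3 && length(genes) == 0) {
    stop("element has no recognizable parts")
  }
  parts <- character(0)
  if (has5 && has3) {
    parts <- c("LTR", genes, "LTR")
  } else if (has5) {
    parts <- c("(LTR)", genes)
  } else if (has3) {
    parts <- c(genes, "(LTR)")
  } else {
    parts <- genes
  }
  paste(parts, collapse = "-")
}

#' Tabulate structure categories across elements
#'
#' @param elements Element table (see [classify_structure()]).
#' @return data.frame with `category`, `count`, `fraction`, plus an
#'   attribute `both_ltr_fraction` (fraction of elements with LTRs at both
#'   ends). Fractions sum to 1.
#' @export
structure_census <- function(elements) {
  if (is.null(elements) || nrow(elements) == 0) {
    out <- data.frame(category = character(0), count = integer(0),
                      fraction = numeric(0), stringsAsFactors = FALSE)
    attr(out, "both_ltr_fraction") <- NA_real_
    return(out)
  }
  cats <- vapply(seq_len(nrow(elements)), function(i) {
    classify_structure(elements[i, ])
  }, character(1))
  tab <- sort(table(cats), decreasing = TRUE)
  out <- data.frame(category = names(tab), count = as.integer(tab),
                    fraction = as.numeric(tab) / nrow(elements),
                    stringsAsFactors = FALSE)
  both <- grepl("^LTR-.*LTR$", out$category) | out$category == "LTR-LTR"
  attr(out, "both_ltr_fraction") <- sum(out$fraction[both])
  out
}

#' Assign a retroviral class by nearest reference
#'
#' The query (an RT-region or internal nucleotide sequence) is locally
#' aligned against every panel reference; the best reference's label is
#' returned when the alignment identity reaches `min_identity` AND the
#' alignment covers at least half of the shorter sequence (the coverage
#' requirement prevents short spurious perfect matches in random sequence
#' from classifying). Ties go to the first-listed reference.
#'
#' @param rt_seq Query nucleotide sequence.
#' @param panel Named nucleotide vector (`label|accession` names), e.g.
#'   [default_rt_panel()].
#' @param min_identity Identity floor on the local alignment (default 0.6).
#' @param min_coverage Minimum alignment length as a fraction of the
#'   shorter of query/reference (default 0.5).
#' @param both_strands Also try the reverse complement of the query and
#'   keep the better strand (default FALSE).
#' @return List with `class_label` ("unclassified" when no reference
#'   qualifies), `identity`, `coverage`, `reference`.
#' @export
assign_class_by_reference <- function(rt_seq, panel, min_identity = 0.6,
                                      min_coverage = 0.5,
                                      both_strands = FALSE) {
  if (both_strands) {
    fwd <- assign_class_by_reference(rt_seq, panel, min_identity, min_coverage)
    rev <- assign_class_by_reference(revcomp(rt_seq), panel, min_identity,
                                     min_coverage)
    pick <- if (rev$identity * rev$coverage > fwd$identity * fwd$coverage) {
      rev
    } else fwd
    return(pick)
  }
  if (is.null(rt_seq) || is.na(rt_seq) || nchar(rt_seq) == 0) {
    stop("empty query sequence")
  }
  if (length(panel) == 0) stop("empty reference panel")
  labels <- panel_labels(panel)
  bad <- setdiff(unique(labels), ERV_CLASSES)
  if (length(bad) > 0) stop("unknown panel label(s): ", paste(bad, collapse = ", "))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  best <- list(label = "unclassified", identity = 0, coverage = 0,
               reference = NA_character_, score = -Inf)
  q <- Biostrings::DNAString(rt_seq)
  for (i in seq_along(panel)) {
    aln <- Biostrings::pairwiseAlignment(q, Biostrings::DNAString(panel[[i]]),
                                         type = "local",
                                         substitutionMatrix = mat,
                                         gapOpening = 5, gapExtension = 2)
    alen <- nchar(as.character(Biostrings::pattern(aln)))
    ident <- Biostrings::pid(aln, type = "PID1") / 100
    cov <- alen / min(nchar(rt_seq), nchar(panel[[i]]))
    sc <- Biostrings::score(aln)
    if (ident >= min_identity && cov >= min_coverage && sc > best$score) {
      best <- list(label = labels[i], identity = ident, coverage = cov,
                   reference = names(panel)[i], score = sc)
    }
  }
  list(class_label = best$label, identity = best$identity,
       coverage = best$coverage, reference = best$reference)
}

VALID_CLASS_LETTERS <- c("E", "AB", "S", "")
OUT_OF_BOUND_SUFFIXES <- c("G", "P", "E", "")

#' Construct a validated name-field record
#'
#' @param prefix "ERV" (class I-III related) or "ERVL" (ERV-like).
#' @param class_letter "E" (epsilon-related), "AB" (alpha/beta-related),
#'   "S" (spuma-related), or "" (none). ERVL names carry no class letter.
#' @param chrom_token Chromosome token (digits).
#' @param fragment_index 1-based 9-Mb fragment index within the chromosome.
#' @param ordinal 1-based rank of the element within the fragment.
#' @param out_of_bound_suffix "G"/"P"/"E" when a gag/pol/env gene lies
#'   beyond the LTR-to-LTR span, else "".
#' @param species_token Species token (default "DanRer").
#' @return An `erv_name` list.
#' @export
erv_name <- function(prefix, class_letter = "", chrom_token,
                     fragment_index, ordinal, out_of_bound_suffix = "",
                     species_token = "DanRer") {
  if (!prefix %in% c("ERV", "ERVL")) stop("prefix must be ERV or ERVL")
  if (!class_letter %in% VALID_CLASS_LETTERS) {
    stop("class_letter must be one of E, AB, S or empty")
  }
  if (prefix == "ERVL" && class_letter != "") {
    stop("ERVL names carry no class letter")
  }
  if (!grepl("^[0-9]+$", chrom_token)) stop("chrom_token must be digits")
  if (fragment_index < 1 || ordinal < 1) {
    stop("fragment_index and ordinal are 1-based")
  }
  if (!out_of_bound_suffix %in% OUT_OF_BOUND_SUFFIXES) {
    stop("out_of_bound_suffix must be G, P, E or empty")
  }
  if (!grepl("^[A-Za-z][A-Za-z0-9]*$", species_token)) {
    stop("invalid species_token")
  }
  structure(list(prefix = prefix, class_letter = class_letter,
                 chrom_token = chrom_token,
                 fragment_index = as.integer(fragment_index),
                 ordinal = as.integer(ordinal),
                 out_of_bound_suffix = out_of_bound_suffix,
                 species_token = species_token),
            class = "erv_name")
}

#' Format name fields into a name string
#'
#' `"ERV-E5.1.38-DanRer"`: prefix, then class letter + chromosome,
#' fragment index, ordinal (dot-separated; an out-of-bound gene suffix
#' G/P/E attaches to the ordinal), then the species token.
#'
#' @param fields An [erv_name()] record.
#' @return Name string.
#' @export
format_name <- function(fields) {
  stopifnot(inherits(fields, "erv_name"))
  paste0(fields$prefix, "-", fields$class_letter, fields$chrom_token, ".",
         fields$fragment_index, ".", fields$ordinal,
         fields$out_of_bound_suffix, "-", fields$species_token)
}

#' Parse a name string back into fields
#'
#' Inverse of [format_name()]: `parse_name(format_name(x))` is identical to
#' `x` for every valid field record.
#'
#' @param name Name string.
#' @return An [erv_name()] record.
#' @export
parse_name <- function(name) {
  m <- regexec(paste0("^(ERVL|ERV)-(AB|E|S)?([0-9]+)\\.([0-9]+)\\.([0-9]+)",
                      "([GPE])?-([A-Za-z][A-Za-z0-9]*)$"), name)
  g <- regmatches(name, m)[[1]]
  if (length(g) == 0) {
    stop("malformed name: ", name, " (expected <prefix>-<locus>-<species>)")
  }
  prefix <- g[2]
  class_letter <- g[3]
  if (prefix == "ERVL" && class_letter != "") {
    stop("malformed name: ", name, " (ERVL with class letter)")
  }
  erv_name(prefix = prefix, class_letter = class_letter,
           chrom_token = g[4], fragment_index = as.integer(g[5]),
           ordinal = as.integer(g[6]), out_of_bound_suffix = g[7],
           species_token = g[8])
}

## Class label -> (prefix, class letter). Class I-III are true ERVs; the
## epsilon-related letter E is used for class I (the class I elements named
## in fish surveys carry E), AB for class II, S for class III. Gypsy, Bel
## and Copia are ERV-like (ERVL) and carry no letter.
class_to_name_parts <- function(class_label) {
  if (is.na(class_label) || !class_label %in% c("classI", "classII", "classIII")) {
    return(list(prefix = "ERVL", class_letter = ""))
  }
  letter <- switch(class_label, classI = "E", classII = "AB", classIII = "S")
  list(prefix = "ERV", class_letter = letter)
}

#' Assign nomenclature names to an element table
#'
#' Chromosomes are segmented into 9-Mb fragments with 2-kb overlaps; an
#' element is assigned to the earliest fragment containing its start, and
#' its ordinal is the rank of its start within that fragment. An element
#' whose gag/pol/env interval extends beyond the LTR-to-LTR span gets the
#' corresponding G/P/E suffix (first such gene in gag < pol < env order).
#'
#' @param elements Element table with `chrom`, `start` and (optionally)
#'   `class_label`, gene and LTR interval columns.
#' @param fragment_size,overlap Segmentation parameters.
#' @param species_token Species token for all names.
#' @return `elements` with a `name` column added.
#' @export
assign_names <- function(elements, fragment_size = 9e6, overlap = 2e3,
                         species_token = "DanRer") {
  if (nrow(elements) == 0) {
    elements$name <- character(0)
    return(elements)
  }
  frag <- fragment_of_position(elements$start, fragment_size, overlap)
  ord <- integer(nrow(elements))
  key <- paste(elements$chrom, frag)
  for (k in unique(key)) {
    idx <- which(key == k)
    ord[idx] <- rank(elements$start[idx], ties.method = "first")
  }
  names_out <- character(nrow(elements))
  for (i in seq_len(nrow(elements))) {
    cls <- if ("class_label" %in% names(elements)) elements$class_label[i] else NA
    parts <- class_to_name_parts(cls)
    suffix <- out_of_bound_suffix(elements[i, ])
    nm <- erv_name(prefix = parts$prefix, class_letter = parts$class_letter,
                   chrom_token = as.character(elements$chrom[i]),
                   fragment_index = frag[i], ordinal = ord[i],
                   out_of_bound_suffix = suffix,
                   species_token = species_token)
    names_out[i] <- format_name(nm)
  }
  elements$name <- names_out
  elements
}

## First gene (gag < pol < env) whose interval extends beyond [start, end).
out_of_bound_suffix <- function(el) {
  for (g in c("gag", "pol", "env")) {
    s <- el[[paste0(g, "_start")]]; e <- el[[paste0(g, "_end")]]
    if (!is.null(s) && !is.na(s) && (s < el$start || e > el$end)) {
      return(toupper(substr(g, 1, 1)))
    }
  }
  ""
}
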