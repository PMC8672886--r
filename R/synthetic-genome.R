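## ---------------------------------------------------------------------------
## Synthetic proviral genome simulator.
##
## The simulator inverts the LTR molecular clock: a provirus integrates with
## two identical LTRs; each LTR then accumulates Poisson(rate * age * length)
## substitutions independently, so the expected pairwise divergence is
## 2 * rate * age substitutions/site (before multiple-hit saturation).
## ---------------------------------------------------------------------------

#' Default neutral substitution rate for fish genomes (subs/site/year)
#' @export
DEFAULT_RATE <- 1.46e-8

## Canonical peptides embedded for each motif identifier. The ISD is the
## 17-aa immunosuppressive domain; its 14th residue is the on/off switch
## (Q = suppressive "on", R/K = "off"). Sequences are synthetic consensi.
MOTIF_PEPTIDES <- c(
  furin  = "RSKR",
  isd_on  = "AQNRRGLDLLFLKQEGL",
  isd_off = "AQNRRGLDLLFLKKEGL",
  cxxc   = "CWLC",
  cx5cc  = "CGLSATCC",
  cx6cc  = "CGLSATVCC",
  cx7cc  = "CGLSATVECC"
)
MOTIF_TM <- "AILAVLILLAVILGIAFLILAVLII"  # 25-aa strongly hydrophobic segment

## Scaffold alphabet for synthetic Env proteins: polar, non-C, non-R/K,
## non-hydrophobic residues so planted motifs are the only matches.
ENV_SCAFFOLD_AA <- c("S", "T", "N", "Q", "D", "E", "G", "H", "P", "Y")

env_scaffold <- function(n) {
  paste(sample(ENV_SCAFFOLD_AA, n, replace = TRUE), collapse = "")
}

#' Describe one provirus to be synthesized
#'
#' @param structure_category Structure token over \{(LTR), LTR, gag, pol,
#'   env\} joined by "-", e.g. `"LTR-gag-pol-env-LTR"` (complete provirus),
#'   `"LTR-LTR"`, `"(LTR)-gag"`.
#' @param age_mya Insertion age in millions of years (>= 0).
#' @param ltr_length LTR length in bp (>= 1).
#' @param internal_length Target internal-region length in bp (expanded if
#'   the requested open reading frames do not fit).
#' @param class_label One of Gypsy, Bel, Copia, classI, classII, classIII,
#'   or NA for an unclassifiable element.
#' @param motif_payload Character vector of motif identifiers to embed in
#'   the env ORF: any of `r paste(names(MOTIF_PEPTIDES), collapse = ", ")`,
#'   plus `"tm"`.
#' @param strand "+" or "-".
#' @param tsd_length Target-site duplication length in bp (0 allowed;
#'   default 4).
#' @return An `erv_element_spec` list.
#' @export
element_spec <- function(structure_category = "LTR-gag-pol-env-LTR",
                         age_mya = 0,
                         ltr_length = 500,
                         internal_length = 5000,
                         class_label = "Gypsy",
                         motif_payload = character(0),
                         strand = "+",
                         tsd_length = 4) {
  if (ltr_length < 1) stop("ltr_length must be >= 1")
  if (age_mya < 0) stop("age_mya must be >= 0")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (tsd_length < 0) stop("tsd_length must be >= 0")
  if (!is.na(class_label) && !class_label %in% ERV_CLASSES) {
    stop("unknown class_label: ", class_label)
  }
  parse_structure_token(structure_category)  # validates
  bad <- setdiff(motif_payload, c(names(MOTIF_PEPTIDES), "tm"))
  if (length(bad) > 0) stop("unknown motif id(s): ", paste(bad, collapse = ", "))
  structure(list(structure_category = structure_category,
                 age_mya = age_mya, ltr_length = ltr_length,
                 internal_length = internal_length, class_label = class_label,
                 motif_payload = motif_payload, strand = strand,
                 tsd_length = tsd_length),
            class = "erv_element_spec")
}

## Parse a structure token into leading/trailing LTR status and gene flags.
parse_structure_token <- function(token) {
  parts <- strsplit(token, "-", fixed = TRUE)[[1]]
  if (length(parts) == 0) stop("empty structure token")
  ltr_tokens <- c("LTR", "(LTR)")
  lead <- if (parts[1] %in% ltr_tokens) parts[1] else NA_character_
  trail <- if (length(parts) > 1 && parts[length(parts)] %in% ltr_tokens) {
    parts[length(parts)]
  } else NA_character_
  genes <- parts
  if (!is.na(lead)) genes <- genes[-1]
  if (!is.na(trail) && length(genes) > 0) genes <- genes[-length(genes)]
  if (any(genes %in% ltr_tokens)) {
    stop("invalid structure token (interior LTR): ", token)
  }
  if (!all(genes %in% c("gag", "pol", "env"))) {
    stop("invalid structure token: ", token)
  }
  if (!identical(genes, intersect(c("gag", "pol", "env"), genes))) {
    stop("genes out of order in structure token: ", token)
  }
  if (is.na(lead) && is.na(trail) && length(genes) == 0) {
    stop("structure token has no parts: ", token)
  }
  ## A single-LTR element "(LTR)" alone: leading only.
  list(lead = lead, trail = trail, genes = genes)
}

## Build a synthetic env protein with the requested motifs in canonical
## order (CXXC in SU, then furin, ISD, C-Xn-CC, TM) and record 0-based
## protein coordinates of each planted motif.
build_env_protein <- function(motif_payload) {
  segs <- character(0)
  coords <- data.frame(motif_id = character(0), aa_start = integer(0),
                       aa_end = integer(0), stringsAsFactors = FALSE)
  pos <- 0L
  add <- function(peptide, id = NA_character_) {
    segs[[length(segs) + 1L]] <<- peptide
    if (!is.na(id)) {
      coords[nrow(coords) + 1L, ] <<- list(id, pos, pos + nchar(peptide))
    }
    pos <<- pos + nchar(peptide)
  }
  order_ids <- c("cxxc", "furin", "isd_on", "isd_off", "cx5cc", "cx6cc",
                 "cx7cc", "tm")
  wanted <- order_ids[order_ids %in% motif_payload]
  add(env_scaffold(40))
  for (id in wanted) {
    if (id == "tm") add(MOTIF_TM, "tm") else add(MOTIF_PEPTIDES[[id]], id)
    add(env_scaffold(18))
  }
  add(env_scaffold(15))
  list(protein = paste(segs, collapse = ""), coords = coords)
}

## Internal ORF builders return list(nt, protein, rt_rel = c(start,end) or NULL)
build_gag_orf <- function() {
  prot <- random_protein(350)
  list(nt = paste0("ATG", reverse_translate(prot), "TAA"), protein = prot,
       rt_rel = NULL)
}

build_pol_orf <- function(class_label, panel) {
  lab <- panel_labels(panel)
  rt_nt <- if (!is.na(class_label) && class_label %in% lab) {
    panel[[which(lab == class_label)[1]]]
  } else {
    reverse_translate(random_protein(220))
  }
  f1 <- reverse_translate(random_protein(150))
  f2 <- reverse_translate(random_protein(100))
  nt <- paste0("ATG", f1, rt_nt, f2, "TAA")
  ## RT interval relative to ORF start (0-based half-open, nt coords)
  rt_rel <- c(3L + nchar(f1), 3L + nchar(f1) + nchar(rt_nt))
  list(nt = nt, protein = NULL, rt_rel = rt_rel)
}

#' Synthesize one proviral element with known truth
#'
#' Builds `TSD + 5'LTR + internal + 3'LTR + TSD` (per the structure token),
#' then ages it: the two LTRs are independent mutants of one ancestral LTR,
#' each carrying Poisson(rate x age x ltr_length) substitutions, and the
#' internal region diverges along a single lineage at the same rate. Motif
#' payloads are reverse-translated in frame into the env ORF; the RT region
#' of pol carries the panel reference for the element's class.
#'
#' @inheritParams element_spec
#' @param spec An [element_spec()].
#' @param rate Substitution rate (subs/site/year), default `DEFAULT_RATE`.
#' @param gc GC fraction for background/filler sequence.
#' @param panel RT reference panel, default [default_rt_panel()].
#' @param element_id Identifier recorded in the truth record.
#' @param seed Optional seed.
#' @return List with `sequence` (character), `truth` (one-row data.frame)
#'   and `motifs` (data.frame of planted protein-relative motif intervals).
#' @export
synthesize_element <- function(spec, rate = DEFAULT_RATE, gc = 0.366,
                               panel = default_rt_panel(),
                               element_id = "elem1", seed = NULL) {
  stopifnot(inherits(spec, "erv_element_spec"))
  if (!is.null(seed)) set.seed(seed)
  st <- parse_structure_token(spec$structure_category)
  years <- spec$age_mya * 1e6

  anc_ltr <- generate_background(spec$ltr_length, gc)
  ltr5 <- if (!is.na(st$lead)) mutate_sequence(anc_ltr, rate, years) else NULL
  ltr3 <- if (!is.na(st$trail)) mutate_sequence(anc_ltr, rate, years) else NULL

  orfs <- list(); motif_df <- NULL
  for (g in st$genes) {
    if (g == "gag") orfs$gag <- build_gag_orf()
    if (g == "pol") orfs$pol <- build_pol_orf(spec$class_label, panel)
    if (g == "env") {
      ep <- build_env_protein(spec$motif_payload)
      orfs$env <- list(nt = paste0("ATG", reverse_translate(ep$protein), "TAA"),
                       protein = ep$protein, rt_rel = NULL)
      motif_df <- ep$coords
      if (nrow(motif_df) > 0) {
        ## coordinates are relative to the translated ORF, whose start
        ## codon contributes a leading Met
        motif_df$aa_start <- motif_df$aa_start + 1L
        motif_df$aa_end <- motif_df$aa_end + 1L
      }
    }
  }
  orf_total <- sum(vapply(orfs, function(o) nchar(o$nt), numeric(1)))
  internal_len <- max(spec$internal_length, orf_total)
  n_gaps <- length(orfs) + 1L
  filler_total <- internal_len - orf_total
  gap_sizes <- rep(filler_total %/% n_gaps, n_gaps)
  gap_sizes[n_gaps] <- gap_sizes[n_gaps] + filler_total %% n_gaps

  pieces <- character(0); gene_iv <- list(); rt_iv <- NULL
  pos <- 0L
  push <- function(s) { pieces[[length(pieces) + 1L]] <<- s; pos <<- pos + nchar(s) }
  for (i in seq_along(orfs)) {
    if (gap_sizes[i] > 0) push(generate_background(gap_sizes[i], gc))
    g <- names(orfs)[i]
    gene_iv[[g]] <- c(pos, pos + nchar(orfs[[g]]$nt))
    if (!is.null(orfs[[g]]$rt_rel)) rt_iv <- pos + orfs[[g]]$rt_rel
    push(orfs[[g]]$nt)
  }
  if (gap_sizes[n_gaps] > 0) push(generate_background(gap_sizes[n_gaps], gc))
  internal <- if (length(pieces)) paste(pieces, collapse = "") else ""
  internal <- mutate_sequence_if(internal, rate, years)

  tsd <- if (spec$tsd_length > 0) generate_background(spec$tsd_length, gc) else ""

  ## Assemble on the element's coding strand; record 0-based offsets.
  off <- nchar(tsd)
  ltr5_iv <- ltr3_iv <- c(NA_integer_, NA_integer_)
  body <- character(0); p <- off
  if (!is.null(ltr5)) { ltr5_iv <- c(p, p + nchar(ltr5)); body <- c(body, ltr5); p <- p + nchar(ltr5) }
  int_off <- p
  body <- c(body, internal); p <- p + nchar(internal)
  if (!is.null(ltr3)) { ltr3_iv <- c(p, p + nchar(ltr3)); body <- c(body, ltr3); p <- p + nchar(ltr3) }
  seqn <- paste0(tsd, paste(body, collapse = ""), tsd)
  len <- nchar(seqn)

  shift_iv <- function(iv) if (is.null(iv)) c(NA_integer_, NA_integer_) else iv + int_off
  gag_iv <- shift_iv(gene_iv$gag); pol_iv <- shift_iv(gene_iv$pol)
  env_iv <- shift_iv(gene_iv$env)
  rt_abs <- if (!is.null(rt_iv)) rt_iv + int_off else c(NA_integer_, NA_integer_)

  if (spec$strand == "-") {
    seqn <- revcomp(seqn)
    flip <- function(iv) if (any(is.na(iv))) iv else c(len - iv[2], len - iv[1])
    tmp <- flip(ltr5_iv); ltr5_iv <- flip(ltr3_iv); ltr3_iv <- tmp
    gag_iv <- flip(gag_iv); pol_iv <- flip(pol_iv); env_iv <- flip(env_iv)
    rt_abs <- flip(rt_abs)
  }

  truth <- data.frame(
    element_id = element_id, chrom = NA_character_,
    start = 0L, end = len, strand = spec$strand,
    structure_category = spec$structure_category,
    age_mya = spec$age_mya, ltr_length = spec$ltr_length,
    internal_length = internal_len,
    class_label = if (is.na(spec$class_label)) NA_character_ else spec$class_label,
    tsd_length = spec$tsd_length,
    expected_divergence = 2 * rate * years,
    ltr5_start = ltr5_iv[1], ltr5_end = ltr5_iv[2],
    ltr3_start = ltr3_iv[1], ltr3_end = ltr3_iv[2],
    gag_start = gag_iv[1], gag_end = gag_iv[2],
    pol_start = pol_iv[1], pol_end = pol_iv[2],
    env_start = env_iv[1], env_end = env_iv[2],
    rt_start = rt_abs[1], rt_end = rt_abs[2],
    stringsAsFactors = FALSE
  )
  motifs <- if (is.null(motif_df) || nrow(motif_df) == 0) {
    data.frame(element_id = character(0), motif_id = character(0),
               aa_start = integer(0), aa_end = integer(0),
               stringsAsFactors = FALSE)
  } else {
    cbind(element_id = element_id, motif_df, stringsAsFactors = FALSE)
  }
  list(sequence = seqn, truth = truth, motifs = motifs)
}

mutate_sequence_if <- function(seq, rate, years) {
  if (nchar(seq) == 0 || years == 0) seq else mutate_sequence(seq, rate, years)
}

#' Plant synthesized elements into a background genome
#'
#' Insertion points are drawn uniformly per chromosome (chromosomes chosen
#' with probability proportional to length) and rejection-sampled so that
#' planted elements are separated by at least `min_gap` bp in the original
#' backbone. Truth coordinates are exact post-insertion coordinates.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param specs List of [element_spec()] objects.
#' @param min_gap Minimum backbone gap between insertion points (bp).
#' @param rate,gc,panel Passed to [synthesize_element()].
#' @param seed Optional seed (fixes both placement and synthesis).
#' @param max_tries Rejection-sampling cap per genome.
#' @return List with `genome` (modified sequences), `truth` (data.frame,
#'   one row per planted element, absolute 0-based half-open coordinates)
#'   and `motifs` (protein-relative planted motif table).
#' @export
plant_elements <- function(genome, specs, min_gap = 10000,
                           rate = DEFAULT_RATE, gc = 0.366,
                           panel = default_rt_panel(), seed = NULL,
                           max_tries = 1000) {
  if (!is.null(seed)) set.seed(seed)
  empty_truth <- synthesize_element(element_spec("LTR-LTR", ltr_length = 2,
                                                 internal_length = 0,
                                                 tsd_length = 0),
                                    panel = panel)$truth[0, ]
  if (length(specs) == 0) {
    return(list(genome = genome, truth = empty_truth,
                motifs = data.frame(element_id = character(0),
                                    motif_id = character(0),
                                    aa_start = integer(0),
                                    aa_end = integer(0))))
  }
  lens <- nchar(genome)
  if (sum(vapply(specs, function(s) 2 * s$ltr_length + s$internal_length +
                   2 * s$tsd_length, numeric(1))) >= sum(lens)) {
    stop("total planted length exceeds genome length")
  }
  n <- length(specs)
  chrom <- sample(names(genome), n, replace = TRUE, prob = lens / sum(lens))
  pos <- integer(n)
  for (tries in seq_len(max_tries)) {
    pos <- vapply(chrom, function(cn) sample.int(lens[[cn]] - 1L, 1), integer(1))
    ok <- TRUE
    for (cn in unique(chrom)) {
      p <- sort(pos[chrom == cn])
      if (length(p) > 1 && any(diff(p) < min_gap)) { ok <- FALSE; break }
    }
    if (ok) break
    if (tries == max_tries) {
      stop("could not place ", n, " elements without overlap; unplaced spec indices: ",
           paste(seq_len(n), collapse = ", "))
    }
  }

  synths <- lapply(seq_len(n), function(i) {
    synthesize_element(specs[[i]], rate = rate, gc = gc, panel = panel,
                       element_id = sprintf("sim%03d", i))
  })

  truth_rows <- list(); motif_rows <- list()
  out_genome <- genome
  ## Insert per chromosome, left to right; ties broken by spec index.
  for (cn in unique(chrom)) {
    idx <- which(chrom == cn)
    idx <- idx[order(pos[idx], idx)]
    offset <- 0L
    parts <- character(0)
    cur <- genome[[cn]]
    last_cut <- 0L
    for (i in idx) {
      s <- synths[[i]]
      at <- pos[i]
      parts <- c(parts, substr(cur, last_cut + 1L, at))
      start_abs <- at + offset
      t1 <- s$truth
      t1$chrom <- cn
      iv_cols <- c("ltr5_start", "ltr5_end", "ltr3_start", "ltr3_end",
                   "gag_start", "gag_end", "pol_start", "pol_end",
                   "env_start", "env_end", "rt_start", "rt_end")
      t1[iv_cols] <- lapply(t1[iv_cols], function(v) v + start_abs)
      t1$start <- start_abs
      t1$end <- start_abs + nchar(s$sequence)
      truth_rows[[length(truth_rows) + 1L]] <- t1
      motif_rows[[length(motif_rows) + 1L]] <- s$motifs
      parts <- c(parts, s$sequence)
      offset <- offset + nchar(s$sequence)
      last_cut <- at
    }
    parts <- c(parts, substr(cur, last_cut + 1L, nchar(cur)))
    out_genome[[cn]] <- paste(parts, collapse = "")
  }
  truth <- do.call(rbind, truth_rows)
  truth <- truth[order(truth$chrom, truth$start), ]
  rownames(truth) <- NULL
  motifs <- do.call(rbind, motif_rows)
  list(genome = out_genome, truth = truth, motifs = motifs)
}

#' Simulate the default benchmark genome
#'
#' Study-like conditions: a 10 Mb chromosome at 36.6% GC carrying 20 planted
#' proviruses with ages uniform on \[0, 2\] Mya, LTRs 300-800 bp (centred
#' near the ~500 bp mode seen in fish surveys), a structure mix dominated by
#' LTR-LTR and pol-retaining forms, and classes dominated by Gypsy and
#' class I.
#'
#' @param n_elements Number of planted elements.
#' @param genome_length Background length (bp).
#' @param gc GC fraction.
#' @param max_age_mya Ages drawn uniform on \[0, max_age_mya\].
#' @param seed Seed for the whole simulation.
#' @param rate Substitution rate.
#' @return As [plant_elements()], plus a `specs` component.
#' @export
simulate_erv_genome <- function(n_elements = 20, genome_length = 10e6,
                                gc = 0.366, max_age_mya = 2, seed = 1,
                                rate = DEFAULT_RATE) {
  set.seed(seed)
  structures <- c("LTR-LTR", "LTR-pol-LTR", "LTR-gag-pol-LTR",
                  "LTR-pol-env-LTR", "LTR-gag-LTR", "LTR-gag-pol-env-LTR")
  struct_p <- c(0.35, 0.20, 0.15, 0.10, 0.10, 0.10)
  classes <- c("Gypsy", "classI", "Bel", "Copia", "classII", "classIII")
  class_p <- c(0.55, 0.20, 0.10, 0.05, 0.05, 0.05)
  specs <- lapply(seq_len(n_elements), function(i) {
    stc <- sample(structures, 1, prob = struct_p)
    has_env <- grepl("env", stc)
    payload <- if (has_env) {
      c("furin", sample(c("isd_on", "isd_off"), 1), "cx6cc", "tm")
    } else character(0)
    element_spec(structure_category = stc,
                 age_mya = stats::runif(1, 0, max_age_mya),
                 ltr_length = sample(300:800, 1),
                 internal_length = sample(3500:8000, 1),
                 class_label = sample(classes, 1, prob = class_p),
                 motif_payload = payload,
                 strand = sample(c("+", "-"), 1),
                 tsd_length = 4)
  })
  genome <- c("1" = generate_background(genome_length, gc))
  res <- plant_elements(genome, specs, min_gap = 20000, rate = rate, gc = gc,
                        seed = seed + 1L)
  res$specs <- specs
  res
}
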