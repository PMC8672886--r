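## ---------------------------------------------------------------------------
## Expression simulator: planted condition specificity, virus response and
## cis/trans co-expression, on top of a log-normal x Poisson count model.
## ---------------------------------------------------------------------------

#' Describe a simulated expression experiment
#'
#' Abundances are in normalized units (TPM-scale); background features top
#' the design up so that true abundances total about 1e6 per sample, which
#' makes expected TPM equal the configured abundance.
#'
#' @param conditions Ordered condition labels (e.g. bud, 28hpf, 2dpf,
#'   5dpf; tissue names; or ctrl/infected).
#' @param n_reps Replicates per condition (default 3).
#' @param specificity_map Named list: element id -> condition label(s) in
#'   which it is highly expressed (at `high_abundance`); elsewhere, and
#'   for unmapped elements, `baseline_abundance`.
#' @param response_map Named numeric: element id -> log2 fold change in
#'   the "infected" condition relative to all others.
#' @param cis_pairs,trans_pairs data.frames with columns `element`,
#'   `gene`, `r` (target correlation in \[-1, 1\]): the pair's log
#'   abundances share a latent factor with that correlation.
#' @param sigma Log-normal noise sd on the natural-log scale
#'   (default 0.3; 0 = noise-free).
#' @param count_noise Draw Poisson counts around the expected value
#'   (default TRUE; FALSE gives exact expectations).
#' @param library_sizes Per-sample library sizes (recycled; default 2e7).
#' @param high_abundance,baseline_abundance,gene_abundance Abundance
#'   levels (TPM-scale units).
#' @param corr_amplitude Sd of the shared latent factor on the log2 scale
#'   for correlated pairs (default 1).
#' @param n_background Background transcriptome size (default 1000).
#' @param seed Seed.
#' @return An `expression_design` list.
#' @export
expression_design <- function(conditions, n_reps = 3,
                              specificity_map = list(),
                              response_map = numeric(0),
                              cis_pairs = NULL, trans_pairs = NULL,
                              sigma = 0.3, count_noise = TRUE,
                              library_sizes = 2e7,
                              high_abundance = 500,
                              baseline_abundance = 5,
                              gene_abundance = 100,
                              corr_amplitude = 1,
                              n_background = 1000, seed = 1) {
  stopifnot(length(conditions) >= 1)
  for (pp in list(cis_pairs, trans_pairs)) {
    if (!is.null(pp) && nrow(pp) > 0 && any(abs(pp$r) > 1)) {
      stop("target correlations must be in [-1, 1]")
    }
  }
  if (any(library_sizes <= 0)) stop("library sizes must be > 0")
  bad <- setdiff(unique(unlist(specificity_map)), conditions)
  if (length(bad) > 0) stop("condition label absent from design: ",
                            paste(bad, collapse = ", "))
  structure(list(conditions = conditions, n_reps = n_reps,
                 specificity_map = specificity_map,
                 response_map = response_map,
                 cis_pairs = cis_pairs, trans_pairs = trans_pairs,
                 sigma = sigma, count_noise = count_noise,
                 library_sizes = library_sizes,
                 high_abundance = high_abundance,
                 baseline_abundance = baseline_abundance,
                 gene_abundance = gene_abundance,
                 corr_amplitude = corr_amplitude,
                 n_background = n_background, seed = seed),
            class = "expression_design")
}

#' Simulate a gene annotation matched to a truth table
#'
#' Places one gene within `cis_distance` bp of each element listed in
#' `cis_elements` (on the element's chromosome) and the remaining genes
#' uniformly at least `far_distance` away from every element.
#'
#' @param truth Truth table from [plant_elements()].
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param n_genes Total genes.
#' @param cis_elements Element ids to receive an adjacent gene.
#' @param cis_distance Gap between element end and its cis gene (bp).
#' @param gene_length Gene length (bp).
#' @param far_distance Minimum distance of background genes from elements.
#' @param seed Seed.
#' @return data.frame: gene_id, chrom, start, end, cis_element (NA for
#'   background genes).
#' @export
simulate_gene_annotation <- function(truth, chrom_lengths, n_genes = 30,
                                     cis_elements = character(0),
                                     cis_distance = 5000,
                                     gene_length = 2000,
                                     far_distance = 50000, seed = 1) {
  set.seed(seed)
  rows <- list()
  gi <- 0L
  for (eid in cis_elements) {
    t1 <- truth[truth$element_id == eid, ]
    if (nrow(t1) == 0) stop("cis element not in truth table: ", eid)
    gi <- gi + 1L
    start <- t1$end + cis_distance
    rows[[gi]] <- data.frame(gene_id = sprintf("gene%03d", gi),
                             chrom = t1$chrom, start = start,
                             end = start + gene_length,
                             cis_element = eid, stringsAsFactors = FALSE)
  }
  n_bg <- n_genes - length(cis_elements)
  tries <- 0L
  while (n_bg > 0 && tries < 10000) {
    tries <- tries + 1L
    cn <- sample(names(chrom_lengths), 1)
    start <- sample.int(chrom_lengths[[cn]] - gene_length, 1)
    tt <- truth[truth$chrom == cn, ]
    if (nrow(tt) > 0 &&
          any(start < tt$end + far_distance &
                start + gene_length > tt$start - far_distance)) next
    gi <- gi + 1L
    rows[[gi]] <- data.frame(gene_id = sprintf("gene%03d", gi),
                             chrom = cn, start = start,
                             end = start + gene_length,
                             cis_element = NA_character_,
                             stringsAsFactors = FALSE)
    n_bg <- n_bg - 1L
  }
  do.call(rbind, rows)
}

#' Simulate expression count matrices from a design
#'
#' True abundances (TPM-scale) are assembled per feature and condition
#' from the specificity, response and correlation structure, multiplied by
#' per-replicate log-normal noise, converted to expected counts via
#' feature length and library size, and (optionally) Poisson-sampled.
#'
#' @param truth Truth table ([plant_elements()]); elements become features
#'   with length `end - start`.
#' @param genes Gene annotation ([simulate_gene_annotation()]) or NULL.
#' @param design An [expression_design()].
#' @return List: `counts` (features x samples), `samples` (data.frame
#'   sample/condition/replicate), `lengths` (named bp vector),
#'   `true_abundance` (features x conditions matrix).
#' @export
simulate_expression <- function(truth, genes, design) {
  stopifnot(inherits(design, "expression_design"))
  set.seed(design$seed)
  conds <- design$conditions
  n_samp <- length(conds) * design$n_reps
  samples <- data.frame(
    sample = paste0(rep(conds, each = design$n_reps), "_r",
                    rep(seq_len(design$n_reps), length(conds))),
    condition = rep(conds, each = design$n_reps),
    replicate = rep(seq_len(design$n_reps), length(conds)),
    stringsAsFactors = FALSE)

  elem_ids <- truth$element_id
  gene_ids <- if (!is.null(genes)) genes$gene_id else character(0)
  bad <- setdiff(c(names(design$specificity_map), names(design$response_map),
                   design$cis_pairs$element, design$trans_pairs$element),
                 elem_ids)
  if (length(bad) > 0) stop("element(s) not in truth table: ",
                            paste(bad, collapse = ", "))
  badg <- setdiff(c(design$cis_pairs$gene, design$trans_pairs$gene), gene_ids)
  if (length(badg) > 0) stop("gene(s) not in annotation: ",
                             paste(badg, collapse = ", "))

  bg_ids <- if (design$n_background > 0) {
    sprintf("bg%04d", seq_len(design$n_background))
  } else character(0)
  feats <- c(elem_ids, gene_ids, bg_ids)
  lengths <- c(stats::setNames(truth$end - truth$start, elem_ids),
               if (length(gene_ids)) {
                 stats::setNames(genes$end - genes$start, gene_ids)
               },
               stats::setNames(rep(2000L, length(bg_ids)), bg_ids))

  ## Baseline abundance per feature x condition.
  ab <- matrix(design$baseline_abundance, nrow = length(feats),
               ncol = length(conds), dimnames = list(feats, conds))
  ab[gene_ids, ] <- design$gene_abundance
  for (eid in names(design$specificity_map)) {
    ab[eid, ] <- design$baseline_abundance
    ab[eid, design$specificity_map[[eid]]] <- design$high_abundance
  }
  for (eid in names(design$response_map)) {
    base <- design$gene_abundance
    ab[eid, ] <- base
    if ("infected" %in% conds) {
      ab[eid, "infected"] <- base * 2^design$response_map[[eid]]
    } else {
      stop("response_map requires an 'infected' condition")
    }
  }
  ## Background features: log-normal abundances scaled so column totals
  ## approach 1e6 (keeps TPM approximately equal to configured abundance).
  if (length(bg_ids) > 0) {
    raw <- stats::rlnorm(length(bg_ids), meanlog = 0, sdlog = 1)
    spare <- 1e6 - max(colSums(ab[c(elem_ids, gene_ids), , drop = FALSE]))
    ab[bg_ids, ] <- raw / sum(raw) * max(0, spare)
  }
  true_ab <- ab

  ## Per-sample log2-scale adjustment from shared latent factors
  ## (correlated pairs), plus replicate log-normal noise.
  log_adj <- matrix(0, nrow = length(feats), ncol = n_samp,
                    dimnames = list(feats, samples$sample))
  add_pairs <- function(pairs) {
    if (is.null(pairs) || nrow(pairs) == 0) return()
    for (i in seq_len(nrow(pairs))) {
      z <- stats::rnorm(n_samp)
      eps <- stats::rnorm(n_samp)
      rho <- pairs$r[i]
      log_adj[pairs$element[i], ] <<- log_adj[pairs$element[i], ] +
        design$corr_amplitude * z
      log_adj[pairs$gene[i], ] <<- log_adj[pairs$gene[i], ] +
        design$corr_amplitude * (rho * z + sqrt(1 - rho^2) * eps)
    }
  }
  add_pairs(design$cis_pairs)
  add_pairs(design$trans_pairs)

  counts <- matrix(0, nrow = length(feats), ncol = n_samp,
                   dimnames = list(feats, samples$sample))
  lib <- rep_len(design$library_sizes, n_samp)
  for (s in seq_len(n_samp)) {
    a <- ab[, samples$condition[s]] * 2^log_adj[, s]
    if (design$sigma > 0) {
      a <- a * stats::rlnorm(length(a), meanlog = -design$sigma^2 / 2,
                             sdlog = design$sigma)
    }
    lambda <- a * lengths / 1e9 * lib[s]
    counts[, s] <- if (design$count_noise) stats::rpois(length(lambda), lambda)
    else lambda
  }
  list(counts = counts, samples = samples, lengths = lengths,
       true_abundance = true_ab)
}
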