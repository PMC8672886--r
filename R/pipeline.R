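## ---------------------------------------------------------------------------
## End-to-end orchestration: detect -> classify/name -> date -> distribution
## stats -> protein annotation -> expression, as plain library calls with a
## run manifest. No workflow engine; stages can be toggled.
## ---------------------------------------------------------------------------

#' Build a run configuration
#'
#' Every stage parameter carries its survey default: report threshold 250
#' with the 300 high-confidence flag, 100 bp minimum LTR for dating,
#' substitution rate 1.46e-8 subs/site/year, TPM > 100 (embryo) and
#' FPKM > 1 (tissue) expression floors, the 10 kb cis window, and the
#' |R| > 0.85 / p < 0.01 trans rule.
#'
#' @param stages Stages to run (subset of detect, classify, date, stats,
#'   protein, express).
#' @param report_threshold,high_threshold Detector score thresholds.
#' @param detector Detector parameter list ([detector_params()]).
#' @param rate Substitution rate (subs/site/year).
#' @param dating_model "p" or "JC".
#' @param min_ltr_dating Minimum LTR length for dating eligibility (bp).
#' @param panel RT reference panel.
#' @param min_class_identity Identity floor for class assignment.
#' @param tpm_threshold,fpkm_threshold Expression floors.
#' @param cis_window Cis association window (bp).
#' @param r_min,p_max Trans association rule.
#' @param min_log2fc Virus-response fold-change floor.
#' @param seed Seed recorded in the manifest.
#' @return A `run_config` list.
#' @export
run_config <- function(stages = c("detect", "classify", "date", "stats"),
                       report_threshold = 250, high_threshold = 300,
                       detector = detector_params(), rate = DEFAULT_RATE,
                       dating_model = "p", min_ltr_dating = 100,
                       panel = default_rt_panel(),
                       min_class_identity = 0.6,
                       tpm_threshold = 100, fpkm_threshold = 1,
                       cis_window = 10000, r_min = 0.85, p_max = 0.01,
                       min_log2fc = 1, seed = 1) {
  structure(as.list(environment()), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Scalar fields of the YAML override [run_config()] defaults.
#' @param path YAML file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required to read YAML configs")
  }
  y <- yaml::read_yaml(path)
  cfg <- run_config()
  for (k in intersect(names(y), names(cfg))) cfg[[k]] <- y[[k]]
  cfg
}

#' Run the characterization pipeline on a genome
#'
#' Executes the enabled stages in dependency order and returns all stage
#' outputs plus a manifest (package version, configuration hash, seed).
#' Reruns with the same config and inputs are identical.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param config A [run_config()].
#' @param expression Optional list with `counts`, `samples`, `lengths`
#'   (e.g. from [simulate_expression()]) for the express stage.
#' @param gene_annotation Optional gene table for cis association.
#' @param out_dir Optional directory; when given, stage outputs are
#'   written as BED/GFF3/TSV files.
#' @return A `run_report` list with components per executed stage.
#' @export
run_characterization <- function(genome, config = run_config(),
                                 expression = NULL, gene_annotation = NULL,
                                 out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  report <- list(manifest = list(
    package = as.character(utils::packageVersion("ervatlas")),
    seed = config$seed,
    config_hash = config_hash(config),
    stages = config$stages))
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  elements <- NULL
  if ("detect" %in% config$stages) {
    elements <- run_stage("detect", function() {
      detect_elements(genome, params = config$detector,
                      report_threshold = config$report_threshold)
    })
    report$elements <- elements
  }

  if ("classify" %in% config$stages && !is.null(elements) &&
        nrow(elements) > 0) {
    report$elements <- elements <- run_stage("classify", function() {
      cls <- character(nrow(elements))
      for (i in seq_len(nrow(elements))) {
        el <- elements[i, ]
        internal <- substr(genome[[el$chrom]], el$ltr5_end + 1L, el$ltr3_start)
        cls[i] <- if (nchar(internal) >= 100) {
          assign_class_by_reference(internal, config$panel,
                                    config$min_class_identity,
                                    both_strands = TRUE)$class_label
        } else "unclassified"
      }
      elements$class_label <- ifelse(cls == "unclassified", NA, cls)
      elements$structure_category <- vapply(seq_len(nrow(elements)),
        function(i) classify_structure(elements[i, ]), character(1))
      assign_names(elements)
    })
  }

  if ("date" %in% config$stages && !is.null(elements)) {
    report$dating <- run_stage("date", function() {
      dating_cohort(elements, genome, rate = config$rate,
                    model = config$dating_model,
                    min_score = config$high_threshold,
                    min_ltr = config$min_ltr_dating)
    })
  }

  if ("stats" %in% config$stages && !is.null(elements)) {
    report$chrom_stats <- run_stage("stats", function() {
      lens_mb <- nchar(genome) / 1e6
      detected <- vapply(names(genome), function(cn) {
        sum(elements$chrom == cn)
      }, numeric(1))
      chromosome_stats(names(genome), unname(lens_mb), unname(detected))
    })
  }

  if ("protein" %in% config$stages && !is.null(elements) &&
        nrow(elements) > 0) {
    report$env_annotations <- run_stage("protein", function() {
      out <- list()
      for (i in seq_len(nrow(elements))) {
        el <- elements[i, ]
        if (is.na(el$env_start)) next
        orfs <- find_orfs(substr(genome[[el$chrom]], el$env_start + 1L,
                                 el$env_end), min_len_aa = 100)
        if (nrow(orfs) == 0) next
        out[[el$element_id]] <- annotate_env(orfs$protein[1])
      }
      out
    })
  }

  if ("express" %in% config$stages && !is.null(expression)) {
    report$expression <- run_stage("express", function() {
      tpm <- normalize_counts(expression$counts, expression$lengths, "TPM")
      sets <- expressed_set(tpm, expression$samples$condition,
                            config$tpm_threshold)
      out <- list(tpm = tpm, expressed_sets = sets)
      if (length(sets) >= 2) out$specificity <- specificity_and_overlap(sets)
      if (!is.null(gene_annotation) && !is.null(elements)) {
        out$cis <- cis_neighbors(elements, gene_annotation,
                                 window = config$cis_window)
      }
      out
    })
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(report$elements) && nrow(report$elements) > 0) {
      write_elements_bed(report$elements, file.path(out_dir, "elements.bed"))
      write_elements_gff3(report$elements, file.path(out_dir, "elements.gff3"))
      write_elements_tsv(report$elements, file.path(out_dir, "elements.tsv"))
    }
    if (!is.null(report$dating)) {
      write_elements_tsv(report$dating$results, file.path(out_dir, "dating.tsv"))
    }
    if (!is.null(report$chrom_stats)) {
      write_elements_tsv(report$chrom_stats, file.path(out_dir, "chrom_stats.tsv"))
    }
    writeLines(paste0(names(report$manifest), ": ",
                      vapply(report$manifest, function(x)
                        paste(as.character(x), collapse = ","), character(1))),
               file.path(out_dir, "manifest.txt"))
  }
  class(report) <- "run_report"
  report
}

## Stable hash of the configuration (md5 of its deparsed form).
config_hash <- function(config) {
  cfg <- config[setdiff(names(config), "panel")]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(cfg), tmp)
  unname(tools::md5sum(tmp))
}
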