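#!/usr/bin/env Rscript
# Stage 6: Gag/Env protein feature annotation.
#
# Translates the env ORFs of the planted env-bearing elements and runs the
# feature grammar: furin cleavage site, 17-aa immunosuppressive domain
# (position-14 on/off state), cysteine motifs and the C-terminal
# transmembrane segment, then validates the canonical Env architecture.

library(ervatlas)

genome <- read_genome_fasta("results/sim_genome.fasta")
truth <- read.delim("results/sim_truth.tsv", colClasses = c(chrom = "character"))

envs <- truth[!is.na(truth$env_start), ]
cat("env-bearing planted elements:", nrow(envs), "\n")
rows <- list()
for (i in seq_len(nrow(envs))) {
  t1 <- envs[i, ]
  nt <- substr(genome[[t1$chrom]], t1$env_start + 1, t1$env_end)
  if (t1$strand == "-") {
    nt <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
  }
  orfs <- find_orfs(nt, min_len_aa = 100, both_strands = FALSE)
  if (nrow(orfs) == 0) next
  ann <- annotate_env(orfs$protein[1])
  rows[[length(rows) + 1]] <- data.frame(
    element_id = t1$element_id,
    furin = !is.null(ann$furin_site),
    isd_state = if (is.null(ann$isd)) NA
    else c("off", "on")[ann$isd$suppressive + 1],
    cxncc = !is.null(ann$cxncc),
    tm = !is.null(ann$tm_segment),
    architecture_valid = ann$architecture_valid)
}
out <- do.call(rbind, rows)
write_elements_tsv(out, "results/env_annotations.tsv")
print(out)
cat("Architecture valid:", sum(out$architecture_valid), "/", nrow(out), "\n")
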