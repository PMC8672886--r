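#!/usr/bin/env Rscript
# Stage 5: chromosomal distribution statistics.
#
# First reproduces the packaged 25-chromosome survey table (densities,
# two-cell chi-square enrichment, count-length and count-GC correlations),
# then computes the same statistics plus a windowed density track for the
# simulated genome's detections.

library(ervatlas)

fx <- read_chrom_stats_fixture()
st <- chromosome_stats(fx$chrom, fx$length_mb, fx$detected, fx$gc_percent,
                       total = attr(fx, "total"), expected = fx$expected)
write_elements_tsv(st, "results/chrom_survey_stats.tsv")
cat("Survey table: density chr4 =", round(st$density[st$chrom == "4"], 2),
    "| chi2 chr4 =", round(st$chi2[st$chrom == "4"], 3), "\n")
cat("Enriched chromosomes (alpha 0.01):",
    paste(st$chrom[st$direction == "enriched"], collapse = ", "), "\n")
cc <- count_length_gc_correlation(st)
cat("Pearson R detected~length:", round(cc$length$R, 3),
    "| detected~GC:", round(cc$gc$R, 3), "\n")

calls <- read.delim("results/detected.tsv", colClasses = c(chrom = "character"))
genome <- read_genome_fasta("results/sim_genome.fasta")
track <- windowed_feature_density(calls$start, calls$end,
                                  nchar(genome[["1"]]), window = 5e5)
write_elements_tsv(track, "results/density_track.tsv")
cat("Density track (500 kb windows): max", max(track$count),
    "elements per window\n")
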