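# ervatlas

Genome-wide characterization of endogenous retroviruses (ERVs) in R, built
around the kind of survey done for the zebrafish genome: find
LTR-retroelement insertions in genomic sequence, classify and name them,
date them from LTR divergence, test their chromosomal distribution, annotate
their Gag/Env protein features, and integrate expression data. Because real
surveys can only be validated indirectly, the package ships a first-class
synthetic-genome simulator that plants proviruses of known age, structure,
class and motif content — every downstream stage is scored against that
ground truth.

Intended users: genome-annotation and mobile-element researchers who want a
tested, scriptable desk-scale model of an ERV survey pipeline, and anyone
who needs the individual pieces (LTR-pair detection, molecular dating,
enrichment statistics, Env motif grammar, TPM/FPKM filters) as plain R
functions.

## The model in brief

* **Detection.** A provirus is `5'LTR – gag – pol – env – 3'LTR` flanked by a
  short target-site duplication (TSD). The detector seeds candidate LTR
  pairs from shared k-mers (default k = 15) at a plausible spacing
  (1–15 kb), extends them by x-drop, and scores each candidate as a
  weighted sum of LTR identity, TSD presence, internal ORF/motif evidence
  and spacing plausibility. Calls use a reporting floor of 250 with a
  high-confidence flag above 300.
* **Dating.** The two LTRs are identical at integration and diverge
  independently afterwards, so the insertion time is `T = D / (2R)` with
  `D` the pairwise LTR divergence (p-distance by default, Jukes–Cantor
  optional) and `R = 1.46e-8` substitutions/site/year, the neutral rate for
  fish genomes. Survey filters: score > 300 and LTR > 100 bp.
* **Distribution.** Per-chromosome density (elements/Mb), expected counts
  `length × genome-wide density`, and a two-cell chi-square
  `χ² = (O−E)²/E + ((T−O)−(T−E))²/(T−E)` with 1 df per chromosome, plus
  Pearson correlations of counts with chromosome length and GC.
* **Proteins.** Six-frame ORF finding and the Env feature grammar: furin
  site `R/K-X-R/K-R`, the 17-aa immunosuppressive domain whose 14th residue
  (Q vs R/K) switches activity on/off, `C-X-X-C` and `C-X{5,6,7}-CC`
  motifs, Kyte–Doolittle transmembrane segments, and an architecture check
  (furin < ISD < C-Xn-CC < TM).
* **Expression.** TPM/FPKM normalization, expression floors (TPM > 100,
  FPKM > 1), stage/tissue specificity and overlaps, an explicit
  fold-change rule for virus response (log2FC ≥ 1), cis association within
  10 kb, and trans association at |R| > 0.85 with p < 0.01.
* **Nomenclature.** `ERV-E5.1.38-DanRer` = class letter (E/AB/S for class
  I–III; `ERVL-` prefix for Gypsy/Bel/Copia-like elements), chromosome,
  1-based 9-Mb fragment index, within-fragment ordinal, optional G/P/E
  suffix for out-of-bound genes, species token. `parse_name()` inverts
  `format_name()` exactly.

## Worked example

```r
library(ervatlas)

sim <- simulate_erv_genome(n_elements = 8, genome_length = 2e6, seed = 5)
calls <- detect_elements(sim$genome)
evaluate_detection(calls, sim$truth)[c("recall", "precision")]
#> $recall
#> [1] 1
#> $precision
#> [1] 1

res <- dating_cohort(calls, sim$genome)
head(res$results[res$results$eligible, c("element_id", "D", "T_mya")])
```

On this simulation all 8 planted elements are recovered (recall and
precision 1.0); the dated cohort returns each element's LTR divergence `D`
and age `T_mya`, which track the planted ages (uniform 0–2 Mya) to within a
few tenths of a Mya. The numbered scripts under `analysis/` walk the same
workflow at the full benchmark scale (10 Mb, 20 elements) and print, e.g.:

```
20 elements called; recall 1 precision 1
Scores: 262-537 | 15 high-confidence (score > 300)
True age 2 Mya -> median estimate 2.067 Mya
Survey table: density chr4 = 4.38 | chi2 chr4 = 153.36
Pearson R detected~length: 0.808 | detected~GC: 0.797
```

The packaged 25-chromosome survey table (`inst/extdata/
chrom_survey_table.tsv`) is the in-paper regression fixture: chromosome 4
has 342 elements over 78.09 Mb (4.38/Mb, χ² = 153.3, strongly enriched)
and chromosome 1 is the only other enriched chromosome.

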