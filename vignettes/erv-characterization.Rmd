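---
title: "Methods: simulating and characterizing endogenous retroviruses"
author: "ervatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and characterizing endogenous retroviruses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ervatlas)
```

## Scope and model

ervatlas models a genome-wide ERV survey as six coupled analyses over one
data structure, the annotated element: detection of LTR pairs with internal
gene evidence, structural classification and nomenclature, molecular dating
from LTR divergence, chromosomal distribution statistics, protein feature
annotation, and expression integration. The package is desk-scale by
design: it does not attempt the full-genome numbers of a real survey
(thousands of elements on a 1.4 Gb assembly); instead, every method is
exercised and validated on simulated genomes with planted ground truth.

## The simulator and what it emulates

A provirus integrates with two identical LTRs; each LTR then evolves
independently. `synthesize_element()` inverts this clock: it draws one
ancestral LTR, gives each copy an independent Poisson(R·t·L) number of
substitution events (sites chosen uniformly with replacement, each event
replacing the current base with one of the other three uniformly — a
Jukes–Cantor-style process), and mutates the internal region along a single
lineage at the same rate R (default 1.46e-8 substitutions/site/year, the
neutral rate used for fish genomes). Under this process the expected
per-site LTR-pair divergence is 2·R·t before multiple-hit saturation, which
is what the dating formula assumes.

Structure tokens (`LTR-gag-pol-env-LTR`, `LTR-LTR`, `(LTR)-gag`, ...)
control which parts are synthesized. Gene ORFs are reverse-translated
random proteins; pol embeds a reference RT region from the class panel so
classification has a truth; env is built on a polar scaffold alphabet
(no C, R, K, M or strongly hydrophobic residues) so the planted furin, ISD,
cysteine and transmembrane payloads are the only motif matches — this is
what makes exact planted-coordinate recovery a meaningful test. Elements
are flanked by a 4 bp target-site duplication by default and placed
uniformly (rejection-sampled, deterministic under the seed) with a minimum
backbone gap.

Simplifications worth knowing about: no indels by default (the LTR decay
indel process is not modelled, so alignments are effectively ungapped), no
recombination or solo-LTR formation, TSDs do not mutate, and background
sequence is i.i.d. rather than repeat-rich. Passing tests therefore
demonstrate correctness of the methods under the stated clock model, not
robustness to every property of real genomes — in particular, real
repeat-dense genomes would stress the detector's non-redundancy logic far
more than the simulator does.

The default benchmark (`simulate_erv_genome()`) is a 10 Mb chromosome at
36.6% GC with 20 planted elements: ages uniform on 0–2 Mya, LTRs 300–800 bp
(centred near the ~500 bp mode reported for fish LTRs), a structure mix
dominated by LTR-LTR and pol-retaining forms, and classes dominated by
Gypsy and class I. These sizes keep a full detection run around half a
minute while leaving every stage statistically testable.

## Detection

`find_candidate_ltr_pairs()` hashes all k-mers (default k = 15), collects
position pairs sharing a k-mer at a spacing of 1–15 kb between LTR starts,
clusters pairs on a common diagonal (band ±20 bp, locus break at one
maximum LTR length), and extends each cluster in both directions by
ungapped x-drop extension (match +1, mismatch −2, drop 12). Candidates must
satisfy LTR length 100–2000 bp and pair identity ≥ 0.85; a duplicated 4–6 bp
flank is recorded as the TSD. The identity floor deliberately bounds
sensitivity: elements older than ~5 Mya at the fish rate fall below 0.85
identity and are invisible, matching the design goal of a young-element
detector. Solo LTRs are not called.

Scoring is additive evidence on the survey's reporting scale:
identity term (up to 300, scaled from an 0.70 floor), TSD bonus (30),
spacing plausibility (20), up to three long internal ORFs (120 each,
saturating at 400 aa) and internal motif hits (15 each, capped at 45). The
weights were calibrated once against the simulator so a complete young
provirus scores well above the 300 high-confidence flag, an LTR-LTR element
at ≤2 Mya clears the 250 reporting floor, and candidates from random
sequence (which rarely survive the identity floor at all) stay below 250.
Internal ORFs are tentatively labelled gag/pol/env by the position of their
midpoint in the internal region; this is a heuristic and single-gene
elements can be mislabelled — the labels feed the name suffix logic and
nothing else.

## Classification and nomenclature

Real surveys classify by an RT phylogeny. ervatlas substitutes
nearest-reference assignment: the element's internal region is locally
aligned (match 2, mismatch −3, gap 5/2) against a labelled RT panel, and
the best label is accepted when identity ≥ 0.6 **and** the alignment covers
≥ 50% of the shorter sequence. The coverage requirement is essential:
short perfect local matches occur in random sequence, and identity alone
would misclassify it. Both strands are tried in the pipeline. The shipped
panel is synthetic (one stop-free 220-aa reverse-translated protein per
class, fixed internal seed) so that simulated elements carry a known truth;
for real data, supply a curated panel FASTA (`label|accession` headers).
The class-I→E letter mapping treats unlabelled class I as epsilon-related;
this is the convention most consistent with fish survey names, and the
assignment metadata records that it is a default, not an inference.

Names are `prefix-[letter]chrom.fragment.ordinal[suffix]-species`.
Fragments are the 9 Mb / 2 kb-overlap segmentation; an element starting
inside an overlap zone belongs to the earlier fragment (the survey
convention is silent here; this choice is deterministic and configurable).
The ordinal is the rank of the element start within its fragment. G/P/E
suffixes mark genes extending beyond the LTR-to-LTR span.
`parse_name()∘format_name()` is the identity on all valid field tuples;
chromosome tokens are restricted to digits to keep the grammar unambiguous
against the class letters.

## Dating

`T = D/(2R)` in Mya. D is the p-distance over ungapped alignment columns
by default — the usual reading of "overall nucleotide divergence" — with
Jukes–Cantor `−(3/4)·ln(1 − 4p/3)` as an option. Gapped columns are
excluded from numerator and denominator because the simulator (and the
survey's clock model) has no indel process. Cohort filters mirror the
survey: score > 300 and the shorter LTR > 100 bp. Equal-length LTR pairs
are compared column-wise directly; unequal pairs are globally aligned
(match 1, mismatch −1, gap 5 + 1/base).

Numerical note: at 10 Mya the true path divergence 2·R·t = 0.292 is deep
enough for multiple hits, and the raw p-distance plateaus near 0.24,
biasing T low by ~17%. The parameter-recovery analyses therefore use the
JC model, which restores medians to within a few percent at all tested
ages (0.5, 2, 10 Mya); at ≤2 Mya the two models agree to ~3%. The p model
remains the default for user-facing dating because identical-LTR fractions
and young cohorts — the survey's main dating outputs — are unaffected.

## Distribution statistics

Density is detected/length (elements/Mb); expected counts are
length × genome-wide density; each chromosome gets a two-cell
(on/off-chromosome) chi-square with 1 df against the genome-wide total.
The packaged 25-chromosome fixture carries its published expected counts
and the genome-wide total (3,315) and density (2.31/Mb) as attributes: the
published density implies a slightly larger genome than the table's summed
lengths (unplaced scaffolds, presumably), so the fixture feeds the printed
expected values directly rather than recomputing them, and the per-table
detected sum (3,296) is not forced to match the total. Raw p-values are
reported (as surveys do) with a Bonferroni column alongside. Correlations
are Pearson with two-sided t-tests.

## Protein features

ORFs are scanned in all six frames (start codon required by default; the
reported interval excludes the stop codon). Motif scanners are overlapping
pattern matches in which a wildcard position accepts exactly the 20
standard amino acids — an `X` in the input never matches. The ISD locator
scores every 17-aa window against reference profiles by identity count;
the defaults are the simulator's synthetic consensi (real per-group
consensi are inputs, since published ones are shown only graphically), and
`annotate_env()` requires 12/17 matching columns before accepting a hit.
Residue 14 decides the immunosuppressive state: Q on, R/K off, otherwise
undetermined. Transmembrane segments are maximal runs of 19-residue
Kyte–Doolittle window means ≥ 1.6, merged across gaps < 5. Architecture is
valid when the present features are ordered furin < ISD < C-Xn-CC < TM;
the C-X-X-C motif sits in the surface domain and is deliberately outside
the order rule. Signal-peptide prediction is out of scope.

## Expression

TPM and FPKM follow their defining formulas exactly (FPKM library sizes
default to column sums but can be supplied). Thresholding uses
replicate means; specificity is set difference against the union of other
conditions. Virus response replaces model-based differential testing with
an explicit rule — infected mean above a floor and log2 fold change ≥ 1
with pseudocount 1 — because the survey's "substantially upregulated"
criterion is not parameterized; all rule constants are exposed. Trans
association keeps pairs with |Pearson R| > 0.85 and raw p < 0.01 (a BH
column is emitted alongside); an alternative stricter 0.99 floor seen in
some analyses is reachable via `r_min`. Cis association is interval
adjacency within 10 kb (overlap = distance 0).

The expression simulator works in TPM-scale abundance units topped up by a
background transcriptome to ~1e6 per sample, so expected TPM equals the
configured abundance; correlated pairs share a latent log-scale factor
(amplitude 1 on log2). Defaults: specific elements at 500 against a
baseline of 5, log-normal replicate noise sigma 0.3 (0.2 with planted
log2FC 2 for the infection design, n = 3), planted trans targets 0.99 —
the exponential transform attenuates log-scale correlation on the linear
scale, so targets much below ~0.95 are not reliably recoverable through an
0.85 gate, and the planted design uses the high-correlation regime the
trans rule is meant to capture. Noise-free mode (`sigma = 0`,
`count_noise = FALSE`) reproduces planted fold changes exactly and is used
for exactness tests.

## Reproducibility and problem sizes

All generators are deterministic under their seeds; the pipeline manifest
records the package version, seed, and a hash of the configuration, and
identical runs produce identical outputs. The test-suite and acceptance
problem sizes — 10 Mb / 20 elements for detection, 200 elements per age
for dating recovery, 10,000 cases for the name round trip and motif
oracles, 40 elements × 800 background features for expression — were
chosen as the smallest sizes at which the statistical assertions (recall,
precision, medians within 15%, FPR bounds) are stable across seeds.

## Known limitations

Tentative gag/pol/env labelling is positional; the detector cannot see
elements older than its identity floor or solo LTRs; class assignment is
nearest-reference, not phylogenetic, and inherits the panel's coverage;
dating reports point estimates only (no confidence intervals, no
among-site rate variation or CpG effects); the expression module does not
model read mapping, batch effects or overdispersion beyond the log-normal
layer.
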