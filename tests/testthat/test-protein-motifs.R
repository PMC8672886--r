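test_that("ORF finding matches a per-frame regex oracle", {
  orfs <- find_orfs("ATGAAATAA", min_len_aa = 1)
  expect_true("MK" %in% orfs$protein)
  fwd <- orfs[orfs$strand == "+", ]
  expect_equal(fwd$start[1], 0)
  expect_equal(fwd$end[1], 6)            # stop codon not included

  # no ATG in start-required mode
  expect_equal(nrow(find_orfs("CCCAAACCCAAA", min_len_aa = 1)), 0)
  expect_error(find_orfs("AC", min_len_aa = 1), "shorter")
  expect_error(find_orfs("ATGAAATAA", min_len_aa = 0), "min_len_aa")

  set.seed(21)
  for (i in 1:10) {
    nt <- random_dna_string(3000)
    mine <- sort(find_orfs(nt, min_len_aa = 20)$protein)
    expect_identical(mine, oracle_orf_proteins(nt, 20))
  }
})

test_that("ORFs are reported longest-first with in-bounds coordinates", {
  set.seed(33)
  nt <- random_dna_string(10000)
  orfs <- find_orfs(nt, min_len_aa = 10)
  expect_true(all(diff(orfs$length_aa) <= 0))
  expect_true(all(orfs$start >= 0 & orfs$end <= nchar(nt)))
  expect_true(all(orfs$end - orfs$start == orfs$length_aa * 3))
  # forward-strand coordinates extract a translatable ORF
  f <- orfs[orfs$strand == "+", ][1, ]
  sub <- substr(nt, f$start + 1, f$end)
  expect_equal(as.character(Biostrings::translate(Biostrings::DNAString(sub))),
               f$protein)
})

test_that("simple motif scanners follow their consensus definitions", {
  hits <- scan_simple_motifs("AARSKRGG")
  expect_equal(hits$start[hits$motif == "furin"], 2)
  expect_equal(nrow(scan_simple_motifs("CAAC")), 1)     # C-X-X-C
  expect_equal(nrow(scan_simple_motifs("CAAAC")), 0)
  h6 <- scan_simple_motifs("CAAAAAACC")
  expect_equal(h6$motif, "cx6cc")
  # X never matches a wildcard position
  expect_equal(nrow(scan_simple_motifs("CXXC")), 0)
})

test_that("motif scanners equal the brute-force oracle on random proteins", {
  set.seed(99)
  motifs <- c("furin", "cxxc", "cx5cc", "cx6cc", "cx7cc")
  for (i in 1:300) {
    # C/R/K-enriched alphabet so that matches actually occur
    prot <- paste(sample(c(strsplit("CCRRKKAGST", "")[[1]], "X"), 60,
                         replace = TRUE), collapse = "")
    hits <- scan_simple_motifs(prot)
    for (m in motifs) {
      expect_identical(sort(hits$start[hits$motif == m]),
                       sort(oracle_motif_positions(prot, m)),
                       info = paste(m, prot))
    }
  }
})

test_that("ISD location obeys the position-14 on/off rule", {
  profiles <- default_isd_profiles()
  on <- profiles[1]; stopifnot(substr(on, 14, 14) == "Q")
  prot_on <- paste0("SSTTNNDD", on, "EEGGHH")
  hit <- locate_isd(prot_on, profiles)
  expect_equal(hit$start, 8)
  expect_equal(hit$window, on)
  expect_equal(hit$residue14, "Q")
  expect_true(hit$suppressive)

  off <- sub("Q(...)$", "K\\1", on)     # K at position 14
  expect_false(locate_isd(paste0("SSTT", off, "EE"), profiles)$suppressive)

  amb <- sub("Q(...)$", "A\\1", on)
  expect_true(is.na(locate_isd(paste0("SSTT", amb, "EE"), profiles)$suppressive))

  expect_error(locate_isd("SHORT", profiles), "17")

  # translation invariance: prepending residues shifts the hit exactly
  for (pad in c(1, 5, 12)) {
    shifted <- locate_isd(paste0(strrep("G", pad), prot_on), profiles)
    expect_equal(shifted$start, 8 + pad)
  }
})

test_that("exhaustive ISD window scan matches a brute-force scorer", {
  profiles <- default_isd_profiles()
  set.seed(7)
  for (i in 1:30) {
    prot <- random_protein_string(sample(17:60, 1))
    hit <- locate_isd(prot, profiles)
    # brute force over all windows and profiles
    best <- -Inf; best_start <- NA
    x <- strsplit(prot, "")[[1]]
    for (w in 1:(length(x) - 16)) {
      for (pr in profiles) {
        sc <- sum(x[w:(w + 16)] == strsplit(pr, "")[[1]])
        if (sc > best) { best <- sc; best_start <- w - 1 }
      }
    }
    expect_equal(hit$score, best)
    expect_equal(hit$start, best_start)
  }
})

test_that("transmembrane prediction finds hydrophobic runs", {
  # 30 alanines (hydropathy 1.8) in a polar context
  prot <- paste0(strrep("D", 25), strrep("A", 30), strrep("D", 25))
  tm <- predict_tm(prot)
  expect_equal(nrow(tm), 1)
  expect_gte(tm$start, 20); expect_lte(tm$end, 60)

  expect_equal(nrow(predict_tm(strrep("D", 40))), 0)
  expect_error(predict_tm("AAA"), "shorter")

  # monotone in threshold: stricter threshold covers a subset of positions
  set.seed(13)
  prot2 <- paste(sample(names(ervatlas:::KD_SCALE), 300, replace = TRUE),
                 collapse = "")
  cover <- function(tm) {
    unlist(lapply(seq_len(nrow(tm)), function(i) tm$start[i]:tm$end[i]))
  }
  lo <- cover(predict_tm(prot2, threshold = 1.0))
  hi <- cover(predict_tm(prot2, threshold = 1.8))
  expect_true(all(hi %in% lo))
})

test_that("planted Env payloads are recovered at their planted coordinates", {
  sp <- element_spec("LTR-gag-pol-env-LTR", age_mya = 0, ltr_length = 300,
                     internal_length = 5000,
                     motif_payload = c("furin", "isd_on", "cxxc", "cx6cc", "tm"))
  el <- synthesize_element(sp, seed = 303)
  t1 <- el$truth
  env_nt <- substr(el$sequence, t1$env_start + 1, t1$env_end)
  prot <- find_orfs(env_nt, min_len_aa = 50, both_strands = FALSE)$protein[1]

  planted <- el$motifs
  ann <- annotate_env(prot)
  expect_equal(ann$furin_site,
               planted$aa_start[planted$motif_id == "furin"])
  expect_equal(ann$isd$start, planted$aa_start[planted$motif_id == "isd_on"])
  expect_true(ann$isd$suppressive)
  expect_true(planted$aa_start[planted$motif_id == "cxxc"] %in% ann$cxxc)
  expect_equal(ann$cxncc$start[ann$cxncc$n == 6],
               planted$aa_start[planted$motif_id == "cx6cc"])
  tm_planted <- planted[planted$motif_id == "tm", ]
  expect_true(any(ann$tm_segment$start <= tm_planted$aa_start &
                    ann$tm_segment$end >= tm_planted$aa_end - 3))
  expect_true(ann$architecture_valid)

  # an "off" payload yields suppressive = FALSE
  sp2 <- element_spec("LTR-gag-pol-env-LTR", age_mya = 0, ltr_length = 300,
                      internal_length = 5000,
                      motif_payload = c("furin", "isd_off", "cx6cc", "tm"))
  el2 <- synthesize_element(sp2, seed = 304)
  env2 <- substr(el2$sequence, el2$truth$env_start + 1, el2$truth$env_end)
  prot2 <- find_orfs(env2, min_len_aa = 50, both_strands = FALSE)$protein[1]
  expect_false(annotate_env(prot2)$isd$suppressive)
})

test_that("Env architecture validation enforces feature order", {
  profiles <- default_isd_profiles()
  isd <- profiles[1]
  sp <- function(...) paste0(...)
  good <- sp(strrep("S", 30), "RSKR", strrep("T", 20), isd, strrep("N", 15),
             "CGLSATVCC", strrep("D", 20), strrep("A", 25), strrep("S", 10))
  expect_true(annotate_env(good)$architecture_valid)

  # TM ahead of the furin site violates the order
  bad <- sp(strrep("A", 25), strrep("S", 30), "RSKR", strrep("T", 20), isd,
            strrep("N", 40))
  expect_false(annotate_env(bad)$architecture_valid)

  # featureless protein: vacuously valid, flagged
  none <- annotate_env(strrep("S", 40))
  expect_true(none$architecture_valid)
  expect_true(none$no_features)
})
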