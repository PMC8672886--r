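test_that("chromosome segmentation follows the 9 Mb / 2 kb overlap rule", {
  f1 <- segment_chromosome(9e6)
  expect_equal(nrow(f1), 1)
  expect_equal(c(f1$start, f1$end), c(0, 9e6))

  f2 <- segment_chromosome(18e6)
  expect_equal(f2$start, c(0, 8998000, 17996000))
  expect_equal(f2$end, c(9e6, 17998000, 18e6))

  expect_error(segment_chromosome(0), "length")

  # property: fragments tile [0, length) with the exact overlap
  set.seed(9)
  for (len in sample(3e6:40e6, 8)) {
    fr <- segment_chromosome(len)
    expect_equal(fr$start[1], 0)
    expect_equal(fr$end[nrow(fr)], len)
    if (nrow(fr) > 1) {
      expect_true(all(fr$end[-nrow(fr)] - fr$start[-1] == 2e3))
    }
  }
})

test_that("elements in the overlap zone belong to the earlier fragment", {
  expect_equal(fragment_of_position(0), 1L)
  expect_equal(fragment_of_position(8999000), 1L)     # inside the overlap
  expect_equal(fragment_of_position(9000000), 2L)     # past fragment 1
  expect_equal(fragment_of_position(17999000), 3L)
})

test_that("random sequence yields no candidate LTR pairs", {
  seq <- generate_background(1e5, 0.366, seed = 314)
  cands <- find_candidate_ltr_pairs(seq)
  expect_equal(nrow(cands), 0)
})

test_that("planted LTR pairs are recovered with the expected identity", {
  # age 0: identical LTRs
  el0 <- synthesize_element(element_spec("LTR-LTR", age_mya = 0,
                                         ltr_length = 500,
                                         internal_length = 3000), seed = 8)
  seq0 <- paste0(generate_background(20000, 0.366, seed = 1), el0$sequence,
                 generate_background(20000, 0.366, seed = 2))
  c0 <- find_candidate_ltr_pairs(seq0)
  expect_equal(nrow(c0), 1)
  expect_equal(c0$pair_identity, 1.0)
  expect_false(is.na(c0$tsd))

  # age 1 Mya: identity close to 1 - 2*R*1e6 = 0.9708
  set.seed(15)
  idents <- replicate(5, {
    el <- synthesize_element(element_spec("LTR-LTR", age_mya = 1,
                                          ltr_length = 500,
                                          internal_length = 3000))
    s <- paste0(generate_background(20000, 0.366), el$sequence,
                generate_background(20000, 0.366))
    cc <- find_candidate_ltr_pairs(s)
    expect_equal(nrow(cc), 1)
    cc$pair_identity
  })
  expect_lt(abs(mean(idents) - (1 - 2 * 1.46e-8 * 1e6)), 0.02)
})

test_that("degenerate detector parameters are rejected", {
  expect_error(detector_params(k = 4), "k")
  expect_error(detector_params(min_ltr = 500, max_ltr = 100), "min_ltr")
  expect_error(detector_params(min_spacing = 2e4, max_spacing = 1e3),
               "min_spacing")
})

test_that("the composite score is monotone in identity and calibrated", {
  el <- synthesize_element(element_spec("LTR-gag-pol-env-LTR", age_mya = 0.5,
                                        ltr_length = 500,
                                        internal_length = 5000,
                                        motif_payload = c("furin", "isd_on",
                                                          "cx6cc", "tm")),
                           seed = 99)
  seq <- paste0(generate_background(10000, 0.366, seed = 3), el$sequence,
                generate_background(10000, 0.366, seed = 4))
  cand <- find_candidate_ltr_pairs(seq)
  expect_equal(nrow(cand), 1)
  sc <- score_candidate(cand[1, ], seq)
  # complete planted element clears the high-confidence threshold
  expect_gt(sc$score, 300)
  expect_named(sc$components, c("identity", "tsd", "spacing", "orf", "motif"))
  expect_gt(sc$components[["orf"]], 0)

  # same candidate with degraded identity scores lower
  cand_low <- cand; cand_low$pair_identity <- cand$pair_identity - 0.1
  expect_lt(score_candidate(cand_low[1, ], seq)$score, sc$score)

  # zero weights: zero score
  w0 <- score_weights(identity = 0, tsd = 0, spacing = 0, orf = 0, motif = 0)
  expect_equal(score_candidate(cand[1, ], seq, weights = w0)$score, 0)

  # an LTR-LTR element of the same age scores lower than the complete one
  el2 <- synthesize_element(element_spec("LTR-LTR", age_mya = 0.5,
                                         ltr_length = 500,
                                         internal_length = 5000), seed = 100)
  seq2 <- paste0(generate_background(10000, 0.366, seed = 5), el2$sequence,
                 generate_background(10000, 0.366, seed = 6))
  cand2 <- find_candidate_ltr_pairs(seq2)
  expect_equal(nrow(cand2), 1)
  expect_lt(score_candidate(cand2[1, ], seq2)$score, sc$score)
})

test_that("element calling resolves overlaps and respects the threshold", {
  expect_equal(nrow(call_elements(NULL, "ACGT")), 0)

  el <- synthesize_element(element_spec("LTR-gag-pol-LTR", age_mya = 0.2,
                                        ltr_length = 400,
                                        internal_length = 4000), seed = 12)
  seq <- paste0(generate_background(5000, 0.366, seed = 7), el$sequence,
                generate_background(5000, 0.366, seed = 8))
  cand <- find_candidate_ltr_pairs(seq)
  # duplicate the candidate shifted slightly: the higher-scoring call wins
  cand2 <- rbind(cand, cand)
  cand2$ltr5_start[2] <- cand2$ltr5_start[2] + 10L
  cand2$pair_identity[2] <- cand2$pair_identity[2] - 0.05
  calls <- call_elements(cand2, seq)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$start, cand$ltr5_start[1])
  expect_equal(calls$end, cand$ltr3_end[1])
  expect_true(all(calls$score >= 250))
  # detections stay within bounds and coordinates round-trip through BED
  expect_gte(calls$start, 0)
  expect_lte(calls$end, nchar(seq))
  tmp <- tempfile(fileext = ".bed")
  write_elements_bed(calls, tmp)
  back <- read_elements_bed(tmp)
  expect_equal(back$start, calls$start)
  expect_equal(back$end, calls$end)
})

test_that("the detector recovers planted elements on a small benchmark", {
  sim <- simulate_erv_genome(n_elements = 8, genome_length = 2e6, seed = 5)
  calls <- detect_elements(sim$genome)
  ev <- evaluate_detection(calls, sim$truth)
  expect_gte(ev$recall, 0.9)
  expect_gte(ev$precision, 0.9)
  expect_error(detect_elements(character(0)), "empty genome")
})
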