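el_row <- function(ltr5 = NA, ltr3 = NA, gag = NA, pol = NA, env = NA) {
  data.frame(ltr5_start = ltr5, ltr3_start = ltr3, gag_start = gag,
             pol_start = pol, env_start = env)
}

test_that("structure classification covers all presence/absence patterns", {
  expect_equal(classify_structure(el_row(ltr5 = 0, ltr3 = 5000)), "LTR-LTR")
  expect_equal(classify_structure(el_row(ltr5 = 0, ltr3 = 5000, pol = 1000)),
               "LTR-pol-LTR")
  expect_equal(classify_structure(el_row(ltr5 = 0, gag = 1000)), "(LTR)-gag")
  expect_equal(classify_structure(el_row(ltr3 = 5000, env = 1000)),
               "env-(LTR)")
  expect_equal(classify_structure(
    el_row(ltr5 = 0, ltr3 = 9000, gag = 1000, pol = 3000, env = 6000)),
    "LTR-gag-pol-env-LTR")
  expect_equal(classify_structure(el_row(pol = 0)), "pol")
  expect_error(classify_structure(el_row()), "no recognizable parts")

  # property: a pure function of the five presence flags, genes in order
  for (mask in 1:31) {
    flags <- as.logical(bitwAnd(mask, c(1L, 2L, 4L, 8L, 16L)))
    row <- el_row(ltr5 = if (flags[1]) 0 else NA,
                  ltr3 = if (flags[2]) 9000 else NA,
                  gag = if (flags[3]) 1000 else NA,
                  pol = if (flags[4]) 3000 else NA,
                  env = if (flags[5]) 6000 else NA)
    tok <- classify_structure(row)
    expect_identical(tok, classify_structure(row))
    genes <- intersect(c("gag", "pol", "env"),
                       strsplit(tok, "-", fixed = TRUE)[[1]])
    expect_identical(genes, c("gag", "pol", "env")[flags[3:5]])
  }
})

test_that("the structure census reports correct fractions", {
  els <- rbind(el_row(ltr5 = 0, ltr3 = 5e3), el_row(ltr5 = 0, ltr3 = 5e3),
               el_row(ltr5 = 0, ltr3 = 9e3, gag = 1e3, pol = 3e3, env = 6e3),
               el_row(ltr5 = 0, ltr3 = 9e3, gag = 1e3, pol = 3e3, env = 6e3))
  cen <- structure_census(els)
  expect_equal(sort(cen$fraction), c(0.5, 0.5))
  expect_equal(sum(cen$fraction), 1, tolerance = 1e-12)
  expect_equal(attr(cen, "both_ltr_fraction"), 1)

  single <- structure_census(els[1, , drop = FALSE])
  expect_equal(single$fraction, 1.0)
  expect_equal(nrow(structure_census(els[0, ])), 0)
})

test_that("class assignment matches the reference panel", {
  panel <- default_rt_panel()
  # identical query
  res <- assign_class_by_reference(unname(panel[1]), panel)
  expect_equal(res$class_label, "Gypsy")
  expect_gt(res$identity, 0.99)

  # 5% substitutions keep the label
  set.seed(64)
  q <- ervatlas:::mutate_sequence(unname(panel[2]), rate = 1, years = 0.05)
  expect_equal(assign_class_by_reference(q, panel)$class_label, "Bel")

  # 10% divergence from the panel still classifies (planted-class regime)
  q2 <- ervatlas:::mutate_sequence(unname(panel[4]), rate = 1, years = 0.10)
  expect_equal(assign_class_by_reference(q2, panel)$class_label, "classI")

  # random sequence stays unclassified at the 0.6 identity floor
  rnd <- random_dna_string(660)
  expect_equal(assign_class_by_reference(rnd, panel)$class_label,
               "unclassified")

  expect_error(assign_class_by_reference("", panel), "empty query")
  expect_error(assign_class_by_reference("ACGT", character(0)), "empty")
})

test_that("the panel FASTA round-trips", {
  panel <- default_rt_panel()
  tmp <- tempfile(fileext = ".fasta")
  write_rt_panel(panel, tmp)
  back <- read_rt_panel(tmp)
  expect_identical(unname(back), unname(panel))
  expect_identical(names(back), names(panel))
})

test_that("the worked survey names format and parse", {
  n1 <- erv_name("ERV", "E", "5", 1, 38)
  expect_equal(format_name(n1), "ERV-E5.1.38-DanRer")
  p1 <- parse_name("ERV-E5.1.38-DanRer")
  expect_identical(p1, n1)

  n2 <- erv_name("ERV", "", "21", 2, 63, out_of_bound_suffix = "E")
  expect_equal(format_name(n2), "ERV-21.2.63E-DanRer")
  expect_identical(parse_name("ERV-21.2.63E-DanRer"), n2)

  # non class I-III elements start with ERVL and carry no class letter
  n3 <- erv_name("ERVL", "", "7", 1, 12)
  expect_match(format_name(n3), "^ERVL-")
  expect_error(erv_name("ERVL", "E", "7", 1, 12), "no class letter")

  expect_error(parse_name("ERX-5.1.38-DanRer"), "malformed")
  expect_error(parse_name("ERV-5.1-DanRer"), "malformed")
  expect_error(parse_name("ERVL-E5.1.38-DanRer"), "class letter")
})

test_that("name round-trip is the identity on random valid fields", {
  set.seed(2024)
  ok <- vapply(seq_len(10000), function(i) {
    fields <- random_valid_name_fields()
    identical(parse_name(format_name(fields)), fields)
  }, logical(1))
  expect_true(all(ok))
})

test_that("assign_names uses fragment-of-start and within-fragment rank", {
  els <- data.frame(
    element_id = c("a", "b", "c"),
    chrom = c("5", "5", "5"),
    start = c(100, 9100000, 8999000),  # last one inside the overlap zone
    end = c(5000, 9105000, 9003000),
    class_label = c("classI", NA, "classII"),
    ltr5_start = c(100, 9100000, 8999000), ltr5_end = c(600, 9100500, 8999500),
    ltr3_start = c(4500, 9104500, 9002500), ltr3_end = c(5000, 9105000, 9003000),
    gag_start = NA, gag_end = NA, pol_start = NA, pol_end = NA,
    env_start = NA, env_end = NA, stringsAsFactors = FALSE)
  named <- assign_names(els)
  # element c starts in the 2 kb overlap: earlier fragment (1), ordinal 2
  expect_equal(named$name[1], "ERV-E5.1.1-DanRer")
  expect_equal(named$name[3], "ERV-AB5.1.2-DanRer")
  expect_equal(named$name[2], "ERVL-5.2.1-DanRer")
})

test_that("out-of-bound genes earn the G/P/E suffix", {
  els <- data.frame(
    element_id = "a", chrom = "21", start = 1000, end = 8000,
    class_label = "classI",
    ltr5_start = 1000, ltr5_end = 1400, ltr3_start = 7600, ltr3_end = 8000,
    gag_start = NA, gag_end = NA, pol_start = NA, pol_end = NA,
    env_start = 7900, env_end = 9500,  # extends past the 3' LTR
    stringsAsFactors = FALSE)
  named <- assign_names(els)
  expect_match(named$name, "E-DanRer$")
  expect_equal(parse_name(named$name)$out_of_bound_suffix, "E")
})
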