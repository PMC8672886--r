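test_that("TPM and FPKM follow their defining formulas", {
  counts <- matrix(c(100, 100), ncol = 1,
                   dimnames = list(c("a", "b"), "s1"))
  # single feature: TPM is 1e6
  expect_equal(unname(normalize_counts(counts[1, , drop = FALSE],
                                       c(a = 500), "TPM")[1, 1]), 1e6)
  # equal counts, lengths L and 2L: TPM 2/3 and 1/3 of 1e6
  tpm <- normalize_counts(counts, c(a = 1000, b = 2000), "TPM")
  expect_equal(unname(tpm[, 1]), c(2 / 3, 1 / 3) * 1e6)
  # FPKM formula with explicit library size
  fpkm <- normalize_counts(counts, c(a = 1000, b = 2000), "FPKM",
                           library_sizes = 2e6)
  expect_equal(unname(fpkm[, 1]), c(100 * 1e9 / (1000 * 2e6),
                                    100 * 1e9 / (2000 * 2e6)))
  # property: TPM columns always sum to 1e6; FPKM invariant under joint
  # count-and-library scaling
  set.seed(10)
  m <- matrix(rpois(200, 50), nrow = 20,
              dimnames = list(paste0("f", 1:20), paste0("s", 1:10)))
  lens <- setNames(sample(200:5000, 20), rownames(m))
  expect_equal(unname(colSums(normalize_counts(m, lens, "TPM"))),
               rep(1e6, 10))
  f1 <- normalize_counts(m, lens, "FPKM")
  f2 <- normalize_counts(m * 3, lens, "FPKM")
  expect_equal(f1, f2)
  expect_error(normalize_counts(m, lens * 0, "TPM"), "lengths")
})

test_that("expressed sets apply the threshold to replicate means", {
  mat <- matrix(c(150, 50, 90, 110, 200, 40), nrow = 2,
                dimnames = list(c("e1", "e2"),
                                c("bud_r1", "bud_r2", "dpf5_r1")))
  sets <- expressed_set(mat, c("bud", "bud", "dpf5"), threshold = 100)
  expect_equal(sets$bud, "e1")          # mean(150, 90) = 120 > 100
  expect_equal(sets$dpf5, "e1")
  sets0 <- expressed_set(mat, c("bud", "bud", "dpf5"), threshold = 0)
  expect_setequal(sets0$bud, c("e1", "e2"))
})

test_that("specificity and overlaps obey inclusion-exclusion", {
  sets <- list(a = c("x", "y"), b = c("z"), c = c("w"))
  so <- specificity_and_overlap(sets)
  expect_equal(so$specific$a, c("x", "y"))   # disjoint: all specific
  expect_equal(so$union_size, 4)

  same <- specificity_and_overlap(list(a = c("x", "y"), b = c("x", "y")))
  expect_equal(lengths(same$specific), c(a = 0L, b = 0L))
  expect_equal(same$overlaps$size[same$overlaps$combination == "a&b"], 2)

  # random sets: |union| from inclusion-exclusion over the overlap table
  set.seed(19)
  for (i in 1:20) {
    ss <- lapply(1:3, function(j) {
      sample(paste0("f", 1:15), sample(0:10, 1))
    })
    names(ss) <- c("a", "b", "c")
    so <- specificity_and_overlap(ss)
    ie <- sum(so$overlaps$size * (-1)^(so$overlaps$k + 1))
    expect_equal(so$union_size, ie)
  }
  expect_error(specificity_and_overlap(list(a = "x")), "at least 2")
})

test_that("noise-free responsive elements show exact fold changes", {
  truth <- data.frame(element_id = c("sim001", "sim002"), chrom = "1",
                      start = c(0, 50000), end = c(6000, 56000),
                      stringsAsFactors = FALSE)
  des <- expression_design(conditions = c("ctrl", "infected"), n_reps = 2,
                           response_map = c(sim001 = 1),
                           sigma = 0, count_noise = FALSE,
                           n_background = 50, seed = 2)
  sim <- simulate_expression(truth, NULL, des)
  fpkm <- normalize_counts(sim$counts, sim$lengths, "FPKM",
                           library_sizes = rep(2e7, ncol(sim$counts)))
  ctrl <- fpkm[, sim$samples$condition == "ctrl"]
  inf <- fpkm[, sim$samples$condition == "infected"]
  expect_equal(unname(inf["sim001", 1] / ctrl["sim001", 1]), 2)
  expect_equal(unname(inf["sim002", 1]), unname(ctrl["sim002", 1]))
})

test_that("virus-responsive calls recover the planted response set", {
  truth <- data.frame(element_id = sprintf("sim%03d", 1:40), chrom = "1",
                      start = (0:39) * 5e4, end = (0:39) * 5e4 + 6000,
                      stringsAsFactors = FALSE)
  responsive <- sprintf("sim%03d", 1:10)
  des <- expression_design(conditions = c("ctrl", "infected"), n_reps = 3,
                           response_map = setNames(rep(2, 10), responsive),
                           sigma = 0.2, n_background = 500, seed = 5)
  sim <- simulate_expression(truth, NULL, des)
  fpkm <- normalize_counts(sim$counts, sim$lengths, "FPKM")
  vr <- virus_responsive(fpkm[, sim$samples$condition == "ctrl"],
                         fpkm[, sim$samples$condition == "infected"],
                         min_expr = 1, min_log2fc = 1)
  called <- vr$feature[vr$responsive]
  recall <- mean(responsive %in% called)
  null_feats <- setdiff(truth$element_id, responsive)
  fpr <- mean(null_feats %in% called)
  expect_gte(recall, 0.9)
  expect_lte(fpr, 0.05)
  # infected == control: nothing called
  vr0 <- virus_responsive(fpkm[, 1:3, drop = FALSE],
                          fpkm[, 1:3, drop = FALSE])
  expect_equal(sum(vr0$responsive), 0)
})

test_that("cis neighbours match the all-pairs brute force", {
  elements <- data.frame(element_id = c("e1", "e2"), chrom = c("1", "1"),
                         start = c(1000, 50000), end = c(6000, 56000),
                         stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = c("g1", "g2", "g3"), chrom = "1",
                      start = c(11000, 70990, 2000),
                      end = c(13000, 72000, 3000), stringsAsFactors = FALSE)
  hits <- cis_neighbors(elements, genes, window = 10000)
  # g1 is 5 kb downstream of e1; g3 overlaps e1 (distance 0)
  expect_equal(hits$distance[hits$element_id == "e1" & hits$gene_id == "g1"],
               5000)
  expect_equal(hits$distance[hits$element_id == "e1" & hits$gene_id == "g3"],
               0)
  # g2 is ~15 kb from e2: no hit
  expect_false(any(hits$element_id == "e2" & hits$gene_id == "g2"))

  # brute force on random intervals
  set.seed(23)
  e2 <- data.frame(element_id = paste0("e", 1:30),
                   chrom = sample(c("1", "2"), 30, TRUE),
                   start = sample.int(5e5, 30))
  e2$end <- e2$start + sample(500:8000, 30, TRUE)
  g2 <- data.frame(gene_id = paste0("g", 1:40),
                   chrom = sample(c("1", "2"), 40, TRUE),
                   start = sample.int(5e5, 40))
  g2$end <- g2$start + sample(500:8000, 40, TRUE)
  hits <- cis_neighbors(e2, g2, window = 10000)
  brute <- list()
  for (i in 1:30) for (j in 1:40) {
    if (e2$chrom[i] != g2$chrom[j]) next
    gap <- max(0, max(e2$start[i], g2$start[j]) - min(e2$end[i], g2$end[j]))
    if (gap <= 10000) {
      brute[[length(brute) + 1]] <- paste(e2$element_id[i], g2$gene_id[j], gap)
    }
  }
  expect_setequal(paste(hits$element_id, hits$gene_id, hits$distance),
                  unlist(brute))
})

test_that("trans association applies the correlation and p-value rule", {
  set.seed(31)
  n <- 12
  z <- rnorm(n)
  erv <- rbind(e1 = 10 + 5 * z, e2 = rnorm(n, 10))
  gene <- rbind(g1 = 3 + 2 * z, g2 = rnorm(n, 3))
  hits <- trans_partners(erv, gene, r_min = 0.85, p_max = 0.01)
  expect_true(any(hits$element_id == "e1" & hits$gene_id == "g1"))
  expect_equal(hits$R[hits$element_id == "e1" & hits$gene_id == "g1"], 1)

  # sign symmetry: negating the gene preserves |R| and retention
  hits_neg <- trans_partners(erv, -gene, r_min = 0.85, p_max = 0.01)
  expect_equal(abs(hits_neg$R[hits_neg$gene_id == "g1"]),
               abs(hits$R[hits$gene_id == "g1"]))

  # independent noise pairs are retained at most at the nominal rate
  set.seed(41)
  erv_n <- matrix(rnorm(50 * n), nrow = 50,
                  dimnames = list(paste0("e", 1:50), NULL))
  gene_n <- matrix(rnorm(40 * n), nrow = 40,
                   dimnames = list(paste0("g", 1:40), NULL))
  hits_n <- trans_partners(erv_n, gene_n, r_min = 0.85, p_max = 0.01)
  n_pairs <- 50 * 40
  # note |R| > 0.85 at n = 12 is rarer than p < 0.01 alone
  expect_lte(nrow(hits_n), n_pairs * 0.01 + 3 * sqrt(n_pairs * 0.01))

  # zero-variance features are skipped with a warning
  erv_z <- rbind(erv, e0 = rep(1, n))
  expect_warning(trans_partners(erv_z, gene), "zero-variance")
  expect_error(trans_partners(erv[, 1:2], gene[, 1:2]), ">= 3")
})

test_that("planted trans pairs are recovered from simulated counts", {
  truth <- data.frame(element_id = sprintf("sim%03d", 1:5), chrom = "1",
                      start = (0:4) * 1e5, end = (0:4) * 1e5 + 6000,
                      stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = sprintf("gene%03d", 1:5), chrom = "1",
                      start = (0:4) * 1e5 + 30000,
                      end = (0:4) * 1e5 + 32000, stringsAsFactors = FALSE)
  des <- expression_design(
    conditions = paste0("t", 1:4), n_reps = 3,
    trans_pairs = data.frame(element = "sim001", gene = "gene001", r = 0.99),
    sigma = 0.1, n_background = 300, seed = 8)
  sim <- simulate_expression(truth, genes, des)
  tpm <- normalize_counts(sim$counts, sim$lengths, "TPM")
  hits <- trans_partners(tpm[truth$element_id, , drop = FALSE],
                         tpm[genes$gene_id, , drop = FALSE],
                         r_min = 0.85, p_max = 0.01)
  hit <- hits[hits$element_id == "sim001" & hits$gene_id == "gene001", ]
  expect_equal(nrow(hit), 1)
  expect_gt(abs(hit$R), 0.9)
})

test_that("stage-specific planted elements are recovered under TPM > 100", {
  conds <- c("bud", "hpf28", "dpf2", "dpf5")
  truth <- data.frame(element_id = sprintf("sim%03d", 1:20), chrom = "1",
                      start = (0:19) * 5e4, end = (0:19) * 5e4 + 6000,
                      stringsAsFactors = FALSE)
  spec_map <- setNames(as.list(rep(conds, length.out = 8)),
                       sprintf("sim%03d", 1:8))
  des <- expression_design(conditions = conds, n_reps = 3,
                           specificity_map = spec_map, sigma = 0.3,
                           n_background = 800, seed = 3)
  sim <- simulate_expression(truth, NULL, des)
  tpm <- normalize_counts(sim$counts, sim$lengths, "TPM")
  sets <- expressed_set(tpm[truth$element_id, ], sim$samples$condition, 100)
  for (eid in names(spec_map)) {
    expect_true(eid %in% sets[[spec_map[[eid]]]], info = eid)
  }
  # unmapped elements stay below threshold everywhere
  unmapped <- setdiff(truth$element_id, names(spec_map))
  expect_false(any(unmapped %in% unlist(sets)))
  # and each specific element appears only in its own condition's set
  so <- specificity_and_overlap(sets)
  for (eid in names(spec_map)) {
    expect_true(eid %in% so$specific[[spec_map[[eid]]]], info = eid)
  }
})
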