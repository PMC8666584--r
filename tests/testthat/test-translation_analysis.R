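test_that("FPKM normalisation is correct and scale-invariant", {
  expect_equal(fpkm(100, 1000, total_fragments = 1e6), 100)
  expect_equal(fpkm(0, 500, total_fragments = 1e6), 0)
  withr::with_seed(51, {
    counts <- rpois(50, 200)
    lens <- sample(300:3000, 50)
    expect_equal(fpkm(counts * 10, lens, sum(counts) * 10),
                 fpkm(counts, lens, sum(counts)), tolerance = 1e-12)
  })
  expect_error(fpkm(c(0, 0), c(100, 100)), "total")
  expect_error(fpkm(10, 0, 1e6), "length")
})

test_that("translation efficiency divides polysome by input FPKM", {
  expect_equal(translation_efficiency(30, 10), 3)
  # genes below the input floor are masked, not zeroed
  expect_true(is.na(translation_efficiency(30, 0.5, min_input_fpkm = 1)))
  withr::with_seed(52, {
    poly <- runif(80, 0, 50)
    input <- runif(80, 0, 10)
    te <- translation_efficiency(poly, input, min_input_fpkm = 1)
    keep <- input >= 1
    expect_equal(te[keep], (poly / input)[keep], tolerance = 1e-12)
    expect_true(all(is.na(te[!keep])))
  })
})

test_that("translation ratio contrasts knockdown TE against control", {
  expect_equal(translation_ratio(2, 2)$log2_ratio, 0)
  expect_equal(translation_ratio(1, 2)$ratio, 0.5)
  expect_true(is.na(translation_ratio(NA, 2)$ratio))
})

test_that("measured log2 ratios recover the implanted effect with unit slope", {
  cfg <- te_sim_config(n_genes = 3000, sigma = 0, dispersion = 0.05,
                       seed = 7)
  exp <- simulate_te_experiment(cfg)
  cts <- exp$counts
  te_c <- translation_efficiency(fpkm(cts$poly_ctrl, cts$length_nt),
                                 fpkm(cts$input_ctrl, cts$length_nt),
                                 min_input_fpkm = 0)
  te_k <- translation_efficiency(fpkm(cts$poly_kd, cts$length_nt),
                                 fpkm(cts$input_kd, cts$length_nt),
                                 min_input_fpkm = 0)
  lr <- translation_ratio(te_k, te_c)$log2_ratio
  ok <- is.finite(lr)
  slope <- coef(lm(lr[ok] ~ exp$truth$true_log2_te_ratio[ok]))[2]
  expect_gt(slope, 0.9)
  expect_lt(slope, 1.1)
})

test_that("m7G-codon frequency counts in-frame set codons", {
  p <- m7g_codon_frequency("AAGAAGTTT", "AAG")
  expect_equal(p$f, 2 / 3)
  expect_equal(m7g_codon_frequency("AAGAAGTTT", character(0))$f, 0)
  # terminal stop codon excluded from both sums
  expect_equal(m7g_codon_frequency("AAGTAA", "AAG")$f, 1)
  expect_equal(m7g_codon_frequency("AAGTAA", "AAG")$n_codons, 1)
  # internal stops are counted but flagged
  expect_warning(p2 <- m7g_codon_frequency("AAGTAATTTTAA", "AAG"),
                 "internal stop")
  expect_equal(p2$n_codons, 3)
  expect_error(m7g_codon_frequency("AAGA", "AAG"), "divisible")
})

test_that("frequency/TE correlation handles exact and degenerate input", {
  prof <- tibble::tibble(gene_id = letters[1:5], f = c(1, 2, 3, 4, 5) / 10)
  te <- tibble::tibble(gene_id = letters[1:5], value = c(2, 4, 6, 8, 10))
  res <- correlate_freq_te(prof, te)
  expect_equal(res$r, 1)
  expect_equal(res$n, 5)
  flat <- tibble::tibble(gene_id = letters[1:5], value = rep(1, 5))
  expect_error(correlate_freq_te(prof, flat), "degenerate")
  expect_error(correlate_freq_te(prof[1:2, ], te[1:2, ]), "at least 3")
})

test_that("TE classes use inclusive boundaries toward the extremes", {
  thr <- log2(1.5)
  cls <- classify_te_genes(c(0, -thr, thr, -2, 2, NA))
  expect_equal(as.character(cls),
               c("other", "decreased", "increased", "decreased",
                 "increased", NA))
  # class sizes equal a one-line filter oracle on a random fixture
  withr::with_seed(53, {
    lr <- rnorm(500, 0, 1)
    cls <- classify_te_genes(lr)
    expect_equal(unname(table(cls)["decreased"]),
                 sum(lr <= -thr), ignore_attr = TRUE)
    expect_equal(unname(table(cls)["increased"]),
                 sum(lr >= thr), ignore_attr = TRUE)
  })
  expect_error(classify_te_genes(0, threshold = 0), "threshold")
})

test_that("codon-frequency quantile split yields equal deterministic groups", {
  prof <- tibble::tibble(gene_id = paste0("g", 1:8), f = (1:8) / 10)
  sp <- split_by_codon_frequency(prof, q = 0.25)
  expect_equal(sp$n_per_group, 2)
  expect_equal(sp$low, c("g1", "g2"))
  expect_equal(sp$high, c("g7", "g8"))
  # ties broken by gene_id order, sizes still equal
  tied <- tibble::tibble(gene_id = paste0("g", 1:8), f = rep(0.5, 8))
  sp2 <- split_by_codon_frequency(tied, q = 0.25)
  expect_equal(sp2$low, c("g1", "g2"))
  expect_equal(sp2$high, c("g7", "g8"))
  # high-group mean frequency always >= low-group mean
  withr::with_seed(54, {
    rprof <- tibble::tibble(gene_id = paste0("g", 1:101),
                            f = runif(101))
    sp3 <- split_by_codon_frequency(rprof, q = 0.3)
    expect_gte(mean(rprof$f[rprof$gene_id %in% sp3$high]),
               mean(rprof$f[rprof$gene_id %in% sp3$low]))
  })
  expect_error(split_by_codon_frequency(prof, q = 0.6), "q must")
  expect_error(split_by_codon_frequency(prof[1:2, ], q = 0.1), "too few")
})

test_that("Mann-Whitney comparison matches closed forms and enumeration", {
  # identical groups: no evidence, p = 1
  expect_equal(compare_groups(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # fully separated 3 vs 3: exact two-sided p = 2 / choose(6, 3)
  sep <- compare_groups(c(4, 5, 6), c(1, 2, 3))
  expect_equal(sep$p_value, 0.1)
  expect_equal(sep$method, "exact")
  expect_equal(sep$direction, 1)
  # 5 vs 5 fixtures match the full C(10, 5) enumeration
  withr::with_seed(55, {
    for (i in 1:5) {
      a <- round(rnorm(5), 3)
      b <- round(rnorm(5, 0.8), 3)
      expect_equal(compare_groups(a, b)$p_value, oracle_mann_whitney_p(a, b),
                   tolerance = 1e-12)
    }
  })
  expect_error(compare_groups(1:2, 1:5), "at least 3")
})

test_that("TE-class codon profiles average per-gene codon frequencies", {
  prof <- m7g_codon_frequency(c("AAGAAGAAG", "TTTTTCTTA"), "AAG",
                              gene_id = c("g1", "g2"))
  cls <- factor(c("decreased", "other"),
                levels = c("decreased", "increased", "other"))
  tab <- te_class_codon_profile(prof, cls, "AAG")
  expect_equal(tab$mean_freq[tab$codon == "AAG"], 1)
  expect_true(tab$in_m7g_set[tab$codon == "AAG"])
  expect_equal(sum(tab$mean_freq), 1)
  expect_error(te_class_codon_profile(prof, cls, "AAG", class = "increased"),
               "no genes")

  # near-uniform random codon usage is recovered as ~1/61 per sense codon
  withr::with_seed(56, {
    sense <- setdiff(names(Biostrings::GENETIC_CODE),
                     c("TAA", "TAG", "TGA"))
    cds <- vapply(1:5, function(i) {
      paste(sample(sense, 1000, replace = TRUE), collapse = "")
    }, "")
  })
  suppressWarnings(
    uprof <- m7g_codon_frequency(cds, "AAG", gene_id = paste0("u", 1:5)))
  ucls <- factor(rep("decreased", 5),
                 levels = c("decreased", "increased", "other"))
  utab <- te_class_codon_profile(uprof, ucls, "AAG")
  expect_equal(utab$mean_freq[utab$codon %in% sense],
               rep(1 / 61, 61), tolerance = 0.25)
})
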