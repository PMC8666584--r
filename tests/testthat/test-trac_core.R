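tiny_ref <- function(lens = c(t1 = 79L, t2 = 85L)) {
  withr::with_seed(99, tibble::tibble(
    trna_id = names(lens),
    sequence = vapply(lens, function(l) {
      paste0(random_dna(l - 3L), "CCA")
    }, ""),
    anticodon = "AAA", isotype = "Lys", length = unname(lens),
    source_ids = as.list(names(lens))))
}

test_that("pileup counts depth and start positions correctly", {
  ref <- tiny_ref(c(t1 = 79L))
  one <- tibble::tibble(trna_id = "t1", start = 1L, end = 20L)
  pu <- compute_pileup(one, ref)
  expect_equal(pu$depth, c(rep(1L, 20), rep(0L, 59)))
  expect_equal(pu$starts[1], 1L)
  expect_equal(sum(pu$starts), 1L)

  two <- tibble::tibble(trna_id = "t1", start = c(1L, 46L), end = 79L)
  pu2 <- compute_pileup(two, ref)
  expect_equal(pu2$depth[pu2$position == 46], 2L)
  expect_equal(pu2$starts[pu2$position == 46], 1L)
})

test_that("pileup equals a per-read brute-force oracle exactly", {
  ref <- tiny_ref()
  withr::with_seed(123, {
    aln <- tibble::tibble(
      trna_id = sample(ref$trna_id, 100, replace = TRUE))
    len <- ref$length[match(aln$trna_id, ref$trna_id)]
    aln$start <- vapply(len, function(l) sample(l, 1), 1L)
    aln$end <- aln$start +
      vapply(len - aln$start, function(m) sample(0:m, 1), 1L)
  })
  pu <- compute_pileup(aln, ref)
  for (id in ref$trna_id) {
    o <- oracle_pileup(aln[aln$trna_id == id, ],
                       ref$length[ref$trna_id == id])
    expect_identical(pu$depth[pu$trna_id == id], o$depth)
    expect_identical(pu$starts[pu$trna_id == id], o$starts)
  }
  # conservation: every read starts somewhere, starts never exceed depth
  expect_equal(sum(pu$starts), nrow(aln))
  expect_true(all(pu$starts <= pu$depth))
})

test_that("pileup rejects malformed or inconsistent alignments", {
  ref <- tiny_ref(c(t1 = 79L))
  expect_error(compute_pileup(
    tibble::tibble(trna_id = "nope", start = 1L, end = 5L), ref),
    "unknown")
  expect_error(compute_pileup(
    tibble::tibble(trna_id = "t1", start = 10L, end = 5L), ref),
    "end < start")
  expect_error(compute_pileup(
    tibble::tibble(trna_id = "t1", start = 1L, end = 100L), ref),
    "bounds")
})

test_that("SAM input reproduces the alignment-table pileup", {
  skip_if_not_installed("Rsamtools")
  skip_if_not_installed("GenomicAlignments")
  ref <- tiny_ref(c(t1 = 79L))
  aln <- tibble::tibble(trna_id = "t1", start = c(1L, 46L, 46L),
                        end = c(79L, 79L, 60L))
  sam <- tempfile(fileext = ".sam")
  reads <- substr(rep(ref$sequence, 3), aln$start, aln$end)
  writeLines(c(
    "@HD\tVN:1.6\tSO:unknown",
    "@SQ\tSN:t1\tLN:79",
    sprintf("r%d\t0\tt1\t%d\t42\t%dM\t*\t0\t0\t%s\t*",
            1:3, aln$start, nchar(reads), reads),
    # one unmapped and one secondary record, both to be excluded
    "r4\t4\t*\t0\t0\t*\t*\t0\t0\tACGT\t*",
    sprintf("r5\t256\tt1\t2\t42\t10M\t*\t0\t0\t%s\t*",
            substr(ref$sequence, 2, 11))
  ), sam)
  expect_identical(compute_pileup(sam, ref), compute_pileup(aln, ref))
})

test_that("cleavage ratio divides starts by depth and masks low depth", {
  pu <- tibble::tibble(trna_id = "t1", position = 1:4,
                       depth = c(50L, 0L, 19L, 40L),
                       starts = c(5L, 0L, 10L, 10L))
  cr <- cleavage_ratio(pu, min_depth = 20)
  expect_equal(cr$ratio, c(0.1, NA, NA, 0.25))
  # masked is NA, never zero
  expect_true(is.na(cr$ratio[2]))
  # elementwise oracle where unmasked
  expect_equal(cr$ratio[c(1, 4)], (pu$starts / pu$depth)[c(1, 4)],
               tolerance = 1e-15)
  expect_error(cleavage_ratio(pu, min_depth = 0), "min_depth")
})

make_profile <- function(ratios, depth = 100L) {
  tibble::tibble(trna_id = "t1", position = seq_along(ratios),
                 depth = depth,
                 starts = as.integer(round(ratios * depth)),
                 ratio = ratios)
}

test_that("cleavage score is log2 of the treated/control ratio quotient", {
  tr <- make_profile(c(0.25, 0.32, NA, 0.5))
  ct <- make_profile(c(0.25, 0.02, 0.1, NA))
  sc <- cleavage_score(tr, ct)
  expect_equal(sc$score[1], 0)
  expect_equal(sc$score[2], 4)  # log2(16)
  expect_true(all(is.na(sc$score[3:4])))  # masking propagates

  # antisymmetry under arm exchange
  tr2 <- make_profile(c(0.4, 0.05, 0.2, 0.01))
  ct2 <- make_profile(c(0.01, 0.3, 0.2, 0.25))
  expect_equal(cleavage_score(tr2, ct2)$score,
               -cleavage_score(ct2, tr2)$score)

  # epsilon floors a zero control ratio instead of dividing by zero
  sc0 <- cleavage_score(make_profile(0.32), make_profile(0),
                        epsilon = 1e-4)
  expect_equal(sc0$score, log2(0.32 / 1e-4))

  # literal ratio-of-logs reading available behind the flag
  lit <- cleavage_score(make_profile(0.3), make_profile(0.01),
                        literal = TRUE)
  expect_equal(lit$score, log2(0.3) / log2(0.01))

  expect_error(cleavage_score(tr, ct[1:2, ]), "positions")
})

score_fixture <- function(position, score, ratio) {
  tibble::tibble(trna_id = "t1", position = position,
                 depth_treated = 1000L,
                 starts_treated = as.integer(round(ratio * 1000)),
                 ratio_treated = ratio, depth_control = 1000L,
                 starts_control = 10L, ratio_control = 0.01,
                 score = score)
}

test_that("m7G calls require window, score and ratio thresholds strictly", {
  expect_true(call_m7g_sites(score_fixture(47L, 4.5, 0.15))$passed)
  # outside the 46-48 window: not even a candidate
  expect_equal(nrow(call_m7g_sites(score_fixture(30L, 10, 0.5))), 0)
  # boundary values fail the strict inequalities
  expect_false(call_m7g_sites(score_fixture(46L, 4.0, 0.15))$passed)
  expect_false(call_m7g_sites(score_fixture(46L, 4.5, 0.1))$passed)
  # masked sites cannot be called
  expect_false(call_m7g_sites(score_fixture(46L, NA_real_, 0.2))$passed)
})

test_that("methylation level is the window maximum of the score track", {
  sc <- score_fixture(46:48, c(1, 5, 2), 0.2)
  lev <- methylation_levels(sc)
  expect_equal(lev$level, 5)
  expect_identical(methylation_levels(sc)$level,
                   methylation_levels(sc)$level)
  # all-masked window yields NA
  scna <- score_fixture(46:48, NA_real_, 0.2)
  expect_true(is.na(methylation_levels(scna)$level))
})

test_that("halving site cleavage lowers methylation levels", {
  cfg <- trac_sim_config(n_trnas = 12, reads_per_trna = 2000, seed = 8)
  sim <- simulate_trna_reference(cfg)
  track <- function(p_site, off) {
    tr <- simulate_trac_library(sim$reference, sim$truth, cfg, "treated",
                                p_site = p_site, seed_offset = off)
    ct <- simulate_trac_library(sim$reference, sim$truth, cfg,
                                "non_treated", seed_offset = off)
    cleavage_score(cleavage_ratio(compute_pileup(tr, sim$reference)),
                   cleavage_ratio(compute_pileup(ct, sim$reference)))
  }
  lev_ctrl <- methylation_levels(track(0.3, 0))
  lev_kd <- methylation_levels(track(0.15, 1))
  mod <- sim$truth$trna_id[sim$truth$modified]
  expect_lt(median(lev_kd$level[lev_kd$trna_id %in% mod]),
            median(lev_ctrl$level[lev_ctrl$trna_id %in% mod]))
})

test_that("paired methylation comparison matches closed forms", {
  # all-positive differences, n = 6: one-sided exact p = 2^-6
  ctrl <- c(5.1, 4.8, 6.2, 5.5, 4.9, 5.8)
  kd <- ctrl - c(0.5, 0.7, 0.4, 1.1, 0.2, 0.9)
  res <- compare_methylation_paired(ctrl, kd, alternative = "greater")
  expect_equal(res$p_value, 1 / 64)
  expect_equal(res$method, "exact")
  # perfectly antisymmetric differences: two-sided p = 1
  x <- c(1, 2, 3, 4, 5, 6)
  y <- x + c(-3, -2, -1, 1, 2, 3)
  expect_equal(compare_methylation_paired(x, y)$p_value, 1)
  expect_error(compare_methylation_paired(x, x), "zero")
  expect_error(compare_methylation_paired(1:3, 3:1), "at least 5")
})

test_that("exact signed-rank p-values match full sign enumeration", {
  withr::with_seed(21, {
    for (i in 1:5) {
      x <- round(rnorm(10, 5, 1), 3)
      y <- round(x - rnorm(10, 0.3, 0.8), 3)
      res <- compare_methylation_paired(x, y)
      expect_equal(res$p_value, oracle_signed_rank_p(x, y),
                   tolerance = 1e-12)
    }
  })
})

test_that("the site motif tallies flanking bases around calls", {
  ref <- tiny_ref(c(t1 = 79L, t2 = 85L))
  calls <- tibble::tibble(trna_id = c("t1", "t2"), position = c(46L, 47L),
                          cleavage_score = 5, treated_ratio = 0.3,
                          passed = TRUE)
  m <- site_motif(calls, ref, flank = 3)
  expect_equal(dim(m), c(4L, 7L))
  expect_equal(colSums(m), setNames(rep(1, 7), as.character(-3:3)))
  want <- oracle_motif_counts(ref$sequence, calls$position, 3)
  expect_identical(attr(m, "counts"), want)

  # single call gives one-hot columns spelling the flanking sequence
  one <- site_motif(calls[1, ], ref, flank = 2)
  window <- substr(unname(ref$sequence[1]), 44, 48)
  hot <- apply(one, 2, function(col) rownames(one)[col == 1])
  expect_equal(paste(hot, collapse = ""), window)

  none <- calls; none$passed <- FALSE
  expect_error(site_motif(none, ref), "no passing")
})

test_that("implanted sites are 100% G at the motif centre", {
  cfg <- trac_sim_config(n_trnas = 16, reads_per_trna = 1500, seed = 4)
  sim <- simulate_trna_reference(cfg)
  tr <- simulate_trac_library(sim$reference, sim$truth, cfg, "treated")
  ct <- simulate_trac_library(sim$reference, sim$truth, cfg, "non_treated")
  sc <- cleavage_score(cleavage_ratio(compute_pileup(tr, sim$reference)),
                       cleavage_ratio(compute_pileup(ct, sim$reference)))
  calls <- call_m7g_sites(sc)
  m <- site_motif(calls, sim$reference, flank = 4)
  expect_equal(unname(m["G", "0"]), 1)
})

test_that("raising site cleavage never lowers the site score on average", {
  cfg <- trac_sim_config(n_trnas = 8, reads_per_trna = 2000, seed = 10)
  sim <- simulate_trna_reference(cfg)
  site_scores <- function(p) {
    tr <- simulate_trac_library(sim$reference, sim$truth, cfg, "treated",
                                p_site = p)
    ct <- simulate_trac_library(sim$reference, sim$truth, cfg,
                                "non_treated")
    sc <- cleavage_score(cleavage_ratio(compute_pileup(tr, sim$reference)),
                         cleavage_ratio(compute_pileup(ct, sim$reference)))
    mod <- sim$truth[sim$truth$modified, ]
    sc$score[match(paste(mod$trna_id, mod$m7g_position),
                   paste(sc$trna_id, sc$position))]
  }
  expect_gt(mean(site_scores(0.4)), mean(site_scores(0.2)))
})
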