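test_that("marker completeness/contamination follow the single-copy rule", {
  bins <- tibble::tibble(contig_id = c("c1", "c2", "c3"), bin_id = c(0L, 0L, 1L))
  mk <- tibble::tibble(contig_id = c("c1", "c2"), marker_id = c("m1", "m2"))
  q <- marker_quality(bins, mk, universe = c("m1", "m2"))
  expect_equal(q$completeness, c(100, 0))
  expect_equal(q$contamination, c(0, 0))

  # universe of 100: 50 distinct, one duplicated -> (50, 1)
  universe <- sprintf("m%03d", 1:100)
  mk2 <- tibble::tibble(contig_id = "c1", marker_id = c(universe[1:50], "m001"))
  q2 <- marker_quality(tibble::tibble(contig_id = "c1", bin_id = 0L), mk2,
                       universe = universe)
  expect_equal(q2$completeness, 50)
  expect_equal(q2$contamination, 1)
  expect_error(marker_quality(bins, mk, universe = character()), "empty")
})

test_that("marker quality matches independent multiset arithmetic", {
  set.seed(8)
  contigs <- sprintf("c%d", 1:30)
  bins <- tibble::tibble(contig_id = contigs,
                         bin_id = sample(0:4, 30, replace = TRUE))
  universe <- sprintf("m%d", 1:12)
  mk <- tibble::tibble(contig_id = sample(contigs, 60, replace = TRUE),
                       marker_id = sample(universe, 60, replace = TRUE))
  q <- marker_quality(bins, mk, universe = universe)
  for (b in q$bin_id) {
    members <- bins$contig_id[bins$bin_id == b]
    seen <- mk$marker_id[mk$contig_id %in% members]
    expect_equal(q$completeness[q$bin_id == b],
                 100 * length(unique(seen)) / 12)
    expect_equal(q$contamination[q$bin_id == b],
                 100 * (length(seen) - length(unique(seen))) / 12)
  }
  # permutation invariance in contig order
  perm <- sample(30)
  expect_equal(marker_quality(bins[perm, ], mk, universe = universe), q)
})

test_that("HQ calls use strict inequalities", {
  q <- tibble::tibble(bin_id = 0:3,
                      completeness = c(90, 95, 95, 91),
                      contamination = c(4, 5, 0, 4.9))
  expect_equal(hq_call(q), c(2L, 3L))
})

test_that("checkpoint scores order by HQ count then summed completeness", {
  q0 <- tibble::tibble(bin_id = 0L, completeness = 50, contamination = 0)
  expect_equal(checkpoint_score(q0), list(n_hq = 0L, sum_completeness = 0))
  mk_q <- function(comps) tibble::tibble(bin_id = seq_along(comps) - 1L,
                                         completeness = comps,
                                         contamination = 0)
  s3 <- checkpoint_score(mk_q(c(95, 95, 95)))
  s2 <- checkpoint_score(mk_q(c(95, 95)))
  expect_gt(s3$n_hq, s2$n_hq)
  a <- checkpoint_score(mk_q(c(95, 95, 95)))     # sum 285
  b <- checkpoint_score(mk_q(c(95, 95, 91)))     # sum 281
  expect_equal(a$n_hq, b$n_hq)
  expect_gt(a$sum_completeness, b$sum_completeness)
  # monotone: adding an HQ bin never lowers the score
  expect_gte(s3$n_hq, s2$n_hq)
  expect_gte(s3$sum_completeness, s2$sum_completeness)
})

test_that("label metrics reproduce hand-computed confusion values", {
  # perfect binning
  bins <- tibble::tibble(contig_id = c("a", "b", "c", "d"),
                         bin_id = c(0L, 0L, 1L, 1L))
  gold <- tibble::tibble(contig_id = c("a", "b", "c", "d"),
                         genome_id = c("A", "A", "B", "B"))
  lens <- c(a = 100, b = 200, c = 300, d = 100)
  lm <- label_metrics(bins, gold, lens)
  expect_equal(lm$average_purity, 1)
  expect_equal(lm$average_completeness, 1)
  expect_equal(lm$f1, 1)

  # one bin mixing 800 bp of A with 200 bp of B (all of both genomes)
  bins2 <- tibble::tibble(contig_id = c("a", "b"), bin_id = c(0L, 0L))
  gold2 <- tibble::tibble(contig_id = c("a", "b"), genome_id = c("A", "B"))
  lm2 <- label_metrics(bins2, gold2, c(a = 800, b = 200))
  expect_equal(lm2$per_bin$purity, 0.8)
  expect_equal(lm2$per_bin$completeness, 1)   # all of A is in the bin

  # 3-genome, 6-contig table vs hand-derived numbers
  bins3 <- tibble::tibble(contig_id = sprintf("c%d", 1:6),
                          bin_id = c(0L, 0L, 1L, 1L, 2L, 2L))
  gold3 <- tibble::tibble(contig_id = sprintf("c%d", 1:6),
                          genome_id = c("A", "A", "B", "C", "C", "C"))
  lens3 <- setNames(c(100, 300, 200, 100, 150, 250), sprintf("c%d", 1:6))
  lm3 <- label_metrics(bins3, gold3, lens3)
  # bin0: pure A (400); bin1: majority B 200/300; bin2: pure C (400)
  # weighted purity = (400*1 + 300*(2/3) + 400*1) / 1100
  expect_equal(lm3$average_purity, (400 + 200 + 400) / 1100)
  # completeness: A 400/400, B 200/200, C 400/500; weights 400, 200, 500
  expect_equal(lm3$average_completeness,
               (1 * 400 + 1 * 200 + 0.8 * 500) / 1100)
  p <- lm3$average_purity; cm <- lm3$average_completeness
  expect_equal(lm3$f1, 2 * p * cm / (p + cm))
  expect_error(label_metrics(bins3, gold3[-1, ], lens3), "unlabeled")
})

test_that("purity and completeness are both 1 iff bins match gold", {
  set.seed(44)
  contigs <- sprintf("c%d", 1:20)
  lens <- setNames(sample(100:500, 20), contigs)
  gold <- tibble::tibble(contig_id = contigs,
                         genome_id = sample(c("A", "B", "C"), 20, replace = TRUE))
  # matching partition (relabeled)
  bins_eq <- tibble::tibble(contig_id = contigs,
                            bin_id = as.integer(factor(gold$genome_id,
                                                       levels = c("C", "A", "B"))))
  lm <- label_metrics(bins_eq, gold, lens)
  expect_equal(lm$average_purity, 1)
  expect_equal(lm$average_completeness, 1)
  # perturbed partitions are never perfect on both axes
  for (i in 1:10) {
    bins_p <- bins_eq
    j <- sample(20, 2)
    bins_p$bin_id[j] <- sample(0:3, 2, replace = TRUE)
    lmp <- label_metrics(bins_p, gold, lens)
    same <- isTRUE(all.equal(
      mclust::adjustedRandIndex(bins_p$bin_id, gold$genome_id), 1))
    if (!same)
      expect_true(lmp$average_purity < 1 || lmp$average_completeness < 1)
  }
})

test_that("bin_ari agrees with the reference implementation", {
  bins <- tibble::tibble(contig_id = c("a", "b", "c"), bin_id = c(0L, 0L, 1L))
  gold <- tibble::tibble(contig_id = c("a", "b", "c"),
                         genome_id = c("X", "X", "Y"))
  expect_equal(bin_ari(bins, gold), 1)
})
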