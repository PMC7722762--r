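test_that("jaccard and coverage fractions follow their definitions", {
  a <- intervals("c", c(0, 200), c(100, 300))
  expect_equal(jaccard(a, a), 1)
  expect_equal(jaccard(a, intervals("c", 500, 600)), 0)
  expect_equal(jaccard(intervals("c", 0, 100), intervals("c", 50, 150)),
               50 / 150)
  expect_warning(j0 <- jaccard(a[0, ], a[0, ]), "empty")
  expect_equal(j0, 0)

  expect_equal(coverage_fraction(intervals("c", 10, 20),
                                 intervals("c", 0, 100)), 1)
  expect_equal(coverage_fraction(intervals("c", 0, 100),
                                 intervals("c", 0, 25)), 0.25)
  expect_equal(coverage_fraction(a, intervals("c", 500, 600)), 0)
  expect_error(coverage_fraction(a[0, ], a), "empty query")
})

test_that("shuffling preserves lengths and respects exclusions", {
  g <- genome(c("chrA", "chrB"), c(1e6, 5e5))
  set.seed(5)
  x <- intervals(rep("chrA", 6), seq(0, 5e5, 1e5),
                 seq(0, 5e5, 1e5) + c(2e4, 3e4, 1e4, 5e4, 2e4, 4e4))
  bl <- intervals("chrA", 7e5, 8e5)
  lens <- chrom_lengths(g)
  for (i in 1:20) {
    s <- shuffle_intervals(x, g, blacklist = bl, no_overlap = TRUE)
    expect_equal(sort(s$end - s$start), sort(x$end - x$start))
    expect_equal(nrow(s), nrow(x))
    expect_true(all(s$end <= lens[s$chrom]))
    expect_equal(total_bp(intersect_intervals(s, bl)), 0)
    expect_equal(total_bp(s), sum(s$end - s$start)) # mutually disjoint
  }
  s2 <- shuffle_intervals(x, g, preserve_chrom = TRUE)
  expect_true(all(s2$chrom == "chrA"))
  expect_error(shuffle_intervals(intervals("c", 0, 9e5), genome("c", 1e6),
                                 blacklist = intervals("c", 1e5, 9e5),
                                 max_tries = 20),
               "too dense")
})

test_that("empirical overlap p-values obey the (k+1)/(N+1) bounds", {
  g <- genome("c", 6e6)
  set.seed(8)
  a <- shuffle_intervals(intervals(rep("c", 5), 1:5, 1:5 + 2e5), g)
  # disjoint fixed set: observed JI 0 is never exceeded strictly -> p = 1
  b <- intervals("c", 0, 1) # 1 bp, JI ~ 0
  r <- empirical_overlap_test(a, b, g, n = 10, randomize = "a", seed = 1)
  expect_equal(r$empirical_p, 1)
  expect_equal(length(r$random_jis), 10)
  expect_true(r$empirical_p >= 1 / 11 && r$empirical_p <= 1)

  # b = a shifted slightly: observed JI >> any random placement
  shifted <- intervals(a$chrom, a$start + 1e4, a$end + 1e4)
  r2 <- empirical_overlap_test(a, shifted, g, n = 400, randomize = "b",
                               seed = 2)
  expect_gt(r2$observed_ji, 0.8)
  expect_lte(r2$empirical_p, 0.005)
})

test_that("fisher overlap test equals hypergeometric enumeration", {
  g <- genome("c", 1e5) # 10 bins of 10 kb
  a <- intervals("c", 0, 5e4)       # bins 1..5
  b <- intervals("c", 0, 5e4)
  res <- fisher_overlap_test(a, b, g, bin_size = 1e4)
  expect_equal(res$p_value, 1 / choose(10, 5))
  expect_equal(res$p_value, fisher_upper_oracle(5, 5, 5, 10))
  expect_true(is.infinite(res$odds_ratio))

  # cross-check against stats::fisher.test on random sets
  set.seed(31)
  gg <- tiny_genome()
  for (i in 1:10) {
    x <- random_intervals(gg, 6)
    y <- random_intervals(gg, 6)
    r <- fisher_overlap_test(x, y, gg, bin_size = 500)
    if (is.na(r$odds_ratio)) next
    ft <- stats::fisher.test(r$table, alternative = "greater")
    expect_equal(r$p_value, ft$p.value, tolerance = 1e-9)
  }

  expect_warning(
    rd <- fisher_overlap_test(intervals("c", 0, 1e5), b, g, 1e4),
    "degenerate")
  expect_equal(rd$p_value, 1)
})

test_that("consensus and conservation match per-base support counting", {
  s1 <- intervals("c", 0, 100)
  s2 <- intervals("c", 50, 150)
  s3 <- intervals("c", 0, 150)
  res <- multi_sample_overlap(list(s1, s2, s3), min_support = 2)
  expect_equal(as.data.frame(res$consensus),
               data.frame(chrom = "c", start = 0, end = 150))
  # core (all 3) = [50, 100): fractions 50/100, 50/100, 50/150
  expect_equal(res$per_sample_conserved_fraction,
               c(0.5, 0.5, 50 / 150))

  same <- multi_sample_overlap(list(s1, s1, s1), 2)
  expect_equal(as.data.frame(same$consensus), as.data.frame(s1))
  expect_equal(same$per_sample_conserved_fraction, rep(1, 3))

  disj <- multi_sample_overlap(list(intervals("c", 0, 10),
                                    intervals("c", 20, 30),
                                    intervals("c", 40, 50)), 2)
  expect_equal(nrow(disj$consensus), 0)
  expect_equal(disj$per_sample_conserved_fraction, rep(0, 3))
  expect_error(multi_sample_overlap(list(s1), 2), "at least 2")
})
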