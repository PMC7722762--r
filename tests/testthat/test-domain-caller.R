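lr_track <- function(vals, bin = 1e4) {
  g <- genome("c", bin * length(vals))
  binned_track(g, bin, list(c = vals), normalization = "log2_ratio")
}

test_that("bin scoring splits on the recorded threshold with strict ties", {
  sc <- score_bins(lr_track(c(-1, -1, 2, 2)), gap_penalty = 10,
                   threshold_method = "median")
  expect_equal(sc$scores$c, c(-10, -10, 1, 1))
  expect_equal(sc$polarity_threshold, 0.5)

  sc2 <- score_bins(lr_track(c(-1, -1, 2, 2)), gap_penalty = 10)
  expect_equal(sc2$scores$c, c(-10, -10, 1, 1))

  # constant input: strict > at the split point leaves no enriched bin
  flat <- score_bins(lr_track(rep(0.7, 6)), gap_penalty = 5)
  expect_true(all(flat$scores$c == -5))

  # blacklisted bins are zero and non-informative regardless of ratio
  bl <- intervals("c", 20000, 30000)
  scb <- score_bins(lr_track(c(-1, -1, 9, 2)), 10, blacklist = bl)
  expect_equal(scb$scores$c[3], 0)
  expect_false(scb$informative$c[3])

  # zero reference coverage bins are non-informative
  g <- genome("c", 4e4)
  ref <- binned_track(g, 1e4, list(c = c(5, 0, 5, 5)))
  scr <- score_bins(lr_track(c(1, 1, -1, -1)), 10, reference = ref)
  expect_equal(scr$scores$c[2], 0)

  expect_error(score_bins(lr_track(c(1, 1)), 10,
                          blacklist = intervals("c", 0, 2e4)),
               "non-informative")
})

test_that("maximal segments match hand-worked and exhaustive oracles", {
  allpos <- maximal_segments(rep(1, 7))
  expect_equal(nrow(allpos), 1)
  expect_equal(allpos$score, 7)
  expect_equal(c(allpos$start_bin, allpos$end_bin), c(0, 7))

  ms <- maximal_segments(c(1, 1, -2, 1, 1, 1))
  expect_equal(ms$start_bin, c(0, 3))
  expect_equal(ms$end_bin, c(2, 6))
  expect_equal(ms$score, c(2, 3))

  expect_equal(nrow(maximal_segments(c(-1, -2, 0))), 0)

  set.seed(42)
  for (i in 1:30) {
    G <- sample(c(1, 2, 5), 1)
    x <- sample(c(1, -G), sample(5:25, 1), replace = TRUE)
    got <- maximal_segments(x)
    want <- segments_oracle(x)
    expect_equal(got$start_bin, want$start)
    expect_equal(got$end_bin, want$end)
    expect_equal(got$score, want$score)
  }
})

test_that("raising the gap penalty never increases covered bp", {
  set.seed(9)
  vals <- rnorm(600) + rep(c(0, 2), each = 100, times = 3)
  prev <- Inf
  for (G in c(1, 2, 5, 25, 50)) {
    sc <- score_bins(lr_track(vals), gap_penalty = G)
    segs <- maximal_segments(sc)
    covered <- if (nrow(segs)) sum(segs$end_bin - segs$start_bin) else 0
    expect_lte(covered, prev)
    prev <- covered
  }
})

test_that("self-comparison yields no calls and blacklist is never called", {
  arch <- make_architecture(c(chr1 = 8e6), n_domains = 2,
                            size_range = c(5e5, 1e6), enrichment_factor = 3,
                            seed = 3)
  s4 <- simulate_fraction_reads(arch, "S4", 1e5, seed = 1)
  s2 <- simulate_fraction_reads(arch, "S2", 1e5, seed = 2)

  null_calls <- call_domains(s4, s4, arch$genome, bin_size = 1e4,
                             n_permutations = 200, seed = 5)
  expect_equal(nrow(null_calls), 0)

  bl <- intervals("chr1", 2e6, 2.5e6)
  calls <- call_domains(s4, s2, arch$genome, bin_size = 1e4, blacklist = bl,
                        n_permutations = 300, seed = 5)
  expect_gt(nrow(calls), 0)
  expect_equal(total_bp(intersect_intervals(as_intervals_calls(calls), bl)),
               0)
  # call boundaries are bin-aligned
  expect_true(all(calls$start %% 1e4 == 0))
  expect_warning(call_domains(s4, s2, arch$genome, bin_size = 1e4,
                              n_permutations = 50, seed = 1),
                 "resolution")
})

test_that("caller presets carry the standard parameterizations", {
  ps <- domain_presets()
  expect_equal(ps$sammy[c("gap_penalty", "bin_size")],
               list(gap_penalty = 25, bin_size = 50))
  expect_equal(ps$h3k9me3[c("gap_penalty", "bin_size", "fdr")],
               list(gap_penalty = 10, bin_size = 100, fdr = 0.1))
  expect_equal(ps$laminAC[c("gap_penalty", "bin_size")],
               list(gap_penalty = 25, bin_size = 200))
  expect_equal(ps$laminB1[c("gap_penalty", "bin_size")],
               list(gap_penalty = 5, bin_size = 100))
})

test_that("broad peaks merge adjacent hot windows and stay rare under null", {
  g <- genome("c", 2e6)
  set.seed(4)
  # all reads in one window -> exactly one single-window peak
  hot <- data.frame(chrom = "c", midpoint = floor(runif(500, 10000, 12000)))
  pk <- broad_peaks(hot, g, window = 2000, z_threshold = 3)
  expect_equal(as.data.frame(pk),
               data.frame(chrom = "c", start = 10000, end = 12000))

  # two adjacent hot windows merge into one peak
  hot2 <- rbind(hot,
                data.frame(chrom = "c",
                           midpoint = floor(runif(500, 12000, 14000))))
  bg <- data.frame(chrom = "c", midpoint = floor(runif(50000, 0, 2e6)))
  pk2 <- broad_peaks(rbind(hot2, bg), g, window = 2000)
  hit <- pk2[pk2$start <= 10000 & pk2$end >= 14000, ]
  expect_equal(nrow(hit), 1)

  # uniform reads: significant fraction near the normal upper-tail mass
  pk3 <- broad_peaks(bg, g, window = 2000)
  expect_lte(total_bp(pk3) / 2e6, 0.01)
  expect_error(broad_peaks(bg[0, ], g), "empty")
})
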