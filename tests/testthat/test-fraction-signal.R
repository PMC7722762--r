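test_that("binning counts midpoints and normalizes to cpm", {
  g <- genome("c", 1e5)
  reads <- data.frame(chrom = "c", midpoint = c(5000, 15000, 15500))
  tr <- bin_reads(reads, g, 1e4)
  expect_equal(tr$values$c, c(1, 2, rep(0, 8)))
  expect_equal(sum(tr$values$c), nrow(reads)) # count conservation

  cpm <- bin_reads(reads, g, 1e4, normalize = "cpm")
  expect_equal(sum(cpm$values$c), 1e6, tolerance = 1e-6)

  expect_warning(z <- bin_reads(reads[0, ], g, 1e4, normalize = "cpm"),
                 "empty")
  expect_true(all(z$values$c == 0))
  expect_error(bin_reads(data.frame(chrom = "c", midpoint = 1e5), g, 1e4),
               "beyond chromosome end")
})

test_that("log-ratio is scale-free and matches direct evaluation", {
  g <- genome("c", 4e4)
  t1 <- binned_track(g, 1e4, list(c = c(10, 20, 30, 40)), library_size = 100)
  expect_true(all(log_ratio_track(t1, t1)$values$c == 0))

  set.seed(1)
  base <- rpois(4, 1000)
  r <- binned_track(g, 1e4, list(c = base), library_size = sum(base))
  t2 <- binned_track(g, 1e4, list(c = 2 * base),
                     library_size = sum(2 * base))
  expect_true(all(abs(log_ratio_track(t2, r)$values$c) < 0.01))

  # t = (3+1)/T_eff vs r = (1+1)/R_eff with T_eff = R_eff -> log2(2) = 1
  ta <- binned_track(g, 1e4, list(c = c(3, 1, 2, 2)), library_size = 8)
  tb <- binned_track(g, 1e4, list(c = c(1, 3, 2, 2)), library_size = 8)
  lr <- log_ratio_track(ta, tb, pseudocount = 1)
  expect_equal(lr$values$c[1], 1.0)
  expect_error(log_ratio_track(ta, binned_track(g, 2e4, list(c = c(1, 1)))),
               "mismatched grids")
})

test_that("smoothed difference is antisymmetric and peaks at single reads", {
  g <- genome("c", 2e4)
  a <- data.frame(chrom = "c", midpoint = c(4000, 9000, 9100))
  b <- data.frame(chrom = "c", midpoint = c(1000, 15000))
  expect_error(smoothed_difference(a[0, ], b[0, ], g), "empty")

  s_ab <- smoothed_difference(a, b, g, scale_by_library = FALSE)
  s_ba <- smoothed_difference(b, a, g, scale_by_library = FALSE)
  expect_equal(s_ab$values$c, -s_ba$values$c)

  same <- smoothed_difference(a, a, g, scale_by_library = FALSE)
  expect_true(all(same$values$c == 0))

  one <- smoothed_difference(data.frame(chrom = "c", midpoint = 10000),
                             b[0, ], g, scale_by_library = FALSE)
  expect_equal(which.max(one$values$c), 10000 / one$step + 1)
})

test_that("truncated kernel evaluation matches the dense oracle", {
  set.seed(7)
  g <- genome("c", 5e4)
  a <- data.frame(chrom = "c", midpoint = sort(floor(runif(100, 0, 5e4))))
  b <- data.frame(chrom = "c", midpoint = sort(floor(runif(80, 0, 5e4))))
  h <- 150; step <- 50
  s <- smoothed_difference(a, b, g, bandwidth = h, step = step,
                           scale_by_library = FALSE)
  grid <- (seq_along(s$values$c) - 1) * step
  dense <- vapply(grid, function(x)
    sum(dnorm(x - a$midpoint, 0, h)) - sum(dnorm(x - b$midpoint, 0, h)),
    numeric(1))
  peak <- max(abs(dense))
  expect_lt(max(abs(s$values$c - dense)), 1e-6 * peak)
})

test_that("reads round-trip as BED3 1-bp midpoint intervals", {
  g <- genome("c", 1e5)
  set.seed(14)
  reads <- data.frame(chrom = "c",
                      midpoint = sort(floor(runif(200, 0, 1e5))))
  p <- withr::local_tempfile(fileext = ".bed")
  write_reads_bed(reads, p)
  back <- read_reads_bed(p, genome = g)
  expect_equal(back$midpoint, reads$midpoint)
  expect_equal(back$chrom, reads$chrom)
})

test_that("down-sampling is Bernoulli thinning, deterministic by seed", {
  set.seed(2)
  g <- genome("c", 1e6)
  reads <- data.frame(chrom = "c", midpoint = floor(runif(1e5, 0, 1e6)))
  expect_identical(downsample_reads(reads, 1, seed = 1), reads)

  d1 <- downsample_reads(reads, 0.5, seed = 3)
  d2 <- downsample_reads(reads, 0.5, seed = 3)
  expect_identical(d1, d2)
  n <- nrow(reads)
  expect_lt(abs(nrow(d1) - 0.5 * n), 4 * sqrt(n * 0.25))
  expect_error(downsample_reads(reads, 0), "fraction")
})
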