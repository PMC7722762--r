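sizes <- c(chrA = 30e6, chrB = 30e6)

test_that("architecture placement respects count, bounds and determinism", {
  a0 <- make_architecture(sizes, n_domains = 0, seed = 1)
  expect_equal(nrow(a0$closed_domains), 0)

  a <- make_architecture(sizes, n_domains = 10, size_range = c(1e6, 5e6),
                         enrichment_factor = 3, seed = 7)
  d <- a$closed_domains
  expect_equal(nrow(d), 10)
  expect_true(all(d$start >= 0 & d$end <= chrom_lengths(a$genome)[d$chrom]))
  tot <- total_bp(d)
  expect_true(tot >= 10e6 && tot <= 50e6)
  # non-overlapping: flattening changes nothing
  expect_equal(tot, sum(d$end - d$start))

  b <- make_architecture(sizes, n_domains = 10, size_range = c(1e6, 5e6),
                         enrichment_factor = 3, seed = 7)
  expect_identical(as.data.frame(d), as.data.frame(b$closed_domains))

  expect_error(
    make_architecture(c(chr1 = 1e6), n_domains = 50,
                      size_range = c(5e5, 9e5), seed = 1, max_tries = 50),
    "non-overlapping")
})

test_that("fraction reads follow the planted multinomial weights", {
  # null case: factor 1 gives uniform density
  au <- make_architecture(c(chr1 = 2e6), n_domains = 2,
                          size_range = c(2e5, 4e5), enrichment_factor = 1,
                          seed = 5)
  r <- simulate_fraction_reads(au, "S4", 1e5, seed = 2)
  counts <- bin_reads(r, au$genome, 1e4)$values$chr1
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)

  expect_error(simulate_fraction_reads(au, "S9", 10), "unknown fraction")

  # enrichment contrast: in/out density ratio near the weight ratio
  a <- make_architecture(sizes, n_domains = 10, size_range = c(1e6, 5e6),
                         enrichment_factor = 3, seed = 7)
  memb <- unlist(sammytools:::domain_bin_membership(a$closed_domains,
                                                    a$genome, 1e4))
  ratio_for <- function(frac, seed) {
    v <- unlist(bin_reads(simulate_fraction_reads(a, frac, 1e6, seed),
                          a$genome, 1e4)$values)
    mean(v[memb]) / mean(v[!memb])
  }
  expect_true(ratio_for("S4", 11) >= 2.5 && ratio_for("S4", 11) <= 3.5)
  r2 <- ratio_for("S2", 12)
  expect_true(r2 >= 1 / 3.5 && r2 <= 1 / 2.5)
})

test_that("mark tracks are +/-1 indicators with optional noise", {
  a <- make_architecture(sizes, n_domains = 10, size_range = c(1e6, 5e6),
                         seed = 7)
  memb <- unlist(sammytools:::domain_bin_membership(a$closed_domains,
                                                    a$genome, 1e4))
  t0 <- simulate_mark_track(a, polarity = 1, noise_sd = 0, seed = 1)
  v <- unlist(t0$values)
  expect_true(all(v[memb] == 1) && all(v[!memb] == -1))

  tm <- simulate_mark_track(a, polarity = -1, noise_sd = 0, seed = 1)
  expect_equal(stats::cor(v, unlist(tm$values)), -1)

  tn <- simulate_mark_track(a, polarity = 1, noise_sd = 0.5, seed = 2)
  expect_gt(kernel_correlation(t0, tn, kernel_sd_bins = 3), 0.8)
})

test_that("chromatin-state painting partitions the genome", {
  a <- make_architecture(sizes, n_domains = 10, size_range = c(1e6, 5e6),
                         seed = 7)
  st <- paint_chromatin_states(a, seed = 3)
  # exact partition: covers everything and no base twice
  expect_equal(total_bp(st), sum(a$genome$length))
  expect_equal(sum(st$end - st$start), sum(a$genome$length))
  expect_true(all(st$name %in% sammytools:::CHROMATIN_STATES))

  hetq <- merge_intervals(st[st$name %in% c("Het", "Quies"), ])
  frac <- total_bp(intersect_intervals(hetq, a$closed_domains)) /
    total_bp(a$closed_domains)
  expect_gte(frac, 0.6)

  st2 <- paint_chromatin_states(a, seed = 3)
  expect_identical(as.data.frame(st), as.data.frame(st2))
})

test_that("transcript tables are null except at bivalent TSSs", {
  a <- make_architecture(sizes, n_domains = 10, size_range = c(1e6, 5e6),
                         seed = 7)
  st <- paint_chromatin_states(a, seed = 3)
  tx0 <- simulate_transcript_table(st, 5000, bivalent_effect = 1, seed = 4)
  expect_gt(stats::ks.test(tx0$pval, "punif")$p.value, 0.01)

  tx <- simulate_transcript_table(st, 5000, bivalent_effect = 0.2, seed = 5)
  expect_lt(median(tx$pval[tx$truth_bivalent]), 0.1)
  expect_gt(stats::ks.test(tx$pval[!tx$truth_bivalent], "punif")$p.value,
            0.01)
  expect_error(simulate_transcript_table(st, 10, bivalent_effect = 0),
               "bivalent_effect")
})

test_that("nucleus simulation honors foci count, bias and pixel size", {
  s0 <- simulate_nuclei(3, radius_px = 30, n_foci_range = c(0, 0), seed = 1)
  expect_equal(nrow(s0$truth), 0)
  expect_equal(length(s0$images), 3)

  s1 <- simulate_nuclei(10, radius_px = 40, n_foci_range = c(2, 5),
                        periphery_bias = 1, seed = 2)
  expect_true(all(s1$truth$proximity <= 0.2))

  s2 <- simulate_nuclei(1, radius_px = 50, pixel_size_um = 0.1, seed = 3)
  expect_equal(s2$nuclei$radius_um, 5)
})
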