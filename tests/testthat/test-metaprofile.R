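step_track <- function(domains, g, bin = 1e4) {
  memb <- sammytools:::domain_bin_membership(domains, g, bin)
  binned_track(g, bin, lapply(memb, as.numeric))
}

test_that("border profiles recover constant and step signals", {
  g <- genome("c", 1e7)
  dom <- intervals("c", c(2e6, 6e6), c(4e6, 8e6))
  const <- binned_track(g, 1e4, list(c = rep(3.5, 1000)))
  p <- border_profile(const, dom, side = "start", k_bins = 20)
  expect_true(all(p$mean == 3.5))
  expect_true(all(p$sem == 0))
  expect_equal(attr(p, "n_regions"), 2)

  st <- step_track(dom, g)
  ps <- border_profile(st, dom, side = "start", k_bins = 20)
  expect_equal(ps$mean[1], 0)    # -20 bins: outside
  expect_equal(ps$mean[41], 1)   # +20 bins: inside
  pe <- border_profile(st, dom, side = "end", k_bins = 20)
  expect_equal(pe$mean, rev(ps$mean)) # mirrored orientation

  expect_warning(border_profile(const, dom[1, ], side = "start", k_bins = 5),
                 "single region")
})

test_that("profiles are invariant to a common shift of signal and domains", {
  g <- genome("c", 1e7)
  set.seed(12)
  vals <- rnorm(1000)
  dom <- intervals("c", c(2e6, 5e6), c(3e6, 7e6))
  off <- 50e4 # 50 bins
  tr <- binned_track(g, 1e4, list(c = vals))
  tr_shift <- binned_track(g, 1e4, list(c = c(rep(0, 50), vals[1:950])))
  dom_shift <- intervals("c", dom$start + off, dom$end + off)
  p1 <- border_profile(tr, dom, side = "start", k_bins = 30)
  p2 <- border_profile(tr_shift, dom_shift, side = "start", k_bins = 30)
  expect_equal(p1$mean, p2$mean)
})

test_that("TSS profiles are strand-oriented with 2K+1 positions", {
  g <- genome("c", 1e6)
  set.seed(3)
  vals <- rnorm(10000) # 100-bp bins
  tr <- binned_track(g, 100, list(c = vals))
  tss <- data.frame(chrom = "c", position = c(2e5, 5e5), strand = c("+", "-"))
  p <- tss_profile(tr, tss, flank = 5000, bin = 100)
  expect_equal(nrow(p), 101)
  expect_equal(p$relative_bp, seq(-5000, 5000, 100))

  # a minus-strand TSS mirrors the plus-strand window exactly
  one_plus <- suppressWarnings(
    tss_profile(tr, data.frame(chrom = "c", position = 3e5,
                               strand = "+"), 5000, 100))
  one_minus <- suppressWarnings(
    tss_profile(tr, data.frame(chrom = "c", position = 3e5,
                               strand = "-"), 5000, 100))
  expect_equal(one_minus$mean, rev(one_plus$mean))

  # symmetric bump at the TSS peaks at position 0
  bump <- exp(-((seq_len(10000) - 3001)^2) / (2 * 10^2))
  trb <- binned_track(g, 100, list(c = bump))
  pb <- suppressWarnings(
    tss_profile(trb, data.frame(chrom = "c", position = 3e5 + 50,
                                strand = "+"), 5000, 100))
  expect_equal(which.max(pb$mean), 51)
})

test_that("common-peak gene selection uses strict intersection and window", {
  peaks1 <- intervals("c", c(1000, 5000), c(2000, 6000))
  peaks2 <- intervals("c", c(1500, 5000), c(2500, 6000))
  peaks3 <- intervals("c", 1500, 2500)
  tss <- data.frame(gene = c("g1", "g2", "g3"),
                    chrom = "c", position = c(1900, 5500, 3000))
  # common across all three = [1500, 2000): only g1's window reaches it
  got <- common_peak_gene_set(list(peaks1, peaks2, peaks3), tss,
                              window = 500)
  expect_equal(got, "g1")
  # g2's peak present in 2 of 3 sets only -> not selected
  expect_false("g2" %in% got)

  # TSS exactly `window` bp from the region edge: half-open miss
  tss_edge <- data.frame(gene = "e", chrom = "c", position = 2500)
  expect_equal(length(common_peak_gene_set(list(intervals("c", 1500, 2000)),
                                           tss_edge, window = 500)), 0)
  tss_in <- data.frame(gene = "e", chrom = "c", position = 2499)
  expect_equal(common_peak_gene_set(list(intervals("c", 1500, 2000)),
                                    tss_in, window = 500), "e")
  expect_error(common_peak_gene_set(list(peaks1), tss[0, ]), "empty")
})
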