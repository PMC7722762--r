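test_that("lancaster with weights 2 is Fisher's method", {
  res <- lancaster(c(0.5, 0.5))
  expect_equal(res$T, -2 * (log(0.5) + log(0.5)), tolerance = 1e-10)
  expect_equal(res$df, 4)
  expect_equal(res$p, chisq4_upper(res$T), tolerance = 1e-10)
  expect_equal(res$p, 0.5965736, tolerance = 1e-6)

  # single p with weight 2 returns the input p
  for (p in c(1e-8, 0.01, 0.37, 0.999)) {
    expect_equal(lancaster(p, 2)$p, p, tolerance = 1e-12)
  }
  allone <- lancaster(c(1, 1, 1))
  expect_equal(allone$T, 0)
  expect_equal(allone$p, 1)

  expect_warning(cl <- lancaster(c(0, 0.5)), "clamped")
  expect_true(is.finite(cl$T))
  expect_error(lancaster(numeric(0)), "empty")
  expect_error(lancaster(0.5, -1), "weights")
})

test_that("lancaster is monotone and handles general weights", {
  set.seed(6)
  for (i in 1:50) {
    p <- runif(5)
    w <- runif(5, 0.5, 4)
    base <- lancaster(p, w)$p
    p2 <- p
    j <- sample(5, 1)
    p2[j] <- p[j] * 0.5
    expect_lte(lancaster(p2, w)$p, base)
    expect_equal(base <= 1 && base > 0, TRUE)
  }
})

make_states <- function() {
  intervals("c", c(0, 1000, 2000, 3000, 4000),
            c(1000, 2000, 3000, 4000, 10000),
            name = c("Het", "Tx", "TssBiv", "ReprPC", "Quies"))
}

test_that("context assignment applies the 50% body and 100-nt TSS rules", {
  st <- make_states()
  tx <- data.frame(
    transcript = c("t1", "t2", "t3", "t4"),
    chrom = "c",
    start = c(0,    1020, 2950, 2800),
    end = c(1000,  3000, 3050, 3200),
    tss = c(0,     1020, 2950, 3100),
    pval = rep(0.5, 4), effect = rep(1, 4), weight = rep(2, 4))
  got <- assign_chromatin_context(tx, st)
  expect_equal(got$contexts[1], "Het")          # body 100% in Het
  # t2: 980/1980 in Tx (49.5%) -> Tx not assigned
  expect_false(grepl("Tx", got$contexts[2]))
  # t3: TSS window [2850,3050) overlaps TssBiv by exactly 100 -> bivalent
  expect_true(got$bivalent[3])
  # t4: TSS window [3000,3200) misses TssBiv entirely
  expect_false(got$bivalent[4])

  # domain filter drops transcripts whose body misses the filter
  flt <- intervals("c", 0, 1500)
  kept <- assign_chromatin_context(tx, st, domain_filter = flt)
  expect_equal(kept$transcript, c("t1", "t2"))

  bad <- intervals("c", 0, 10, name = "NotAState")
  expect_error(assign_chromatin_context(tx, bad), "unknown state")
})

test_that("group aggregation splits directions and applies BH", {
  st <- make_states()
  tx <- data.frame(
    transcript = paste0("t", 1:3), chrom = "c",
    start = c(0, 100, 4500), end = c(900, 950, 5400),
    tss = c(0, 100, 4500),
    pval = c(0.01, 0.2, 0.8), effect = c(1, -1, 1), weight = rep(2, 3))
  ctx <- assign_chromatin_context(tx, st)
  agg <- aggregate_by_group(ctx, group_by = "context")
  # one up + one down row for Het, one up row for Quies
  het_up <- agg[agg$group == "Het" & agg$direction == "up", ]
  expect_equal(het_up$n_transcripts, 1)
  expect_equal(het_up$p, 0.01, tolerance = 1e-12) # single-element identity
  expect_true(all(agg$q >= agg$p))

  # pathway mode with a membership table
  pw <- data.frame(pathway = c("P1", "P1", "P2"),
                   transcript = c("t1", "t3", "t2"))
  aggp <- aggregate_by_group(ctx, group_by = "pathway", pathways = pw,
                             direction_split = FALSE)
  p1 <- aggp[aggp$group == "P1", ]
  expect_equal(p1$n_transcripts, 2)
  expect_equal(p1$p, lancaster(c(0.01, 0.8))$p, tolerance = 1e-12)

  rk <- rank_groups_across(list(a = agg, b = agg))
  expect_equal(rk$rank, seq_len(nrow(rk)))
  expect_equal(rk$group[1], agg$group[which.max(-log10(agg$p))])
})

test_that("bivalent enrichment matches hypergeometric enumeration", {
  r <- bivalent_enrichment_test(5, 5, 5, 10)
  expect_equal(r$p_value, 1 / choose(10, 5))
  expect_equal(r$p_value, fisher_upper_oracle(5, 5, 5, 10))

  expect_equal(bivalent_enrichment_test(0, 5, 5, 20)$p_value, 1)

  # proportional draw: no enrichment signal
  r2 <- bivalent_enrichment_test(2, 10, 20, 100)
  expect_gte(r2$p_value, 0.5)

  # agreement with stats::fisher.test one-tailed
  r3 <- bivalent_enrichment_test(39, 144, 300, 4101)
  ft <- stats::fisher.test(r3$table, alternative = "greater")
  expect_equal(r3$p_value, ft$p.value, tolerance = 1e-9)

  expect_error(bivalent_enrichment_test(6, 5, 10, 20), "valid 2x2")
})

test_that("transcript tables round-trip through TSV", {
  st <- make_states()
  arch <- make_architecture(c(c = 1e7), 2, c(5e5, 1e6), 3, seed = 1)
  stp <- paint_chromatin_states(arch, seed = 2)
  tx <- simulate_transcript_table(stp, 50, 0.5, seed = 3)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_transcript_table(tx, p)
  back <- read_transcript_table(p)
  expect_equal(back$transcript, tx$transcript)
  expect_equal(back$pval, tx$pval, tolerance = 1e-9)
  expect_error(read_transcript_table(write_chrom_sizes(arch$genome, p)),
               "missing column")
})
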