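#' Jaccard index of two interval sets
#'
#' Base-pair intersection over union after flattening each set.
#'
#' @param a,b `genomic_intervals`.
#' @return Real in `[0, 1]`; 0 (with a warning) when both sets are empty.
#' @export
jaccard <- function(a, b) {
  ta <- total_bp(a)
  tb <- total_bp(b)
  if (ta + tb == 0) {
    warning("jaccard of two empty sets; returning 0")
    return(0)
  }
  inter <- intersect_bp(a, b)
  inter / (ta + tb - inter)
}

# total intersection bp without materializing the interval set
intersect_bp <- function(a, b) {
  chroms <- intersect(unique(a$chrom), unique(b$chrom))
  tot <- 0
  for (ch in chroms) {
    ai <- a$chrom == ch
    bi <- b$chrom == ch
    r <- .op_flat(.flatten_vec(a$start[ai], a$end[ai]),
                  .flatten_vec(b$start[bi], b$end[bi]), "intersect")
    if (!is.null(r)) tot <- tot + sum(r$end - r$start)
  }
  tot
}

#' Fraction of a query set covered by a subject set
#'
#' Asymmetric by design: `coverage_fraction(calls, lads)` is the precision
#' of the calls with respect to the reference, and
#' `coverage_fraction(lads, calls)` the sensitivity.
#'
#' @param query Non-empty `genomic_intervals`.
#' @param subject `genomic_intervals`.
#' @return Real in `[0, 1]`.
#' @export
coverage_fraction <- function(query, subject) {
  q <- total_bp(query)
  if (q == 0) stop("empty query set")
  intersect_bp(query, subject) / q
}

#' Randomly re-place an interval set along the genome
#'
#' Every interval keeps its length (and count) but gets a uniformly random
#' new position in the genome minus the blacklist; with `no_overlap` the
#' shuffled intervals are also mutually non-overlapping.
#'
#' @param x `genomic_intervals` to re-place.
#' @param genome A `sammy_genome`.
#' @param blacklist Optional `genomic_intervals` the shuffled intervals must
#'   not touch.
#' @param no_overlap Forbid mutual overlap (default TRUE).
#' @param preserve_chrom Keep each interval on its original chromosome.
#' @param max_tries Bounded retries per interval before failing.
#' @return A `genomic_intervals` of the same lengths.
#' @export
shuffle_intervals <- function(x, genome, blacklist = NULL,
                              no_overlap = TRUE, preserve_chrom = FALSE,
                              max_tries = 2000L) {
  if (!nrow(x)) return(empty_intervals())
  lens <- chrom_lengths(genome)
  bl <- if (!is.null(blacklist) && nrow(blacklist))
    merge_intervals(blacklist) else NULL
  widths <- x$end - x$start
  ord <- order(widths, decreasing = TRUE) # longest first eases packing
  placed_ch <- character(nrow(x))
  placed_st <- numeric(nrow(x))
  n_placed <- 0L
  hits_any <- function(set_ch, set_st, set_en, ch, st, en, upto) {
    if (upto == 0L) return(FALSE)
    i <- seq_len(upto)
    any(set_ch[i] == ch & set_st[i] < en & set_en[i] > st)
  }
  placed_en <- numeric(nrow(x))
  for (r in ord) {
    len <- widths[r]
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      if (preserve_chrom) {
        ch <- x$chrom[r]
        if (lens[[ch]] < len) break
      } else {
        fit <- names(lens)[lens >= len]
        if (!length(fit)) break
        ch <- if (length(fit) == 1) fit else
          sample(fit, 1, prob = lens[fit] - len + 1)
      }
      st <- floor(stats::runif(1, 0, lens[[ch]] - len + 1))
      en <- st + len
      if (!is.null(bl)) {
        b <- bl[bl$chrom == ch, , drop = FALSE]
        if (nrow(b) && any(b$start < en & b$end > st)) next
      }
      if (no_overlap &&
          hits_any(placed_ch, placed_st, placed_en, ch, st, en, n_placed))
        next
      n_placed <- n_placed + 1L
      placed_ch[n_placed] <- ch
      placed_st[n_placed] <- st
      placed_en[n_placed] <- en
      ok <- TRUE
      break
    }
    if (!ok)
      stop("could not re-place an interval of ", len,
           " bp after ", max_tries,
           " tries: set too dense for the available space")
  }
  intervals(placed_ch, placed_st, placed_en)
}

#' Shuffle-based empirical test of interval-set overlap
#'
#' Re-places one of the two sets `n` times (lengths and counts preserved,
#' blacklist excluded, optionally without mutual overlap), recomputes the
#' Jaccard index each time, and reports the one-tailed (greater) empirical
#' p-value `(1 + #{random JI >= observed}) / (1 + n)`, which is never 0.
#'
#' @param a,b `genomic_intervals`.
#' @param genome A `sammy_genome`.
#' @param blacklist Optional excluded regions.
#' @param n Number of randomizations (default 10000).
#' @param randomize Which set to re-place: `"a"` or `"b"`.
#' @param no_overlap Forbid mutual overlap among shuffled intervals.
#' @param preserve_chrom Keep intervals on their chromosome when shuffling.
#' @param seed Integer seed.
#' @return Object of class `overlap_shuffle`: `observed_ji`, `random_jis`,
#'   `empirical_p`, `random_mean`, `random_sem`, `n`.
#' @export
empirical_overlap_test <- function(a, b, genome, blacklist = NULL,
                                   n = 10000, randomize = c("a", "b"),
                                   no_overlap = TRUE,
                                   preserve_chrom = FALSE, seed = 1) {
  randomize <- match.arg(randomize)
  obs <- jaccard(a, b)
  mobile <- if (randomize == "a") a else b
  fixed <- if (randomize == "a") b else a
  random_jis <- with_seed(seed, {
    vapply(seq_len(n), function(i) {
      s <- shuffle_intervals(mobile, genome, blacklist = blacklist,
                             no_overlap = no_overlap,
                             preserve_chrom = preserve_chrom)
      jaccard(s, fixed)
    }, numeric(1))
  })
  p <- (1 + sum(random_jis >= obs)) / (1 + n)
  structure(list(observed_ji = obs, random_jis = random_jis,
                 empirical_p = p, random_mean = mean(random_jis),
                 random_sem = stats::sd(random_jis) / sqrt(n), n = n,
                 randomized = randomize),
            class = "overlap_shuffle")
}

#' @export
print.overlap_shuffle <- function(x, ...) {
  cat(sprintf(
    "<overlap shuffle> observed JI %.4f vs %d randomizations of '%s'\n",
    x$observed_ji, x$n, x$randomized))
  cat(sprintf("random JI %.4f +/- %.4f (mean +/- SEM); empirical p = %.4g\n",
              x$random_mean, x$random_sem, x$empirical_p))
  invisible(x)
}

#' Fisher exact test of binned co-occurrence of two interval sets
#'
#' The genome is partitioned into fixed bins; the 2x2 table classifies bins
#' by whether they overlap (>= 1 bp) set `a` and set `b`. The one-tailed
#' (enrichment) p-value is the hypergeometric upper tail.
#'
#' @param a,b `genomic_intervals`.
#' @param genome A `sammy_genome`.
#' @param bin_size Partition width in bp (default 10000).
#' @return List with `odds_ratio` (Inf-coded for perfect association),
#'   `p_value`, and the 2x2 `table` (rows: in/out of `a`; cols: in/out of
#'   `b`).
#' @export
fisher_overlap_test <- function(a, b, genome, bin_size = 10000) {
  if (bin_size <= 0) stop("bin_size must be > 0")
  in_a <- unlist(bins_hit(a, genome, bin_size), use.names = FALSE)
  in_b <- unlist(bins_hit(b, genome, bin_size), use.names = FALSE)
  x11 <- sum(in_a & in_b); x12 <- sum(in_a & !in_b)
  x21 <- sum(!in_a & in_b); x22 <- sum(!in_a & !in_b)
  tab <- matrix(c(x11, x12, x21, x22), 2, 2, byrow = TRUE,
                dimnames = list(a = c("in", "out"), b = c("in", "out")))
  ka <- x11 + x12; kb <- x11 + x21; N <- sum(tab)
  if (ka == 0 || ka == N || kb == 0 || kb == N) {
    warning("degenerate margins in Fisher overlap test; p = 1")
    return(list(odds_ratio = NA_real_, p_value = 1, table = tab))
  }
  p <- stats::phyper(x11 - 1, kb, N - kb, ka, lower.tail = FALSE)
  orat <- if (x12 == 0 || x21 == 0) Inf else (x11 * x22) / (x12 * x21)
  list(odds_ratio = orat, p_value = p, table = tab)
}

# logical per-bin: does the flattened set cover >= 1 bp of the bin
bins_hit <- function(x, genome, bin_size) {
  nb <- bin_counts(genome, bin_size)
  m <- merge_intervals(x)
  out <- lapply(genome$chrom, function(ch) {
    hit <- rep(FALSE, nb[[ch]])
    d <- m[m$chrom == ch, , drop = FALSE]
    for (r in seq_len(nrow(d))) {
      i0 <- floor(d$start[r] / bin_size) + 1
      i1 <- min(ceiling(d$end[r] / bin_size), nb[[ch]])
      if (i0 <= i1) hit[i0:i1] <- TRUE
    }
    hit
  })
  names(out) <- genome$chrom
  out
}

#' Consensus regions and conservation across samples
#'
#' The consensus is the set of bases covered by at least `min_support` of
#' the input sets. The conserved fraction of sample i is the fraction of
#' its bases covered by ALL sets.
#'
#' @param sets List of >= 2 `genomic_intervals`.
#' @param min_support Integer in `[2, length(sets)]`.
#' @return List with `consensus` (`genomic_intervals`) and
#'   `per_sample_conserved_fraction` (numeric, one per input set; NA for an
#'   empty set).
#' @export
multi_sample_overlap <- function(sets, min_support = 2) {
  if (length(sets) < 2) stop("need at least 2 interval sets")
  if (min_support < 2 || min_support > length(sets))
    stop("min_support must be in [2, number of sets]")
  flat <- lapply(sets, merge_intervals)
  support_at_least <- function(k) {
    all_df <- do.call(rbind, lapply(flat, as.data.frame))
    if (is.null(all_df) || !nrow(all_df)) return(empty_intervals())
    out <- lapply(unique(all_df$chrom), function(ch) {
      d <- all_df[all_df$chrom == ch, , drop = FALSE]
      cov <- IRanges::coverage(IRanges::IRanges(d$start + 1, d$end))
      ir <- IRanges::slice(cov, lower = k, rangesOnly = TRUE)
      .from_ir(ir, ch)
    })
    out <- do.call(rbind, out)
    if (is.null(out)) empty_intervals() else as_intervals(out)
  }
  consensus <- support_at_least(min_support)
  core <- support_at_least(length(sets))
  frac <- vapply(flat, function(s) {
    tb <- total_bp(s)
    if (tb == 0) return(NA_real_)
    total_bp(intersect_intervals(s, core)) / tb
  }, numeric(1))
  list(consensus = consensus, per_sample_conserved_fraction = frac)
}
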