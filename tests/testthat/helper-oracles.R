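# Shared fixtures and independent oracles used across the suite.

tiny_genome <- function(len = c(chrA = 10000, chrB = 8000)) {
  genome(names(len), len)
}

# Random interval set on a genome (may overlap itself unless flattened).
random_intervals <- function(g, n, max_len = 500) {
  lens <- chrom_lengths(g)
  ch <- sample(names(lens), n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  st <- floor(runif(n, 0, lens[ch] - len))
  intervals(ch, st, st + len)
}

# --- per-base bitmap oracle for interval algebra (small chromosomes only) --

bitmap_of <- function(x, g) {
  lens <- chrom_lengths(g)
  bm <- lapply(lens, function(L) logical(L))
  for (i in seq_len(nrow(x))) {
    ch <- x$chrom[i]
    bm[[ch]][(x$start[i] + 1):x$end[i]] <- TRUE
  }
  bm
}

intervals_of_bitmap <- function(bm) {
  out <- NULL
  for (ch in names(bm)) {
    v <- bm[[ch]]
    if (!any(v)) next
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    out <- rbind(out, data.frame(chrom = ch, start = starts[keep],
                                 end = ends[keep]))
  }
  if (is.null(out)) empty_intervals_df() else out
}

empty_intervals_df <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric())
}

bitmap_op <- function(a, b, g, op = c("intersect", "subtract", "union")) {
  op <- match.arg(op)
  ba <- bitmap_of(a, g)
  bb <- bitmap_of(b, g)
  bm <- switch(op,
               intersect = Map(`&`, ba, bb),
               subtract = Map(function(x, y) x & !y, ba, bb),
               union = Map(`|`, ba, bb))
  intervals_of_bitmap(bm)
}

bitmap_jaccard <- function(a, b, g) {
  ba <- unlist(bitmap_of(a, g))
  bb <- unlist(bitmap_of(b, g))
  u <- sum(ba | bb)
  if (u == 0) 0 else sum(ba & bb) / u
}

expect_same_intervals <- function(x, df) {
  xd <- as.data.frame(x)[, c("chrom", "start", "end")]
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(xd) <- rownames(df) <- NULL
  expect_equal(xd$chrom, as.character(df$chrom))
  expect_equal(xd$start, as.numeric(df$start))
  expect_equal(xd$end, as.numeric(df$end))
}

# --- exhaustive oracle for maximal scoring segments ------------------------
# Recursive extraction: take the maximum-sum subarray (ties: shortest, then
# leftmost), then recurse on the flanks. Quadratic, for short vectors only.

segments_oracle <- function(x, offset = 0) {
  n <- length(x)
  if (!n) return(NULL)
  best <- NULL
  for (i in seq_len(n)) {
    s <- 0
    for (j in i:n) {
      s <- s + x[j]
      if (s > 0) {
        if (is.null(best) || s > best$s + 1e-9 ||
            (abs(s - best$s) <= 1e-9 && (j - i) < (best$j - best$i))) {
          best <- list(i = i, j = j, s = s)
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  rbind(segments_oracle(x[seq_len(best$i - 1)], offset),
        data.frame(start = offset + best$i - 1, end = offset + best$j,
                   score = best$s),
        segments_oracle(if (best$j < n) x[(best$j + 1):n] else numeric(0),
                        offset + best$j))
}

# --- misc ------------------------------------------------------------------

# chi-square(df = 4) upper tail in closed form: exp(-T/2) * (1 + T/2)
chisq4_upper <- function(t) exp(-t / 2) * (1 + t / 2)

# one-tailed hypergeometric enumeration for a 2x2 table
fisher_upper_oracle <- function(x11, ka, kb, N) {
  ks <- x11:min(ka, kb)
  sum(choose(kb, ks) * choose(N - kb, ka - ks)) / choose(N, ka)
}

# synthetic circle-nucleus image; foci given as (x, y, r) rows
circle_image <- function(side = 200, cx = 100, cy = 100, r = 50,
                         foci = NULL, bg = 0.03, nuc = 0.2, fg = 0.9) {
  xs <- matrix(rep(seq_len(side), each = side), side)
  ys <- matrix(rep(seq_len(side), times = side), side)
  img <- matrix(bg, side, side)
  inside <- (xs - cx)^2 + (ys - cy)^2 <= r^2
  img[inside] <- nuc
  if (!is.null(foci)) {
    for (k in seq_len(nrow(foci))) {
      sel <- (xs - foci$x[k])^2 + (ys - foci$y[k])^2 <= foci$r[k]^2
      img[sel & inside] <- fg
    }
  }
  img
}
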