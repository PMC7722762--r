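#' Convert a log-ratio track into enrichment bin scores
#'
#' Informative bins (outside the blacklist, with non-zero reference
#' coverage) whose log-ratio exceeds a data-driven split point score `+1`;
#' all other informative bins score `-gap_penalty`. Non-informative bins
#' score 0. The default split point maximizes the between-class variance of
#' the informative log-ratios (Otsu's criterion on the raw values), which
#' coincides with the median split whenever the enriched mode covers less
#' than half the informative genome, and stays in the inter-mode gap
#' otherwise; `"median"` selects a strict median split. Ties at the split
#' point are non-enriched (strict `>`), so constant input yields no
#' positive bins.
#'
#' @param log_ratio A `binned_track` from [log_ratio_track()].
#' @param gap_penalty Positive penalty G for non-enriched bins.
#' @param blacklist Optional `genomic_intervals`; overlapping bins become
#'   non-informative.
#' @param reference Optional raw-count `binned_track`; zero-coverage bins
#'   become non-informative.
#' @param threshold_method `"otsu"` (default) or `"median"`.
#' @return Object of class `bin_scores`: per-chromosome `scores` and
#'   `informative` vectors plus `gap_penalty`, `polarity_threshold`,
#'   `threshold_method`, `bin_size`, `genome`.
#' @export
score_bins <- function(log_ratio, gap_penalty, blacklist = NULL,
                       reference = NULL,
                       threshold_method = c("otsu", "median")) {
  threshold_method <- match.arg(threshold_method)
  if (gap_penalty <= 0) stop("gap_penalty must be > 0")
  if (!is.null(reference) && !same_grid(log_ratio, reference))
    stop("mismatched grids")
  g <- log_ratio$genome
  bs <- log_ratio$bin_size
  info <- lapply(g$chrom, function(ch) {
    inf <- rep(TRUE, length(log_ratio$values[[ch]]))
    if (!is.null(reference)) inf <- inf & (reference$values[[ch]] > 0)
    inf
  })
  names(info) <- g$chrom
  if (!is.null(blacklist) && nrow(blacklist)) {
    bl <- merge_intervals(blacklist)
    for (ch in g$chrom) {
      b <- bl[bl$chrom == ch, , drop = FALSE]
      if (!nrow(b)) next
      nbin <- length(info[[ch]])
      for (r in seq_len(nrow(b))) {
        i0 <- floor(b$start[r] / bs) + 1
        i1 <- min(ceiling(b$end[r] / bs), nbin)
        if (i0 <= i1) info[[ch]][i0:i1] <- FALSE
      }
    }
  }
  vals <- unlist(lapply(g$chrom, function(ch)
    log_ratio$values[[ch]][info[[ch]]]), use.names = FALSE)
  if (!length(vals)) stop("all bins are non-informative")
  thr <- if (threshold_method == "median") stats::median(vals)
         else otsu_split(vals)
  scores <- lapply(g$chrom, function(ch) {
    s <- ifelse(log_ratio$values[[ch]] > thr, 1, -gap_penalty)
    s[!info[[ch]]] <- 0
    s
  })
  names(scores) <- g$chrom
  structure(list(scores = scores, informative = info,
                 gap_penalty = gap_penalty, polarity_threshold = thr,
                 threshold_method = threshold_method,
                 bin_size = bs, genome = g),
            class = "bin_scores")
}

# Between-class-variance maximizing split of a numeric vector (Otsu's
# criterion on the empirical values; candidates are midpoints between
# consecutive sorted unique values). Ties resolved toward the lower split.
otsu_split <- function(v) {
  u <- sort(unique(v))
  if (length(u) == 1) return(u)
  x <- sort(v)
  n <- length(x)
  csum <- cumsum(x)
  tot <- csum[n]
  k <- seq_len(n - 1)
  mu1 <- csum[k] / k
  mu2 <- (tot - csum[k]) / (n - k)
  bcv <- (k / n) * ((n - k) / n) * (mu1 - mu2)^2
  # restrict to positions where a split actually separates distinct values
  valid <- x[k] < x[k + 1]
  if (!any(valid)) return(u[1])
  best <- which(valid)[which.max(bcv[valid])]
  (x[best] + x[best + 1]) / 2
}

#' All maximal scoring segments of a bin-score vector
#'
#' Linear-scan implementation of the all-maximal-scoring-subsequences
#' algorithm (Ruzzo & Tompa): every reported segment has positive total
#' score, segments are disjoint, and no extension or trimming increases a
#' segment's score. Segments never span chromosomes.
#'
#' @param scores A `bin_scores` object, or a plain numeric vector (treated
#'   as a single chromosome).
#' @return Data.frame with columns `chrom`, `start_bin`, `end_bin`
#'   (0-based half-open bin indices) and `score`.
#' @export
maximal_segments <- function(scores) {
  if (is.numeric(scores))
    scores <- list(scores = list(seq = scores),
                   genome = genome("seq", max(length(scores), 1)))
  out <- lapply(names(scores$scores), function(ch) {
    seg <- rt_scan(scores$scores[[ch]])
    if (!nrow(seg)) return(NULL)
    data.frame(chrom = ch, start_bin = seg$start, end_bin = seg$end,
               score = seg$score, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(), start_bin = numeric(),
                      end_bin = numeric(), score = numeric())
  rownames(out) <- NULL
  out
}

# Ruzzo-Tompa scan over one numeric vector. Returns 0-based half-open bin
# index segments with their scores.
rt_scan <- function(x) {
  n <- length(x)
  # stack columns: start, end (0-based half-open), L (cum before), R (cum at end)
  st <- matrix(numeric(0), nrow = 4)
  cum <- 0
  k <- 0L
  starts <- numeric(64); ends <- numeric(64)
  Ls <- numeric(64); Rs <- numeric(64)
  for (i in seq_len(n)) {
    xi <- x[i]
    if (xi <= 0) { cum <- cum + xi; next }
    sL <- cum; cum <- cum + xi; sR <- cum
    s0 <- i - 1; s1 <- i
    repeat {
      j <- k
      while (j >= 1L && Ls[j] >= sL) j <- j - 1L
      if (j == 0L || Rs[j] >= sR) break
      # merge segments j..k and the new one
      sL <- Ls[j]; s0 <- starts[j]
      k <- j - 1L
    }
    k <- k + 1L
    if (k > length(starts)) {
      starts <- c(starts, numeric(length(starts)))
      ends <- c(ends, numeric(length(ends)))
      Ls <- c(Ls, numeric(length(Ls)))
      Rs <- c(Rs, numeric(length(Rs)))
    }
    starts[k] <- s0; ends[k] <- s1; Ls[k] <- sL; Rs[k] <- sR
  }
  if (k == 0L)
    return(data.frame(start = numeric(), end = numeric(), score = numeric()))
  idx <- seq_len(k)
  data.frame(start = starts[idx], end = ends[idx],
             score = Rs[idx] - Ls[idx])
}

# Maximum-subarray score (Kadane via cumulative sums); 0 when all <= 0.
max_subarray_score <- function(x) {
  if (!length(x)) return(0)
  cs <- cumsum(x)
  max(0, max(cs - cummin(c(0, cs[-length(cs)]))))
}

#' Built-in caller presets
#'
#' Parameter sets used for the assay's standard comparisons: SAMMY fraction
#' pairs (gap 25, bin 50 bp), H3K9me3 ChIP (fdr 0.1, gap 10, bin 100 bp),
#' Lamin A/C (gap 25, bin 200 bp) and Lamin B1 (gap 5, bin 100 bp).
#'
#' @return Named list of parameter lists.
#' @export
domain_presets <- function() {
  list(
    sammy = list(gap_penalty = 25, bin_size = 50, fdr = 0.05),
    h3k9me3 = list(gap_penalty = 10, bin_size = 100, fdr = 0.1),
    laminAC = list(gap_penalty = 25, bin_size = 200, fdr = 0.05),
    laminB1 = list(gap_penalty = 5, bin_size = 100, fdr = 0.05)
  )
}

#' Call broad enrichment domains from a target/reference fraction pair
#'
#' Full pipeline: bin both read sets, form the library-normalized log2
#' ratio, score bins (+1 / -gap_penalty / 0), extract all maximal scoring
#' segments, and assess significance against a genome-wide permutation null
#' in which the informative-bin scores are shuffled and the maximum segment
#' score recorded. Segment `p = (1 + #{perm max >= observed}) / (1 +
#' n_permutations)`, Benjamini-Hochberg corrected across segments; calls
#' with `q <= fdr` and informative-bin fraction at or above the threshold
#' are retained.
#'
#' @param target_reads,reference_reads Read data.frames (`chrom`,
#'   `midpoint`); the target is the less accessible fraction.
#' @param genome A `sammy_genome`.
#' @param bin_size Bin width in bp.
#' @param gap_penalty Penalty G for non-enriched bins.
#' @param fdr BH q-value cutoff in (0, 1).
#' @param blacklist Optional `genomic_intervals` excluded from scoring.
#' @param required_informative_fraction Minimum fraction of informative bins
#'   per retained call (default 0.98).
#' @param n_permutations Monte-Carlo permutations (default 1000; < 100
#'   warns about p-value resolution).
#' @param seed Integer seed for the permutation null.
#' @param pseudocount Pseudo-reads per bin for the log ratio.
#' @param threshold_method Split-point rule, see [score_bins()].
#' @param preset Optional name from [domain_presets()]; overrides bin_size,
#'   gap_penalty and fdr.
#' @return Object of class `domain_calls`: a data.frame (chrom, start, end,
#'   score, p_value, q_value, informative_fraction) with the call
#'   parameters, the polarity threshold and all pre-filter segments stored
#'   as attributes.
#' @examples
#' \donttest{
#' arch <- make_architecture(c(chrA = 5e6), n_domains = 2,
#'                           size_range = c(4e5, 8e5), seed = 2)
#' s4 <- simulate_fraction_reads(arch, "S4", 5e4, seed = 3)
#' s2 <- simulate_fraction_reads(arch, "S2", 5e4, seed = 4)
#' calls <- call_domains(s4, s2, arch$genome, bin_size = 1e4,
#'                       n_permutations = 200, seed = 5)
#' summary(calls)
#' }
#' @export
call_domains <- function(target_reads, reference_reads, genome,
                         bin_size = 10000, gap_penalty = 25, fdr = 0.05,
                         blacklist = NULL,
                         required_informative_fraction = 0.98,
                         n_permutations = 1000, seed = 1,
                         pseudocount = 0.5,
                         threshold_method = c("otsu", "median"),
                         preset = NULL) {
  if (!is.null(preset)) {
    ps <- domain_presets()[[match.arg(preset, names(domain_presets()))]]
    bin_size <- ps$bin_size; gap_penalty <- ps$gap_penalty; fdr <- ps$fdr
  }
  if (fdr <= 0 || fdr >= 1) stop("fdr must be in (0, 1)")
  if (!nrow(target_reads) || !nrow(reference_reads))
    stop("reads must be non-empty")
  if (n_permutations < 100)
    warning("n_permutations < 100: empirical p-value resolution is coarse")
  tt <- bin_reads(target_reads, genome, bin_size)
  rt <- bin_reads(reference_reads, genome, bin_size)
  lr <- log_ratio_track(tt, rt, pseudocount = pseudocount)
  sc <- score_bins(lr, gap_penalty, blacklist = blacklist, reference = rt,
                   threshold_method = threshold_method)
  segs <- maximal_segments(sc)
  params <- list(bin_size = bin_size, gap_penalty = gap_penalty, fdr = fdr,
                 required_informative_fraction = required_informative_fraction,
                 n_permutations = n_permutations, seed = seed,
                 pseudocount = pseudocount,
                 polarity_threshold = sc$polarity_threshold,
                 threshold_method = sc$threshold_method)
  empty <- function() {
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), score = numeric(),
                      p_value = numeric(), q_value = numeric(),
                      informative_fraction = numeric())
    structure(out, class = c("domain_calls", "data.frame"),
              params = params, segments = segs)
  }
  if (!nrow(segs)) return(empty())
  # permutation null on the pooled informative scores
  pooled <- unlist(lapply(genome$chrom, function(ch)
    sc$scores[[ch]][sc$informative[[ch]]]), use.names = FALSE)
  chrom_info <- lapply(genome$chrom, function(ch) sc$informative[[ch]])
  names(chrom_info) <- genome$chrom
  perm_max <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      shuf <- pooled[sample.int(length(pooled))]
      pos <- 0
      m <- 0
      for (ch in genome$chrom) {
        inf <- chrom_info[[ch]]
        v <- numeric(length(inf))
        ni <- sum(inf)
        if (ni) {
          v[inf] <- shuf[(pos + 1):(pos + ni)]
          pos <- pos + ni
        }
        m <- max(m, max_subarray_score(v))
      }
      m
    }, numeric(1))
  })
  pv <- vapply(segs$score, function(s)
    (1 + sum(perm_max >= s)) / (1 + n_permutations), numeric(1))
  qv <- stats::p.adjust(pv, method = "BH")
  inf_frac <- vapply(seq_len(nrow(segs)), function(i) {
    idx <- (segs$start_bin[i] + 1):segs$end_bin[i]
    mean(chrom_info[[segs$chrom[i]]][idx])
  }, numeric(1))
  lens <- chrom_lengths(genome)
  out <- data.frame(chrom = segs$chrom,
                    start = segs$start_bin * bin_size,
                    end = pmin(segs$end_bin * bin_size, lens[segs$chrom]),
                    score = segs$score, p_value = pv, q_value = qv,
                    informative_fraction = inf_frac,
                    stringsAsFactors = FALSE)
  keep <- out$q_value <= fdr &
    out$informative_fraction >= required_informative_fraction
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("domain_calls", "data.frame"),
            params = params, segments = segs, perm_max = perm_max)
}

#' @export
print.domain_calls <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf(
    "<domain calls> %d call(s), %s bp (bin %d, gap %g, fdr %g, thr %.3f)\n",
    nrow(x), format(if (nrow(x)) sum(x$end - x$start) else 0,
                    big.mark = ","),
    as.integer(p$bin_size), p$gap_penalty, p$fdr, p$polarity_threshold))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10),
                                row.names = FALSE)
  invisible(x)
}

#' @export
summary.domain_calls <- function(object, ...) {
  p <- attr(object, "params")
  n <- nrow(object)
  widths <- if (n) object$end - object$start else numeric()
  res <- list(n_calls = n, total_bp = sum(widths),
              mean_size = if (n) mean(widths) else NA_real_,
              median_q = if (n) stats::median(object$q_value) else NA_real_,
              params = p)
  class(res) <- "summary.domain_calls"
  res
}

#' @export
print.summary.domain_calls <- function(x, ...) {
  cat(sprintf("Domain calls: %d; total %s bp; mean size %s bp\n",
              x$n_calls, format(x$total_bp, big.mark = ","),
              format(round(x$mean_size), big.mark = ",")))
  cat(sprintf("bin %d bp, gap penalty %g, fdr %g, %d permutations\n",
              as.integer(x$params$bin_size), x$params$gap_penalty,
              x$params$fdr, x$params$n_permutations))
  invisible(x)
}

#' Domain calls as a plain interval set
#' @param x A `domain_calls` object.
#' @param ... Unused.
#' @return A `genomic_intervals` with `name` = call rank and `score` =
#'   segment score.
#' @export
as_intervals_calls <- function(x, ...) {
  if (!nrow(x)) return(empty_intervals())
  intervals(x$chrom, x$start, x$end,
            name = as.character(seq_len(nrow(x))), score = x$score)
}

#' Write domain calls as BED6 plus a statistics TSV
#' @param x A `domain_calls`.
#' @param bed_path,tsv_path Output paths (either may be NULL to skip).
#' @export
write_domains <- function(x, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) write_bed(as_intervals_calls(x), bed_path)
  if (!is.null(tsv_path)) {
    df <- as.data.frame(x)
    df$p_value <- format_num(df$p_value)
    df$q_value <- format_num(df$q_value)
    df$informative_fraction <- format_num(df$informative_fraction)
    utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(x)
}

#' @export
plot.domain_calls <- function(x, chrom = NULL, ...) {
  if (!nrow(x)) {
    graphics::plot.new()
    graphics::title("no domain calls")
    return(invisible(x))
  }
  ch <- if (is.null(chrom)) x$chrom[1] else chrom
  d <- x[x$chrom == ch, , drop = FALSE]
  graphics::plot(NA, xlim = range(c(d$start, d$end)) / 1e6,
                 ylim = c(0, max(d$score) * 1.1),
                 xlab = sprintf("%s position (Mb)", ch),
                 ylab = "segment score", ...)
  graphics::rect(d$start / 1e6, 0, d$end / 1e6, d$score,
                 col = "steelblue", border = NA)
  invisible(x)
}

#' Broad enrichment peaks from a single read set
#'
#' Tiles the genome in fixed windows; a window is significant when its read
#' count's z-score against a genome-wide Poisson background (mean count per
#' window) reaches `z_threshold`. Adjacent significant windows merge into
#' peaks.
#'
#' @param reads Read data.frame (`chrom`, `midpoint`).
#' @param genome A `sammy_genome`.
#' @param window Window size in bp (default 2000).
#' @param z_threshold z-score cutoff (default 3).
#' @return A `genomic_intervals` of peaks.
#' @export
broad_peaks <- function(reads, genome, window = 2000, z_threshold = 3) {
  if (window <= 0) stop("window must be > 0")
  if (!nrow(reads)) stop("empty read set")
  tr <- bin_reads(reads, genome, window)
  lambda <- nrow(reads) / sum(lengths(tr$values))
  lens <- chrom_lengths(genome)
  out <- lapply(genome$chrom, function(ch) {
    v <- tr$values[[ch]]
    z <- (v - lambda) / sqrt(lambda)
    sig <- which(z >= z_threshold)
    if (!length(sig)) return(NULL)
    runs <- split(sig, cumsum(c(1, diff(sig) != 1)))
    do.call(rbind, lapply(runs, function(r)
      data.frame(chrom = ch, start = (min(r) - 1) * window,
                 end = min(max(r) * window, lens[[ch]]),
                 stringsAsFactors = FALSE)))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty_intervals() else as_intervals(out)
}
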