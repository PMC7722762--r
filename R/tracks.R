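#' Construct a binned genome track
#'
#' Per-chromosome numeric values on a fixed bin grid. Bin i (0-based) covers
#' `[i*bin_size, (i+1)*bin_size)`; the final partial bin is kept.
#'
#' @param genome A `sammy_genome`.
#' @param bin_size Bin width in bp.
#' @param values Named list (one numeric vector per chromosome) matching
#'   `bin_counts(genome, bin_size)`.
#' @param library_size Total reads the track was built from (NA when not
#'   applicable).
#' @param normalization Free-text tag ("none", "cpm", ...).
#' @return Object of class `binned_track`.
#' @export
binned_track <- function(genome, bin_size, values, library_size = NA_real_,
                         normalization = "none") {
  nb <- bin_counts(genome, bin_size)
  if (!identical(sort(names(values)), sort(names(nb))))
    stop("values must have one vector per chromosome")
  for (ch in names(nb)) {
    if (length(values[[ch]]) != nb[[ch]])
      stop("wrong number of bins for ", ch, ": got ", length(values[[ch]]),
           ", expected ", nb[[ch]])
    if (any(!is.finite(values[[ch]])))
      stop("non-finite values in track on ", ch)
  }
  structure(list(genome = genome, bin_size = bin_size,
                 values = values[genome$chrom],
                 library_size = library_size,
                 normalization = normalization),
            class = "binned_track")
}

#' @export
print.binned_track <- function(x, ...) {
  cat(sprintf("<binned track> %d chromosome(s), bin %d bp, %s bins (%s)\n",
              nrow(x$genome), as.integer(x$bin_size),
              format(sum(lengths(x$values)), big.mark = ","),
              x$normalization))
  invisible(x)
}

same_grid <- function(a, b) {
  identical(a$genome$chrom, b$genome$chrom) &&
    identical(a$genome$length, b$genome$length) &&
    a$bin_size == b$bin_size
}

track_values <- function(x) unlist(x$values, use.names = FALSE)

#' Bin read midpoints into a normalized track
#'
#' @param reads Data.frame with columns `chrom`, `midpoint` (0-based bp).
#' @param genome A `sammy_genome`.
#' @param bin_size Bin width in bp (> 0).
#' @param normalize `"none"` (raw counts) or `"cpm"` (counts per million
#'   mapped reads).
#' @return A `binned_track`; `library_size` records the input read count.
#' @export
bin_reads <- function(reads, genome, bin_size, normalize = c("none", "cpm")) {
  normalize <- match.arg(normalize)
  if (bin_size <= 0) stop("bin_size must be > 0")
  lens <- chrom_lengths(genome)
  n <- nrow(reads)
  if (n) {
    unk <- setdiff(unique(reads$chrom), names(lens))
    if (length(unk)) stop("reads on unknown chromosome: ", unk[1])
    if (any(reads$midpoint < 0 | reads$midpoint >= lens[reads$chrom]))
      stop("read midpoint beyond chromosome end")
  }
  nb <- bin_counts(genome, bin_size)
  vals <- lapply(genome$chrom, function(ch) {
    m <- reads$midpoint[reads$chrom == ch]
    tabulate(floor(m / bin_size) + 1L, nbins = nb[[ch]])
  })
  names(vals) <- genome$chrom
  if (normalize == "cpm") {
    if (n == 0) {
      warning("cpm normalization of an empty read set; returning zeros")
    } else {
      vals <- lapply(vals, function(v) v * 1e6 / n)
    }
  }
  binned_track(genome, bin_size, vals, library_size = n,
               normalization = normalize)
}

#' Library-normalized log2 ratio of two binned tracks
#'
#' `value_i = log2(((t_i + c) / T_eff) / ((r_i + c) / R_eff))` with
#' `T_eff = library_size + c * n_bins` (same for the reference), so the
#' global scale cancels and every bin is finite.
#'
#' @param target,reference `binned_track`s of raw counts on the same grid.
#' @param pseudocount Pseudo-reads per bin (> 0), default 0.5.
#' @return A `binned_track` (normalization `"log2_ratio"`).
#' @export
log_ratio_track <- function(target, reference, pseudocount = 0.5) {
  if (!same_grid(target, reference)) stop("mismatched grids")
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  n_bins <- sum(lengths(target$values))
  t_eff <- sum(track_values(target)) + pseudocount * n_bins
  r_eff <- sum(track_values(reference)) + pseudocount * n_bins
  vals <- lapply(target$genome$chrom, function(ch) {
    log2(((target$values[[ch]] + pseudocount) / t_eff) /
           ((reference$values[[ch]] + pseudocount) / r_eff))
  })
  names(vals) <- target$genome$chrom
  out <- binned_track(target$genome, target$bin_size, vals,
                      library_size = NA_real_,
                      normalization = "log2_ratio")
  out$pseudocount <- pseudocount
  out
}

#' Gaussian-smoothed differential read density
#'
#' At each grid point x, `D(x) = sum_a K_h(x - m) s_a - sum_b K_h(x - m)
#' s_b` with a Gaussian kernel of standard deviation `bandwidth` truncated
#' at 6 bandwidths, evaluated at the exact read midpoints (no grid
#' snapping). `s = 1/library size` when `scale_by_library` else 1.
#'
#' @param reads_a,reads_b Read data.frames (`chrom`, `midpoint`); the signal
#'   is positive where `reads_a` is denser.
#' @param genome A `sammy_genome`.
#' @param bandwidth Kernel SD in bp (> 0), default 150.
#' @param step Grid spacing in bp (> 0), default 50.
#' @param scale_by_library Scale each set by its library size.
#' @return Object of class `signal_track` (genome, step, bandwidth,
#'   per-chromosome values at grid points 0, step, 2*step, ...).
#' @export
smoothed_difference <- function(reads_a, reads_b, genome, bandwidth = 150,
                                step = 50, scale_by_library = TRUE) {
  if (bandwidth <= 0 || step <= 0) stop("bandwidth and step must be > 0")
  if (!nrow(reads_a) && !nrow(reads_b)) stop("both read sets are empty")
  sa <- if (scale_by_library && nrow(reads_a)) 1 / nrow(reads_a) else 1
  sb <- if (scale_by_library && nrow(reads_b)) 1 / nrow(reads_b) else 1
  lens <- chrom_lengths(genome)
  vals <- lapply(genome$chrom, function(ch) {
    npts <- floor((lens[[ch]] - 1) / step) + 1
    v <- kernel_accumulate(reads_a$midpoint[reads_a$chrom == ch], npts,
                           step, bandwidth) * sa
    v - kernel_accumulate(reads_b$midpoint[reads_b$chrom == ch], npts,
                          step, bandwidth) * sb
  })
  names(vals) <- genome$chrom
  structure(list(genome = genome, step = step, bandwidth = bandwidth,
                 values = vals),
            class = "signal_track")
}

# Sum of truncated Gaussian kernels centred at read midpoints, evaluated at
# grid points (j-1)*step, j = 1..npts.
kernel_accumulate <- function(mid, npts, step, h) {
  v <- numeric(npts)
  if (!length(mid)) return(v)
  w_bins <- ceiling(6 * h / step) + 1L
  g <- round(mid / step)
  for (k in -w_bins:w_bins) {
    idx <- g + k + 1L
    ok <- idx >= 1L & idx <= npts
    if (!any(ok)) next
    x <- (idx[ok] - 1) * step
    d <- x - mid[ok]
    w <- ifelse(abs(d) <= 6 * h, stats::dnorm(d, 0, h), 0)
    agg <- rowsum(w, idx[ok])
    at <- as.integer(rownames(agg))
    v[at] <- v[at] + agg[, 1]
  }
  v
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("<signal track> step %d bp, bandwidth %d bp, %s points\n",
              as.integer(x$step), as.integer(x$bandwidth),
              format(sum(lengths(x$values)), big.mark = ",")))
  invisible(x)
}

#' Bernoulli down-sampling of reads
#'
#' Each read is kept independently with probability `fraction`; this is the
#' coordinate-level analogue of sampling raw reads to a given percentage.
#'
#' @param reads Read data.frame.
#' @param fraction Keep probability in `(0, 1]`.
#' @param seed Integer seed.
#' @return The thinned read data.frame.
#' @export
downsample_reads <- function(reads, fraction, seed = 1) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  with_seed(seed, {
    keep <- stats::runif(nrow(reads)) < fraction
    out <- reads[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Read midpoints as BED3 1-bp intervals
#'
#' Each read midpoint is emitted as the interval `[midpoint, midpoint + 1)`.
#'
#' @param reads Read data.frame (`chrom`, `midpoint`).
#' @param path Output path.
#' @export
write_reads_bed <- function(reads, path) {
  writeLines(sprintf("%s\t%d\t%d", reads$chrom, as.integer(reads$midpoint),
                     as.integer(reads$midpoint) + 1L), path)
  invisible(path)
}

#' @rdname write_reads_bed
#' @param genome Optional `sammy_genome` for validation.
#' @return `read_reads_bed` returns a read data.frame (`chrom`, `midpoint`),
#'   taking each interval's start as the midpoint.
#' @export
read_reads_bed <- function(path, genome = NULL) {
  x <- read_bed(path, genome = genome)
  data.frame(chrom = x$chrom, midpoint = x$start, stringsAsFactors = FALSE)
}

#' Write a track as 4-column bedGraph
#'
#' Adjacent equal-valued bins are not merged, so records map 1:1 to bins
#' (for a `binned_track`) or grid steps (for a `signal_track`).
#'
#' @param x A `binned_track` or `signal_track`.
#' @param path Output path.
#' @export
write_bedgraph <- function(x, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  lens <- chrom_lengths(x$genome)
  width <- if (inherits(x, "signal_track")) x$step else x$bin_size
  for (ch in x$genome$chrom) {
    v <- x$values[[ch]]
    if (!length(v)) next
    st <- (seq_along(v) - 1) * width
    en <- pmin(st + width, lens[[ch]])
    writeLines(sprintf("%s\t%d\t%d\t%s", ch, as.integer(st), as.integer(en),
                       format_num(v)), con)
  }
  invisible(path)
}

#' Read a 4-column bedGraph into a binned track
#'
#' Records must be non-overlapping and aligned to the `bin_size` grid;
#' uncovered bins are 0.
#'
#' @param path Input path.
#' @param genome A `sammy_genome`.
#' @param bin_size Grid width in bp.
#' @return A `binned_track`.
#' @export
read_bedgraph <- function(path, genome, bin_size) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "track") &
    !startsWith(lines, "#")
  lines <- lines[keep]
  nb <- bin_counts(genome, bin_size)
  vals <- lapply(nb, function(n) numeric(n))
  if (length(lines)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(vapply(parts, length, 1L) < 4L))
      stop("bedGraph requires 4 tab-separated columns")
    ch <- vapply(parts, `[[`, "", 1L)
    st <- as.numeric(vapply(parts, `[[`, "", 2L))
    v <- as.numeric(vapply(parts, `[[`, "", 4L))
    unk <- setdiff(unique(ch), names(nb))
    if (length(unk)) stop("unknown chromosome in bedGraph: ", unk[1])
    if (any(st %% bin_size != 0))
      stop("bedGraph records not aligned to the ", bin_size, " bp grid")
    for (cc in unique(ch)) {
      i <- ch == cc
      vals[[cc]][st[i] / bin_size + 1] <- v[i]
    }
  }
  binned_track(genome, bin_size, vals, normalization = "bedgraph")
}
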