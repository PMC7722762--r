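#' Average signal around domain borders
#'
#' Samples the track in a window of `2*k_bins + 1` bins centered on each
#' domain border. Windows are oriented so the domain interior lies on the
#' positive side for `side = "start"` and on the negative side for
#' `side = "end"`. Window positions beyond the chromosome are missing and
#' excluded from that position's mean. The smoothed curve is a cubic
#' smoothing spline with generalized cross-validation; the band smooths
#' `mean +/- 1.96 SEM`.
#'
#' @param signal A `binned_track` (its bin size is used) or a
#'   `signal_track` (averaged into `bin_size` bins).
#' @param domains Non-empty `genomic_intervals`.
#' @param side `"start"` or `"end"` border.
#' @param k_bins Half-window in bins (default 50).
#' @param bin_size Bin width in bp when `signal` is a `signal_track`.
#' @return Object of class `metaprofile`: data.frame columns
#'   `relative_bp`, `mean`, `sem`, `smoothed`, `lo`, `hi`, `n`, plus
#'   attributes `n_regions`, `side`.
#' @export
border_profile <- function(signal, domains, side = c("start", "end"),
                           k_bins = 50, bin_size = 10000) {
  side <- match.arg(side)
  if (!nrow(domains)) stop("domains must be non-empty")
  tr <- as_binned(signal, bin_size)
  bs <- tr$bin_size
  borders <- lapply(seq_len(nrow(domains)), function(i) {
    ch <- domains$chrom[i]
    b0 <- if (side == "start") floor(domains$start[i] / bs)
          else floor((domains$end[i] - 1) / bs)
    list(chrom = ch, bin = b0)
  })
  rel <- -k_bins:k_bins
  mat <- matrix(NA_real_, nrow = length(borders), ncol = length(rel))
  for (i in seq_along(borders)) {
    ch <- borders[[i]]$chrom
    v <- tr$values[[ch]]
    idx <- borders[[i]]$bin + rel + 1L
    ok <- idx >= 1L & idx <= length(v)
    mat[i, ok] <- v[idx[ok]]
  }
  if (all(is.na(mat))) stop("all border windows fall out of bounds")
  build_metaprofile(mat, rel * bs, side = side)
}

#' Average signal around transcription start sites
#'
#' Windows of `2*(flank/bin) + 1` bins centered on the TSS, oriented by
#' strand (minus-strand windows are reversed so downstream is positive).
#'
#' @param signal A `binned_track` with `bin_size == bin`, or a
#'   `signal_track` (averaged into `bin`-bp bins).
#' @param tss Data.frame with columns `chrom`, `position`, `strand`.
#' @param flank Flank on each side in bp (default 5000).
#' @param bin Bin width in bp (default 100).
#' @return A `metaprofile` (see [border_profile()]).
#' @export
tss_profile <- function(signal, tss, flank = 5000, bin = 100) {
  if (!nrow(tss)) stop("tss list must be non-empty")
  tr <- as_binned(signal, bin)
  if (tr$bin_size != bin)
    stop("signal bin size (", tr$bin_size, ") must equal bin (", bin, ")")
  k <- floor(flank / bin)
  rel <- -k:k
  mat <- matrix(NA_real_, nrow = nrow(tss), ncol = length(rel))
  for (i in seq_len(nrow(tss))) {
    ch <- tss$chrom[i]
    v <- tr$values[[ch]]
    if (is.null(v)) next
    b0 <- floor(tss$position[i] / bin)
    o <- if (!is.null(tss$strand) && tss$strand[i] == "-") -rel else rel
    idx <- b0 + o + 1L
    ok <- idx >= 1L & idx <= length(v)
    mat[i, ok] <- v[idx[ok]]
  }
  if (all(is.na(mat))) stop("all TSS windows fall out of bounds")
  build_metaprofile(mat, rel * bin, side = "tss")
}

as_binned <- function(signal, bin_size) {
  if (inherits(signal, "binned_track")) return(signal)
  if (!inherits(signal, "signal_track"))
    stop("signal must be a binned_track or signal_track")
  # average grid points falling in each bin
  g <- signal$genome
  nb <- bin_counts(g, bin_size)
  vals <- lapply(g$chrom, function(ch) {
    v <- signal$values[[ch]]
    pos <- (seq_along(v) - 1) * signal$step
    idx <- floor(pos / bin_size) + 1L
    out <- rep(NA_real_, nb[[ch]])
    agg <- rowsum(v, idx)
    cnt <- rowsum(rep(1, length(v)), idx)
    out[as.integer(rownames(agg))] <- agg[, 1] / cnt[, 1]
    out[is.na(out)] <- 0
    out
  })
  names(vals) <- g$chrom
  binned_track(g, bin_size, vals, normalization = "rebinned_signal")
}

build_metaprofile <- function(mat, relative_bp, side) {
  n_at <- colSums(!is.na(mat))
  mu <- colMeans(mat, na.rm = TRUE)
  mu[n_at == 0] <- NA_real_
  sdv <- apply(mat, 2, stats::sd, na.rm = TRUE)
  sem <- ifelse(n_at > 1, sdv / sqrt(n_at), 0)
  if (nrow(mat) == 1)
    warning("single region: SEM coded as 0")
  sem[is.na(sem)] <- 0
  ok <- !is.na(mu)
  sm <- fit_spline(relative_bp[ok], mu[ok], relative_bp)
  lo <- fit_spline(relative_bp[ok], (mu - 1.96 * sem)[ok], relative_bp)
  hi <- fit_spline(relative_bp[ok], (mu + 1.96 * sem)[ok], relative_bp)
  out <- data.frame(relative_bp = relative_bp, mean = mu, sem = sem,
                    smoothed = sm, lo = lo, hi = hi, n = n_at)
  structure(out, class = c("metaprofile", "data.frame"),
            n_regions = nrow(mat), side = side)
}

# Cubic smoothing spline with GCV; falls back to the raw values when the
# input is too short or constant for smooth.spline.
fit_spline <- function(x, y, at) {
  if (length(unique(x)) < 4 || stats::sd(y) == 0) {
    out <- rep(NA_real_, length(at))
    out[match(x, at)] <- y
    return(out)
  }
  fit <- tryCatch(stats::smooth.spline(x, y, cv = FALSE),
                  error = function(e) NULL)
  if (is.null(fit)) {
    out <- rep(NA_real_, length(at))
    out[match(x, at)] <- y
    return(out)
  }
  stats::predict(fit, at)$y
}

#' @export
print.metaprofile <- function(x, ...) {
  cat(sprintf("<metaprofile> %d position(s), %d region(s), side = %s\n",
              nrow(x), attr(x, "n_regions"), attr(x, "side")))
  invisible(x)
}

#' @export
plot.metaprofile <- function(x, ...) {
  graphics::plot(x$relative_bp, x$mean, type = "l", col = "grey50",
                 xlab = "relative position (bp)", ylab = "mean signal", ...)
  graphics::polygon(c(x$relative_bp, rev(x$relative_bp)),
                    c(x$lo, rev(x$hi)), col = grDevices::adjustcolor(
                      "steelblue", 0.3), border = NA)
  graphics::lines(x$relative_bp, x$smoothed, col = "steelblue", lwd = 2)
  invisible(x)
}

#' Write a metaprofile as TSV
#' @param x A `metaprofile`.
#' @param path Output path.
#' @export
write_metaprofile <- function(x, path) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], format_num)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Genes whose TSS window touches a peak region common to all samples
#'
#' Common regions are the base-pair intersection across all peak sets; a
#' gene is selected when its half-open window `[TSS - window, TSS + window)`
#' overlaps a common region by at least 1 bp.
#'
#' @param peak_sets List of >= 1 `genomic_intervals`.
#' @param tss_table Data.frame with columns `gene`, `chrom`, `position`.
#' @param window Half-window in bp around the TSS (default 500).
#' @return Character vector of unique genes, input order preserved.
#' @export
common_peak_gene_set <- function(peak_sets, tss_table, window = 500) {
  if (!length(peak_sets)) stop("need at least one peak set")
  if (!nrow(tss_table)) stop("empty tss_table")
  common <- Reduce(intersect_intervals, lapply(peak_sets, merge_intervals))
  if (!nrow(common)) return(character())
  st <- pmax(0, tss_table$position - window)
  en <- tss_table$position + window
  ov <- interval_overlap_bp(tss_table$chrom, st, en, common)
  unique(tss_table$gene[ov >= 1])
}
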