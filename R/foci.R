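#' Read a single-channel nucleus image
#'
#' Reads TIFF/PNG via EBImage; multi-channel images are reduced to the
#' first channel. Returns a plain numeric matrix in `[0, 1]` with rows = y
#' (image lines) and columns = x.
#'
#' @param path Image path.
#' @return Numeric matrix.
#' @export
read_nucleus_image <- function(path) {
  img <- EBImage::readImage(path)
  d <- dim(img)
  if (length(d) > 2) img <- img[, , 1]
  t(EBImage::imageData(img))
}

# 8-connectivity labelling: EBImage::bwlabel for the heavy lifting, then
# labels adjacent in any of the 8 directions are merged by union-find, so
# the result is 8-connected regardless of bwlabel's own convention.
# Components are relabelled 1..k in raster order (minimum column-major
# linear index).
label8 <- function(mask) {
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  lbl <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  lbl <- matrix(as.integer(lbl), nrow(mask), ncol(mask))
  nr <- nrow(lbl); nc <- ncol(lbl)
  pairs <- list()
  shift_pairs <- function(a, b) {
    ok <- a > 0L & b > 0L & a != b
    if (any(ok)) cbind(a[ok], b[ok]) else NULL
  }
  # right, down, down-right, down-left neighbours
  pairs[[1]] <- shift_pairs(lbl[, -nc, drop = FALSE], lbl[, -1, drop = FALSE])
  pairs[[2]] <- shift_pairs(lbl[-nr, , drop = FALSE], lbl[-1, , drop = FALSE])
  pairs[[3]] <- shift_pairs(lbl[-nr, -nc, drop = FALSE],
                            lbl[-1, -1, drop = FALSE])
  pairs[[4]] <- shift_pairs(lbl[-nr, -1, drop = FALSE],
                            lbl[-1, -nc, drop = FALSE])
  pr <- unique(do.call(rbind, pairs))
  nl <- max(lbl)
  parent <- seq_len(nl)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (!is.null(pr)) {
    for (r in seq_len(nrow(pr))) {
      a <- find(pr[r, 1]); b <- find(pr[r, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(nl), find, 1L)
  lbl[lbl > 0L] <- root[lbl[lbl > 0L]]
  # raster-order relabelling
  first_idx <- tapply(seq_along(lbl)[lbl > 0L], lbl[lbl > 0L], min)
  ord <- order(first_idx)
  remap <- integer(nl)
  remap[as.integer(names(first_idx))[ord]] <- seq_along(ord)
  lbl[lbl > 0L] <- remap[lbl[lbl > 0L]]
  lbl
}

#' Segment nuclei with a global two-class Otsu threshold
#'
#' Thresholds the whole image by Otsu's method, labels connected components
#' (8-connectivity), fills holes, and removes components below `min_area`
#' or touching the image border. Labels are deterministic (raster order).
#'
#' @param image Numeric matrix in `[0, 1]` (rows = y, columns = x).
#' @param min_area Minimum nucleus area in pixels (default 200).
#' @return Integer label matrix (0 = background).
#' @export
segment_nuclei <- function(image, min_area = 200) {
  if (length(unique(as.vector(image))) == 1) stop("constant image")
  thr <- EBImage::otsu(EBImage::Image(t(image)))
  mask <- image > thr
  filled <- EBImage::imageData(
    EBImage::fillHull(EBImage::Image(t(mask) * 1)))
  mask <- t(matrix(filled > 0, ncol(image), nrow(image)))
  lbl <- label8(mask)
  if (!max(lbl)) return(lbl)
  keep <- logical(max(lbl))
  for (id in seq_len(max(lbl))) {
    px <- which(lbl == id, arr.ind = TRUE)
    touches <- any(px[, 1] == 1 | px[, 1] == nrow(lbl) |
                     px[, 2] == 1 | px[, 2] == ncol(lbl))
    keep[id] <- nrow(px) >= min_area && !touches
  }
  lbl[!(lbl %in% which(keep))] <- 0L
  relabel_raster(lbl)
}

relabel_raster <- function(lbl) {
  ids <- sort(unique(lbl[lbl > 0L]))
  if (!length(ids)) return(lbl)
  first_idx <- vapply(ids, function(id) min(which(lbl == id)), 1L)
  remap <- integer(max(ids))
  remap[ids[order(first_idx)]] <- seq_along(ids)
  lbl[lbl > 0L] <- remap[lbl[lbl > 0L]]
  lbl
}

# Exhaustive two-threshold (three-class) Otsu on a 256-bin histogram:
# maximizes the between-class variance over all bin-boundary pairs.
# Returns the two intensity thresholds (upper bin edges).
otsu_two_thresholds <- function(v, n_bins = 256) {
  rng <- range(v)
  if (rng[1] == rng[2]) return(c(rng[1], rng[2]))
  br <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(pmin(findInterval(v, br, rightmost.closed = TRUE), n_bins),
                nbins = n_bins)
  mids <- (br[-1] + br[-length(br)]) / 2
  w <- cumsum(h)
  m <- cumsum(h * mids)
  tot_w <- w[n_bins]; tot_m <- m[n_bins]
  best <- -Inf; best_t <- c(1L, 2L)
  for (t1 in 1:(n_bins - 2)) {
    w1 <- w[t1]
    if (w1 == 0) next
    mu1 <- m[t1] / w1
    for (t2 in (t1 + 1):(n_bins - 1)) {
      w2 <- w[t2] - w[t1]
      w3 <- tot_w - w[t2]
      if (w2 == 0 || w3 == 0) next
      mu2 <- (m[t2] - m[t1]) / w2
      mu3 <- (tot_m - m[t2]) / w3
      mu <- tot_m / tot_w
      bcv <- w1 * (mu1 - mu)^2 + w2 * (mu2 - mu)^2 + w3 * (mu3 - mu)^2
      if (bcv > best) { best <- bcv; best_t <- c(t1, t2) }
    }
  }
  if (!is.finite(best)) { # < 3 occupied levels: two-class split
    thr <- otsu_split(v)
    return(c(thr, thr))
  }
  c(br[best_t[1] + 1], br[best_t[2] + 1])
}

#' Detect intranuclear foci with a per-nucleus three-class Otsu threshold
#'
#' Within each nucleus mask independently, an exhaustive two-threshold Otsu
#' search on a 256-bin histogram of that nucleus's intensities splits the
#' pixels into three classes; the top class yields candidate foci, which
#' are labelled with 8-connectivity. Components below `min_area` pixels are
#' removed. Nuclei with fewer than `min_nucleus_px` pixels are skipped with
#' a warning. Spots merged below the connectivity resolution count once.
#'
#' @param image Numeric matrix.
#' @param nuclei Label matrix from [segment_nuclei()].
#' @param min_area Minimum focus area in pixels (default 2).
#' @param min_nucleus_px Minimum analyzable nucleus size (default 10).
#' @return Integer foci label matrix with attribute `nucleus_of` (integer
#'   vector mapping focus label to nucleus label).
#' @export
detect_foci <- function(image, nuclei, min_area = 2, min_nucleus_px = 10) {
  foci <- matrix(0L, nrow(image), ncol(image))
  nucleus_of <- integer(0)
  next_id <- 0L
  for (id in seq_len(max(nuclei, 0L))) {
    sel <- nuclei == id
    npx <- sum(sel)
    if (npx == 0) next
    if (npx < min_nucleus_px) {
      warning("nucleus ", id, " has fewer than ", min_nucleus_px,
              " pixels; skipped")
      next
    }
    v <- image[sel]
    if (length(unique(v)) < 2) next # uniform interior: no foci
    thr <- otsu_two_thresholds(v)
    cand <- sel & image > thr[2]
    if (!any(cand)) next
    lbl <- label8(cand)
    sizes <- tabulate(lbl[lbl > 0L])
    drop <- which(sizes < min_area)
    if (length(drop)) lbl[lbl %in% drop] <- 0L
    lbl <- relabel_raster(lbl)
    k <- max(lbl)
    if (k > 0) {
      foci[lbl > 0L] <- lbl[lbl > 0L] + next_id
      nucleus_of <- c(nucleus_of, rep.int(id, k))
      next_id <- next_id + k
    }
  }
  attr(foci, "nucleus_of") <- nucleus_of
  foci
}

#' Measure focus size and periphery proximity
#'
#' For each focus: `min_dist_px` is the minimum Euclidean distance from any
#' focus pixel to a background pixel of its nucleus; `B` is the background
#' pixel realizing that minimum (ties broken in raster order); proximity is
#' `min_dist_px / ||nucleus centroid - B||`, clamped to `[0, 1]`, so 0
#' means at the periphery and 1 at the centroid regardless of nucleus size.
#'
#' @param nuclei Nucleus label matrix.
#' @param foci Foci label matrix from [detect_foci()].
#' @param pixel_size_um Physical pixel size in micrometers.
#' @return Data.frame of class `foci_measures`: nucleus, focus, area_px,
#'   x, y (centroid), min_dist_px, min_dist_um, proximity; attribute
#'   `nuclei` holds the per-nucleus table (id, area, centroid), attribute
#'   `pixel_size_um` the pixel size.
#' @export
measure_foci <- function(nuclei, foci, pixel_size_um) {
  nucleus_of <- attr(foci, "nucleus_of")
  n_foci <- max(foci, 0L)
  if (is.null(nucleus_of) || length(nucleus_of) != n_foci)
    stop("foci matrix lacks a consistent nucleus_of attribute")
  nr <- nrow(nuclei)
  nuc_ids <- sort(unique(nuclei[nuclei > 0L]))
  nuc_tab <- do.call(rbind, lapply(nuc_ids, function(id) {
    px <- which(nuclei == id, arr.ind = TRUE)
    data.frame(nucleus = id, area_px = nrow(px),
               cx = mean(px[, 2]), cy = mean(px[, 1]))
  }))
  if (is.null(nuc_tab))
    nuc_tab <- data.frame(nucleus = integer(), area_px = integer(),
                          cx = numeric(), cy = numeric())
  rows <- list()
  for (f in seq_len(n_foci)) {
    nid <- nucleus_of[f]
    fidx <- which(foci == f)
    if (any(nuclei[fidx] != nid))
      stop("focus ", f, " overlaps background: mask inconsistency")
    fy <- (fidx - 1) %% nr + 1
    fx <- (fidx - 1) %/% nr + 1
    # background pixels near the nucleus (bounding box + margin)
    npx <- which(nuclei == nid, arr.ind = TRUE)
    r0 <- max(1, min(npx[, 1]) - 2); r1 <- min(nr, max(npx[, 1]) + 2)
    c0 <- max(1, min(npx[, 2]) - 2); c1 <- min(ncol(nuclei), max(npx[, 2]) + 2)
    sub <- nuclei[r0:r1, c0:c1, drop = FALSE]
    bidx <- which(sub != nid)
    by <- (bidx - 1) %% nrow(sub) + r0
    bx <- (bidx - 1) %/% nrow(sub) + c0
    best_d <- Inf; best_b <- c(NA_real_, NA_real_)
    for (j in seq_along(fidx)) { # focus pixels in raster order
      d2 <- (bx - fx[j])^2 + (by - fy[j])^2
      k <- which.min(d2) # first minimum = raster order among bg pixels
      if (d2[k] < best_d) {
        best_d <- d2[k]
        best_b <- c(bx[k], by[k])
      }
    }
    cen <- nuc_tab[nuc_tab$nucleus == nid, ]
    dmin <- sqrt(best_d)
    dcb <- sqrt((cen$cx - best_b[1])^2 + (cen$cy - best_b[2])^2)
    rows[[length(rows) + 1]] <- data.frame(
      nucleus = nid, focus = f, area_px = length(fidx),
      x = mean(fx), y = mean(fy), min_dist_px = dmin,
      min_dist_um = dmin * pixel_size_um,
      proximity = min(dmin / dcb, 1))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(nucleus = integer(), focus = integer(), area_px = integer(),
               x = numeric(), y = numeric(), min_dist_px = numeric(),
               min_dist_um = numeric(), proximity = numeric())
  rownames(out) <- NULL
  structure(out, class = c("foci_measures", "data.frame"),
            nuclei = nuc_tab, pixel_size_um = pixel_size_um)
}

#' Segment, detect and measure in one call
#'
#' @param images A numeric matrix or a list of matrices.
#' @param pixel_size_um Physical pixel size in micrometers.
#' @param ... Passed to [segment_nuclei()] / [detect_foci()].
#' @return A combined `foci_measures` (nucleus ids unique across images).
#' @export
analyze_foci <- function(images, pixel_size_um, ...) {
  if (is.matrix(images)) images <- list(images)
  all_rows <- list()
  all_nuc <- list()
  offset <- 0L
  for (img in images) {
    nuc <- segment_nuclei(img)
    fc <- detect_foci(img, nuc)
    m <- measure_foci(nuc, fc, pixel_size_um)
    nt <- attr(m, "nuclei")
    if (nrow(nt)) nt$nucleus <- nt$nucleus + offset
    if (nrow(m)) m$nucleus <- m$nucleus + offset
    all_rows[[length(all_rows) + 1]] <- as.data.frame(m)
    all_nuc[[length(all_nuc) + 1]] <- nt
    offset <- offset + max(nuc, 0L)
  }
  out <- do.call(rbind, all_rows)
  rownames(out) <- NULL
  structure(out, class = c("foci_measures", "data.frame"),
            nuclei = do.call(rbind, all_nuc),
            pixel_size_um = pixel_size_um)
}

#' Summarize focus proximity to the nuclear periphery
#'
#' Reports the number of analyzed cells, total foci, and foci within
#' `cutoff_um` of the periphery (the triple usually reported as
#' cells/bodies/within), plus the percentage.
#'
#' @param measures A `foci_measures`.
#' @param cutoff_um Distance cutoff in micrometers (default 1).
#' @return List of class `periphery_summary`: `n_cells`, `n_bodies`,
#'   `n_within`, `percent_within` (NA when there are no foci).
#' @export
summarize_periphery <- function(measures, cutoff_um = 1.0) {
  nuc <- attr(measures, "nuclei")
  n_cells <- if (!is.null(nuc)) nrow(nuc) else length(unique(measures$nucleus))
  n_bodies <- nrow(measures)
  n_within <- sum(measures$min_dist_um <= cutoff_um)
  pct <- if (n_bodies > 0) 100 * n_within / n_bodies else {
    warning("no foci: percentage undefined")
    NA_real_
  }
  structure(list(n_cells = n_cells, n_bodies = n_bodies,
                 n_within = n_within, percent_within = pct,
                 cutoff_um = cutoff_um),
            class = "periphery_summary")
}

#' @export
print.periphery_summary <- function(x, ...) {
  cat(sprintf("%d/%d/%d cells/bodies/within %.2g um (%.1f%%)\n",
              x$n_cells, x$n_bodies, x$n_within, x$cutoff_um,
              x$percent_within))
  invisible(x)
}

#' Write per-focus measurements and the population summary
#' @param measures A `foci_measures`.
#' @param tsv_path Per-focus TSV path.
#' @param summary_path Optional summary TSV path.
#' @param cutoff_um Cutoff for the summary (default 1).
#' @export
write_foci <- function(measures, tsv_path, summary_path = NULL,
                       cutoff_um = 1.0) {
  df <- as.data.frame(measures)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], format_num)
  utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(summary_path)) {
    s <- summarize_periphery(measures, cutoff_um)
    utils::write.table(
      data.frame(n_cells = s$n_cells, n_bodies = s$n_bodies,
                 n_within = s$n_within,
                 percent_within = format_num(s$percent_within)),
      summary_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(measures)
}
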