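#' Plant a closed-chromatin domain architecture on a toy genome
#'
#' Places `n_domains` non-overlapping megabase-scale domains uniformly at
#' random. These play the role of compacted / lamina-associated regions: the
#' most condensed fraction (S4) is enriched inside them, the most accessible
#' fraction (S2) depleted.
#'
#' @param chrom_sizes A `sammy_genome`, or a named numeric vector of
#'   chromosome lengths.
#' @param n_domains Number of domains to place.
#' @param size_range Length-2 numeric, min/max domain size in bp.
#' @param enrichment_factor Relative per-bp read density of the closed (S4)
#'   fraction inside domains (> 1). S2 uses its reciprocal; S3 uses
#'   `s3_factor` (default `sqrt(enrichment_factor)`).
#' @param condition `"control"` or `"disrupted"`. In the disrupted condition
#'   each simulated read switches, with probability `disruption_rho`, to a
#'   freshly re-placed random copy of the domain architecture, flattening and
#'   scattering the fraction contrast.
#' @param disruption_rho Probability of re-assignment in the disrupted
#'   condition, in `[0, 1]`.
#' @param s3_factor In-domain weight of the S3 fraction; defaults to
#'   `sqrt(enrichment_factor)`.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments including the seed.
#' @param max_tries Bounded retries for non-overlapping placement.
#' @return An object of class `domain_architecture` with elements `genome`,
#'   `closed_domains` (a `genomic_intervals`), `enrichment_factor`,
#'   `s3_factor`, `condition_label`, `disruption_rho`, `seed`.
#' @examples
#' arch <- make_architecture(c(chrA = 30e6, chrB = 30e6), n_domains = 10,
#'                           size_range = c(1e6, 5e6), enrichment_factor = 3,
#'                           seed = 7)
#' arch$closed_domains
#' @export
make_architecture <- function(chrom_sizes, n_domains = 10,
                              size_range = c(1e6, 5e6),
                              enrichment_factor = 3,
                              condition = c("control", "disrupted"),
                              disruption_rho = 0.5,
                              s3_factor = sqrt(enrichment_factor),
                              seed = 1, max_tries = 1000L) {
  g <- if (inherits(chrom_sizes, "sammy_genome")) chrom_sizes
       else genome(names(chrom_sizes), chrom_sizes)
  condition <- match.arg(condition)
  if (enrichment_factor < 1)
    stop("enrichment_factor must be >= 1 (1 = no contrast)")
  if (size_range[1] > size_range[2] || size_range[1] <= 0)
    stop("invalid size_range")
  if (nrow(g) && size_range[2] > max(g$length))
    stop("size_range does not fit within any chromosome")
  dom <- with_seed(seed, place_domains(g, n_domains, size_range, max_tries))
  structure(list(genome = g, closed_domains = dom,
                 enrichment_factor = enrichment_factor,
                 s3_factor = s3_factor,
                 condition_label = condition,
                 disruption_rho = disruption_rho,
                 seed = as.integer(seed)),
            class = "domain_architecture")
}

place_domains <- function(g, n_domains, size_range, max_tries = 1000L) {
  if (n_domains == 0) return(empty_intervals())
  lens <- chrom_lengths(g)
  fits <- lens >= size_range[1]
  if (!any(fits)) stop("no chromosome can hold a domain of the minimum size")
  placed <- data.frame(chrom = character(), start = numeric(),
                       end = numeric(), stringsAsFactors = FALSE)
  sizes <- sort(round(stats::runif(n_domains, size_range[1], size_range[2])),
                decreasing = TRUE)
  for (len in sizes) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      avail <- names(lens)[lens >= len]
      ch <- if (length(avail) == 1) avail else
        sample(avail, 1, prob = lens[avail] - len + 1)
      st <- floor(stats::runif(1, 0, lens[ch] - len + 1))
      if (!any(placed$chrom == ch & placed$start < st + len &
                 placed$end > st)) {
        placed <- rbind(placed, data.frame(chrom = ch, start = st,
                                           end = st + len,
                                           stringsAsFactors = FALSE))
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("could not place ", n_domains, " non-overlapping domains of ",
           size_range[1], "-", size_range[2],
           " bp after ", max_tries, " tries: genome too dense")
  }
  as_intervals(placed)
}

#' @export
print.domain_architecture <- function(x, ...) {
  cat(sprintf(
    "<domain architecture> %s: %d domain(s), %s bp closed, factor %.2f\n",
    x$condition_label, nrow(x$closed_domains),
    format(total_bp(x$closed_domains), big.mark = ","),
    x$enrichment_factor))
  invisible(x)
}

# Draw n integer positions uniformly over a flat interval set.
sample_positions <- function(iset, n) {
  if (!nrow(iset) || n == 0)
    return(data.frame(chrom = character(), midpoint = numeric(),
                      stringsAsFactors = FALSE))
  w <- iset$end - iset$start
  cum <- cumsum(w)
  u <- stats::runif(n, 0, cum[length(cum)])
  idx <- findInterval(u, cum, left.open = TRUE) + 1L
  off <- u - c(0, cum)[idx]
  data.frame(chrom = iset$chrom[idx],
             midpoint = floor(iset$start[idx] + off),
             stringsAsFactors = FALSE)
}

genome_intervals <- function(g) {
  if (!nrow(g)) return(empty_intervals())
  intervals(g$chrom, rep(0, nrow(g)), g$length)
}

#' Simulate aligned-fragment midpoints for one chromatin fraction
#'
#' Read midpoints are drawn from a genome-wide multinomial whose per-bp
#' weight is `enrichment_factor` inside the closed domains for S4,
#' `s3_factor` for S3, `1/enrichment_factor` for S2, and 1 elsewhere. In the
#' "disrupted" condition each read is re-drawn, with probability
#' `disruption_rho`, under a uniformly random re-placement of the domains,
#' emulating scattered low signal-to-noise profiles.
#'
#' @param arch A `domain_architecture`.
#' @param fraction One of `"S2"`, `"S3"`, `"S4"`.
#' @param n_reads Number of reads (> 0).
#' @param seed Integer seed.
#' @return Data.frame with columns `chrom`, `midpoint` (0-based bp).
#' @export
simulate_fraction_reads <- function(arch, fraction, n_reads, seed = 1) {
  stopifnot(inherits(arch, "domain_architecture"))
  if (!fraction %in% c("S2", "S3", "S4"))
    stop("unknown fraction label: ", fraction)
  if (n_reads <= 0) stop("n_reads must be > 0")
  f <- arch$enrichment_factor
  w_in <- switch(fraction, S4 = f, S3 = arch$s3_factor, S2 = 1 / f)
  with_seed(seed, {
    n_alt <- 0L
    if (arch$condition_label == "disrupted" && arch$disruption_rho > 0) {
      n_alt <- stats::rbinom(1, n_reads, arch$disruption_rho)
      sizes <- arch$closed_domains$end - arch$closed_domains$start
      alt_dom <- if (length(sizes))
        place_domains(arch$genome, length(sizes),
                      range(sizes)) else empty_intervals()
    }
    out <- draw_weighted_reads(arch$genome, arch$closed_domains, w_in,
                               n_reads - n_alt)
    if (n_alt > 0) {
      out <- rbind(out, draw_weighted_reads(arch$genome, alt_dom, w_in,
                                            n_alt))
      out <- out[sample.int(nrow(out)), , drop = FALSE]
      rownames(out) <- NULL
    }
    out
  })
}

draw_weighted_reads <- function(g, domains, w_in, n) {
  dom <- merge_intervals(domains)
  outside <- subtract_intervals(genome_intervals(g), dom)
  bp_in <- total_bp(dom)
  bp_out <- total_bp(outside)
  mass_in <- w_in * bp_in
  p_in <- if (mass_in + bp_out > 0) mass_in / (mass_in + bp_out) else 0
  k <- stats::rbinom(1, n, p_in)
  rbind(sample_positions(dom, k), sample_positions(outside, n - k))
}

#' Simulate a binned reference mark track tied to the architecture
#'
#' Produces a `binned_track` whose value is `polarity` inside the closed
#' domains and `-polarity` outside (bin assigned by its midpoint), plus
#' Gaussian noise. Polarity +1 emulates Lamin/H3K9me3-like tracks, -1
#' open-chromatin (ATAC/H3K4me1)-like tracks.
#'
#' @param arch A `domain_architecture`.
#' @param polarity `+1` or `-1`.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param bin_size Bin width in bp (> 0).
#' @param seed Integer seed.
#' @return A `binned_track`.
#' @export
simulate_mark_track <- function(arch, polarity = 1, noise_sd = 0.5,
                                bin_size = 10000, seed = 1) {
  stopifnot(inherits(arch, "domain_architecture"))
  if (bin_size <= 0) stop("bin_size must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!polarity %in% c(1, -1)) stop("polarity must be +1 or -1")
  g <- arch$genome
  nb <- bin_counts(g, bin_size)
  memb <- domain_bin_membership(arch$closed_domains, g, bin_size)
  with_seed(seed, {
    vals <- lapply(g$chrom, function(ch) {
      base <- polarity * (2 * memb[[ch]] - 1)
      base + stats::rnorm(length(base), 0, noise_sd)
    })
    names(vals) <- g$chrom
    binned_track(g, bin_size, vals, library_size = NA_real_,
                 normalization = "synthetic")
  })
}

# Logical per-bin membership: TRUE when the bin midpoint lies in a domain.
domain_bin_membership <- function(domains, g, bin_size) {
  nb <- bin_counts(g, bin_size)
  dom <- merge_intervals(domains)
  out <- lapply(g$chrom, function(ch) {
    mids <- (seq_len(nb[[ch]]) - 0.5) * bin_size
    d <- dom[dom$chrom == ch, , drop = FALSE]
    inside <- rep(FALSE, length(mids))
    if (nrow(d)) {
      idx <- findInterval(mids, d$start)
      inside <- idx >= 1 & mids < d$end[pmax(idx, 1)]
    }
    inside
  })
  names(out) <- g$chrom
  out
}

CHROMATIN_STATES <- c("TssBiv", "BivFlnk", "EnhBiv", "ReprPC", "ReprPCWk",
                      "Het", "Tx", "TxWk", "ZNF/Rpts", "Quies")
BIVALENT_STATES <- c("TssBiv", "BivFlnk", "EnhBiv")

#' Paint a Roadmap-like chromatin-state partition over the genome
#'
#' Every base receives exactly one of the 10 state mnemonics used downstream
#' (TssBiv, BivFlnk, EnhBiv, ReprPC, ReprPCWk, Het, Tx, TxWk, ZNF/Rpts,
#' Quies). Closed domains are painted mostly Het/Quies with embedded minority
#' Polycomb/bivalent islands; the rest of the genome mostly Tx/TxWk/Quies.
#'
#' @param arch A `domain_architecture`.
#' @param seed Integer seed.
#' @param mean_segment Mean painted segment length in bp.
#' @return A `genomic_intervals` with state labels in `name`, carrying the
#'   genome as attribute `"genome"`.
#' @export
paint_chromatin_states <- function(arch, seed = 1, mean_segment = 50000) {
  stopifnot(inherits(arch, "domain_architecture"))
  g <- arch$genome
  dom <- merge_intervals(arch$closed_domains)
  outside <- subtract_intervals(genome_intervals(g), dom)
  w_in <- c(Het = 0.45, Quies = 0.25, ReprPC = 0.08, ReprPCWk = 0.05,
            TssBiv = 0.07, BivFlnk = 0.04, EnhBiv = 0.03, `ZNF/Rpts` = 0.03)
  w_out <- c(Tx = 0.30, TxWk = 0.25, Quies = 0.28, TssBiv = 0.04,
             BivFlnk = 0.02, EnhBiv = 0.02, `ZNF/Rpts` = 0.03, Het = 0.03,
             ReprPC = 0.02, ReprPCWk = 0.01)
  paint_region <- function(reg, w) {
    len <- reg$end - reg$start
    n_max <- max(2L, ceiling(len / mean_segment * 3))
    seg <- pmax(2000, round(stats::rexp(n_max, 1 / mean_segment)))
    cs <- cumsum(seg)
    k <- which(cs >= len)[1]
    if (is.na(k)) { seg <- c(seg, len); k <- length(seg) }
    seg <- seg[seq_len(k)]
    ends <- pmin(cumsum(seg), len)
    starts <- c(0, ends[-k])
    keep <- ends > starts
    lab <- sample(names(w), k, replace = TRUE, prob = w)
    data.frame(chrom = reg$chrom, start = reg$start + starts[keep],
               end = reg$start + ends[keep], name = lab[keep],
               stringsAsFactors = FALSE)
  }
  with_seed(seed, {
    pieces <- list()
    for (i in seq_len(nrow(dom)))
      pieces[[length(pieces) + 1]] <- paint_region(dom[i, ], w_in)
    for (i in seq_len(nrow(outside)))
      pieces[[length(pieces) + 1]] <- paint_region(outside[i, ], w_out)
    out <- as_intervals(do.call(rbind, pieces))
    attr(out, "genome") <- g
    out
  })
}

#' Simulate a transcript-level differential-expression table
#'
#' Transcripts are placed uniformly on the genome. Transcripts whose 200-nt
#' TSS window overlaps a bivalent state (TssBiv/BivFlnk/EnhBiv) by at least
#' 100 nt draw their p-value from `Beta(bivalent_effect, 1)` and get a
#' positive signed effect with probability 0.8; all others are null
#' (`p ~ Uniform(0, 1)`, symmetric effect). `bivalent_effect = 1` is the
#' global null.
#'
#' @param states Painted chromatin states from [paint_chromatin_states()].
#' @param n_transcripts Number of transcripts (> 0).
#' @param bivalent_effect Beta shape in `(0, 1]`; smaller = stronger signal.
#' @param seed Integer seed.
#' @param genome A `sammy_genome`; defaults to the one attached to `states`.
#' @param length_range Transcript body length range in bp.
#' @return Data.frame of class `transcript_table` with columns transcript,
#'   gene, chrom, start, end, strand, tss, pval, effect, weight, and the
#'   generator ground-truth column `truth_bivalent`.
#' @export
simulate_transcript_table <- function(states, n_transcripts,
                                      bivalent_effect = 0.2, seed = 1,
                                      genome = attr(states, "genome"),
                                      length_range = c(5000, 50000)) {
  if (n_transcripts <= 0) stop("n_transcripts must be > 0")
  if (bivalent_effect <= 0 || bivalent_effect > 1)
    stop("bivalent_effect must be in (0, 1]")
  if (is.null(genome)) stop("states carry no genome; supply one")
  lens <- chrom_lengths(genome)
  biv <- merge_intervals(states[states$name %in% BIVALENT_STATES, ,
                                drop = FALSE])
  with_seed(seed, {
    len <- round(stats::runif(n_transcripts, length_range[1],
                              length_range[2]))
    ch <- sample(names(lens), n_transcripts, replace = TRUE, prob = lens)
    strand <- sample(c("+", "-"), n_transcripts, replace = TRUE)
    start <- floor(stats::runif(n_transcripts, 0, lens[ch] - len))
    end <- start + len
    tss <- ifelse(strand == "+", start, end - 1)
    win <- intervals(ch, pmax(0, tss - 100), pmin(lens[ch], tss + 100))
    # overlap of each (unsorted) TSS window with bivalent states
    ov <- interval_overlap_bp(ch, pmax(0, tss - 100), pmin(lens[ch], tss + 100),
                              biv)
    is_biv <- ov >= 100
    pval <- stats::runif(n_transcripts)
    effect <- stats::rnorm(n_transcripts)
    if (bivalent_effect < 1 && any(is_biv)) {
      nb <- sum(is_biv)
      pval[is_biv] <- stats::rbeta(nb, bivalent_effect, 1)
      sgn <- ifelse(stats::runif(nb) < 0.8, 1, -1)
      effect[is_biv] <- sgn * abs(stats::rnorm(nb, mean = 1))
    }
    pval <- pmin(pmax(pval, 1e-300), 1)
    out <- data.frame(
      transcript = sprintf("TX%05d", seq_len(n_transcripts)),
      gene = sprintf("G%05d", seq_len(n_transcripts)),
      chrom = ch, start = start, end = end, strand = strand, tss = tss,
      pval = pval, effect = effect, weight = 2,
      truth_bivalent = is_biv, stringsAsFactors = FALSE)
    rownames(out) <- NULL
    class(out) <- c("transcript_table", "data.frame")
    out
  })
}

# bp overlap of ad-hoc windows (parallel vectors) with a flat interval set
interval_overlap_bp <- function(chrom, start, end, flat) {
  out <- numeric(length(chrom))
  for (ch in unique(chrom)) {
    i <- chrom == ch
    f <- flat[flat$chrom == ch, , drop = FALSE]
    if (!nrow(f)) next
    q <- IRanges::IRanges(start[i] + 1, end[i])
    s <- IRanges::IRanges(f$start + 1, f$end)
    hits <- IRanges::findOverlaps(q, s)
    if (length(hits)) {
      qi <- S4Vectors::queryHits(hits)
      si <- S4Vectors::subjectHits(hits)
      w <- pmin(IRanges::end(q)[qi], IRanges::end(s)[si]) -
        pmax(IRanges::start(q)[qi], IRanges::start(s)[si]) + 1
      agg <- rowsum(w, qi)
      out[i][as.integer(rownames(agg))] <- agg[, 1]
    }
  }
  out
}

#' Simulate fluorescence nucleus images with peripherally biased foci
#'
#' Each image holds one elliptical nucleus of moderate intensity on a dark
#' background, with bright 2-D Gaussian foci. The radial position of each
#' focus is drawn toward the periphery with strength `periphery_bias`
#' (`1` confines foci to the outer shell, true proximity <= 0.2). Ground
#' truth (centers, areas, exact minimum boundary distance and proximity) is
#' computed analytically from the ellipse.
#'
#' @param n_nuclei Number of images.
#' @param radius_px Major semi-axis in pixels (>= 10).
#' @param n_foci_range Length-2 integer range of foci per nucleus.
#' @param periphery_bias Real in `[0, 1]`.
#' @param pixel_size_um Physical pixel size in micrometers.
#' @param seed Integer seed.
#' @param focus_sd_px Gaussian focus width (pixels).
#' @param noise_sd Additive Gaussian pixel noise.
#' @return List with `images` (list of numeric matrices in `[0, 1]`),
#'   `truth` (per-focus data.frame: nucleus, focus, x, y, area_px,
#'   min_dist_px, min_dist_um, proximity), `nuclei` (per-nucleus table with
#'   physical radius in um) and `pixel_size_um`.
#' @export
simulate_nuclei <- function(n_nuclei, radius_px = 50, n_foci_range = c(2, 6),
                            periphery_bias = 0.5, pixel_size_um = 0.1,
                            seed = 1, focus_sd_px = 1.6, noise_sd = 0.01) {
  if (radius_px < 10) stop("radius_px must be >= 10")
  if (periphery_bias < 0 || periphery_bias > 1)
    stop("periphery_bias must be in [0, 1]")
  side <- as.integer(4 * radius_px)
  with_seed(seed, {
    images <- vector("list", n_nuclei)
    truth <- list()
    nuc <- list()
    for (i in seq_len(n_nuclei)) {
      a <- radius_px
      b <- radius_px * stats::runif(1, 0.85, 1)
      cx <- side / 2 + stats::runif(1, -2, 2)
      cy <- side / 2 + stats::runif(1, -2, 2)
      th <- seq(0, 2 * pi, length.out = 3600L)
      bx <- cx + a * cos(th)
      by <- cy + b * sin(th)
      xs <- matrix(rep(seq_len(side), each = side), nrow = side) # col = x
      ys <- matrix(rep(seq_len(side), times = side), nrow = side) # row = y
      inside <- ((xs - cx) / a)^2 + ((ys - cy) / b)^2 <= 1
      img <- matrix(0.03, side, side)
      img[inside] <- 0.2
      nf <- if (n_foci_range[2] > n_foci_range[1])
        sample(n_foci_range[1]:n_foci_range[2], 1) else n_foci_range[1]
      t_max <- 1 - 0.83 * periphery_bias
      fxs <- numeric(0); fys <- numeric(0)
      for (j in seq_len(nf)) {
        repeat {
          phi <- stats::runif(1, 0, 2 * pi)
          rphi <- a * b / sqrt((b * cos(phi))^2 + (a * sin(phi))^2)
          t <- stats::runif(1, 0, t_max)
          fx <- cx + (1 - t) * rphi * cos(phi)
          fy <- cy + (1 - t) * rphi * sin(phi)
          # foci are simulated as resolvable bodies: keep centers at least
          # 5 focus widths apart so truth and detections correspond 1:1
          sep_ok <- !length(fxs) ||
            min((fxs - fx)^2 + (fys - fy)^2) >= (5 * focus_sd_px)^2
          if (sep_ok && ((fx - cx) / a)^2 + ((fy - cy) / b)^2 < 1) break
        }
        fxs <- c(fxs, fx); fys <- c(fys, fy)
        bump <- 0.8 * exp(-((xs - fx)^2 + (ys - fy)^2) / (2 * focus_sd_px^2))
        img <- img + bump * inside
        d2b <- sqrt((bx - fx)^2 + (by - fy)^2)
        k <- which.min(d2b)
        dmin <- d2b[k]
        dcb <- sqrt((bx[k] - cx)^2 + (by[k] - cy)^2)
        area <- sum(bump >= 0.4 & inside)
        truth[[length(truth) + 1]] <- data.frame(
          nucleus = i, focus = j, x = fx, y = fy, area_px = area,
          min_dist_px = dmin, min_dist_um = dmin * pixel_size_um,
          proximity = min(dmin / dcb, 1), stringsAsFactors = FALSE)
      }
      img <- img + stats::rnorm(side * side, 0, noise_sd)
      images[[i]] <- pmin(pmax(img, 0), 1)
      nuc[[i]] <- data.frame(nucleus = i, cx = cx, cy = cy, a_px = a,
                             b_px = b, radius_um = a * pixel_size_um,
                             stringsAsFactors = FALSE)
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(nucleus = integer(), focus = integer(), x = numeric(),
                 y = numeric(), area_px = numeric(), min_dist_px = numeric(),
                 min_dist_um = numeric(), proximity = numeric())
    list(images = images, truth = truth, nuclei = do.call(rbind, nuc),
         pixel_size_um = pixel_size_um)
  })
}

#' Write simulated nuclei as 16-bit TIFF images plus a truth table
#' @param sim Output of [simulate_nuclei()].
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_nuclei_images <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(sim$images)) {
    img <- EBImage::Image(t(sim$images[[i]]))
    EBImage::writeImage(img, file.path(dir, sprintf("nucleus_%03d.tiff", i)),
                        type = "tiff", bits.per.sample = 16L)
  }
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
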