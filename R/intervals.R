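#' Construct a set of genomic intervals
#'
#' Intervals are 0-based half-open `[start, end)`, sorted by (chrom, start).
#' This is the common currency for domains, LADs, chromatin states and
#' blacklists throughout the package.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Numeric coordinates with `0 <= start < end`.
#' @param name Optional character labels (e.g. chromatin-state mnemonics).
#' @param score Optional numeric scores.
#' @param genome Optional `sammy_genome`; when supplied, coordinates are
#'   validated against chromosome bounds.
#' @return A data.frame of class `genomic_intervals` with columns chrom,
#'   start, end and optionally name, score.
#' @examples
#' intervals("chr1", c(0, 500), c(100, 900))
#' @export
intervals <- function(chrom, start, end, name = NULL, score = NULL,
                      genome = NULL) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  n <- max(length(chrom), length(start), length(end))
  if (length(chrom) == 1) chrom <- rep(chrom, n)
  if (length(start) != n || length(end) != n || length(chrom) != n)
    stop("chrom, start, end must have equal lengths (scalar chrom recycles)")
  df <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- as.character(name)
  if (!is.null(score)) df$score <- as.numeric(score)
  validate_intervals(df, genome)
  o <- order(df$chrom, df$start, df$end)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("genomic_intervals", "data.frame")
  df
}

validate_intervals <- function(x, genome = NULL) {
  if (nrow(x)) {
    if (anyNA(x$start) || anyNA(x$end))
      stop("missing coordinates in interval set")
    bad <- which(x$start < 0 | x$start >= x$end)
    if (length(bad))
      stop("invalid interval at record ", bad[1], ": start=", x$start[bad[1]],
           " end=", x$end[bad[1]], " (need 0 <= start < end)")
    if (any(x$start != floor(x$start)) || any(x$end != floor(x$end)))
      stop("non-integer coordinates in interval set")
  }
  if (!is.null(genome)) {
    lens <- chrom_lengths(genome)
    unk <- setdiff(unique(x$chrom), names(lens))
    if (length(unk)) stop("unknown chromosome: ", unk[1])
    over <- which(x$end > lens[x$chrom])
    if (length(over))
      stop("interval at record ", over[1], " exceeds length of ",
           x$chrom[over[1]])
  }
  invisible(x)
}

as_intervals <- function(df, genome = NULL) {
  intervals(df$chrom, df$start, df$end,
            name = if ("name" %in% names(df)) df$name else NULL,
            score = if ("score" %in% names(df)) df$score else NULL,
            genome = genome)
}

empty_intervals <- function() {
  intervals(character(), numeric(), numeric())
}

#' @export
print.genomic_intervals <- function(x, ...) {
  cat(sprintf("<intervals> %d record(s), %s bp\n", nrow(x),
              format(total_bp(x), big.mark = ",")))
  print.data.frame(utils::head(x, 8), row.names = FALSE)
  if (nrow(x) > 8) cat("...\n")
  invisible(x)
}

# IRanges bridge: 0-based half-open -> 1-based closed and back.
.to_ir <- function(x) IRanges::IRanges(start = x$start + 1, end = x$end)
.from_ir <- function(ir, chrom) {
  if (!length(ir)) return(NULL)
  data.frame(chrom = chrom, start = IRanges::start(ir) - 1,
             end = IRanges::end(ir), stringsAsFactors = FALSE)
}

# --- vectorized flat-interval kernels (per chromosome, numeric vectors) ----
# Coalesce possibly overlapping/bookended [s, e) pairs into a flat list.
.flatten_vec <- function(s, e) {
  o <- order(s, e)
  s <- s[o]; e <- e[o]
  ec <- cummax(e)
  n <- length(s)
  new_grp <- c(TRUE, s[-1] > ec[-n])
  idx_last <- c(which(new_grp)[-1] - 1L, n)
  list(start = s[new_grp], end = ec[idx_last])
}

# Is each position p covered by the flat list f (sorted, disjoint)?
.in_flat <- function(p, f) {
  if (!length(f$start)) return(rep(FALSE, length(p)))
  idx <- findInterval(p, f$start)
  idx >= 1 & p < f$end[pmax(idx, 1L)]
}

# intersect/subtract two flat lists by sweeping the gap decomposition.
.op_flat <- function(a, b, op) {
  pos <- sort(unique(c(a$start, a$end, b$start, b$end)))
  if (length(pos) < 2) return(NULL)
  gs <- pos[-length(pos)]
  in_a <- .in_flat(gs, a)
  keep <- if (op == "intersect") in_a & .in_flat(gs, b)
          else in_a & !.in_flat(gs, b)
  if (!any(keep)) return(NULL)
  .flatten_vec(gs[keep], pos[-1][keep])
}

.apply_op <- function(a, b, op) {
  chroms <- sort(unique(a$chrom))
  pieces <- lapply(chroms, function(ch) {
    ai <- a$chrom == ch
    bi <- b$chrom == ch
    if (op == "intersect" && !any(bi)) return(NULL)
    fa <- .flatten_vec(a$start[ai], a$end[ai])
    fb <- if (any(bi)) .flatten_vec(b$start[bi], b$end[bi])
          else list(start = numeric(0), end = numeric(0))
    r <- .op_flat(fa, fb, op)
    if (is.null(r)) NULL
    else data.frame(chrom = ch, start = r$start, end = r$end,
                    stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) empty_intervals() else as_intervals(out)
}

#' Flatten an interval set (merge overlapping and bookended intervals)
#'
#' @param x A `genomic_intervals`.
#' @return A flat `genomic_intervals` covering exactly the union of `x`.
#' @export
merge_intervals <- function(x) {
  if (!nrow(x)) return(empty_intervals())
  chroms <- sort(unique(x$chrom))
  out <- do.call(rbind, lapply(chroms, function(ch) {
    i <- x$chrom == ch
    f <- .flatten_vec(x$start[i], x$end[i])
    data.frame(chrom = ch, start = f$start, end = f$end,
               stringsAsFactors = FALSE)
  }))
  as_intervals(out)
}

#' Base-pair intersection of two interval sets
#' @param a,b `genomic_intervals`.
#' @return Flat `genomic_intervals` of bases present in both sets.
#' @export
intersect_intervals <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(empty_intervals())
  .apply_op(a, b, "intersect")
}

#' Base-pair subtraction of two interval sets
#' @param a,b `genomic_intervals`.
#' @return Flat `genomic_intervals` of bases in `a` but not in `b`.
#' @export
subtract_intervals <- function(a, b) {
  if (!nrow(a)) return(empty_intervals())
  if (!nrow(b)) return(merge_intervals(a))
  .apply_op(a, b, "subtract")
}

#' Union of two interval sets
#' @param a,b `genomic_intervals`.
#' @return Flat `genomic_intervals` covering the union.
#' @export
union_intervals <- function(a, b) {
  ab <- rbind(as.data.frame(a)[, c("chrom", "start", "end")],
              as.data.frame(b)[, c("chrom", "start", "end")])
  if (!nrow(ab)) return(empty_intervals())
  merge_intervals(as_intervals(ab))
}

#' Total base pairs covered by an interval set
#'
#' Overlaps are flattened first, so every base counts once.
#'
#' @param x A `genomic_intervals`.
#' @return Numeric, total covered bp.
#' @export
total_bp <- function(x) {
  m <- merge_intervals(x)
  if (!nrow(m)) return(0)
  sum(m$end - m$start)
}

#' Read a BED file
#'
#' Accepts BED3 or more columns; column 4 is taken as `name` and column 5 as
#' `score` when present. Coordinates are 0-based half-open. Records are
#' normalized to sorted order.
#'
#' @param path Path to the BED file.
#' @param genome Optional `sammy_genome` used to validate chromosome names
#'   and bounds.
#' @return A `genomic_intervals`.
#' @export
read_bed <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "track") &
    !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(empty_intervals())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- vapply(parts, length, 1L)
  if (any(ncols < 3L))
    stop("line ", lineno[which(ncols < 3L)[1]],
         ": expected >= 3 tab-separated columns")
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) |
                 start != floor(start) | end != floor(end))
  if (length(bad))
    stop("line ", lineno[bad[1]], ": non-integer coordinates")
  bad <- which(start < 0 | start >= end)
  if (length(bad))
    stop("line ", lineno[bad[1]], ": invalid interval (start=",
         start[bad[1]], ", end=", end[bad[1]], ")")
  nm <- if (all(ncols >= 4L)) vapply(parts, `[[`, "", 4L) else NULL
  sc <- if (all(ncols >= 5L))
    suppressWarnings(as.numeric(vapply(parts, `[[`, "", 5L))) else NULL
  if (!is.null(genome)) {
    lens <- chrom_lengths(genome)
    unk <- which(!(chrom %in% names(lens)))
    if (length(unk))
      stop("line ", lineno[unk[1]], ": unknown chromosome ", chrom[unk[1]])
    over <- which(end > lens[chrom])
    if (length(over))
      stop("line ", lineno[over[1]], ": interval exceeds length of ",
           chrom[over[1]])
  }
  intervals(chrom, start, end, name = nm, score = sc)
}

#' Write a BED file
#'
#' Emits BED3, BED4 or BED6 depending on which optional columns are present.
#'
#' @param x A `genomic_intervals`.
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  if (!nrow(x)) {
    writeLines(character(), path)
    return(invisible(path))
  }
  has_name <- "name" %in% names(x)
  has_score <- "score" %in% names(x)
  lines <- if (has_name && has_score) {
    sprintf("%s\t%d\t%d\t%s\t%s\t.", x$chrom, as.integer(x$start),
            as.integer(x$end), x$name, format_num(x$score))
  } else if (has_name) {
    sprintf("%s\t%d\t%d\t%s", x$chrom, as.integer(x$start),
            as.integer(x$end), x$name)
  } else {
    sprintf("%s\t%d\t%d", x$chrom, as.integer(x$start), as.integer(x$end))
  }
  writeLines(lines, path)
  invisible(path)
}

# Locale-independent numeric formatting for deterministic text output.
format_num <- function(x, digits = 6) {
  out <- formatC(x, format = "g", digits = digits)
  gsub(" ", "", out)
}
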