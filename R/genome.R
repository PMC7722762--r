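#' Define a genome as an ordered set of chromosomes
#'
#' A genome is the coordinate system every other object in the package lives
#' on: an ordered list of chromosome names with lengths in base pairs. All
#' coordinates in the package are 0-based, half-open (BED convention).
#'
#' @param chrom Character vector of unique chromosome names.
#' @param length Numeric vector of chromosome lengths in bp (> 0).
#' @return An object of class `sammy_genome`: a data.frame with columns
#'   `chrom` and `length`, in the order given.
#' @examples
#' g <- genome(c("chr1", "chr2"), c(30e6, 30e6))
#' chrom_lengths(g)
#' @export
genome <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (length(chrom) != length(length))
    stop("chrom and length must have the same length")
  if (anyDuplicated(chrom))
    stop("duplicate chromosome names: ",
         paste(unique(chrom[duplicated(chrom)]), collapse = ", "))
  if (length(length) && any(!is.finite(length) | length <= 0))
    stop("chromosome lengths must be positive and finite")
  structure(data.frame(chrom = chrom, length = length,
                       stringsAsFactors = FALSE),
            class = c("sammy_genome", "data.frame"))
}

#' @export
print.sammy_genome <- function(x, ...) {
  cat(sprintf("<genome> %d chromosome(s), %s bp total\n",
              nrow(x), format(sum(x$length), big.mark = ",")))
  print.data.frame(utils::head(x, 10), row.names = FALSE)
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Named vector of chromosome lengths
#' @param genome A `sammy_genome`.
#' @return Named numeric vector (names = chromosomes).
#' @export
chrom_lengths <- function(genome) {
  stopifnot(inherits(genome, "sammy_genome"))
  stats::setNames(genome$length, genome$chrom)
}

#' Read a chrom.sizes file
#'
#' Two tab-separated columns: chromosome name and length. Order is preserved.
#'
#' @param path Path to the chrom.sizes file.
#' @return A `sammy_genome`.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty chrom.sizes file: ", path)
    return(genome(character(), numeric()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 2L)
  if (length(bad))
    stop("line ", bad[1], ": expected two tab-separated columns")
  nm <- vapply(parts, `[[`, "", 1L)
  len <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(len))
    stop("line ", which(is.na(len))[1], ": non-numeric chromosome length")
  if (any(len <= 0))
    stop("line ", which(len <= 0)[1], ": non-positive chromosome length")
  if (anyDuplicated(nm))
    stop("duplicate chromosome name: ", nm[duplicated(nm)][1])
  genome(nm, len)
}

#' Write a chrom.sizes file
#' @param genome A `sammy_genome`.
#' @param path Output path.
#' @export
write_chrom_sizes <- function(genome, path) {
  stopifnot(inherits(genome, "sammy_genome"))
  writeLines(sprintf("%s\t%d", genome$chrom, as.integer(genome$length)), path)
  invisible(path)
}

#' Number of bins per chromosome on a fixed grid
#'
#' Bin i (0-based) covers `[i*bin_size, (i+1)*bin_size)`; the final partial
#' bin is kept.
#'
#' @param genome A `sammy_genome`.
#' @param bin_size Bin width in bp (> 0).
#' @return Named integer vector of bin counts.
#' @export
bin_counts <- function(genome, bin_size) {
  stopifnot(inherits(genome, "sammy_genome"), bin_size > 0)
  stats::setNames(as.integer(ceiling(genome$length / bin_size)), genome$chrom)
}

# Run code under a fixed RNG seed, restoring the caller's RNG state after.
# All generators in the package are pure functions of (arguments, seed).
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(code)
}
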