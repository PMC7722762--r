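#' Lancaster aggregation of p-values
#'
#' The weighted generalization of Fisher's combined-probability method:
#' `T = sum_i Qgamma(shape = w_i/2, scale = 2; 1 - p_i)`, which under the
#' null is chi-square with `df = sum(w_i)`. All weights equal to 2 recover
#' Fisher's method exactly.
#'
#' @param p_values Numeric vector of p-values in `(0, 1]`; zeros are clamped
#'   to 1e-300 with a warning.
#' @param weights Positive weights, same length (default all 2 = Fisher).
#' @return List with `T` (statistic), `df`, `p` (chi-square upper tail).
#' @examples
#' lancaster(c(0.5, 0.5)) # Fisher: T = 2.7726, p ~ 0.5966
#' @export
lancaster <- function(p_values, weights = rep(2, length(p_values))) {
  if (!length(p_values)) stop("empty p-value vector")
  if (length(weights) != length(p_values))
    stop("p_values and weights must have equal lengths")
  if (any(weights <= 0)) stop("weights must be > 0")
  if (any(p_values < 0 | p_values > 1)) stop("p-values must be in [0, 1]")
  if (any(p_values == 0)) {
    warning("p-value of 0 clamped to 1e-300")
    p_values[p_values == 0] <- 1e-300
  }
  tstat <- sum(stats::qgamma(p_values, shape = weights / 2, scale = 2,
                             lower.tail = FALSE))
  df <- sum(weights)
  list(T = tstat, df = df,
       p = stats::pchisq(tstat, df = df, lower.tail = FALSE))
}

#' Assign chromatin-state contexts to transcripts
#'
#' Body states (Tx, TxWk, ReprPC, ReprPCWk, Het, ZNF/Rpts) are assigned
#' when at least 50% of the transcript body overlaps the state. Bivalent
#' states (TssBiv, BivFlnk, EnhBiv) are assigned when the 200-nt window
#' centered on the TSS overlaps the state by at least 100 nt. A transcript
#' may carry several context labels; `bivalent` flags any bivalent
#' assignment. With `domain_filter`, transcripts whose body does not
#' intersect the filter set are dropped.
#'
#' @param transcripts Data.frame with columns `transcript`, `chrom`,
#'   `start`, `end`, `tss` (plus anything else, preserved).
#' @param states `genomic_intervals` with state mnemonics in `name`.
#' @param domain_filter Optional `genomic_intervals` (e.g. called domains).
#' @param body_overlap Body-state threshold (default 0.5).
#' @param tss_window Total TSS window in nt (default 200, i.e. TSS +/- 100).
#' @return The transcript table with added columns `contexts`
#'   (comma-separated labels, "" when none) and `bivalent` (logical).
#' @export
assign_chromatin_context <- function(transcripts, states,
                                     domain_filter = NULL,
                                     body_overlap = 0.5, tss_window = 200) {
  unk <- setdiff(unique(states$name), CHROMATIN_STATES)
  if (length(unk)) stop("unknown state label: ", unk[1])
  tx <- as.data.frame(transcripts)
  if (!is.null(domain_filter)) {
    ov <- interval_overlap_bp(tx$chrom, tx$start, tx$end,
                              merge_intervals(domain_filter))
    tx <- tx[ov >= 1, , drop = FALSE]
  }
  n <- nrow(tx)
  ctx <- vector("list", n)
  body_states <- c("Tx", "TxWk", "ReprPC", "ReprPCWk", "Het", "ZNF/Rpts")
  for (s in intersect(body_states, unique(states$name))) {
    flat <- merge_intervals(states[states$name == s, , drop = FALSE])
    ov <- interval_overlap_bp(tx$chrom, tx$start, tx$end, flat)
    hit <- ov / (tx$end - tx$start) >= body_overlap
    for (i in which(hit)) ctx[[i]] <- c(ctx[[i]], s)
  }
  half <- tss_window / 2
  biv <- rep(FALSE, n)
  for (s in intersect(BIVALENT_STATES, unique(states$name))) {
    flat <- merge_intervals(states[states$name == s, , drop = FALSE])
    ov <- interval_overlap_bp(tx$chrom, pmax(0, tx$tss - half),
                              tx$tss + half, flat)
    hit <- ov >= tss_window * 0.5
    for (i in which(hit)) ctx[[i]] <- c(ctx[[i]], s)
    biv <- biv | hit
  }
  tx$contexts <- vapply(ctx, function(v)
    paste(unique(v), collapse = ","), "")
  tx$bivalent <- biv
  class(tx) <- c("transcript_table", "data.frame")
  tx
}

#' Aggregate transcript p-values per group with the Lancaster method
#'
#' Groups are chromatin-state contexts (from
#' [assign_chromatin_context()]) or pathways (membership table). With
#' `direction_split`, upregulated (`effect > 0`) and downregulated
#' (`effect < 0`) transcripts are aggregated separately. Benjamini-Hochberg
#' correction is applied across all rows of the run.
#'
#' @param transcripts Transcript table with `pval`, `effect` and either a
#'   `contexts` column or entries in `pathways`.
#' @param group_by `"context"` or `"pathway"`.
#' @param pathways Data.frame (`pathway`, `transcript`) when
#'   `group_by = "pathway"`.
#' @param direction_split Aggregate up/down separately (default TRUE).
#' @param weights_mode `"equal"` (all weights 2 = Fisher) or `"supplied"`
#'   (use the transcript `weight` column).
#' @return Data.frame of class `aggregation_rows`: `group`, `direction`,
#'   `n_transcripts`, `T_statistic`, `df`, `p`, `q`.
#' @export
aggregate_by_group <- function(transcripts, group_by = c("context", "pathway"),
                               pathways = NULL, direction_split = TRUE,
                               weights_mode = c("equal", "supplied")) {
  group_by <- match.arg(group_by)
  weights_mode <- match.arg(weights_mode)
  tx <- as.data.frame(transcripts)
  if (group_by == "context") {
    if (is.null(tx$contexts))
      stop("transcripts carry no contexts; run assign_chromatin_context()")
    memb <- strsplit(tx$contexts, ",", fixed = TRUE)
    idx <- rep(seq_len(nrow(tx)), lengths(memb))
    grp <- unlist(memb)
    keep <- nzchar(grp)
    idx <- idx[keep]; grp <- grp[keep]
  } else {
    if (is.null(pathways)) stop("pathway membership table required")
    m <- match(pathways$transcript, tx$transcript)
    ok <- !is.na(m)
    idx <- m[ok]; grp <- pathways$pathway[ok]
  }
  dirs <- if (direction_split) c("up", "down") else "all"
  rows <- list()
  for (g in unique(grp)) {
    members <- idx[grp == g]
    for (d in dirs) {
      sel <- switch(d, up = members[tx$effect[members] > 0],
                    down = members[tx$effect[members] < 0], all = members)
      if (!length(sel)) {
        message("group ", g, " (", d, "): no transcripts, skipped")
        next
      }
      w <- if (weights_mode == "equal") rep(2, length(sel))
           else tx$weight[sel]
      res <- lancaster(tx$pval[sel], w)
      rows[[length(rows) + 1]] <- data.frame(
        group = g, direction = d, n_transcripts = length(sel),
        T_statistic = res$T, df = res$df, p = res$p,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(structure(data.frame(group = character(), direction = character(),
                                n_transcripts = integer(),
                                T_statistic = numeric(), df = numeric(),
                                p = numeric(), q = numeric()),
                     class = c("aggregation_rows", "data.frame")))
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("aggregation_rows", "data.frame"))
}

#' Rank groups by summed -log10 p across conditions
#'
#' Utility for comparing aggregation runs from several conditions: groups
#' are ranked by the sum over runs of `-log10(p)`.
#'
#' @param runs Named list of `aggregation_rows` (one per condition).
#' @param direction Restrict to one direction label (default use all rows).
#' @return Data.frame `group`, `sum_neg_log10_p`, `rank`.
#' @export
rank_groups_across <- function(runs, direction = NULL) {
  pieces <- lapply(runs, function(r) {
    df <- as.data.frame(r)
    if (!is.null(direction)) df <- df[df$direction == direction, ,
                                      drop = FALSE]
    df
  })
  all_groups <- unique(unlist(lapply(pieces, function(d) d$group)))
  s <- vapply(all_groups, function(g) {
    sum(vapply(pieces, function(d) {
      p <- d$p[d$group == g]
      if (!length(p)) 0 else sum(-log10(p))
    }, numeric(1)))
  }, numeric(1))
  out <- data.frame(group = all_groups, sum_neg_log10_p = s,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$sum_neg_log10_p), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' One-tailed Fisher test of bivalent-gene enrichment among hits
#'
#' Tests whether differentially expressed (hit) genes are enriched for
#' bivalent genes, via the hypergeometric upper tail of the 2x2 table
#' (bivalent x hit).
#'
#' @param n_bivalent_hits Bivalent genes among the hits.
#' @param n_hits Total hit genes.
#' @param n_bivalent_total Bivalent genes in the universe.
#' @param n_total Genes in the universe.
#' @return List with `odds_ratio` (Inf-coded when a zero cell makes the
#'   association perfect), `p_value`, `table`.
#' @export
bivalent_enrichment_test <- function(n_bivalent_hits, n_hits,
                                     n_bivalent_total, n_total) {
  x11 <- n_bivalent_hits
  x12 <- n_hits - n_bivalent_hits
  x21 <- n_bivalent_total - n_bivalent_hits
  x22 <- (n_total - n_hits) - x21
  if (min(x11, x12, x21, x22) < 0)
    stop("counts do not form a valid 2x2 table")
  tab <- matrix(c(x11, x12, x21, x22), 2, 2, byrow = TRUE,
                dimnames = list(bivalent = c("yes", "no"),
                                hit = c("yes", "no")))
  p <- stats::phyper(x11 - 1, n_bivalent_total,
                     n_total - n_bivalent_total, n_hits,
                     lower.tail = FALSE)
  orat <- if (x12 == 0 || x21 == 0) {
    if (x11 == 0) NA_real_ else Inf
  } else (x11 * x22) / (x12 * x21)
  list(odds_ratio = orat, p_value = p, table = tab)
}

#' Read / write transcript tables
#'
#' TSV with columns transcript, gene, chrom, start, end, strand, tss, pval,
#' effect, weight (extra columns preserved).
#'
#' @param path File path.
#' @return A `transcript_table` data.frame.
#' @export
read_transcript_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript", "chrom", "start", "end", "tss", "pval", "effect")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("transcript table missing column(s): ", paste(miss, collapse = ", "))
  class(df) <- c("transcript_table", "data.frame")
  df
}

#' @rdname read_transcript_table
#' @param x A `transcript_table`.
#' @export
write_transcript_table <- function(x, path) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], format_num, digits = 10)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
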