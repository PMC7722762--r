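#' Default pipeline configuration
#'
#' Returns the configuration for a fully simulated run at desk scale: a
#' 2 x 30 Mb genome, 10 planted domains of 1-5 Mb, S4/S2 contrast factor 3,
#' the standard fraction pairs (S3 vs S2, S4 vs S3, S4 vs S2), 10-kb bins
#' and gap penalty 25 for the caller. All stage seeds are derived from the
#' single `seed` entry.
#'
#' @param seed Base seed.
#' @return Nested named list; serializable to YAML losslessly.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    genome = list(chroms = c("chrA", "chrB"), lengths = c(30e6, 30e6)),
    simulate = list(n_domains = 10, size_min = 1e6, size_max = 5e6,
                    enrichment_factor = 3, condition = "control",
                    disruption_rho = 0.5, n_reads = 2e5, replicates = 1),
    pairs = list(c("S3", "S2"), c("S4", "S3"), c("S4", "S2")),
    caller = list(bin_size = 1e4, gap_penalty = 25, fdr = 0.05,
                  n_permutations = 1000,
                  required_informative_fraction = 0.98),
    marks = list(bin_size = 1e4, noise_sd = 0.5, kernel_sd_bins = 3),
    metaprofile = list(k_bins = 50),
    aggregation = list(n_transcripts = 2000, bivalent_effect = 0.2),
    foci = list(enabled = FALSE, n_nuclei = 10, radius_px = 40,
                periphery_bias = 0.7, pixel_size_um = 0.1, cutoff_um = 1.0)
  )
}

#' Validate a pipeline configuration
#'
#' Checks structure and value ranges before any computation. A config may
#' either carry a `genome` block (chroms + lengths) or a `chrom_sizes` file
#' path.
#'
#' @param config Nested list (or path to a YAML file).
#' @return The normalized config list, invisibly; errors on problems.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or YAML path")
  if (is.null(config$seed)) stop("config requires a 'seed'")
  if (is.null(config$genome) && is.null(config$chrom_sizes))
    stop("config requires 'genome' (chroms + lengths) or a 'chrom_sizes' path")
  if (!is.null(config$chrom_sizes) && !file.exists(config$chrom_sizes))
    stop("chrom_sizes file not found: ", config$chrom_sizes)
  if (!is.null(config$genome)) {
    if (is.null(config$genome$chroms) || is.null(config$genome$lengths) ||
        length(config$genome$chroms) != length(config$genome$lengths))
      stop("genome block needs matching 'chroms' and 'lengths'")
  }
  sim <- config$simulate
  if (is.null(sim)) stop("config requires a 'simulate' block")
  if (!sim$condition %in% c("control", "disrupted"))
    stop("simulate$condition must be 'control' or 'disrupted'")
  if (sim$enrichment_factor <= 1)
    stop("simulate$enrichment_factor must be > 1")
  invisible(config)
}

#' Run the full simulated analysis pipeline
#'
#' Simulates fraction reads on a planted domain architecture, calls domains
#' for every configured fraction pair and replicate, computes pairwise
#' Jaccard matrices, recovery statistics against the planted truth, mark
#' track kernel correlations, domain border metaprofiles, chromatin-state
#' p-value aggregation, and (optionally) nuclear foci summaries. All
#' outputs are deterministic text files; re-running the same config yields
#' byte-identical results.
#'
#' @param config Config list (see [default_config()]) or YAML path.
#' @param out_dir Output directory (created).
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  g <- if (!is.null(config$chrom_sizes)) read_chrom_sizes(config$chrom_sizes)
       else genome(config$genome$chroms, config$genome$lengths)
  sim <- config$simulate
  arch <- make_architecture(
    g, n_domains = sim$n_domains,
    size_range = c(sim$size_min, sim$size_max),
    enrichment_factor = sim$enrichment_factor,
    condition = sim$condition,
    disruption_rho = if (is.null(sim$disruption_rho)) 0.5
                     else sim$disruption_rho,
    seed = seed)
  write_bed(arch$closed_domains, file.path(out_dir, "planted_domains.bed"))
  cal <- config$caller
  reps <- seq_len(sim$replicates)
  fracs <- unique(unlist(config$pairs))
  reads <- list()
  for (r in reps) {
    for (fr in fracs) {
      reads[[paste(fr, r, sep = "_")]] <- simulate_fraction_reads(
        arch, fr, sim$n_reads,
        seed = seed + 1000L * r + match(fr, c("S2", "S3", "S4")))
    }
  }
  # domain calls per pair and replicate
  calls <- list()
  for (r in reps) {
    for (pair in config$pairs) {
      key <- sprintf("%svs%s_rep%d", pair[1], pair[2], r)
      dc <- call_domains(reads[[paste(pair[1], r, sep = "_")]],
                         reads[[paste(pair[2], r, sep = "_")]], g,
                         bin_size = cal$bin_size,
                         gap_penalty = cal$gap_penalty, fdr = cal$fdr,
                         required_informative_fraction =
                           cal$required_informative_fraction,
                         n_permutations = cal$n_permutations,
                         seed = seed + 7L)
      calls[[key]] <- dc
      write_domains(dc, file.path(out_dir, paste0("domains_", key, ".bed")),
                    file.path(out_dir, paste0("domains_", key, ".tsv")))
    }
  }
  # overlap matrix: planted-truth recovery + pairwise JI across replicates
  recov <- do.call(rbind, lapply(names(calls), function(k) {
    ci <- as_intervals_calls(calls[[k]])
    data.frame(comparison = k,
               ji_vs_planted = format_num(jaccard(ci, arch$closed_domains),
                                          10),
               called_bp = if (nrow(ci)) sum(ci$end - ci$start) else 0,
               n_calls = nrow(ci), stringsAsFactors = FALSE)
  }))
  utils::write.table(recov, file.path(out_dir, "domain_recovery.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(reps) > 1) {
    pairkeys <- vapply(config$pairs, function(p)
      sprintf("%svs%s", p[1], p[2]), "")
    ji_rows <- list()
    for (pk in pairkeys) {
      for (i in reps) for (j in reps) if (i < j) {
        a <- as_intervals_calls(calls[[sprintf("%s_rep%d", pk, i)]])
        b <- as_intervals_calls(calls[[sprintf("%s_rep%d", pk, j)]])
        jj <- if (nrow(a) && nrow(b)) jaccard(a, b) else 0
        ji_rows[[length(ji_rows) + 1]] <- data.frame(
          comparison = pk, rep_i = i, rep_j = j,
          jaccard = format_num(jj, 10), stringsAsFactors = FALSE)
      }
    }
    utils::write.table(do.call(rbind, ji_rows),
                       file.path(out_dir, "pairwise_jaccard.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  # mark tracks and kernel correlations against the S4/S2 log ratio
  mk <- config$marks
  lamin_like <- simulate_mark_track(arch, polarity = 1,
                                    noise_sd = mk$noise_sd,
                                    bin_size = mk$bin_size, seed = seed + 21L)
  open_like <- simulate_mark_track(arch, polarity = -1,
                                   noise_sd = mk$noise_sd,
                                   bin_size = mk$bin_size, seed = seed + 22L)
  lr <- log_ratio_track(
    bin_reads(reads[[paste("S4", reps[1], sep = "_")]], g, mk$bin_size),
    bin_reads(reads[[paste("S2", reps[1], sep = "_")]], g, mk$bin_size))
  kc <- data.frame(
    track = c("lamin_like", "open_like"),
    kernel_r = format_num(c(
      kernel_correlation(lr, lamin_like, mk$kernel_sd_bins),
      kernel_correlation(lr, open_like, mk$kernel_sd_bins)), 10),
    stringsAsFactors = FALSE)
  utils::write.table(kc, file.path(out_dir, "kernel_correlation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_bedgraph(lr, file.path(out_dir, "log_ratio_S4vsS2_rep1.bedGraph"))
  # border metaprofile of the log-ratio around planted domain starts
  mp <- border_profile(lr, arch$closed_domains, side = "start",
                       k_bins = config$metaprofile$k_bins)
  write_metaprofile(mp, file.path(out_dir, "border_profile_start.tsv"))
  # chromatin states + aggregation
  agg_cfg <- config$aggregation
  states <- paint_chromatin_states(arch, seed = seed + 31L)
  write_bed(states, file.path(out_dir, "chromatin_states.bed"))
  tx <- simulate_transcript_table(states, agg_cfg$n_transcripts,
                                  bivalent_effect = agg_cfg$bivalent_effect,
                                  seed = seed + 32L)
  tx <- assign_chromatin_context(tx, states)
  write_transcript_table(tx, file.path(out_dir, "transcripts.tsv"))
  agg <- aggregate_by_group(tx, group_by = "context")
  adf <- as.data.frame(agg)
  num <- vapply(adf, is.numeric, TRUE)
  adf[num] <- lapply(adf[num], format_num, digits = 10)
  utils::write.table(adf, file.path(out_dir, "aggregation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  # optional foci analysis
  fc <- config$foci
  if (isTRUE(fc$enabled)) {
    nsim <- simulate_nuclei(fc$n_nuclei, radius_px = fc$radius_px,
                            periphery_bias = fc$periphery_bias,
                            pixel_size_um = fc$pixel_size_um,
                            seed = seed + 41L)
    meas <- analyze_foci(nsim$images, fc$pixel_size_um)
    write_foci(meas, file.path(out_dir, "foci.tsv"),
               file.path(out_dir, "foci_summary.tsv"),
               cutoff_um = fc$cutoff_um)
  }
  # machine-readable run log (no timestamps: outputs stay byte-identical)
  log <- list(package = "sammytools",
              version = as.character(utils::packageVersion("sammytools")),
              seed = seed, config = config,
              planted_domains = nrow(arch$closed_domains),
              comparisons = names(calls))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
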