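# End-to-end orchestration: trim -> screen -> profile -> assemble (pooled
# transgenic experiments) -> map both genotypes -> classify -> triage ->
# characterize -> report, with Table-style accounting per sample and
# experiment and merged totals.

#' Element-wise merge of per-experiment count summaries
#'
#' @param per_experiment data.frame of numeric per-experiment counts (one
#'   row per experiment) or a list coercible to one.
#' @return named numeric vector of column sums.
#' @examples
#' merge_experiments(data.frame(reads = c(2238, 6212),
#'                              fragments = c(1879, 5273)))
#' @export
merge_experiments <- function(per_experiment) {
  if (is.list(per_experiment) && !is.data.frame(per_experiment))
    per_experiment <- as.data.frame(do.call(rbind, per_experiment))
  stopifnot(nrow(per_experiment) >= 1)
  colSums(per_experiment)
}

#' Run the complete insertion screen
#'
#' Takes either a `simulation_config` (the study is simulated first) or a
#' ready `tdna_study`, and runs the full screen: quality trimming, vector
#' k-mer screening of every sample and experiment, k-mer frequency
#' profiles, pooled assembly of the transgenic sample's matching reads,
#' mapping of all trimmed reads of both genotypes against the contigs,
#' presence classification, five-step triage and insertion
#' characterization.
#'
#' @param x a `simulation_config` or `tdna_study`.
#' @param k screen k-mer length.
#' @param circular index the vector as a circular plasmid.
#' @param quality_cutoff,min_length trimming parameters.
#' @param min_quality minimum per-base Phred inside a matching k-mer
#'   window.
#' @param min_overlap,max_mismatch_frac assembler parameters.
#' @param map_mismatch_frac mapper mismatch cap.
#' @param min_abs_depth,min_covered_frac presence-call thresholds.
#' @param triage_params threshold overrides passed to [triage_all()].
#' @param outdir optional directory; when given, all result tables are
#'   written there.
#' @return a list of class `tdna_run`: `summary` (RunSummary),
#'   `profiles`, `contigs`, `placements`, `patterns`, `triage`, `calls`,
#'   `study`.
#' @export
run_pipeline <- function(x, k = 20, circular = TRUE, quality_cutoff = 30,
                         min_length = 50, min_quality = 20,
                         min_overlap = 30, max_mismatch_frac = 0.02,
                         map_mismatch_frac = 0.05, min_abs_depth = 3,
                         min_covered_frac = 0.8, triage_params = list(),
                         outdir = NULL) {
  study <- if (inherits(x, "simulation_config")) simulate_study(x) else x
  stopifnot(inherits(study, "tdna_study"))
  cfg <- study$config
  if (length(cfg$experiments) == 0) stop("no experiments configured")
  index <- extract_vector_kmers(study$vector, k = k, circular = circular)

  samples <- c("transgenic", "wildtype")
  experiments <- names(cfg$experiments)
  read_groups <- split(study$reads,
                       paste(study$reads$sample, study$reads$experiment,
                             sep = "_"))
  trimmed <- list(); screened <- list(); profiles <- list()
  acc <- list()
  for (s in samples) {
    for (e in experiments) {
      key <- paste(s, e, sep = "_")
      px <- read_groups[[key]]
      tr <- trim_reads(px, quality_cutoff, min_length)
      sc <- screen_pairs(tr$pairs, index, min_quality)
      trimmed[[key]] <- tr
      screened[[key]] <- sc
      profiles[[key]] <- kmer_frequency_profile(sc, index)
      acc[[key]] <- data.frame(
        sample = s, experiment = e,
        raw_reads = tr$counts$raw_reads,
        trimmed_reads = tr$counts$trimmed_reads,
        reads_with_vector_identity = sc$counts$reads_matched,
        fragments_with_vector_identity = sc$counts$fragments_matched,
        stringsAsFactors = FALSE)
    }
  }
  accounting <- do.call(rbind, c(acc, list(make.row.names = FALSE)))

  # pool the transgenic sample's screened reads across experiments
  tg_keys <- paste("transgenic", experiments, sep = "_")
  tg_screened <- merge_screened(screened[tg_keys])
  contigs <- assemble_contigs(tg_screened, index,
                              min_overlap = min_overlap,
                              max_mismatch_frac = max_mismatch_frac,
                              vec = study$vector$sequence)
  frag_len <- max(vapply(cfg$experiments, `[[`, numeric(1),
                         "fragment_mean"))
  for (ci in names(contigs$contigs))
    contigs$contigs[[ci]] <- attach_context(contigs$contigs[[ci]],
                                            tg_screened,
                                            fragment_len = frag_len)

  # all trimmed reads of both genotypes against the contigs
  uid <- seqs <- smp <- expx <- vector("list", 0)
  for (key in names(trimmed)) {
    tr <- trimmed[[key]]
    p <- tr$pairs
    sp <- strsplit(key, "_")[[1]]
    s <- sp[1]
    e <- paste(sp[-1], collapse = "_")
    n2 <- 2L * nrow(p)
    uid[[key]] <- c(paste_ids(p$pair_id, "/1"), paste_ids(p$pair_id, "/2"),
                    tr$orphans$read_id)
    seqs[[key]] <- c(p$seq1, p$seq2, tr$orphans$seq)
    smp[[key]] <- rep(s, n2 + nrow(tr$orphans))
    expx[[key]] <- rep(e, n2 + nrow(tr$orphans))
  }
  all_reads <- data.frame(uid = unlist(uid, use.names = FALSE),
                          seq = unlist(seqs, use.names = FALSE),
                          sample = unlist(smp, use.names = FALSE),
                          experiment = unlist(expx, use.names = FALSE),
                          stringsAsFactors = FALSE)
  placements <- map_reads(all_reads, contigs,
                          seed_length = k,
                          max_mismatch_frac = map_mismatch_frac)
  coverage <- depth_profiles(placements, contigs, samples = samples)

  genome_size <- cfg$host_length * cfg$n_chromosomes * cfg$ploidy
  bases <- tapply(nchar(all_reads$seq), all_reads$sample, sum)
  sample_depths <- setNames(as.numeric(bases[samples]) / genome_size,
                            samples)

  patterns <- list()
  for (ci in names(contigs$contigs))
    patterns[[ci]] <- classify_presence(
      coverage[[ci]], contigs$contigs[[ci]]$segments, sample_depths,
      min_abs_depth = min_abs_depth, min_covered_frac = min_covered_frac)

  triage <- triage_all(contigs, patterns,
                       host_ref = study$host$reference,
                       vec = study$vector,
                       contaminant_db = study$contaminants,
                       params = triage_params)

  merged <- merge_experiments(
    accounting[accounting$sample == "transgenic",
               c("raw_reads", "trimmed_reads",
                 "reads_with_vector_identity",
                 "fragments_with_vector_identity")])
  category_counts <- table(triage$table$category)
  summary <- list(accounting = accounting,
                  merged_transgenic = merged,
                  n_contigs = length(contigs$contigs),
                  category_counts = as.list(category_counts),
                  sample_depths = sample_depths,
                  n_ambiguous_reads = placements$n_ambiguous)

  run <- structure(list(summary = summary, profiles = profiles,
                        index = index, contigs = contigs,
                        placements = placements, coverage = coverage,
                        patterns = patterns, triage = triage,
                        calls = triage$calls, study = study),
                   class = "tdna_run")
  if (!is.null(outdir)) write_run(run, outdir)
  run
}

#' @export
print.tdna_run <- function(x, ...) {
  s <- x$summary
  cat("Whole-genome insertion screen\n")
  cat(sprintf("  contigs: %d\n", s$n_contigs))
  acc <- s$accounting
  for (i in seq_len(nrow(acc)))
    cat(sprintf("  %s %s: raw %d, trimmed %d, vector reads %d, fragments %d\n",
                acc$sample[i], acc$experiment[i], acc$raw_reads[i],
                acc$trimmed_reads[i], acc$reads_with_vector_identity[i],
                acc$fragments_with_vector_identity[i]))
  m <- s$merged_transgenic
  cat(sprintf("  transgenic merged: vector reads %d, fragments %d\n",
              m[["reads_with_vector_identity"]],
              m[["fragments_with_vector_identity"]]))
  cat("  triage:",
      paste(names(s$category_counts), unlist(s$category_counts),
            sep = "=", collapse = ", "), "\n")
  for (ci in names(x$calls)) {
    cat(sprintf("  %s:\n", ci))
    print(x$calls[[ci]])
  }
  invisible(x)
}

#' Write all result tables of a run
#'
#' @param run a `tdna_run`.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_run <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(run$summary$accounting, file.path(outdir, "accounting.tsv"))
  write_tsv(run$triage$table, file.path(outdir, "triage.tsv"))
  for (key in names(run$profiles))
    write_tsv(run$profiles[[key]],
              file.path(outdir, sprintf("profile_%s.tsv", key)))
  cseqs <- vapply(run$contigs$contigs, `[[`, character(1), "consensus")
  write_fasta(cseqs, file.path(outdir, "contigs.fasta"))
  segs <- list(); plc <- list(); ctxs <- list()
  for (ci in names(run$contigs$contigs)) {
    ct <- run$contigs$contigs[[ci]]
    if (nrow(ct$segments) > 0)
      segs[[ci]] <- cbind(contig = ci, ct$segments)
    if (nrow(ct$placements) > 0) {
      p <- ct$placements
      plc[[ci]] <- data.frame(contig = ci, read = p$uid,
                              offset0 = p$offset - 1L, strand = p$strand,
                              mismatches = p$mismatches,
                              stringsAsFactors = FALSE)
    }
    if (nrow(ct$contexts) > 0)
      ctxs[[ci]] <- cbind(contig = ci, ct$contexts)
  }
  if (length(segs) > 0)
    write_tsv(do.call(rbind, c(segs, list(make.row.names = FALSE))),
              file.path(outdir, "vector_segments.tsv"))
  if (length(plc) > 0)
    write_tsv(do.call(rbind, c(plc, list(make.row.names = FALSE))),
              file.path(outdir, "placements.tsv"))
  if (length(ctxs) > 0) {
    cx <- do.call(rbind, c(ctxs, list(make.row.names = FALSE)))
    write_fasta(setNames(cx$sequence,
                         paste(cx$contig, cx$side, cx$source, sep = "|")),
                file.path(outdir, "contexts.fasta"))
  }
  depth_rows <- list()
  for (ci in names(run$coverage)) {
    d <- run$coverage[[ci]]$depth
    depth_rows[[ci]] <- data.frame(contig = ci, pos = seq_len(nrow(d)),
                                   depth_transgenic = d[, "transgenic"],
                                   depth_wildtype = d[, "wildtype"],
                                   stringsAsFactors = FALSE)
  }
  write_tsv(do.call(rbind, c(depth_rows, list(make.row.names = FALSE))),
            file.path(outdir, "depth.tsv"))
  calls <- lapply(run$calls, function(cl)
    list(chrom = cl$chrom, right_junction = cl$right_junction,
         left_junction = cl$left_junction, deleted_bp = cl$deleted_bp,
         integrated_interval = cl$integrated_interval,
         strand = cl$strand, flanks = cl$flanks))
  jsonlite::write_json(
    list(merged_transgenic = as.list(run$summary$merged_transgenic),
         n_contigs = run$summary$n_contigs,
         category_counts = run$summary$category_counts,
         insertion_calls = calls),
    file.path(outdir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
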