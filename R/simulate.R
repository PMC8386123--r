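# Synthetic study generator: a diploid host, a circular transformation
# vector, one planted T-DNA integration with a small host deletion, decoy
# host loci sharing exact 20-mers with the vector, endophyte-like
# contaminant genomes carrying vector-backbone segments, paired-end reads
# for two sequencing experiments, and chimeric library artifacts -- all with
# machine-readable ground truth.

#' Describe one sequencing experiment
#'
#' @param read_length read length in bp.
#' @param fragment_mean,fragment_sd mean and sd of the (Gaussian) insert
#'   size in bp; fragments are truncated to at least `read_length`.
#' @param depth mean x-fold coverage of the diploid genome mix the reads are
#'   drawn from (so the depth against a haploid reference is about twice
#'   this value).
#' @param substitution_error_rate per-base substitution probability.
#' @param quality_model list with `q_start`, `q_end` (mean Phred at first and
#'   last cycle, linearly interpolated), `sd`, `floor`, `ceiling`.
#' @param contamination_fraction fraction of read pairs drawn from the
#'   contaminant panel instead of the host.
#' @param contaminant_ids which contaminant genomes are present.
#' @return a list of class `experiment_block`.
#' @export
experiment_block <- function(read_length = 100, fragment_mean = 350,
                             fragment_sd = 35, depth = 30,
                             substitution_error_rate = 0.002,
                             quality_model = list(q_start = 38, q_end = 33,
                                                  sd = 3, floor = 3,
                                                  ceiling = 40),
                             contamination_fraction = 0,
                             contaminant_ids = character(0)) {
  stopifnot(read_length >= 30, fragment_mean >= read_length, fragment_sd >= 0,
            depth > 0, substitution_error_rate >= 0,
            substitution_error_rate <= 1, contamination_fraction >= 0,
            contamination_fraction <= 1)
  structure(list(read_length = as.integer(read_length),
                 fragment_mean = fragment_mean, fragment_sd = fragment_sd,
                 depth = depth,
                 substitution_error_rate = substitution_error_rate,
                 quality_model = quality_model,
                 contamination_fraction = contamination_fraction,
                 contaminant_ids = contaminant_ids),
            class = "experiment_block")
}

#' Configuration of a synthetic insertion-screen study
#'
#' Defaults emulate the study design the package is validated against: a
#' 500 kb diploid host, a 10,699 bp circular vector whose T-DNA spans
#' positions 8..5,726 of which 29..5,484 integrate, an 11 bp host deletion
#' at the integration site, two sequencing experiments (100 bp pairs at 30x
#' and 150 bp pairs at 60x of the diploid mix), 2% endophyte-like
#' contamination in experiment 1 only, five decoy host loci carrying exact
#' vector 20-mers, and a handful of chimeric vector-host artifact reads.
#'
#' @param seed integer seed; the same config and seed give byte-identical
#'   output.
#' @param host_length chromosome length in bp (per chromosome).
#' @param n_chromosomes number of chromosomes.
#' @param ploidy number of haplotypes per chromosome (2 = diploid).
#' @param gc_content host GC fraction.
#' @param snp_rate per-base heterozygosity between haplotypes.
#' @param vector_length plasmid length in bp.
#' @param tdna_interval 1-based inclusive T-DNA interval on the vector.
#' @param integrated_interval sub-interval of the T-DNA actually integrated.
#' @param insertion_chrom,insertion_pos,insertion_haplotype where the insert
#'   lands: `insertion_pos` is the last host base retained before the
#'   insert; exactly one haplotype carries it.
#' @param host_deletion_bp host bases deleted at the integration site.
#' @param experiments named list of [experiment_block()]s.
#' @param contaminated_samples which samples receive contaminant reads
#'   (`"transgenic"`, `"wildtype"`, or both).
#' @param chimeric_artifact_rate expected chimeric artifact reads per
#'   sequenced read (experiment 1, transgenic sample).
#' @param decoy_kmer_count number of host loci seeded with exact 20 bp
#'   vector matches.
#' @param flank_paralog optional list `(enabled, target_pos, width)` copying
#'   the insertion-flank region to a second locus, emulating collinear
#'   duplicated flanks.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              host_length = 500000L,
                              n_chromosomes = 1L,
                              ploidy = 2L,
                              gc_content = 0.38,
                              snp_rate = 0.005,
                              vector_length = 10699L,
                              tdna_interval = c(8L, 5726L),
                              integrated_interval = c(29L, 5484L),
                              insertion_chrom = "chr1",
                              insertion_pos = 250000L,
                              host_deletion_bp = 11L,
                              insertion_haplotype = "A",
                              experiments = list(
                                exp1 = experiment_block(
                                  read_length = 100, fragment_mean = 350,
                                  fragment_sd = 35, depth = 30,
                                  substitution_error_rate = 0.002,
                                  contamination_fraction = 0.02,
                                  contaminant_ids = c("endo_bla",
                                                      "endo_cole1")),
                                exp2 = experiment_block(
                                  read_length = 150, fragment_mean = 500,
                                  fragment_sd = 50, depth = 60,
                                  substitution_error_rate = 0.001,
                                  quality_model = list(q_start = 37,
                                                       q_end = 34, sd = 2.5,
                                                       floor = 3,
                                                       ceiling = 40))),
                              contaminated_samples = "transgenic",
                              chimeric_artifact_rate = 2e-05,
                              decoy_kmer_count = 5L,
                              flank_paralog = list(enabled = FALSE,
                                                   target_pos = 100000L,
                                                   width = 4000L)) {
  cfg <- list(seed = as.integer(seed), host_length = as.integer(host_length),
              n_chromosomes = as.integer(n_chromosomes),
              ploidy = as.integer(ploidy), gc_content = gc_content,
              snp_rate = snp_rate, vector_length = as.integer(vector_length),
              tdna_interval = as.integer(tdna_interval),
              integrated_interval = as.integer(integrated_interval),
              insertion_chrom = insertion_chrom,
              insertion_pos = as.integer(insertion_pos),
              host_deletion_bp = as.integer(host_deletion_bp),
              insertion_haplotype = insertion_haplotype,
              experiments = experiments,
              contaminated_samples = contaminated_samples,
              chimeric_artifact_rate = chimeric_artifact_rate,
              decoy_kmer_count = as.integer(decoy_kmer_count),
              flank_paralog = flank_paralog)
  validate_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_config <- function(cfg) {
  with(cfg, {
    stopifnot(host_length >= 1000, n_chromosomes >= 1, ploidy >= 1,
              gc_content >= 0, gc_content <= 1, snp_rate >= 0, snp_rate <= 1,
              host_deletion_bp >= 0, host_deletion_bp < host_length,
              length(tdna_interval) == 2, length(integrated_interval) == 2,
              tdna_interval[1] >= 1, tdna_interval[2] <= vector_length,
              tdna_interval[1] <= tdna_interval[2],
              integrated_interval[1] >= tdna_interval[1],
              integrated_interval[2] <= tdna_interval[2],
              integrated_interval[1] <= integrated_interval[2],
              insertion_pos >= 1,
              insertion_pos + host_deletion_bp <= host_length,
              chimeric_artifact_rate >= 0, decoy_kmer_count >= 0,
              length(experiments) >= 1)
    stopifnot(insertion_haplotype %in% LETTERS[seq_len(ploidy)])
  })
  invisible(cfg)
}

# deterministic per-stage seeds derived from the master seed
stage_seed <- function(cfg, offset) (cfg$seed %% 2000000000L) + offset

hap_names <- function(ploidy) LETTERS[seq_len(ploidy)]

#' Generate the diploid host genome
#'
#' Draws a random reference of `n_chromosomes` x `host_length` bp at the
#' configured GC content; haplotype A is the reference itself and further
#' haplotypes differ from it by heterozygous SNPs at `snp_rate`.
#'
#' @param config a [simulation_config()].
#' @return a list with `reference` (named character vector of chromosome
#'   sequences) and `haplotypes` (list of named character vectors, one per
#'   haplotype).
#' @export
generate_host <- function(config) {
  stopifnot(config$host_length >= 1000)
  set.seed(stage_seed(config, 11L))
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  reference <- setNames(
    vapply(chroms, function(ch) random_dna(config$host_length,
                                           config$gc_content),
           character(1)), chroms)
  haps <- hap_names(config$ploidy)
  haplotypes <- setNames(vector("list", length(haps)), haps)
  haplotypes[["A"]] <- reference
  if (length(haps) > 1) {
    for (h in haps[-1]) {
      mutated <- reference
      for (ch in chroms) {
        n_snp <- rbinom(1, config$host_length, config$snp_rate)
        if (n_snp > 0) {
          pos <- sort(sample.int(config$host_length, n_snp))
          orig <- substring(mutated[[ch]], pos, pos)
          shift <- sample.int(3, n_snp, replace = TRUE)
          new <- DNA_BASES[(match(orig, DNA_BASES) - 1L + shift) %% 4L + 1L]
          mutated[[ch]] <- replace_bases(mutated[[ch]], pos, new)
        }
      }
      haplotypes[[h]] <- mutated
    }
  }
  list(reference = reference, haplotypes = haplotypes)
}

#' Build the transformation-vector record
#'
#' A random circular plasmid with an annotated T-DNA interval delimited by
#' 25 bp (right) and 24 bp (left) border motifs, and two designated
#' backbone segments -- a "bla-like" selection-marker analog and a
#' "ColE1-like" replication-origin analog -- whose coordinates are recorded
#' and reused verbatim inside contaminant genomes.
#'
#' @param config a [simulation_config()].
#' @return a list of class `vector_record` with `sequence`, `length`,
#'   `circular`, `tdna_interval`, `integrated_interval`, `borders`,
#'   `segments` (data.frame of annotated features).
#' @export
build_vector <- function(config) {
  L <- config$vector_length
  td <- config$tdna_interval
  if (td[1] <= 1 && td[2] >= L)
    stop("tdna_interval covers the whole vector: no backbone remains")
  if (interval_length(td[1], td[2]) >= L)
    stop("tdna_interval leaves no backbone")
  set.seed(stage_seed(config, 12L))
  sequence <- random_dna(L, 0.5)

  backbone_start <- td[2] + 1L
  backbone_len <- L - td[2]
  bla_len <- as.integer(min(861, backbone_len %/% 4))
  cole1_len <- as.integer(min(651, backbone_len %/% 5))
  bla_start <- backbone_start + as.integer(round(0.25 * backbone_len))
  cole1_start <- backbone_start + as.integer(round(0.62 * backbone_len))
  stopifnot(bla_start + bla_len - 1L < cole1_start,
            cole1_start + cole1_len - 1L <= L)

  segments <- data.frame(
    feature = c("tdna", "right_border", "left_border", "integrated",
                "bla_like", "cole1_like"),
    start = c(td[1], td[1], td[2] - 23L, config$integrated_interval[1],
              bla_start, cole1_start),
    end = c(td[2], td[1] + 24L, td[2], config$integrated_interval[2],
            bla_start + bla_len - 1L, cole1_start + cole1_len - 1L),
    stringsAsFactors = FALSE)

  structure(list(sequence = sequence, length = L, circular = TRUE,
                 tdna_interval = td,
                 integrated_interval = config$integrated_interval,
                 borders = segments[segments$feature %in%
                                      c("right_border", "left_border"), ],
                 segments = segments),
            class = "vector_record")
}

vector_feature <- function(vec, feature) {
  row <- vec$segments[vec$segments$feature == feature, ]
  c(row$start, row$end)
}

#' Synthesize contaminant genomes
#'
#' Random bacterial-like backbones carrying the vector's bla-like and
#' ColE1-like segments verbatim, emulating endophytes whose plasmids share
#' backbone sequence with binary transformation vectors.
#'
#' @param config a [simulation_config()].
#' @param vec a `vector_record`.
#' @param genome_length length of each contaminant genome in bp.
#' @return named character vector of contaminant genome sequences.
#' @export
make_contaminants <- function(config, vec, genome_length = 30000L) {
  set.seed(stage_seed(config, 13L))
  embed <- function(feature) {
    seg <- vector_feature(vec, feature)
    seg_seq <- substring(vec$sequence, seg[1], seg[2])
    backbone <- random_dna(genome_length, 0.5)
    at <- as.integer(genome_length / 2)
    paste0(substring(backbone, 1, at - 1), seg_seq,
           substring(backbone, at + nchar(seg_seq),
                     genome_length))
  }
  c(endo_bla = embed("bla_like"), endo_cole1 = embed("cole1_like"))
}

#' Integrate a vector segment into a host haplotype
#'
#' Replaces `host_deletion_bp` bases following `insertion_pos` with the
#' integrated vector interval: the retained host prefix ends at
#' `insertion_pos` and the retained suffix starts at
#' `insertion_pos + deletion_bp + 1`.
#'
#' @param haplotype host chromosome sequence (character string).
#' @param vec a `vector_record` (or a plain character string).
#' @param integrated_interval 1-based inclusive interval on the vector; a
#'   zero-length insert may be requested with `NULL`.
#' @param insertion_pos last retained host base before the insert.
#' @param deletion_bp host bases deleted at the site.
#' @return the modified haplotype sequence.
#' @export
plant_insertion <- function(haplotype, vec, integrated_interval,
                            insertion_pos, deletion_bp) {
  L <- nchar(haplotype)
  if (insertion_pos < 0 || insertion_pos + deletion_bp > L)
    stop("insertion coordinates out of range")
  vseq <- if (inherits(vec, "vector_record")) vec$sequence else vec
  insert <- if (is.null(integrated_interval)) "" else {
    stopifnot(integrated_interval[1] >= 1,
              integrated_interval[2] <= nchar(vseq))
    substring(vseq, integrated_interval[1], integrated_interval[2])
  }
  paste0(substring(haplotype, 1, insertion_pos), insert,
         substring(haplotype, insertion_pos + deletion_bp + 1, L))
}

# Plant decoy loci: exact vector 20-mers copied into the reference and every
# haplotype at identical coordinates, flanked so that the exact match cannot
# extend beyond 20 bp (keeps the ground-truth match length well-defined).
plant_decoys <- function(host, vec, config, k = 20L) {
  n <- config$decoy_kmer_count
  if (n == 0)
    return(list(host = host,
                decoys = data.frame(chrom = character(0), start = integer(0),
                                    end = integer(0),
                                    vector_start = integer(0),
                                    vector_end = integer(0))))
  set.seed(stage_seed(config, 14L))
  L <- config$vector_length
  td <- config$tdna_interval
  bla <- vector_feature(vec, "bla_like")
  cole1 <- vector_feature(vec, "cole1_like")
  # candidate source positions: backbone, clear of the reused segments
  cand <- setdiff(seq(td[2] + 1L, L - k), c(seq(bla[1] - k, bla[2] + k),
                                            seq(cole1[1] - k, cole1[2] + k)))
  vstart <- sort(sample(cand, n))
  chrom <- sample(names(host$reference), n, replace = TRUE)
  hl <- config$host_length
  stopifnot(hl >= 5000)
  tries <- 0L
  repeat {
    tries <- tries + 1L
    start <- 1000L + as.integer(floor(runif(n) * (hl - 2000L - k)))
    away <- abs(start - config$insertion_pos) > 5000 |
      chrom != config$insertion_chrom
    spaced <- TRUE
    for (ch in unique(chrom)) {
      s <- sort(start[chrom == ch])
      if (length(s) > 1 && min(diff(s)) < 1000) spaced <- FALSE
    }
    if ((all(away) && spaced) || tries > 200L) break
  }
  if (tries > 200L) stop("could not place decoy loci; host too small")
  vb <- function(p) substring(vec$sequence, p, p)
  other_base <- function(b) DNA_BASES[match(b, DNA_BASES) %% 4L + 1L]
  for (i in seq_len(n)) {
    kmer <- substring(vec$sequence, vstart[i], vstart[i] + k - 1L)
    pos <- seq(start[i], start[i] + k - 1L)
    guard_left <- other_base(vb(vstart[i] - 1L))
    guard_right <- other_base(vb(vstart[i] + k))
    ins <- c(guard_left, strsplit(kmer, "")[[1]], guard_right)
    all_pos <- c(start[i] - 1L, pos, start[i] + k)
    host$reference[[chrom[i]]] <-
      replace_bases(host$reference[[chrom[i]]], all_pos, ins)
    for (h in names(host$haplotypes))
      host$haplotypes[[h]][[chrom[i]]] <-
        replace_bases(host$haplotypes[[h]][[chrom[i]]], all_pos, ins)
  }
  list(host = host,
       decoys = data.frame(chrom = chrom, start = start,
                           end = start + k - 1L, vector_start = vstart,
                           vector_end = vstart + k - 1L,
                           stringsAsFactors = FALSE))
}

# Force the host bases adjacent to the planted insert to differ from the
# vector bases adjacent to the integrated interval, so that the true
# junction coordinates and integrated interval are unambiguous.
disambiguate_junctions <- function(host, vec, config) {
  ii <- config$integrated_interval
  P <- config$insertion_pos
  del <- config$host_deletion_bp
  ch <- config$insertion_chrom
  fix <- function(host_pos, vector_pos) {
    if (vector_pos < 1 || vector_pos > vec$length) return(host)
    vbase <- substring(vec$sequence, vector_pos, vector_pos)
    hbase <- substring(host$reference[[ch]], host_pos, host_pos)
    if (hbase == vbase) {
      new <- DNA_BASES[match(vbase, DNA_BASES) %% 4L + 1L]
      host$reference[[ch]] <<- replace_bases(host$reference[[ch]],
                                             host_pos, new)
      for (h in names(host$haplotypes))
        host$haplotypes[[h]][[ch]] <<-
          replace_bases(host$haplotypes[[h]][[ch]], host_pos, new)
    }
    host
  }
  host <- fix(P, ii[1] - 1L)
  host <- fix(P + del + 1L, ii[2] + 1L)
  host
}

# Copy the insertion-flank region to a second locus on the reference and all
# haplotypes, emulating a collinear duplicated segment of the flanks.
apply_flank_paralog <- function(host, config) {
  fp <- config$flank_paralog
  if (!isTRUE(fp$enabled)) return(host)
  ch <- config$insertion_chrom
  half <- fp$width %/% 2L
  src <- c(config$insertion_pos - half, config$insertion_pos + half)
  stopifnot(src[1] >= 1, src[2] <= config$host_length)
  block <- substring(host$reference[[ch]], src[1], src[2])
  at <- fp$target_pos
  stopifnot(at + nchar(block) - 1L <= config$host_length,
            abs(at - config$insertion_pos) > fp$width + 1000)
  paste_in <- function(seq) {
    paste0(substring(seq, 1, at - 1), block,
           substring(seq, at + nchar(block), nchar(seq)))
  }
  host$reference[[ch]] <- paste_in(host$reference[[ch]])
  for (h in names(host$haplotypes))
    host$haplotypes[[h]][[ch]] <- paste_in(host$haplotypes[[h]][[ch]])
  host
}

#' Simulate one paired-end sequencing experiment
#'
#' Fragments are drawn uniformly from the genome mix (sequence picked
#' proportionally to length), fragment sizes are Gaussian truncated to at
#' least `read_length`, both strands are sampled equally, substitution
#' errors are applied at the configured rate and Phred strings follow the
#' position-dependent quality model.
#'
#' @param genome_mix named character vector: the sample's haplotype
#'   chromosome sequences (names become ground-truth source ids).
#' @param block an [experiment_block()].
#' @param seed integer seed for this experiment.
#' @param sample_id,experiment_id labels recorded with every pair.
#' @param contaminants named character vector of contaminant genomes
#'   (only those in `block$contaminant_ids` are used).
#' @param truth_ctx optional list describing the planted insert on a
#'   modified haplotype (`source`, `insert_start`, `insert_end`) used to
#'   label junction and vector-interior reads.
#' @return data.frame with one row per pair: ids, mate sequences and
#'   qualities, source coordinates and per-mate origin labels.
#' @export
simulate_paired_reads <- function(genome_mix, block, seed, sample_id = "S",
                                  experiment_id = "e1",
                                  contaminants = character(0),
                                  truth_ctx = NULL) {
  stopifnot(block$depth > 0)
  if (block$read_length > block$fragment_mean)
    stop("read_length exceeds fragment_mean")
  set.seed(seed %% 2000000000L)
  rl <- block$read_length
  G <- sum(nchar(genome_mix))
  n_pairs <- as.integer(round(block$depth * G / (2 * rl)))
  use_cont <- contaminants[intersect(names(contaminants),
                                     block$contaminant_ids)]
  is_cont <- if (length(use_cont) > 0 && block$contamination_fraction > 0)
    runif(n_pairs) < block$contamination_fraction else rep(FALSE, n_pairs)

  pick_source <- function(pool, n) {
    if (n == 0) return(character(0))
    sample(names(pool), n, replace = TRUE,
           prob = nchar(pool) / sum(nchar(pool)))
  }
  source <- character(n_pairs)
  source[!is_cont] <- pick_source(genome_mix, sum(!is_cont))
  source[is_cont] <- pick_source(use_cont, sum(is_cont))
  pool <- c(genome_mix, use_cont)
  src_len <- nchar(pool)[match(source, names(pool))]

  frag <- as.integer(round(rnorm(n_pairs, block$fragment_mean,
                                 block$fragment_sd)))
  frag <- pmax(frag, rl)
  frag <- pmin(frag, src_len)
  start <- as.integer(floor(runif(n_pairs) * (src_len - frag + 1))) + 1L
  end <- start + frag - 1L
  minus <- runif(n_pairs) < 0.5

  seq_fwd <- character(n_pairs)  # read off the fragment 5' end, + strand
  seq_rev <- character(n_pairs)  # read off the fragment 3' end, - strand
  for (id in unique(source)) {
    idx <- which(source == id)
    s <- pool[[id]]
    rc <- revcomp(s)
    L <- nchar(s)
    seq_fwd[idx] <- substring(s, start[idx], start[idx] + rl - 1L)
    seq_rev[idx] <- substring(rc, L - end[idx] + 1L, L - end[idx] + rl)
  }
  seq1 <- seq_fwd; seq1[minus] <- seq_rev[minus]
  seq2 <- seq_rev; seq2[minus] <- seq_fwd[minus]
  # source intervals covered by each mate
  fs <- start; fe <- start + rl - 1L       # fragment 5' mate
  rs <- end - rl + 1L; re <- end           # fragment 3' mate
  s1 <- fs; s1[minus] <- rs[minus]
  e1 <- fe; e1[minus] <- re[minus]
  s2 <- rs; s2[minus] <- fs[minus]
  e2 <- re; e2[minus] <- fe[minus]

  err <- block$substitution_error_rate
  apply_errors <- function(seqs) {
    if (err <= 0) return(seqs)
    n_err <- rbinom(length(seqs), rl, err)
    hit <- which(n_err > 0)
    if (length(hit) == 0) return(seqs)
    reads <- rep(hit, n_err[hit])
    pos <- sample.int(rl, length(reads), replace = TRUE)
    rank <- stats::ave(seq_along(reads), reads, FUN = seq_along)
    for (r in seq_len(max(rank))) {
      sel <- rank == r
      ri <- reads[sel]; pi <- pos[sel]
      orig <- substring(seqs[ri], pi, pi)
      shift <- sample.int(3, length(ri), replace = TRUE)
      new <- DNA_BASES[(match(orig, DNA_BASES) - 1L + shift) %% 4L + 1L]
      x <- seqs[ri]             # ri has no duplicates within one rank
      substr(x, pi, pi) <- new
      seqs[ri] <- x
    }
    seqs
  }
  seq1 <- apply_errors(seq1)
  seq2 <- apply_errors(seq2)

  qm <- block$quality_model
  curve <- seq(qm$q_start, qm$q_end, length.out = rl)
  qual1 <- qual_strings_cpp(n_pairs, curve, qm$sd, qm$floor, qm$ceiling, 33L)
  qual2 <- qual_strings_cpp(n_pairs, curve, qm$sd, qm$floor, qm$ceiling, 33L)

  label <- function(src, a, b) {
    out <- ifelse(src %in% names(use_cont),
                  paste0("contaminant:", src), "host-wt")
    if (!is.null(truth_ctx)) {
      on_mod <- src == truth_ctx$source
      P <- truth_ctx$insert_start - 1L  # last host base before insert
      Q <- truth_ctx$insert_end         # last insert base
      junction <- on_mod & ((a <= P & b >= P + 1L) | (a <= Q & b >= Q + 1L))
      interior <- on_mod & a >= P + 1L & b <= Q & !junction
      out[junction] <- "host-transgenic-junction"
      out[interior] <- "vector-interior"
    }
    out
  }

  data.frame(pair_id = sprintf("%s_%s_p%07d", sample_id, experiment_id,
                               seq_len(n_pairs)),
             sample = sample_id, experiment = experiment_id,
             source = source, frag_start = start, frag_end = end,
             minus_strand = minus,
             seq1 = seq1, qual1 = qual1, src_start1 = s1, src_end1 = e1,
             seq2 = seq2, qual2 = qual2, src_start2 = s2, src_end2 = e2,
             origin1 = label(source, s1, e1),
             origin2 = label(source, s2, e2),
             stringsAsFactors = FALSE)
}

#' Spike chimeric library artifacts into a read set
#'
#' Builds one chimeric template -- a vector substring joined to a host
#' substring at a random breakpoint -- and replaces the first mate of a few
#' randomly chosen host pairs with reads drawn from it, each containing at
#' least 20 bp of exact vector sequence and at least 20 bp of exact host
#' sequence. Emulates ligation artifacts arising during library
#' preparation.
#'
#' @param pairs data.frame from [simulate_paired_reads()].
#' @param vec a `vector_record`.
#' @param host_seq host chromosome sequence the host part is copied from.
#' @param rate expected artifact reads per sequenced read.
#' @param seed integer seed.
#' @param vector_part_bp length of the template's vector part.
#' @return list with modified `pairs` and a `template` descriptor
#'   (vector/host coordinates and breakpoint), or unchanged input when no
#'   artifact read is drawn.
#' @export
spike_chimeric_artifacts <- function(pairs, vec, host_seq, rate, seed,
                                     vector_part_bp = 52L) {
  stopifnot(rate >= 0)
  if (rate == 0 || nrow(pairs) == 0)
    return(list(pairs = pairs, template = NULL))
  set.seed(seed %% 2000000000L)
  rl <- nchar(pairs$seq1[1])
  n_art <- rpois(1, rate * 2 * nrow(pairs))
  if (n_art == 0) return(list(pairs = pairs, template = NULL))

  ii <- vec$integrated_interval
  vstart <- sample(seq(ii[1], ii[2] - vector_part_bp + 1L), 1)
  vpart <- substring(vec$sequence, vstart, vstart + vector_part_bp - 1L)
  hstart <- sample(seq(1L, nchar(host_seq) - rl), 1)
  hpart <- substring(host_seq, hstart, hstart + rl - 1L)
  template <- paste0(vpart, hpart)

  host_rows <- which(pairs$origin1 == "host-wt")
  n_art <- min(n_art, length(host_rows))
  rows <- sample(host_rows, n_art)
  # offsets keeping >=20 bp vector and >=20 bp host in each read:
  # vector bases = vector_part_bp - off + 1, host bases = off + rl - 1 -
  # vector_part_bp
  lo <- max(1L, vector_part_bp + 21L - rl)
  hi <- vector_part_bp - 19L
  stopifnot(lo <= hi)
  off <- lo + as.integer(floor(runif(n_art) * (hi - lo + 1L)))
  reads <- substring(template, off, off + rl - 1L)
  pairs$seq1[rows] <- reads
  pairs$origin1[rows] <- "chimeric-artifact"
  if (!"source" %in% names(pairs)) pairs$source <- NA_character_
  if (!"src_start1" %in% names(pairs)) pairs$src_start1 <- NA_integer_
  if (!"src_end1" %in% names(pairs)) pairs$src_end1 <- NA_integer_
  pairs$source[rows] <- "chimeric-template"
  pairs$src_start1[rows] <- off
  pairs$src_end1[rows] <- off + rl - 1L
  list(pairs = pairs,
       template = list(sequence = template,
                       vector_interval = c(vstart,
                                           vstart + vector_part_bp - 1L),
                       host_interval = c(hstart, hstart + rl - 1L),
                       breakpoint = vector_part_bp,
                       n_reads = n_art))
}

#' Simulate a complete two-genotype insertion-screen study
#'
#' Runs the full generator: vector, diploid host, decoy loci, contaminant
#' genomes, the planted integration, paired-end reads for every sample and
#' experiment, and chimeric artifacts -- and assembles the ground truth.
#'
#' @param config a [simulation_config()].
#' @return a list of class `tdna_study`: `config`, `vector`, `host`
#'   (reference and wild-type haplotypes), `transgenic` (haplotypes after
#'   integration), `contaminants`, `reads` (one data.frame, all samples and
#'   experiments), and `truth` (insertion site, deleted interval and bases,
#'   integrated interval, decoy loci, chimera template, per-read origin
#'   counts).
#' @export
simulate_study <- function(config) {
  validate_config(config)
  vec <- build_vector(config)
  host <- generate_host(config)
  host <- apply_flank_paralog(host, config)
  dec <- plant_decoys(host, vec, config)
  host <- dec$host
  host <- disambiguate_junctions(host, vec, config)
  contaminants <- make_contaminants(config, vec)

  ch <- config$insertion_chrom
  hap <- config$insertion_haplotype
  P <- config$insertion_pos
  del <- config$host_deletion_bp
  ii <- config$integrated_interval
  ilen <- interval_length(ii[1], ii[2])

  transgenic <- host$haplotypes
  transgenic[[hap]][[ch]] <- plant_insertion(
    host$haplotypes[[hap]][[ch]], vec, ii, P, del)

  mix_of <- function(haplos) {
    out <- character(0)
    for (h in names(haplos))
      out <- c(out, setNames(haplos[[h]],
                             paste0(names(haplos[[h]]), "_hap", h)))
    out
  }
  wt_mix <- mix_of(host$haplotypes)
  tg_mix <- mix_of(transgenic)
  truth_ctx <- list(source = paste0(ch, "_hap", hap),
                    insert_start = P + 1L, insert_end = P + ilen)

  reads <- list()
  chimera_template <- NULL
  for (ei in seq_along(config$experiments)) {
    eid <- names(config$experiments)[ei]
    block <- config$experiments[[eid]]
    for (si in 1:2) {
      sid <- c("transgenic", "wildtype")[si]
      cont <- if (sid %in% config$contaminated_samples) contaminants
              else character(0)
      px <- simulate_paired_reads(
        if (sid == "transgenic") tg_mix else wt_mix, block,
        seed = stage_seed(config, 100L + 10L * ei + si),
        sample_id = sid, experiment_id = eid, contaminants = cont,
        truth_ctx = if (sid == "transgenic") truth_ctx else NULL)
      if (sid == "transgenic" && ei == 1 &&
          config$chimeric_artifact_rate > 0) {
        sp <- spike_chimeric_artifacts(
          px, vec, host$reference[[ch]], config$chimeric_artifact_rate,
          seed = stage_seed(config, 15L))
        px <- sp$pairs
        chimera_template <- sp$template
      }
      reads[[paste(sid, eid, sep = "_")]] <- px
    }
  }
  reads <- do.call(rbind, c(reads, list(make.row.names = FALSE)))

  deleted_seq <- substring(host$reference[[ch]], P + 1L, P + del)
  origins <- c(reads$origin1, reads$origin2)
  truth <- list(
    insertion = list(chrom = ch, haplotype = hap,
                     left_flank_end = P, right_flank_start = P + del + 1L,
                     deleted_interval = if (del > 0) c(P + 1L, P + del)
                                        else integer(0),
                     deleted_bp = del, deleted_seq = deleted_seq,
                     integrated_interval = ii),
    decoys = dec$decoys,
    chimera = chimera_template,
    origin_counts = as.list(table(origins)),
    n_pairs = nrow(reads))

  structure(list(config = config, vector = vec, host = host,
                 transgenic = transgenic, contaminants = contaminants,
                 reads = reads, truth = truth),
            class = "tdna_study")
}

#' Write a simulated study to disk
#'
#' FASTA for the reference, haplotypes, vector and contaminants; gzipped
#' paired FASTQ per sample and experiment; ground truth as JSON; the
#' configuration echoed as YAML.
#'
#' @param study a `tdna_study` from [simulate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wfa <- function(x, file) Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(x), file.path(dir, file))
  wfa(study$host$reference, "host_reference.fasta")
  for (h in names(study$host$haplotypes))
    wfa(study$host$haplotypes[[h]],
        sprintf("wildtype_hap%s.fasta", h))
  for (h in names(study$transgenic))
    wfa(study$transgenic[[h]], sprintf("transgenic_hap%s.fasta", h))
  wfa(setNames(study$vector$sequence, "vector"), "vector.fasta")
  if (length(study$contaminants) > 0)
    wfa(study$contaminants, "contaminants.fasta")
  write_tsv(study$vector$segments, file.path(dir, "vector_annotation.tsv"))

  for (grp in split(study$reads,
                    paste(study$reads$sample, study$reads$experiment,
                          sep = "_"))) {
    tag <- paste(grp$sample[1], grp$experiment[1], sep = "_")
    write_fastq(grp$seq1, grp$qual1, paste0(grp$pair_id, "/1"),
                file.path(dir, paste0(tag, "_R1.fastq.gz")))
    write_fastq(grp$seq2, grp$qual2, paste0(grp$pair_id, "/2"),
                file.path(dir, paste0(tag, "_R2.fastq.gz")))
  }
  jsonlite::write_json(study$truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  yaml::write_yaml(config_as_list(study$config),
                   file.path(dir, "config.yaml"))
  invisible(dir)
}

config_as_list <- function(cfg) {
  out <- unclass(cfg)
  out$experiments <- lapply(out$experiments, unclass)
  out
}
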