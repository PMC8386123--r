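# Shared fixtures and independent oracles. Fixtures are generated in code;
# oracles are deliberately naive (enumeration / dynamic programming) and
# stay independent of the implementation paths they check.

# quality string of n bases at constant Phred q
qstr <- function(n, q) strrep(intToUtf8(q + 33L), n)

# minimal pair table from parallel sequence vectors
make_pairs <- function(seq1, seq2 = NULL, q = 38, sample = "transgenic",
                       experiment = "e1") {
  n <- length(seq1)
  if (is.null(seq2)) seq2 <- vapply(nchar(seq1), function(l)
    tdnascreen::random_dna(l, 0.5), character(1))
  data.frame(pair_id = sprintf("%s_%s_p%07d", sample, experiment, seq_len(n)),
             sample = sample, experiment = experiment,
             seq1 = seq1, qual1 = vapply(nchar(seq1), qstr, character(1), q = q),
             seq2 = seq2, qual2 = vapply(nchar(seq2), qstr, character(1), q = q),
             stringsAsFactors = FALSE)
}

# a small but complete study configuration (fast to simulate end to end)
small_config <- function(seed = 1, ...) {
  defaults <- list(
    seed = seed, host_length = 40000L, insertion_pos = 20000L,
    decoy_kmer_count = 2L, chimeric_artifact_rate = 2e-4,
    experiments = list(
      exp1 = experiment_block(read_length = 100, fragment_mean = 350,
                              fragment_sd = 35, depth = 30,
                              substitution_error_rate = 0.002,
                              contamination_fraction = 0.02,
                              contaminant_ids = c("endo_bla", "endo_cole1")),
      exp2 = experiment_block(read_length = 150, fragment_mean = 500,
                              fragment_sd = 50, depth = 60,
                              substitution_error_rate = 0.001)))
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}

# force the host bases adjacent to a constructed integration site to
# differ from the vector bases adjacent to the integrated interval, so the
# fixture's true junctions are unambiguous (the study generator does the
# same for planted insertions)
guard_junctions <- function(ref, vec, pos, del = 11L,
                            ii = c(29L, 5484L)) {
  s <- ref[[1]]
  vb <- function(p) substring(vec$sequence, p, p)
  other <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
  if (substring(s, pos, pos) == vb(ii[1] - 1L))
    substr(s, pos, pos) <- other(vb(ii[1] - 1L))
  p2 <- pos + del + 1L
  if (substring(s, p2, p2) == vb(ii[2] + 1L))
    substr(s, p2, p2) <- other(vb(ii[2] + 1L))
  ref[[1]] <- s
  ref
}

# --- oracle: naive all-substring screen ------------------------------------
# every length-k window of every mate checked against the set of vector
# k-mers (both strands), with the per-base quality rule
oracle_screen <- function(pairs, vector_seq, k = 20, circular = TRUE,
                          min_quality = 20) {
  L <- nchar(vector_seq)
  ext <- if (circular) paste0(vector_seq, substring(vector_seq, 1, k - 1)) else
    vector_seq
  starts <- seq_len(if (circular) L else L - k + 1)
  kmers <- substring(ext, starts, starts + k - 1)
  kmer_set <- unique(c(kmers, tdnascreen::revcomp(kmers)))
  read_matches <- function(seq, qual) {
    n <- nchar(seq)
    if (n < k) return(FALSE)
    qs <- utf8ToInt(qual) - 33L
    for (o in seq_len(n - k + 1)) {
      if (min(qs[o:(o + k - 1)]) < min_quality) next
      if (substring(seq, o, o + k - 1) %in% kmer_set) return(TRUE)
    }
    FALSE
  }
  m1 <- mapply(read_matches, pairs$seq1, pairs$qual1, USE.NAMES = FALSE)
  m2 <- mapply(read_matches, pairs$seq2, pairs$qual2, USE.NAMES = FALSE)
  list(reads_matched = sum(m1) + sum(m2),
       fragments_matched = sum(m1 | m2),
       matched_uids = sort(c(paste0(pairs$pair_id[m1], "/1"),
                             paste0(pairs$pair_id[m2], "/2"))))
}

# --- oracle: maximal exact matches by diagonal enumeration -----------------
# all maximal exact matches >= min_len between a and b (b both strands),
# by scanning every diagonal of the match matrix
oracle_mems <- function(a, b, min_len = 20) {
  av <- strsplit(a, "")[[1]]
  out <- list()
  scan_one <- function(bv, strand) {
    na <- length(av); nb <- length(bv)
    for (d in seq(-(na - 1), nb - 1)) {
      i <- max(1, 1 - d); j <- i + d
      run <- 0L
      while (i <= na && j <= nb) {
        if (av[i] == bv[j]) run <- run + 1L
        else {
          if (run >= min_len)
            out[[length(out) + 1L]] <<- c(i - run, i - 1L, strand)
          run <- 0L
        }
        i <- i + 1L; j <- j + 1L
      }
      if (run >= min_len)
        out[[length(out) + 1L]] <<- c(i - run, i - 1L, strand)
    }
  }
  scan_one(strsplit(b, "")[[1]], 1L)
  scan_one(strsplit(tdnascreen::revcomp(b), "")[[1]], -1L)
  if (length(out) == 0)
    return(data.frame(contig_start = integer(0), contig_end = integer(0),
                      strand = integer(0)))
  df <- unique(as.data.frame(do.call(rbind, out)))
  names(df) <- c("contig_start", "contig_end", "strand")
  df[order(df$contig_start, df$contig_end), , drop = FALSE]
}

# --- oracle: best ungapped local alignment by full DP ----------------------
# best +1/-2 ungapped local alignment between query and subject over both
# strands; returns the maximum score and its alignment length/matches
oracle_best_ungapped <- function(query, subject) {
  score_one <- function(qv, sv) {
    best <- 0
    for (d in seq(-(length(qv) - 1), length(sv) - 1)) {
      i <- max(1, 1 - d); j <- i + d
      cur <- 0
      while (i <= length(qv) && j <= length(sv)) {
        cur <- cur + if (qv[i] == sv[j]) 1 else -2
        if (cur < 0) cur <- 0
        if (cur > best) best <- cur
        i <- i + 1; j <- j + 1
      }
    }
    best
  }
  qv <- strsplit(query, "")[[1]]
  sv <- strsplit(subject, "")[[1]]
  rv <- strsplit(tdnascreen::revcomp(query), "")[[1]]
  max(score_one(qv, sv), score_one(rv, sv))
}

# --- oracle: brute-force best read placement -------------------------------
# best placement of a read on a set of contigs: every offset, both strands,
# scored by matching bases over the overlap, subject to the mismatch cap
oracle_best_placement <- function(read, contigs, min_overlap = 20,
                                  max_mismatch_frac = 0.05) {
  best <- NULL
  for (ci in seq_along(contigs)) {
    cv <- strsplit(contigs[[ci]], "")[[1]]
    for (strand in c("+", "-")) {
      rv <- strsplit(if (strand == "+") read else
        tdnascreen::revcomp(read), "")[[1]]
      for (off in seq(-(length(rv) - 1), length(cv) - 1)) {
        a <- max(1, off + 1); b <- min(length(cv), off + length(rv))
        ov <- b - a + 1
        if (ov < min_overlap) next
        mism <- sum(rv[(a - off):(b - off)] != cv[a:b])
        if (mism > max_mismatch_frac * ov) next
        sc <- ov - mism
        if (is.null(best) || sc > best$score)
          best <- list(score = sc, contig = ci, start = a, end = b,
                       strand = strand, mismatches = mism)
      }
    }
  }
  best
}
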