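# Read screening: quality trimming, the vector k-mer index, retention of
# read pairs carrying a quality-passing vector k-mer, and the per-position
# k-mer frequency profile.

#' Quality-trim a pair table
#'
#' BWA-style 3' quality trimming (the running-sum rule also used by Trim
#' Galore) followed by a length filter. A read trimmed below `min_length`
#' is dropped; its mate, if long enough, is kept as an orphan excluded from
#' pairing.
#'
#' @param pairs pair data.frame (`pair_id`, `seq1`, `qual1`, `seq2`,
#'   `qual2`, plus any bookkeeping columns).
#' @param quality_cutoff Phred cutoff for the running-sum trim.
#' @param min_length minimum retained read length in bp.
#' @return list with `pairs` (both mates passing), `orphans` (data.frame
#'   `read_id`, `seq`, `qual`) and `counts` (raw/trimmed read and pair
#'   totals).
#' @export
trim_reads <- function(pairs, quality_cutoff = 30, min_length = 50) {
  n <- nrow(pairs)
  if (n == 0) {
    return(list(pairs = pairs,
                orphans = data.frame(read_id = character(0),
                                     seq = character(0),
                                     qual = character(0)),
                counts = list(raw_reads = 0L, trimmed_reads = 0L,
                              raw_pairs = 0L, pairs_retained = 0L,
                              orphans = 0L)))
  }
  len1 <- trim_len_cpp(pairs$qual1, quality_cutoff, 33L)
  len2 <- trim_len_cpp(pairs$qual2, quality_cutoff, 33L)
  pairs$seq1 <- substring(pairs$seq1, 1L, len1)
  pairs$qual1 <- substring(pairs$qual1, 1L, len1)
  pairs$seq2 <- substring(pairs$seq2, 1L, len2)
  pairs$qual2 <- substring(pairs$qual2, 1L, len2)
  ok1 <- len1 >= min_length
  ok2 <- len2 >= min_length
  both <- ok1 & ok2
  orphan1 <- ok1 & !ok2
  orphan2 <- ok2 & !ok1
  orphans <- data.frame(
    read_id = c(paste_ids(pairs$pair_id[orphan1], "/1"),
                paste_ids(pairs$pair_id[orphan2], "/2")),
    seq = c(pairs$seq1[orphan1], pairs$seq2[orphan2]),
    qual = c(pairs$qual1[orphan1], pairs$qual2[orphan2]),
    stringsAsFactors = FALSE)
  list(pairs = pairs[both, , drop = FALSE],
       orphans = orphans,
       counts = list(raw_reads = 2L * n,
                     trimmed_reads = 2L * sum(both) + nrow(orphans),
                     raw_pairs = n, pairs_retained = sum(both),
                     orphans = nrow(orphans)))
}

#' Build the vector k-mer index
#'
#' Extracts every continuous k-mer of the transformation vector. In
#' circular mode the k-1 k-mers spanning the plasmid origin are included,
#' so the index holds L starting positions; in linear mode L-k+1. K-mers
#' containing non-ACGT characters are excluded and counted. Matching
#' against the index considers both strands; reverse-complement hits are
#' recorded at the forward-strand start position.
#'
#' @param vec a `vector_record`, or a plain character string.
#' @param k k-mer length (the screen's sequence-identity threshold).
#' @param circular index k-mers across the origin of the circular plasmid.
#' @return a list of class `kmer_index`: `k`, `circular`, `length`,
#'   `sequence` (the origin-extended search sequence), `positions`
#'   (data.frame `kmer`, `vector_pos`), `n_excluded`.
#' @export
extract_vector_kmers <- function(vec, k = 20, circular = TRUE) {
  seqs <- if (inherits(vec, "vector_record")) vec$sequence else vec
  L <- nchar(seqs)
  if (L < k) stop("vector shorter than k")
  ext <- if (circular) paste0(seqs, substring(seqs, 1, k - 1)) else seqs
  starts <- seq_len(if (circular) L else L - k + 1)
  kmers <- substring(ext, starts, starts + k - 1)
  valid <- !grepl("[^ACGT]", kmers)
  structure(list(k = as.integer(k), circular = circular, length = L,
                 sequence = ext,
                 positions = data.frame(kmer = kmers[valid],
                                        vector_pos = starts[valid],
                                        stringsAsFactors = FALSE),
                 n_excluded = sum(!valid)),
            class = "kmer_index")
}

#' Retain read pairs containing a quality-passing vector k-mer
#'
#' A read matches when some length-k window equals a vector k-mer on either
#' strand and every base of that window has Phred quality of at least
#' `min_quality`. A pair is retained when at least one mate matches; the
#' non-matching mate is kept as the source of context sequence.
#'
#' @param pairs trimmed pair data.frame.
#' @param index a `kmer_index`.
#' @param min_quality minimum per-base Phred score inside the matching
#'   window.
#' @return a list of class `screened_pairs`: `pairs` (retained rows),
#'   `matches` (data.frame `pair_id`, `mate`, `read_offset` 1-based,
#'   `vector_pos` 1-based, `strand`), `counts` (`reads_matched`,
#'   `fragments_matched`).
#' @export
screen_pairs <- function(pairs, index, min_quality = 20) {
  stopifnot(inherits(index, "kmer_index"))
  n <- nrow(pairs)
  empty <- data.frame(pair_id = character(0), mate = integer(0),
                      read_offset = integer(0), vector_pos = integer(0),
                      strand = character(0), stringsAsFactors = FALSE)
  if (n == 0)
    return(structure(list(pairs = pairs, matches = empty,
                          counts = list(reads_matched = 0L,
                                        fragments_matched = 0L)),
                     class = "screened_pairs"))
  reads <- c(pairs$seq1, pairs$seq2)
  quals <- c(pairs$qual1, pairs$qual2)
  hits <- kmer_hits_cpp(index$sequence, reads, index$k, quals,
                        as.integer(min_quality), 33L)
  if (nrow(hits) == 0) {
    matches <- empty
  } else {
    vpos <- (hits$ref_pos - 1L) %% index$length + 1L
    matches <- data.frame(
      pair_id = pairs$pair_id[(hits$read - 1L) %% n + 1L],
      mate = ifelse(hits$read > n, 2L, 1L),
      read_offset = hits$read_pos,
      vector_pos = vpos,
      strand = ifelse(hits$fwd, "+", "-"),
      stringsAsFactors = FALSE)
    matches <- matches[order(matches$pair_id, matches$mate,
                             matches$read_offset, matches$vector_pos), ,
                       drop = FALSE]
    rownames(matches) <- NULL
  }
  retained <- pairs$pair_id %in% matches$pair_id
  structure(list(
    pairs = pairs[retained, , drop = FALSE],
    matches = matches,
    counts = screen_counts(matches)),
    class = "screened_pairs")
}

screen_counts <- function(matches) {
  key <- paste(matches$pair_id, matches$mate)
  list(reads_matched = sum(!duplicated(key)),
       fragments_matched = sum(!duplicated(matches$pair_id)))
}

#' Per-position vector k-mer frequency profile
#'
#' How often a quality-passing k-mer starting at each vector position
#' occurs in the screened read set: the screening result viewed along the
#' vector, which separates T-DNA coverage from backbone coverage.
#'
#' @param screened a `screened_pairs` object.
#' @param index the `kmer_index` used for screening.
#' @return data.frame with `position` (1..L) and `count`.
#' @export
kmer_frequency_profile <- function(screened, index) {
  counts <- tabulate(screened$matches$vector_pos, nbins = index$length)
  data.frame(position = seq_len(index$length), count = as.integer(counts))
}

#' Merge screened read sets of several experiments
#'
#' Pools the retained pairs and match tables of one sample's experiments,
#' as the pipeline assembles the vector-matching reads of all experiments
#' together.
#'
#' @param screened_list list of `screened_pairs` objects.
#' @return one combined `screened_pairs` object.
#' @export
merge_screened <- function(screened_list) {
  stopifnot(length(screened_list) >= 1)
  pairs <- do.call(rbind, c(lapply(screened_list, `[[`, "pairs"),
                            list(make.row.names = FALSE)))
  matches <- do.call(rbind, c(lapply(screened_list, `[[`, "matches"),
                              list(make.row.names = FALSE)))
  structure(list(
    pairs = pairs, matches = matches,
    counts = screen_counts(matches)),
    class = "screened_pairs")
}
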