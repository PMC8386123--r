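# Coverage comparison: map all trimmed reads of both genotypes against the
# contigs with a seed-and-extend mapper, build per-base depth profiles per
# sample (and experiment), and classify each contig's presence pattern.

#' Map reads against contigs
#'
#' Seed-and-extend: exact `seed_length`-mer hits define candidate
#' (contig, offset, strand) placements which are scored by ungapped
#' comparison over the overlapping bases; placements above the mismatch
#' cap are dropped, and each read keeps its best placement(s) by number of
#' matching bases. Reads with several equally good placements are counted
#' at all of them with weight 1/n, so total depth is conserved.
#'
#' @param reads data.frame with `uid`, `seq`, `sample`, `experiment`.
#' @param contigs a `contig_set` (or named character vector of contig
#'   sequences).
#' @param seed_length exact seed length in bp.
#' @param max_mismatch_frac maximum mismatch fraction over the overlap.
#' @param min_overlap minimum read-contig overlap in bp.
#' @return a list of class `read_placements`: `placements` data.frame
#'   (`uid`, `sample`, `experiment`, `contig`, `start`, `end`, `strand`,
#'   `mismatches`, `weight`), `n_ambiguous` (reads placed at more than one
#'   best position).
#' @export
map_reads <- function(reads, contigs, seed_length = 20,
                      max_mismatch_frac = 0.05, min_overlap = 20) {
  cseqs <- if (inherits(contigs, "contig_set"))
    vapply(contigs$contigs, `[[`, character(1), "consensus")
  else contigs
  stopifnot(length(cseqs) > 0)
  empty <- data.frame(uid = character(0), sample = character(0),
                      experiment = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0),
                      weight = numeric(0), stringsAsFactors = FALSE)
  if (nrow(reads) == 0)
    return(structure(list(placements = empty, n_ambiguous = 0L,
                          contig_names = names(cseqs)),
                     class = "read_placements"))
  hits <- kmer_hits_cpp(unname(cseqs), reads$seq, as.integer(seed_length),
                        character(0), 0L, 33L)
  if (nrow(hits) == 0)
    return(structure(list(placements = empty, n_ambiguous = 0L,
                          contig_names = names(cseqs)),
                     class = "read_placements"))
  len <- nchar(reads$seq)[hits$read]
  # contig coordinate of the (oriented) read's first base
  off <- ifelse(hits$fwd,
                hits$ref_pos - hits$read_pos + 1L,
                hits$ref_pos - (len - (hits$read_pos +
                                         as.integer(seed_length) - 1L)))
  # dedupe candidate placements without the cost of unique.data.frame
  key <- (as.numeric(hits$read) * (length(cseqs) + 1) +
            hits$ref) * 2e5 + (off + 1e5) + ifelse(hits$fwd, 0, 0.5)
  first <- !duplicated(key)
  cand <- data.frame(read = hits$read[first], contig = hits$ref[first],
                     off = off[first], fwd = hits$fwd[first])
  clen <- nchar(cseqs)[cand$contig]
  rlen <- nchar(reads$seq)[cand$read]
  a <- pmax(cand$off, 1L)
  b <- pmin(cand$off + rlen - 1L, clen)
  overlap <- b - a + 1L
  ok <- overlap >= max(min_overlap, seed_length)
  cand <- cand[ok, , drop = FALSE]
  a <- a[ok]; b <- b[ok]; overlap <- overlap[ok]; rlen <- rlen[ok]
  if (nrow(cand) == 0)
    return(structure(list(placements = empty, n_ambiguous = 0L,
                          contig_names = names(cseqs)),
                     class = "read_placements"))
  oriented <- reads$seq[cand$read]
  flip <- !cand$fwd
  oriented[flip] <- revcomp(oriented[flip])
  rseg <- substring(oriented, a - cand$off + 1L, b - cand$off + 1L)
  cseg <- substring(cseqs[cand$contig], a, b)
  mism <- mismatch_pairs_cpp(rseg, cseg)
  score <- overlap - mism
  pass <- mism <= max_mismatch_frac * overlap
  cand <- cand[pass, , drop = FALSE]
  if (nrow(cand) == 0)
    return(structure(list(placements = empty, n_ambiguous = 0L,
                          contig_names = names(cseqs)),
                     class = "read_placements"))
  a <- a[pass]; b <- b[pass]; mism <- mism[pass]; score <- score[pass]
  best <- stats::ave(score, cand$read, FUN = max)
  top <- score == best
  cand <- cand[top, , drop = FALSE]
  a <- a[top]; b <- b[top]; mism <- mism[top]
  nbest <- stats::ave(rep(1L, nrow(cand)), cand$read, FUN = sum)
  placements <- data.frame(
    uid = reads$uid[cand$read],
    sample = reads$sample[cand$read],
    experiment = reads$experiment[cand$read],
    contig = names(cseqs)[cand$contig],
    start = a, end = b,
    strand = ifelse(cand$fwd, "+", "-"),
    mismatches = mism,
    weight = 1 / nbest,
    stringsAsFactors = FALSE)
  placements <- placements[order(placements$contig, placements$start,
                                 placements$uid), , drop = FALSE]
  rownames(placements) <- NULL
  structure(list(placements = placements,
                 n_ambiguous = length(unique(cand$read[nbest > 1L])),
                 contig_names = names(cseqs)),
            class = "read_placements")
}

#' Per-base depth profiles per contig and sample
#'
#' @param placements a `read_placements` object.
#' @param contigs the `contig_set` (or named character vector) mapped
#'   against.
#' @param samples sample names to profile (defaults to those observed).
#' @return a list of class `coverage_set`: per contig a list with `depth`
#'   (matrix positions x samples) and `by_experiment` (named list of such
#'   matrices).
#' @export
depth_profiles <- function(placements, contigs, samples = NULL) {
  cseqs <- if (inherits(contigs, "contig_set"))
    vapply(contigs$contigs, `[[`, character(1), "consensus")
  else contigs
  pl <- placements$placements
  samples <- samples %||% sort(unique(pl$sample))
  experiments <- sort(unique(pl$experiment))
  cover <- function(rows, width) {
    d <- numeric(width + 1L)
    if (nrow(rows) > 0) {
      add <- tapply(rows$weight, rows$start, sum)
      d[as.integer(names(add))] <- d[as.integer(names(add))] + add
      sub <- tapply(rows$weight, rows$end + 1L, sum)
      d[as.integer(names(sub))] <- d[as.integer(names(sub))] - sub
    }
    cumsum(d)[seq_len(width)]
  }
  out <- list()
  for (ci in names(cseqs)) {
    width <- nchar(cseqs[[ci]])
    rows <- pl[pl$contig == ci, , drop = FALSE]
    depth <- vapply(samples, function(s)
      cover(rows[rows$sample == s, , drop = FALSE], width),
      numeric(width))
    depth <- matrix(depth, nrow = width,
                    dimnames = list(NULL, samples))
    by_exp <- lapply(setNames(experiments, experiments), function(e) {
      er <- rows[rows$experiment == e, , drop = FALSE]
      m <- vapply(samples, function(s)
        cover(er[er$sample == s, , drop = FALSE], width), numeric(width))
      matrix(m, nrow = width, dimnames = list(NULL, samples))
    })
    out[[ci]] <- list(depth = depth, by_experiment = by_exp)
  }
  structure(out, class = "coverage_set")
}

#' Classify a contig's presence pattern across genotypes
#'
#' A region is "present" in a sample when at least `min_covered_frac` of
#' its bases reach a normalized depth of `min_abs_depth`; normalization
#' rescales each sample's raw depth by the ratio of the across-sample mean
#' genome depth to that sample's genome depth, so genotypes sequenced at
#' different depths are comparable. A contig is `TARGET_ONLY_SEGMENT` when
#' at least one vector-identity segment is present in the transgenic
#' sample and absent in the wild type; otherwise `SHARED_TYPE1` when the
#' whole contig is present in both genotypes, else `SHARED_TYPE2`.
#'
#' @param coverage one element of a `coverage_set` (list with `depth`).
#' @param segments the contig's vector-identity segment data.frame.
#' @param sample_depths named numeric: mean genome depth per sample.
#' @param transgenic,wildtype sample names of the two genotypes.
#' @param min_abs_depth,min_covered_frac presence thresholds.
#' @return a list of class `presence_pattern`: `category`, `calls`
#'   (data.frame per region: presence in each genotype).
#' @export
classify_presence <- function(coverage, segments, sample_depths,
                              transgenic = "transgenic",
                              wildtype = "wildtype",
                              min_abs_depth = 3, min_covered_frac = 0.8) {
  depth <- coverage$depth
  stopifnot(all(c(transgenic, wildtype) %in% colnames(depth)))
  factor <- mean(sample_depths[c(transgenic, wildtype)]) /
    sample_depths[c(transgenic, wildtype)]
  norm <- sweep(depth[, c(transgenic, wildtype), drop = FALSE], 2,
                factor, `*`)
  present <- function(from, to, sample)
    mean(norm[from:to, sample] >= min_abs_depth) >= min_covered_frac
  width <- nrow(depth)
  regions <- data.frame(region = "whole", from = 1L, to = width,
                        stringsAsFactors = FALSE)
  if (nrow(segments) > 0)
    regions <- rbind(regions, data.frame(
      region = paste0("segment_", seq_len(nrow(segments))),
      from = segments$contig_start, to = segments$contig_end,
      stringsAsFactors = FALSE))
  calls <- data.frame(
    region = regions$region, from = regions$from, to = regions$to,
    present_transgenic = vapply(seq_len(nrow(regions)), function(i)
      present(regions$from[i], regions$to[i], transgenic), logical(1)),
    present_wildtype = vapply(seq_len(nrow(regions)), function(i)
      present(regions$from[i], regions$to[i], wildtype), logical(1)),
    stringsAsFactors = FALSE)
  seg_calls <- calls[calls$region != "whole", , drop = FALSE]
  # a vector-identity segment missing from the wild type means the contig
  # is not "equally present in both genotypes": the contig exists because
  # the transgenic read pool produced it, so wild-type absence decides
  category <- if (nrow(seg_calls) > 0 &&
                  any(!seg_calls$present_wildtype)) {
    "TARGET_ONLY_SEGMENT"
  } else if (calls$present_transgenic[1] && calls$present_wildtype[1]) {
    "SHARED_TYPE1"
  } else {
    "SHARED_TYPE2"
  }
  structure(list(category = category, calls = calls),
            class = "presence_pattern")
}
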