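# Keep-all-reads overlap-layout-consensus assembly of screened reads.
# Reads are clustered by shared vector k-mer starting positions, laid out
# by their vector-coordinate anchors, extended into contigs when they
# overlap by at least `min_overlap`, and a column-majority consensus is
# called. Reads whose anchored alignment disagrees with the consensus
# beyond the mismatch cap (chimeric artifacts, decoy-locus reads caught in
# a larger cluster) are re-assembled among themselves, and reads that
# cannot be placed anywhere end as singleton contigs -- no read is ever
# discarded.

# matching-read table: one row per (pair, mate) with >=1 match
screened_read_table <- function(screened) {
  m <- screened$matches
  key <- paste0(m$pair_id, "/", m$mate)
  uids <- sort(unique(key))
  p <- screened$pairs
  idx <- match(sub("/[12]$", "", uids), p$pair_id)
  mate <- as.integer(sub("^.*/", "", uids))
  data.frame(uid = uids,
             pair_id = sub("/[12]$", "", uids),
             mate = mate,
             seq = ifelse(mate == 1L, p$seq1[idx], p$seq2[idx]),
             qual = ifelse(mate == 1L, p$qual1[idx], p$qual2[idx]),
             experiment = if ("experiment" %in% names(p))
               p$experiment[idx] else "e1",
             stringsAsFactors = FALSE)
}

#' Cluster screened reads by shared vector k-mers
#'
#' Union-find over the matching reads: two reads fall into the same
#' cluster when they share at least one matched vector k-mer starting
#' position, taken to transitive closure.
#'
#' @param screened a `screened_pairs` object.
#' @return a list of class `read_clusters`: `reads` (matching-read table),
#'   `matches` (per-read match table with `uid`), `clusters` (list of uid
#'   character vectors, deterministic order).
#' @export
cluster_reads <- function(screened) {
  reads <- screened_read_table(screened)
  m <- screened$matches
  m$uid <- paste0(m$pair_id, "/", m$mate)
  n <- nrow(reads)
  if (n == 0)
    return(structure(list(reads = reads, matches = m, clusters = list()),
                     class = "read_clusters"))
  ri <- match(m$uid, reads$uid)
  # link every read of a position group to the group's first read
  first <- stats::ave(ri, m$vector_pos, FUN = function(x) x[1])
  comp <- uf_components(n, first, ri)
  clusters <- split(reads$uid, comp)
  names(clusters) <- NULL
  structure(list(reads = reads, matches = m, clusters = clusters),
            class = "read_clusters")
}

# orient reads to the vector forward strand and compute anchor offsets;
# returns per-read: oriented seq, original-orientation flag, anchor
# positions (vector coordinate of read start)
orient_and_anchor <- function(reads, matches, k, vector_length, circular) {
  ms <- split(matches, matches$uid)[reads$uid]
  strand <- vapply(ms, function(d)
    if (sum(d$strand == "-") > sum(d$strand == "+")) "-" else "+",
    character(1))
  seq <- reads$seq
  flip <- strand == "-"
  seq[flip] <- revcomp(seq[flip])
  len <- nchar(seq)
  anchors <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    d <- ms[[i]]
    use <- d[d$strand == strand[i], , drop = FALSE]
    off <- if (strand[i] == "+") use$read_offset
           else len[i] - (use$read_offset + k - 1L) + 1L
    anchors[[i]] <- use$vector_pos - off + 1L
  }
  # circular unwrap: if the anchored positions wrap around the origin,
  # shift those before the largest circular gap by L
  allpos <- sort(unique(unlist(lapply(seq_along(anchors), function(i)
    anchors[[i]] + 0L))))
  if (circular && length(allpos) > 1) {
    gaps <- diff(allpos)
    wrap_gap <- allpos[1] + vector_length - allpos[length(allpos)]
    if (max(gaps) > wrap_gap) {
      cut <- allpos[which.max(gaps)]
      anchors <- lapply(anchors, function(a)
        ifelse(a <= cut, a + vector_length, a))
    }
  }
  offset <- vapply(anchors, function(a) {
    tab <- sort(table(a), decreasing = TRUE)
    as.integer(names(tab)[1])
  }, integer(1))
  data.frame(uid = reads$uid, seq = seq, len = len, strand = strand,
             offset = offset, stringsAsFactors = FALSE)
}

# column-majority consensus with ties broken toward the earliest-placed
# read (smallest offset, then uid)
consensus_call <- function(layout) {
  base0 <- min(layout$offset)
  width <- max(layout$offset + layout$len - 1L) - base0 + 1L
  ord <- order(layout$offset, layout$uid)
  layout <- layout[ord, , drop = FALSE]
  chars <- strsplit(layout$seq, "", fixed = TRUE)
  pos <- unlist(lapply(seq_len(nrow(layout)), function(i)
    seq(layout$offset[i] - base0 + 1L, length.out = layout$len[i])))
  code <- match(unlist(chars), DNA_BASES)
  keep <- !is.na(code)
  pos <- pos[keep]; code <- code[keep]
  votes <- matrix(tabulate((pos - 1L) * 4L + code, nbins = 4L * width),
                  nrow = 4L)
  cons <- max.col(t(votes), ties.method = "first")
  top <- apply(votes, 2, max)
  tied_cols <- which(colSums(votes == rep(top, each = 4L)) > 1L & top > 0L)
  for (cc in tied_cols) {
    cand <- which(votes[, cc] == top[cc])
    for (i in seq_len(nrow(layout))) {
      p <- cc + base0 - 1L
      if (layout$offset[i] <= p &&
          layout$offset[i] + layout$len[i] - 1L >= p) {
        b <- match(substring(layout$seq[i], p - layout$offset[i] + 1L,
                             p - layout$offset[i] + 1L), DNA_BASES)
        if (!is.na(b) && b %in% cand) { cons[cc] <- b; break }
      }
    }
  }
  covered <- top > 0L
  list(sequence = paste(DNA_BASES[cons[covered]], collapse = ""),
       base0 = base0, covered = covered)
}

#' Assemble one read cluster into contigs
#'
#' Greedy anchored layout: each read is placed at the vector coordinate of
#' its matched k-mers, reads overlapping by at least `min_overlap` extend
#' a contig, a column-majority consensus is called, and reads whose
#' alignment to the consensus exceeds `max_mismatch_frac` are taken out
#' and re-assembled among themselves. Every read of the cluster is placed
#' in some emitted contig; reads that cannot be joined become singleton
#' contigs.
#'
#' @param reads matching-read table rows for this cluster.
#' @param matches per-read match rows (with `uid`).
#' @param k k-mer length the matches were computed with.
#' @param vector_length,circular properties of the vector index.
#' @param min_overlap minimum suffix-prefix overlap in bp.
#' @param max_mismatch_frac per-read mismatch cap against the consensus.
#' @return list of contig objects (`consensus`, `placements`, `n_reads`,
#'   `experiments`).
#' @export
assemble_cluster <- function(reads, matches, k, vector_length,
                             circular = TRUE, min_overlap = 30,
                             max_mismatch_frac = 0.02) {
  stopifnot(nrow(reads) > 0)
  oriented <- orient_and_anchor(reads, matches, k, vector_length, circular)
  oriented$experiment <- reads$experiment[match(oriented$uid, reads$uid)]
  out <- list()
  queue <- list(oriented)
  while (length(queue) > 0) {
    lay <- queue[[1]]; queue <- queue[-1]
    # split the layout into pieces connected by >= min_overlap overlaps
    lay <- lay[order(lay$offset, lay$uid), , drop = FALSE]
    piece_id <- integer(nrow(lay))
    cur <- 0L; cur_end <- -Inf
    for (i in seq_len(nrow(lay))) {
      if (lay$offset[i] > cur_end - min_overlap + 1L) cur <- cur + 1L
      piece_id[i] <- cur
      cur_end <- max(cur_end, lay$offset[i] + lay$len[i] - 1L)
    }
    for (piece in split(lay, piece_id)) {
      cons <- consensus_call(piece)
      rel <- piece$offset - cons$base0 + 1L
      mism <- mismatch_pairs_cpp(
        piece$seq, substring(cons$sequence, rel, rel + piece$len - 1L))
      bad <- mism > max_mismatch_frac * piece$len
      if (any(bad) && !all(bad)) {
        keep <- piece[!bad, , drop = FALSE]
        cons <- consensus_call(keep)
        rel <- keep$offset - cons$base0 + 1L
        mism <- mismatch_pairs_cpp(
          keep$seq, substring(cons$sequence, rel, rel + keep$len - 1L))
        out[[length(out) + 1L]] <- list(
          consensus = cons$sequence,
          placements = data.frame(uid = keep$uid, offset = rel,
                                  strand = keep$strand, mismatches = mism,
                                  stringsAsFactors = FALSE),
          n_reads = nrow(keep),
          experiments = sort(unique(keep$experiment)))
        queue[[length(queue) + 1L]] <- piece[bad, , drop = FALSE]
      } else if (all(bad) && nrow(piece) > 1L) {
        # irreconcilable set: emit the earliest read alone, retry the rest
        out[[length(out) + 1L]] <- list(
          consensus = piece$seq[1],
          placements = data.frame(uid = piece$uid[1], offset = 1L,
                                  strand = piece$strand[1],
                                  mismatches = 0L,
                                  stringsAsFactors = FALSE),
          n_reads = 1L, experiments = piece$experiment[1])
        queue[[length(queue) + 1L]] <- piece[-1, , drop = FALSE]
      } else {
        out[[length(out) + 1L]] <- list(
          consensus = cons$sequence,
          placements = data.frame(uid = piece$uid, offset = rel,
                                  strand = piece$strand, mismatches = mism,
                                  stringsAsFactors = FALSE),
          n_reads = nrow(piece),
          experiments = sort(unique(piece$experiment)))
      }
    }
  }
  out
}

#' Assemble all screened reads of a sample
#'
#' Clusters the matching reads, assembles every cluster, annotates exact
#' vector-identity segments, orders contigs by descending total
#' vector-identity length and names them `contig_0`, `contig_1`, ...
#' following the convention that contig 0 carries the longest vector
#' segment.
#'
#' @param screened a `screened_pairs` object (one sample, experiments
#'   merged).
#' @param index the `kmer_index` used for screening.
#' @param min_overlap,max_mismatch_frac see [assemble_cluster()].
#' @param vec the `vector_record` (for segment annotation); defaults to
#'   the index sequence.
#' @return a list of class `contig_set`: `contigs` (named list; each with
#'   `id`, `consensus`, `length`, `placements`, `n_reads`, `experiments`,
#'   `segments`, `contexts`), `reads` (matching-read table).
#' @export
assemble_contigs <- function(screened, index, min_overlap = 30,
                             max_mismatch_frac = 0.02, vec = NULL) {
  cl <- cluster_reads(screened)
  vseq <- if (!is.null(vec)) vec else
    substring(index$sequence, 1, index$length)
  raw <- list()
  for (uids in cl$clusters) {
    reads <- cl$reads[cl$reads$uid %in% uids, , drop = FALSE]
    m <- cl$matches[cl$matches$uid %in% uids, , drop = FALSE]
    raw <- c(raw, assemble_cluster(reads, m, index$k, index$length,
                                   index$circular, min_overlap,
                                   max_mismatch_frac))
  }
  for (i in seq_along(raw)) {
    raw[[i]]$length <- nchar(raw[[i]]$consensus)
    raw[[i]]$segments <- annotate_vector_segments(raw[[i]]$consensus, vseq,
                                                  k = index$k,
                                                  circular = index$circular)
    raw[[i]]$contexts <- data.frame(side = character(0),
                                    sequence = character(0),
                                    source = character(0),
                                    stringsAsFactors = FALSE)
  }
  vid <- vapply(raw, function(ct)
    if (nrow(ct$segments) == 0) 0L else
      sum(ct$segments$contig_end - ct$segments$contig_start + 1L),
    integer(1))
  first_uid <- vapply(raw, function(ct) min(ct$placements$uid), character(1))
  ord <- order(-vid, first_uid)
  raw <- raw[ord]
  for (i in seq_along(raw)) raw[[i]]$id <- paste0("contig_", i - 1L)
  names(raw) <- vapply(raw, `[[`, character(1), "id")
  structure(list(contigs = raw, reads = cl$reads), class = "contig_set")
}

#' Annotate exact vector-identity segments of a contig
#'
#' Maximal exact matches of at least `min_len` bp between the contig
#' (either strand) and the (circular) vector, with contig and vector
#' coordinates, pruned to a non-overlapping set on the contig (longest
#' first).
#'
#' @param contig contig consensus sequence (character string) or contig
#'   object.
#' @param vec vector sequence or `vector_record`.
#' @param k seed length (also the minimum reportable match, 20 bp by the
#'   screen's definition).
#' @param min_len minimum segment length.
#' @param circular treat the vector as circular.
#' @return data.frame `contig_start`, `contig_end`, `vector_start`,
#'   `vector_end`, `strand`, `length` (1-based inclusive).
#' @export
annotate_vector_segments <- function(contig, vec, k = 20, min_len = 20,
                                     circular = TRUE) {
  cseq <- if (is.list(contig)) contig$consensus else contig
  vseq <- if (inherits(vec, "vector_record")) vec$sequence else vec
  L <- nchar(vseq)
  # doubling the circular sequence keeps matches across the origin on a
  # single diagonal; duplicated interior matches collapse in the
  # non-overlap pruning below
  ext <- if (circular) paste0(vseq, vseq) else vseq
  empty <- data.frame(contig_start = integer(0), contig_end = integer(0),
                      vector_start = integer(0), vector_end = integer(0),
                      strand = character(0), length = integer(0),
                      stringsAsFactors = FALSE)
  if (nchar(cseq) < k) return(empty)
  hits <- kmer_hits_cpp(ext, cseq, as.integer(k), character(0), 0L, 33L)
  if (nrow(hits) == 0) return(empty)
  segs <- list()
  plus <- hits[hits$fwd, , drop = FALSE]
  if (nrow(plus) > 0) {
    d <- plus$ref_pos - plus$read_pos
    for (dd in unique(d)) {
      p <- sort(unique(plus$read_pos[d == dd]))
      run <- cumsum(c(1L, diff(p) != 1L))
      for (r in split(p, run)) {
        cs <- r[1]; ce <- r[length(r)] + k - 1L
        segs[[length(segs) + 1L]] <- data.frame(
          contig_start = cs, contig_end = ce,
          vector_start = cs + dd, vector_end = ce + dd,
          strand = "+", stringsAsFactors = FALSE)
      }
    }
  }
  minus <- hits[!hits$fwd, , drop = FALSE]
  if (nrow(minus) > 0) {
    a <- minus$ref_pos + minus$read_pos  # anti-diagonal
    for (aa in unique(a)) {
      p <- sort(unique(minus$read_pos[a == aa]))
      run <- cumsum(c(1L, diff(p) != 1L))
      for (r in split(p, run)) {
        cs <- r[1]; ce <- r[length(r)] + k - 1L
        vs <- aa - (r[length(r)])       # vector start (extended coords)
        ve <- aa - r[1] + k - 1L
        segs[[length(segs) + 1L]] <- data.frame(
          contig_start = cs, contig_end = ce,
          vector_start = vs, vector_end = ve,
          strand = "-", stringsAsFactors = FALSE)
      }
    }
  }
  segs <- do.call(rbind, segs)
  segs$length <- segs$contig_end - segs$contig_start + 1L
  segs <- segs[segs$length >= min_len, , drop = FALSE]
  if (nrow(segs) == 0) return(empty)
  # map extended vector coordinates back onto the circle
  segs$vector_start <- (segs$vector_start - 1L) %% L + 1L
  segs$vector_end <- (segs$vector_end - 1L) %% L + 1L
  # non-overlapping on the contig, longest first
  segs <- segs[order(-segs$length, segs$contig_start, segs$strand), ,
               drop = FALSE]
  keep <- rep(FALSE, nrow(segs))
  occupied <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(segs))) {
    iv <- c(segs$contig_start[i], segs$contig_end[i])
    if (nrow(occupied) == 0 ||
        all(iv[1] > occupied[, 2] | iv[2] < occupied[, 1])) {
      keep[i] <- TRUE
      occupied <- rbind(occupied, iv)
    }
  }
  segs <- segs[keep, , drop = FALSE]
  segs <- segs[order(segs$contig_start), , drop = FALSE]
  rownames(segs) <- NULL
  segs[, c("contig_start", "contig_end", "vector_start", "vector_end",
           "strand", "length")]
}

#' Attach mate-derived context sequences to contig ends
#'
#' For every placed read whose mate did not place inside the same contig
#' and whose placement lies within one fragment length of a contig end,
#' the mate's sequence is attached as context on the side the fragment
#' extends to (right of forward-placed reads, left of reverse-placed
#' ones), oriented to the contig's forward strand.
#'
#' @param contig a contig object.
#' @param screened the `screened_pairs` object (for mate sequences).
#' @param fragment_len expected fragment length in bp.
#' @return the contig with its `contexts` data.frame filled.
#' @export
attach_context <- function(contig, screened, fragment_len = 500) {
  pl <- contig$placements
  if (nrow(pl) == 0) return(contig)
  p <- screened$pairs
  pair_id <- sub("/[12]$", "", pl$uid)
  mate <- as.integer(sub("^.*/", "", pl$uid))
  other <- paste0(pair_id, "/", 3L - mate)
  idx <- match(pair_id, p$pair_id)
  mate_seq <- ifelse(mate == 1L, p$seq2[idx], p$seq1[idx])
  clen <- contig$length
  read_len <- nchar(mate_seq)
  usable <- !(other %in% pl$uid) & !is.na(mate_seq) & nzchar(mate_seq)
  plus <- usable & pl$strand == "+" &
    (clen - pl$offset + 1L) <= fragment_len
  minus <- usable & pl$strand == "-" &
    (pl$offset + read_len - 1L) <= fragment_len
  contig$contexts <- data.frame(
    side = c(rep("right", sum(plus)), rep("left", sum(minus))),
    sequence = c(revcomp(mate_seq[plus]), mate_seq[minus]),
    source = c(other[plus], other[minus]),
    stringsAsFactors = FALSE)
  contig
}
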