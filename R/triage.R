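# Five-step contig triage. Each contig receives exactly one category, at
# the earliest applicable step: the known T-DNA insertion (1), sequence
# equally present in both genotypes (2), vector-identity present in the
# host reference (3), underrepresented contigs (4), and an origin
# assessment of the remainder by local homology search against host,
# vector and contaminant panels (5). Step 6 of the laboratory procedure
# (PCR confirmation) is outside the package: chimeric survivors are
# flagged CANDIDATE_INSERTION.

#' Seed-and-extend ungapped local homology search
#'
#' A self-contained stand-in for a remote nucleotide BLAST: exact
#' `seed_len`-mer hits between query and subject are grouped by diagonal
#' and extended ungapped under +1/-2 match/mismatch scoring; the
#' best-scoring segment of each diagonal stretch is reported when it
#' reaches `min_hit_len` and `min_identity`. Both strands are searched.
#' Deterministic: hits are ordered by descending score, then subject and
#' coordinates.
#'
#' @param query named character vector of query sequences (a single
#'   unnamed string is allowed).
#' @param subject_db named character vector of subject sequences.
#' @param seed_len exact seed length.
#' @param min_identity minimum percent identity of a reported hit.
#' @param min_hit_len minimum alignment length of a reported hit.
#' @param subject_index optional prebuilt [build_search_index()] of
#'   `subject_db`; avoids re-indexing a large subject on repeated calls.
#' @return data.frame of hits: `query`, `subject`, `query_start`,
#'   `query_end`, `subject_start`, `subject_end`, `strand`, `matches`,
#'   `alignment_length`, `identity`, `score`.
#' @export
local_search <- function(query, subject_db, seed_len = 12,
                         min_identity = 80, min_hit_len = 20,
                         subject_index = NULL) {
  if (!is.null(subject_index)) {
    stopifnot(inherits(subject_index, "search_index"))
    subject_db <- subject_index$db
    seed_len <- subject_index$k
  }
  stopifnot(length(subject_db) > 0)
  if (is.null(names(query)))
    names(query) <- paste0("query_", seq_along(query))
  empty <- data.frame(query = character(0), subject = character(0),
                      query_start = integer(0), query_end = integer(0),
                      subject_start = integer(0), subject_end = integer(0),
                      strand = character(0), matches = integer(0),
                      alignment_length = integer(0), identity = numeric(0),
                      score = integer(0), stringsAsFactors = FALSE)
  keep <- nchar(query) >= seed_len
  if (!any(keep)) return(empty)
  q <- query[keep]
  hits <- if (!is.null(subject_index))
    kmer_hits_prebuilt_cpp(subject_index$ptr, unname(q), character(0),
                           0L, 33L)
  else
    kmer_hits_cpp(unname(subject_db), unname(q), as.integer(seed_len),
                  character(0), 0L, 33L)
  if (nrow(hits) == 0) return(empty)
  out <- list()
  qlen <- nchar(q)
  slen <- nchar(subject_db)
  # all maximal positive-scoring segments along one gapless alignment
  scan_diagonal <- function(qs, ss) {
    m <- strsplit(qs, "", fixed = TRUE)[[1]] ==
      strsplit(ss, "", fixed = TRUE)[[1]]
    sc <- ifelse(m, 1L, -2L)
    n <- length(sc)
    res <- list()
    i <- 1L
    while (i <= n) {
      cur <- 0L; best <- 0L; start <- i; bi <- i; bj <- i - 1L
      j <- i
      while (j <= n) {
        cur <- cur + sc[j]
        if (cur > best) { best <- cur; bi <- start; bj <- j }
        if (cur <= 0L) { cur <- 0L; start <- j + 1L }
        if (cur == 0L && best > 0L && j - bj > 3L * seed_len) break
        j <- j + 1L
      }
      if (best > 0L) {
        matches <- sum(m[bi:bj]); alen <- bj - bi + 1L
        res[[length(res) + 1L]] <- c(bi, bj, matches, alen, best)
        i <- max(bj + 1L, i + 1L)   # rescan past the reported segment
      } else {
        i <- j + 1L
      }
    }
    res
  }
  # group seed hits into diagonal stretches per (query, subject, strand)
  hits$diag <- ifelse(hits$fwd, hits$ref_pos - hits$read_pos,
                      hits$ref_pos + hits$read_pos)
  groups <- unique(hits[c("read", "ref", "fwd", "diag")])
  for (g in seq_len(nrow(groups))) {
    qi <- groups$read[g]; si <- groups$ref[g]
    fwd <- groups$fwd[g]; dg <- groups$diag[g]
    ql <- qlen[qi]; sl <- slen[si]
    if (fwd) {
      # subject_pos = query_pos + dg
      q0 <- max(1L, 1L - dg); q1 <- min(ql, sl - dg)
      if (q1 - q0 + 1L < seed_len) next
      qs <- substring(q[[qi]], q0, q1)
      ss <- substring(subject_db[[si]], q0 + dg, q1 + dg)
      for (seg in scan_diagonal(qs, ss)) {
        bi <- seg[1]; bj <- seg[2]
        alen <- seg[4]; matches <- seg[3]
        ident <- 100 * matches / alen
        if (alen < min_hit_len || ident < min_identity) next
        out[[length(out) + 1L]] <- data.frame(
          query = names(q)[qi], subject = names(subject_db)[si],
          query_start = q0 + bi - 1L, query_end = q0 + bj - 1L,
          subject_start = q0 + dg + bi - 1L,
          subject_end = q0 + dg + bj - 1L,
          strand = "+", matches = matches, alignment_length = alen,
          identity = ident, score = seg[5], stringsAsFactors = FALSE)
      }
    } else {
      # reverse strand: work on the reverse-complemented query; a window
      # at query_pos maps to rq position ql - query_pos - seed_len + 2,
      # so subject_pos = rq_pos + d' with d' = dg - ql + seed_len - 2
      rq <- revcomp(q[[qi]])
      dprime <- dg - ql + as.integer(seed_len) - 2L
      q0 <- max(1L, 1L - dprime); q1 <- min(ql, sl - dprime)
      if (q1 - q0 + 1L < seed_len) next
      qs <- substring(rq, q0, q1)
      ss <- substring(subject_db[[si]], q0 + dprime, q1 + dprime)
      for (seg in scan_diagonal(qs, ss)) {
        bi <- seg[1]; bj <- seg[2]
        alen <- seg[4]; matches <- seg[3]
        ident <- 100 * matches / alen
        if (alen < min_hit_len || ident < min_identity) next
        rq_start <- q0 + bi - 1L; rq_end <- q0 + bj - 1L
        out[[length(out) + 1L]] <- data.frame(
          query = names(q)[qi], subject = names(subject_db)[si],
          query_start = ql - rq_end + 1L, query_end = ql - rq_start + 1L,
          subject_start = rq_start + dprime,
          subject_end = rq_end + dprime,
          strand = "-", matches = matches, alignment_length = alen,
          identity = ident, score = seg[5], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) return(empty)
  res <- unique(do.call(rbind, out))
  res <- res[order(-res$score, res$query, res$subject, res$query_start,
                   res$subject_start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Prebuild a homology-search index of a subject database
#'
#' @param subject_db named character vector of subject sequences.
#' @param seed_len seed k-mer length used by [local_search()].
#' @return a list of class `search_index` (external pointer plus the
#'   subject sequences); valid for the current session only.
#' @export
build_search_index <- function(subject_db, seed_len = 12) {
  stopifnot(length(subject_db) > 0)
  structure(list(ptr = kmer_index_build_cpp(unname(subject_db),
                                            as.integer(seed_len)),
                 k = as.integer(seed_len), db = subject_db),
            class = "search_index")
}

# orient a contig so that its principal (longest) vector segment is on the
# vector's forward strand
orient_to_principal <- function(contig) {
  segs <- contig$segments
  if (nrow(segs) == 0) return(contig)
  principal <- segs[order(-segs$length, segs$contig_start), ][1, ]
  if (principal$strand == "-") {
    n <- contig$length
    contig$consensus <- revcomp(contig$consensus)
    segs <- data.frame(
      contig_start = n - contig$segments$contig_end + 1L,
      contig_end = n - contig$segments$contig_start + 1L,
      vector_start = contig$segments$vector_start,
      vector_end = contig$segments$vector_end,
      strand = ifelse(contig$segments$strand == "+", "-", "+"),
      length = contig$segments$length, stringsAsFactors = FALSE)
    contig$segments <- segs[order(segs$contig_start), , drop = FALSE]
  }
  contig
}

principal_segment <- function(contig) {
  segs <- contig$segments
  if (nrow(segs) == 0) return(NULL)
  segs[order(-segs$length, segs$contig_start), ][1, ]
}

#' Step 1: does the contig represent the known T-DNA insertion?
#'
#' A contig is the known insertion when its principal vector-identity
#' segment lies inside the annotated T-DNA interval and both contig ends
#' beyond the segment map to the host reference at high identity, at loci
#' separated by at most `max_deletion` bases.
#'
#' @param contig a contig object (with `segments`).
#' @param host_ref named character vector of host reference chromosomes.
#' @param vec the `vector_record`.
#' @param flank_identity minimum percent identity of the host flanks.
#' @param max_deletion maximum host gap between the flank loci in bp.
#' @param min_flank minimum flank length available for mapping.
#' @param host_index optional prebuilt [build_search_index()] of
#'   `host_ref`.
#' @return list `decided` (logical) and, when decided, `call` (an
#'   `insertion_call`).
#' @export
step1_known_insertion <- function(contig, host_ref, vec,
                                  flank_identity = 98, max_deletion = 100,
                                  min_flank = 20, host_index = NULL) {
  if (nrow(contig$segments) == 0) return(list(decided = FALSE))
  call <- tryCatch(
    call_insertion(contig, host_ref, vec, flank_identity = flank_identity,
                   min_flank = min_flank, host_index = host_index),
    error = function(e) NULL)
  if (is.null(call)) return(list(decided = FALSE))
  td <- vec$tdna_interval
  in_tdna <- call$integrated_interval[1] >= td[1] &&
    call$integrated_interval[2] <= td[2]
  if (!in_tdna || call$deleted_bp > max_deletion)
    return(list(decided = FALSE))
  list(decided = TRUE, call = call)
}

#' Step 2: is the contig's vector identity present in both genotypes?
#'
#' @param contig a contig object.
#' @param pattern the contig's `presence_pattern`.
#' @return list `decided` and `type` (`SHARED_TYPE1`/`SHARED_TYPE2`).
#' @export
step2_shared <- function(contig, pattern) {
  if (pattern$category %in% c("SHARED_TYPE1", "SHARED_TYPE2"))
    list(decided = TRUE, type = pattern$category)
  else list(decided = FALSE)
}

#' Step 3: are the vector-identity segments present in the host reference?
#'
#' @param contig a contig object.
#' @param host_ref named character vector of reference chromosomes.
#' @param min_identity minimum percent identity over the full segment.
#' @param host_index optional prebuilt [build_search_index()] of
#'   `host_ref`.
#' @return list `decided` and `hits` (best hit per segment).
#' @export
step3_in_reference <- function(contig, host_ref, min_identity = 95,
                               host_index = NULL) {
  segs <- contig$segments
  if (nrow(segs) == 0) return(list(decided = FALSE))
  best <- list()
  for (i in seq_len(nrow(segs))) {
    qseq <- substring(contig$consensus, segs$contig_start[i],
                      segs$contig_end[i])
    hits <- local_search(setNames(qseq, "segment"), host_ref,
                         min_identity = min_identity,
                         min_hit_len = min(20, segs$length[i]),
                         subject_index = host_index)
    full <- hits[100 * hits$matches / segs$length[i] >= min_identity, ,
                 drop = FALSE]
    if (nrow(full) == 0) return(list(decided = FALSE))
    best[[i]] <- full[1, ]
  }
  list(decided = TRUE, hits = do.call(rbind, best))
}

#' Step 4: is the contig underrepresented in the sequencing data?
#'
#' The decision uses the supporting-read criterion (at most `max_reads`
#' reads); whether the contig was seen in a single experiment is computed
#' and reported as evidence, and can be promoted to a deciding criterion
#' with `rule = "either"`.
#'
#' @param contig a contig object.
#' @param max_reads read-count threshold.
#' @param rule `"reads"` (default) or `"either"`.
#' @return list `decided`, `n_reads`, `single_experiment`.
#' @export
step4_underrepresented <- function(contig, max_reads = 2,
                                   rule = c("reads", "either")) {
  rule <- match.arg(rule)
  single <- length(contig$experiments) == 1L
  few <- contig$n_reads <= max_reads
  decided <- if (rule == "reads") few else (few || single)
  list(decided = decided, n_reads = contig$n_reads,
       single_experiment = single)
}

#' Step 5: assess the origin of a remaining contig
#'
#' Local homology search of the contig and its context sequences against
#' host reference, vector and contaminant panel. The contig is
#' `CANDIDATE_INSERTION` when it is chimeric (disjoint regions hitting
#' vector and host), `CONTAMINANT` when the contaminant panel explains
#' strictly more of the sequence than the vector does and no host
#' identity exists, otherwise `VECTOR_ONLY` (vector identity without any
#' host identity: no evidence of an insertion).
#'
#' @param contig a contig object (with `contexts`).
#' @param host_ref,vec,contaminant_db subject databases.
#' @param host_identity,host_hit_len thresholds for a qualifying host hit.
#' @param host_index optional prebuilt [build_search_index()] of
#'   `host_ref`.
#' @return list `decided` (always TRUE), `category`, `evidence` (hit
#'   table).
#' @export
step5_origin <- function(contig, host_ref, vec, contaminant_db,
                         host_identity = 95, host_hit_len = 30,
                         host_index = NULL) {
  queries <- c(setNames(contig$consensus, "contig"))
  if (nrow(contig$contexts) > 0)
    queries <- c(queries,
                 setNames(contig$contexts$sequence,
                          paste0("context_", seq_len(nrow(contig$contexts)))))
  vseq <- if (inherits(vec, "vector_record")) vec$sequence else vec
  dbs <- list(host = host_ref,
              vector = c(vector = vseq),
              contaminant = contaminant_db)
  all_hits <- list()
  for (s in names(dbs)) {
    if (length(dbs[[s]]) == 0) next
    h <- local_search(queries, dbs[[s]], min_identity = 80,
                      min_hit_len = 20,
                      subject_index = if (s == "host") host_index)
    if (nrow(h) > 0) { h$db <- s; all_hits[[s]] <- h }
  }
  hits <- if (length(all_hits) > 0)
    do.call(rbind, c(all_hits, list(make.row.names = FALSE)))
  else data.frame()
  host_hits <- if (nrow(hits) > 0)
    hits[hits$db == "host" & hits$identity >= host_identity &
           hits$alignment_length >= host_hit_len, , drop = FALSE]
  else data.frame()
  contig_host <- if (nrow(host_hits) > 0)
    host_hits[host_hits$query == "contig", , drop = FALSE]
  else data.frame()
  # chimeric: a vector region and a disjoint qualifying host region on
  # the contig itself
  chimeric <- FALSE
  if (nrow(contig_host) > 0 && nrow(contig$segments) > 0) {
    for (i in seq_len(nrow(contig$segments))) {
      vs <- c(contig$segments$contig_start[i], contig$segments$contig_end[i])
      for (j in seq_len(nrow(contig_host))) {
        hs <- c(contig_host$query_start[j], contig_host$query_end[j])
        ovl <- min(vs[2], hs[2]) - max(vs[1], hs[1]) + 1L
        if (ovl <= 10L) { chimeric <- TRUE; break }
      }
      if (chimeric) break
    }
  }
  matched_bases <- function(db)
    if (nrow(hits) == 0) 0L else sum(hits$matches[hits$db == db])
  category <- if (chimeric) {
    "CANDIDATE_INSERTION"
  } else if (nrow(host_hits) == 0 &&
             matched_bases("contaminant") > matched_bases("vector")) {
    "CONTAMINANT"
  } else {
    "VECTOR_ONLY"
  }
  list(decided = TRUE, category = category, evidence = hits)
}

#' Apply the five-step triage to every contig
#'
#' Steps are applied in order; the first applicable step decides. Every
#' contig receives exactly one category.
#'
#' @param contigs a `contig_set` (contexts attached).
#' @param patterns named list of `presence_pattern`s per contig.
#' @param host_ref named character vector of reference chromosomes.
#' @param vec the `vector_record`.
#' @param contaminant_db named character vector of contaminant genomes
#'   (may be empty).
#' @param params optional list of threshold overrides (`flank_identity`,
#'   `max_deletion`, `ref_identity`, `max_reads`, `step4_rule`,
#'   `host_identity`, `host_hit_len`).
#' @return a list of class `triage_result`: `table` (data.frame `contig`,
#'   `category`, `step`, `supporting_reads`, `experiments`), `calls`
#'   (insertion calls for KNOWN_INSERTION contigs), `evidence` (per
#'   contig).
#' @export
triage_all <- function(contigs, patterns, host_ref, vec,
                       contaminant_db = character(0), params = list()) {
  p <- modifyList(list(flank_identity = 98, max_deletion = 100,
                       ref_identity = 95, max_reads = 2,
                       step4_rule = "reads", host_identity = 95,
                       host_hit_len = 30), params)
  host_index <- build_search_index(host_ref)
  rows <- list(); calls <- list(); evidence <- list()
  for (ci in names(contigs$contigs)) {
    ct <- contigs$contigs[[ci]]
    s1 <- step1_known_insertion(ct, host_ref, vec,
                                flank_identity = p$flank_identity,
                                max_deletion = p$max_deletion,
                                host_index = host_index)
    if (s1$decided) {
      category <- "KNOWN_INSERTION"; step <- 1L
      calls[[ci]] <- s1$call
      evidence[[ci]] <- list(call = s1$call)
    } else {
      s2 <- step2_shared(ct, patterns[[ci]])
      if (s2$decided) {
        category <- "SHARED_BOTH"; step <- 2L
        evidence[[ci]] <- list(pattern = patterns[[ci]]$category)
      } else {
        s3 <- step3_in_reference(ct, host_ref,
                                 min_identity = p$ref_identity,
                                 host_index = host_index)
        if (s3$decided) {
          category <- "IN_REFERENCE"; step <- 3L
          evidence[[ci]] <- list(hits = s3$hits)
        } else {
          s4 <- step4_underrepresented(ct, max_reads = p$max_reads,
                                       rule = p$step4_rule)
          if (s4$decided) {
            category <- "UNDERREPRESENTED"; step <- 4L
            evidence[[ci]] <- s4[c("n_reads", "single_experiment")]
          } else {
            s5 <- step5_origin(ct, host_ref, vec, contaminant_db,
                               host_identity = p$host_identity,
                               host_hit_len = p$host_hit_len,
                               host_index = host_index)
            category <- s5$category; step <- 5L
            evidence[[ci]] <- list(hits = s5$evidence)
          }
        }
      }
    }
    rows[[ci]] <- data.frame(
      contig = ci, category = category, step = step,
      supporting_reads = ct$n_reads,
      experiments = paste(ct$experiments, collapse = ","),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  structure(list(table = tab, calls = calls, evidence = evidence),
            class = "triage_result")
}
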