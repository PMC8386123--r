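# Triage: the local homology search against a DP oracle, each decision
# step on constructed cases, and the partition/order invariants of the
# whole five-step procedure.

# minimal contig object for step-level tests
mk_contig <- function(consensus, vec, n_reads = 10,
                      experiments = c("exp1", "exp2"),
                      contexts = NULL, k = 20) {
  vseq <- if (inherits(vec, "vector_record")) vec$sequence else vec
  ct <- list(consensus = consensus, length = nchar(consensus),
             placements = data.frame(
               uid = sprintf("p%03d/1", seq_len(n_reads)),
               offset = 1L, strand = "+", mismatches = 0L,
               stringsAsFactors = FALSE),
             n_reads = as.integer(n_reads), experiments = experiments,
             segments = annotate_vector_segments(consensus, vseq, k = k),
             contexts = contexts %||% data.frame(
               side = character(0), sequence = character(0),
               source = character(0), stringsAsFactors = FALSE))
  ct
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("local search finds exact and near-exact hits deterministically", {
  set.seed(61)
  subject <- c(chrA = random_dna(5000, 0.4))
  q284 <- substring(subject[[1]], 1001, 1284)
  h <- local_search(c(q = q284), subject)
  expect_equal(h$identity[1], 100)
  expect_equal(h$alignment_length[1], 284L)
  expect_equal(c(h$subject_start[1], h$subject_end[1]), c(1001L, 1284L))
  # reverse-complement query is found on the minus strand, same locus
  hrc <- local_search(c(q = revcomp(q284)), subject)
  expect_equal(hrc$strand[1], "-")
  expect_equal(c(hrc$subject_start[1], hrc$subject_end[1]), c(1001L, 1284L))
  expect_equal(hrc$identity[1], 100)
  # a random query yields no hit of >= 20 bp at >= 80% identity
  for (seed in 1:5) {
    set.seed(seed)
    expect_equal(nrow(local_search(c(q = random_dna(150, 0.5)), subject)),
                 0L)
  }
  expect_identical(local_search(c(q = q284), subject),
                   local_search(c(q = q284), subject))
  # prebuilt index gives identical results
  ix <- build_search_index(subject)
  expect_identical(local_search(c(q = q284), subject),
                   local_search(c(q = q284), subject_index = ix))
})

test_that("local search matches the ungapped DP oracle on toy strings", {
  set.seed(62)
  for (trial in 1:12) {
    subject <- random_dna(300, 0.5)
    core <- substring(subject, 101, 170)
    # mutate a few positions so identity stays near but below 100%
    n_mut <- sample(0:4, 1)
    if (n_mut > 0) {
      pos <- sample(70, n_mut)
      for (p in pos)
        substr(core, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                             substring(core, p, p)), 1)
    }
    query <- paste0(random_dna(25, 0.5), core, random_dna(25, 0.5))
    if (trial %% 2 == 0) query <- revcomp(query)
    got <- local_search(c(q = query), c(s = subject), min_identity = 50,
                        min_hit_len = 12)
    orc <- oracle_best_ungapped(query, subject)
    expect_equal(got$score[1], orc, label = sprintf("trial %d", trial))
  }
})

test_that("step 1 accepts only contigs with host flanks around T-DNA", {
  cfg <- simulation_config(seed = 63, host_length = 30000L,
                           insertion_pos = 15000L)
  vec <- build_vector(cfg)
  host <- generate_host(cfg)
  ref <- guard_junctions(host$reference, vec, 15000L)
  # well-formed insertion contig: host flanks around the integrated part
  ins <- paste0(substring(ref[[1]], 14880, 15000),
                substring(vec$sequence, 29, 5484),
                substring(ref[[1]], 15012, 15130))
  ct <- mk_contig(ins, vec)
  s1 <- step1_known_insertion(ct, ref, vec)
  expect_true(s1$decided)
  expect_equal(s1$call$deleted_bp, 11L)
  expect_equal(s1$call$right_junction, 15000L)
  expect_equal(s1$call$left_junction, 15012L)
  expect_equal(s1$call$integrated_interval, c(29L, 5484L))
  # vector-only contig: no host flanks to map
  vonly <- mk_contig(substring(vec$sequence, 100, 800), vec)
  expect_false(step1_known_insertion(vonly, ref, vec)$decided)
  # host-only contig: no vector-identity segment at all
  honly <- mk_contig(substring(ref[[1]], 5000, 5500), vec)
  expect_false(step1_known_insertion(honly, ref, vec)$decided)
  # backbone insert: flanks map but the interior is not T-DNA
  bb <- paste0(substring(ref[[1]], 14901, 15000),
               substring(vec$sequence, 7000, 7400),
               substring(ref[[1]], 15012, 15111))
  expect_false(step1_known_insertion(mk_contig(bb, vec), ref, vec)$decided)
})

test_that("step 2 excludes exactly the shared presence patterns", {
  pat <- function(category) structure(list(category = category,
                                           calls = data.frame()),
                                      class = "presence_pattern")
  ct <- list(n_reads = 5L)
  expect_true(step2_shared(ct, pat("SHARED_TYPE1"))$decided)
  expect_true(step2_shared(ct, pat("SHARED_TYPE2"))$decided)
  expect_false(step2_shared(ct, pat("TARGET_ONLY_SEGMENT"))$decided)
})

test_that("step 3 requires the vector segment verbatim-near in the host", {
  cfg <- simulation_config(seed = 64, host_length = 30000L,
                           insertion_pos = 15000L)
  vec <- build_vector(cfg)
  ref <- generate_host(cfg)$reference
  kmer <- substring(vec$sequence, 8000, 8019)
  # contig 112 analog: 270 bp of host with the 20-mer planted in both the
  # contig and the reference
  region <- substring(ref[[1]], 20001, 20270)
  substr(region, 126, 145) <- kmer
  ref2 <- ref
  substr(ref2[[1]], 20126, 20145) <- kmer
  ct <- mk_contig(region, vec)
  expect_equal(nrow(ct$segments), 1L)
  s3 <- step3_in_reference(ct, ref2)
  expect_true(s3$decided)
  # the same contig against the unmodified reference: segment absent
  expect_false(step3_in_reference(ct, ref)$decided)
  # a 40 bp segment present at only 90% identity stays below the cutoff
  seg40 <- substring(vec$sequence, 8100, 8139)
  ct40 <- mk_contig(paste0(random_dna(60, 0.4), seg40, random_dna(60, 0.4)),
                    vec)
  diverged <- seg40
  for (p in c(5, 15, 25, 35))
    substr(diverged, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                             substring(diverged, p, p)), 1)
  ref3 <- ref
  substr(ref3[[1]], 22001, 22040) <- diverged
  expect_false(step3_in_reference(ct40, ref3, min_identity = 95)$decided)
})

test_that("step 4 decides on read count, reporting experiment support", {
  two <- list(n_reads = 2L, experiments = "exp1")
  many <- list(n_reads = 122L, experiments = "exp1")
  three <- list(n_reads = 3L, experiments = c("exp1", "exp2"))
  expect_true(step4_underrepresented(two)$decided)
  s <- step4_underrepresented(many)
  expect_false(s$decided)          # 122 reads proceed to step 5
  expect_true(s$single_experiment) # but the evidence is still reported
  expect_false(step4_underrepresented(three)$decided)
  expect_true(step4_underrepresented(many, rule = "either")$decided)
})

test_that("step 5 separates contamination, vector-only and chimeras", {
  cfg <- simulation_config(seed = 65, host_length = 30000L,
                           insertion_pos = 15000L)
  vec <- build_vector(cfg)
  ref <- generate_host(cfg)$reference
  cont <- make_contaminants(cfg, vec)
  cole <- vec$segments[vec$segments$feature == "cole1_like", ]
  # contaminant-origin contig: ColE1-like segment plus contaminant
  # backbone overhangs, with a contaminant-matching context
  at <- regexpr(substring(vec$sequence, cole$start, cole$end),
                cont[["endo_cole1"]], fixed = TRUE)
  ctg_seq <- substring(cont[["endo_cole1"]], at - 80,
                       at + (cole$end - cole$start) + 80)
  ctx <- data.frame(side = "right",
                    sequence = substring(cont[["endo_cole1"]], at + 600,
                                         at + 699),
                    source = "p001/2", stringsAsFactors = FALSE)
  s5 <- step5_origin(mk_contig(ctg_seq, vec, contexts = ctx), ref, vec, cont)
  expect_equal(s5$category, "CONTAMINANT")
  # wholly vector-backbone contig, no contaminant panel hit beyond the
  # vector itself: origin unresolved, no evidence of insertion
  bb <- substring(vec$sequence, 6000, 6283)
  s5b <- step5_origin(mk_contig(bb, vec), ref, vec,
                      c(other = random_dna(5000, 0.5)))
  expect_equal(s5b$category, "VECTOR_ONLY")
  # chimeric vector||host contig: candidate insertion, PCR would decide
  chim <- paste0(substring(vec$sequence, 2000, 2051),
                 substring(ref[[1]], 9000, 9099))
  s5c <- step5_origin(mk_contig(chim, vec), ref, vec, cont)
  expect_equal(s5c$category, "CANDIDATE_INSERTION")
})

test_that("triage partitions all contigs and ignores input order", {
  cfg <- small_config(seed = 66, host_length = 25000L,
                      insertion_pos = 12000L)
  run <- run_pipeline(simulate_study(cfg))
  tab <- run$triage$table
  expect_equal(nrow(tab), length(run$contigs$contigs))
  expect_equal(sum(unlist(run$summary$category_counts)), nrow(tab))
  expect_equal(sum(tab$category == "KNOWN_INSERTION"), 1L)
  # reversing contig order changes no category
  contigs_rev <- run$contigs
  contigs_rev$contigs <- rev(contigs_rev$contigs)
  tri2 <- triage_all(contigs_rev, run$patterns,
                     run$study$host$reference, run$study$vector,
                     run$study$contaminants)
  m <- match(tab$contig, tri2$table$contig)
  expect_identical(tab$category, tri2$table$category[m])
  # with contamination disabled no contig is called CONTAMINANT
  cfg0 <- small_config(seed = 67, host_length = 25000L,
                       insertion_pos = 12000L)
  cfg0$experiments$exp1$contamination_fraction <- 0
  run0 <- run_pipeline(simulate_study(cfg0))
  expect_false(any(run0$triage$table$category == "CONTAMINANT"))
})
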