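# Screening: quality trimming, the vector k-mer index, quality-gated pair
# retention (against a naive oracle) and the frequency profile.

test_that("quality trimming follows the running-sum rule and length filter", {
  good <- make_pairs(strrep("A", 100))
  tr <- trim_reads(good)
  expect_identical(tr$pairs$seq1, good$seq1)   # all Q38: untouched
  expect_equal(tr$counts$trimmed_reads, 2L)

  # 100 bp with a 60 bp Q2 tail: trimmed to 40, dropped, mate orphaned
  p <- make_pairs(strrep("A", 100))
  p$qual1 <- paste0(qstr(40, 38), qstr(60, 2))
  tr <- trim_reads(p, quality_cutoff = 30, min_length = 50)
  expect_equal(nrow(tr$pairs), 0L)
  expect_equal(tr$orphans$read_id, paste0(p$pair_id, "/2"))
  expect_equal(tr$counts$trimmed_reads, 1L)
  expect_equal(tr$counts$raw_reads, 2L)

  # simulated reads with a Q35 floor never fall below a Q30 cutoff
  block <- experiment_block(read_length = 100, fragment_mean = 300,
                            fragment_sd = 20, depth = 2,
                            substitution_error_rate = 0,
                            quality_model = list(q_start = 38, q_end = 36,
                                                 sd = 1, floor = 35,
                                                 ceiling = 40))
  px <- simulate_paired_reads(c(g = random_dna(50000, 0.5)), block, seed = 2)
  tr <- trim_reads(px, quality_cutoff = 30, min_length = 50)
  expect_equal(tr$counts$trimmed_reads, tr$counts$raw_reads)
  expect_identical(tr$pairs$seq1, px$seq1)
})

test_that("k-mer index counts positions for linear and circular mode", {
  s <- random_dna(20, 0.5)
  expect_equal(nrow(extract_vector_kmers(s, 20, circular = FALSE)$positions),
               1L)
  v <- random_dna(10699, 0.5)
  lin <- extract_vector_kmers(v, 20, circular = FALSE)
  circ <- extract_vector_kmers(v, 20, circular = TRUE)
  expect_equal(nrow(lin$positions), 10680L)   # L - k + 1
  expect_equal(nrow(circ$positions), 10699L)  # L
  expect_true(all(nchar(lin$positions$kmer) == 20L))
  # non-ACGT k-mers are excluded and counted
  ix <- extract_vector_kmers(paste0("ACGTN", random_dna(40, 0.5)), 20,
                             circular = FALSE)
  expect_equal(ix$n_excluded, 5L)
  expect_equal(nrow(ix$positions), 45 - 20 + 1 - 5)
  expect_error(extract_vector_kmers(random_dna(10, 0.5), 20), "shorter")
})

test_that("pair retention applies the per-base quality rule over the window", {
  vec <- random_dna(500, 0.5)
  index <- extract_vector_kmers(vec, 20, circular = FALSE)
  kmer <- substring(vec, 101, 120)
  carrier <- paste0(random_dna(40, 0.5), kmer, random_dna(40, 0.5))

  # a random read sharing no 20-mer with the vector is not retained
  sc <- screen_pairs(make_pairs(random_dna(100, 0.5)), index)
  expect_equal(sc$counts$fragments_matched, 0L)

  # one base at Q19 inside the only matching window kills the match
  p <- make_pairs(carrier)
  p$qual1 <- paste0(qstr(50, 38), qstr(1, 19), qstr(49, 38))  # pos 51 in window
  expect_equal(screen_pairs(p, index, min_quality = 20)$counts$reads_matched,
               0L)
  # at exactly Q20 the window passes, and the pair keeps both mates
  p$qual1 <- paste0(qstr(50, 38), qstr(1, 20), qstr(49, 38))
  sc <- screen_pairs(p, index, min_quality = 20)
  expect_equal(sc$counts$reads_matched, 1L)
  expect_equal(sc$counts$fragments_matched, 1L)
  expect_equal(nrow(sc$pairs), 1L)
  # match coordinates: offset 41, vector position 101, forward
  expect_true(any(sc$matches$read_offset == 41L &
                    sc$matches$vector_pos == 101L &
                    sc$matches$strand == "+"))

  # reverse-complement carrier matches at the forward-strand position
  prc <- make_pairs(revcomp(carrier))
  src <- screen_pairs(prc, index)
  expect_equal(src$counts$reads_matched, 1L)
  expect_true(any(src$matches$vector_pos == 101L & src$matches$strand == "-"))
})

test_that("screen equals the naive all-substrings oracle on a small study", {
  cfg <- small_config(seed = 6, host_length = 20000L, insertion_pos = 10000L)
  st <- simulate_study(cfg)
  px <- st$reads[st$reads$sample == "transgenic" &
                   st$reads$experiment == "exp1", ][1:400, ]
  index <- extract_vector_kmers(st$vector, 20, circular = TRUE)
  sc <- screen_pairs(px, index, min_quality = 20)
  orc <- oracle_screen(px, st$vector$sequence, 20, circular = TRUE,
                       min_quality = 20)
  expect_equal(sc$counts$reads_matched, orc$reads_matched)
  expect_equal(sc$counts$fragments_matched, orc$fragments_matched)
  got <- sort(unique(paste0(sc$matches$pair_id, "/", sc$matches$mate)))
  expect_identical(got, orc$matched_uids)
})

test_that("raising the quality floor never adds matches; strand-symmetric", {
  cfg <- small_config(seed = 8, host_length = 20000L, insertion_pos = 10000L)
  st <- simulate_study(cfg)
  px <- st$reads[st$reads$sample == "transgenic" &
                   st$reads$experiment == "exp1", ][1:600, ]
  index <- extract_vector_kmers(st$vector, 20, circular = TRUE)
  counts <- vapply(c(0, 10, 20, 30, 38),
                   function(q) screen_pairs(px, index, q)$counts$reads_matched,
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
  # reverse-complementing every read (and reversing qualities) changes nothing
  flip <- px
  flip$seq1 <- revcomp(px$seq1)
  flip$seq2 <- revcomp(px$seq2)
  rev_q <- function(q) vapply(strsplit(q, ""), function(x)
    paste(rev(x), collapse = ""), character(1))
  flip$qual1 <- rev_q(px$qual1)
  flip$qual2 <- rev_q(px$qual2)
  expect_equal(screen_pairs(flip, index, 20)$counts$reads_matched,
               screen_pairs(px, index, 20)$counts$reads_matched)
})

test_that("frequency profile localizes T-DNA and backbone coverage", {
  index0 <- extract_vector_kmers(random_dna(1000, 0.5), 20)
  empty <- screen_pairs(make_pairs(random_dna(100, 0.5)), index0)
  expect_true(all(kmer_frequency_profile(empty, index0)$count == 0))

  # transgenic sample, no contamination, no errors: counts only inside the
  # integrated interval, at about depth x (rl - k + 1) / rl
  cfg <- simulation_config(
    seed = 12, host_length = 30000L, insertion_pos = 15000L,
    decoy_kmer_count = 0L, chimeric_artifact_rate = 0,
    experiments = list(exp1 = experiment_block(
      depth = 30, substitution_error_rate = 0,
      quality_model = list(q_start = 38, q_end = 36, sd = 1, floor = 35,
                           ceiling = 40))))
  st <- simulate_study(cfg)
  index <- extract_vector_kmers(st$vector, 20, circular = TRUE)
  tg <- st$reads[st$reads$sample == "transgenic", ]
  prof <- kmer_frequency_profile(screen_pairs(tg, index, 20), index)
  ii <- cfg$integrated_interval
  nz <- prof$position[prof$count > 0]
  expect_true(all(nz >= ii[1] & nz <= ii[2] - 19L))
  interior <- prof$count[prof$position %in% seq(ii[1] + 200, ii[2] - 200)]
  expected <- 30 * (100 - 20 + 1) / 100
  expect_lt(abs(mean(interior) - expected) / expected, 0.3)

  # wild type with backbone contamination: counts only over the bla/ColE1
  # analog segments
  cfg2 <- simulation_config(
    seed = 13, host_length = 30000L, insertion_pos = 15000L,
    decoy_kmer_count = 0L, chimeric_artifact_rate = 0,
    contaminated_samples = c("transgenic", "wildtype"),
    experiments = list(exp1 = experiment_block(
      depth = 30, substitution_error_rate = 0,
      contamination_fraction = 0.05,
      contaminant_ids = c("endo_bla", "endo_cole1"),
      quality_model = list(q_start = 38, q_end = 36, sd = 1, floor = 35,
                           ceiling = 40))))
  st2 <- simulate_study(cfg2)
  wt <- st2$reads[st2$reads$sample == "wildtype", ]
  index2 <- extract_vector_kmers(st2$vector, 20, circular = TRUE)
  prof2 <- kmer_frequency_profile(screen_pairs(wt, index2, 20), index2)
  segs <- st2$vector$segments
  bla <- segs[segs$feature == "bla_like", ]
  cole <- segs[segs$feature == "cole1_like", ]
  backbone <- c(seq(bla$start, bla$end - 19L), seq(cole$start, cole$end - 19L))
  nz2 <- prof2$position[prof2$count > 0]
  expect_gt(length(nz2), 0)
  expect_true(all(nz2 %in% backbone))
})
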