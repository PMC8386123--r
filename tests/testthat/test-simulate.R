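# Synthetic-data generator: determinism, composition of the genomes,
# insertion arithmetic, read-simulation statistics and ground truth.

test_that("host generation is deterministic, diploid and on-target GC", {
  cfg <- simulation_config(seed = 5, host_length = 100000L,
                           gc_content = 0.5, insertion_pos = 50000L)
  h1 <- generate_host(cfg)
  h2 <- generate_host(cfg)
  expect_identical(h1, h2)
  expect_length(h1$haplotypes, 2)
  expect_identical(h1$haplotypes$A, h1$reference)
  gc <- function(s) {
    b <- table(strsplit(s, "")[[1]])
    sum(b[c("G", "C")]) / sum(b)
  }
  # binomial tolerance: sd = sqrt(0.25/1e5) ~ 0.0016, so 0.01 is > 6 sd
  expect_lt(abs(gc(h1$reference[["chr1"]]) - 0.5), 0.01)
  # heterozygous sites between haplotypes near the configured rate
  d <- sum(strsplit(h1$haplotypes$A[["chr1"]], "")[[1]] !=
             strsplit(h1$haplotypes$B[["chr1"]], "")[[1]])
  expect_gt(d, 0.5 * cfg$snp_rate * cfg$host_length)
  expect_lt(d, 1.5 * cfg$snp_rate * cfg$host_length)
  expect_error(generate_host(simulation_config(host_length = 500L)))
})

test_that("vector record annotates T-DNA, borders and backbone segments", {
  cfg <- simulation_config(seed = 2)
  v1 <- build_vector(cfg)
  expect_s3_class(v1, "vector_record")
  expect_equal(nchar(v1$sequence), 10699L)
  expect_equal(v1$tdna_interval, c(8L, 5726L))
  expect_equal(v1$integrated_interval, c(29L, 5484L))
  rb <- v1$segments[v1$segments$feature == "right_border", ]
  lb <- v1$segments[v1$segments$feature == "left_border", ]
  expect_equal(interval_length(rb$start, rb$end), 25L)
  expect_equal(interval_length(lb$start, lb$end), 24L)
  bla <- v1$segments[v1$segments$feature == "bla_like", ]
  expect_gt(bla$start, v1$tdna_interval[2])  # backbone feature
  expect_identical(v1, build_vector(cfg))
  # degenerate: T-DNA covering the whole plasmid leaves no backbone
  bad <- cfg
  bad$tdna_interval <- c(1L, cfg$vector_length)
  expect_error(build_vector(bad), "backbone")
})

test_that("contaminant genomes embed the backbone segments verbatim", {
  cfg <- simulation_config(seed = 2)
  vec <- build_vector(cfg)
  cont <- make_contaminants(cfg, vec)
  expect_named(cont, c("endo_bla", "endo_cole1"))
  bla <- vec$segments[vec$segments$feature == "bla_like", ]
  seg <- substring(vec$sequence, bla$start, bla$end)
  expect_true(grepl(seg, cont[["endo_bla"]], fixed = TRUE))
  expect_false(grepl(seg, cont[["endo_cole1"]], fixed = TRUE))
})

test_that("plant_insertion splices with the expected length arithmetic", {
  set.seed(42)
  host <- random_dna(100000, 0.4)
  cfg <- simulation_config(seed = 2)
  vec <- build_vector(cfg)
  # identity case: nothing inserted, nothing deleted
  expect_identical(plant_insertion(host, vec, NULL, 5000L, 0L), host)
  # 100,000 - 11 + 5,456
  out <- plant_insertion(host, vec, c(29L, 5484L), 50000L, 11L)
  expect_equal(nchar(out), 105445L)
  # the deleted bases are exactly the 11 host bases after the junction
  expect_identical(substring(out, 1, 50000), substring(host, 1, 50000))
  expect_identical(substring(out, 50001, 55456),
                   substring(vec$sequence, 29, 5484))
  expect_identical(substring(out, 55457, 105445),
                   substring(host, 50012, 100000))
  expect_error(plant_insertion(host, vec, c(29L, 5484L), 99995L, 11L),
               "range")
})

test_that("read simulation honours count, purity and contamination rates", {
  genome <- c(g1 = random_dna(100000, 0.4))
  block <- experiment_block(read_length = 100, fragment_mean = 300,
                            fragment_sd = 30, depth = 30,
                            substitution_error_rate = 0)
  px <- simulate_paired_reads(genome, block, seed = 9)
  # depth x G / (2 x read_length), within 1%
  expect_lt(abs(nrow(px) - 15000), 150)
  # error-free reads are exact substrings of the source or its RC
  rc <- revcomp(genome[["g1"]])
  sub <- sample(nrow(px), 200)
  ok <- vapply(sub, function(i)
    grepl(px$seq1[i], genome[["g1"]], fixed = TRUE) ||
      grepl(px$seq1[i], rc, fixed = TRUE), logical(1))
  expect_true(all(ok))
  # contamination fraction within binomial tolerance (4 sd ~ 0.005)
  block2 <- experiment_block(read_length = 100, fragment_mean = 300,
                             fragment_sd = 30, depth = 30,
                             contamination_fraction = 0.02,
                             contaminant_ids = "c1")
  px2 <- simulate_paired_reads(genome, block2, seed = 10,
                               contaminants = c(c1 = random_dna(20000, 0.5)))
  frac <- mean(startsWith(px2$origin1, "contaminant"))
  expect_lt(abs(frac - 0.02), 0.005)
  # rejected: read longer than fragment
  expect_error(simulate_paired_reads(
    genome, experiment_block(read_length = 150, fragment_mean = 140), 1))
})

test_that("chimeric artifact spiking is rate-driven and well-formed", {
  cfg <- small_config(seed = 3)
  vec <- build_vector(cfg)
  host <- random_dna(30000, 0.4)
  px <- make_pairs(vapply(1:2000, function(i) random_dna(100, 0.4),
                          character(1)))
  px$origin1 <- "host-wt"
  # rate 0: untouched
  expect_identical(spike_chimeric_artifacts(px, vec, host, 0, 1)$pairs, px)
  # rate tuned for ~6 artifact reads; Poisson 4 sd tolerance
  sp <- spike_chimeric_artifacts(px, vec, host, 6 / 4000, 1)
  n_art <- sum(sp$pairs$origin1 == "chimeric-artifact")
  expect_gt(n_art, 0)
  expect_lt(n_art, 16)
  expect_equal(sp$template$n_reads, n_art)
  # construction: every artifact read is a template substring containing
  # >= 20 bp of exact vector and >= 20 bp of exact host sequence
  tpl <- sp$template
  expect_identical(substring(tpl$sequence, 1, tpl$breakpoint),
                   substring(vec$sequence, tpl$vector_interval[1],
                             tpl$vector_interval[2]))
  expect_identical(substring(tpl$sequence, tpl$breakpoint + 1,
                             nchar(tpl$sequence)),
                   substring(host, tpl$host_interval[1],
                             tpl$host_interval[2]))
  arts <- sp$pairs[sp$pairs$origin1 == "chimeric-artifact", ]
  expect_true(all(grepl2 <- vapply(arts$seq1, grepl, logical(1),
                                   x = tpl$sequence, fixed = TRUE)))
  expect_true(all(arts$src_start1 <= tpl$breakpoint - 19L))
  expect_true(all(arts$src_end1 >= tpl$breakpoint + 20L))
})

test_that("study-level ground truth is conserved and junction-covered", {
  cfg <- small_config(seed = 4)
  st <- simulate_study(cfg)
  # byte-identical on re-simulation
  expect_identical(st, simulate_study(cfg))
  # conservation: per-origin counts sum to the number of emitted reads
  expect_equal(sum(unlist(st$truth$origin_counts)), 2L * nrow(st$reads))
  # read ids unique; junction labels only in the transgenic sample
  expect_false(any(duplicated(st$reads$pair_id)))
  jn <- st$reads$origin1 == "host-transgenic-junction" |
    st$reads$origin2 == "host-transgenic-junction"
  expect_true(all(st$reads$sample[jn] == "transgenic"))
  # deleted bases recorded verbatim from the reference
  tru <- st$truth$insertion
  expect_equal(nchar(tru$deleted_seq), cfg$host_deletion_bp)
  expect_identical(
    tru$deleted_seq,
    substring(st$host$reference[[tru$chrom]], tru$deleted_interval[1],
              tru$deleted_interval[2]))
})

test_that("junction-spanning pairs exist at 30x in every seed", {
  # both insertion junctions must be covered by at least one read pair
  for (seed in 1:20) {
    cfg <- simulation_config(
      seed = seed, host_length = 20000L, insertion_pos = 10000L,
      decoy_kmer_count = 0L, chimeric_artifact_rate = 0,
      experiments = list(exp1 = experiment_block(depth = 30)))
    st <- simulate_study(cfg)
    tg <- st$reads[st$reads$sample == "transgenic", ]
    src <- paste0(cfg$insertion_chrom, "_hap", cfg$insertion_haplotype)
    P <- st$truth$insertion$left_flank_end
    Q <- P + interval_length(cfg$integrated_interval[1],
                             cfg$integrated_interval[2])
    on_mod <- tg$source == src
    covers <- function(jpos)
      any(on_mod & ((tg$src_start1 <= jpos & tg$src_end1 >= jpos + 1) |
                      (tg$src_start2 <= jpos & tg$src_end2 >= jpos + 1)))
    expect_true(covers(P), label = sprintf("seed %d junction 1", seed))
    expect_true(covers(Q), label = sprintf("seed %d junction 2", seed))
  }
})
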