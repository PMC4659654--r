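# The repeat-genome simulator: library anatomy, genome construction, ground
# truth bookkeeping, and read sampling.

test_that("LTR elements satisfy the TG...CA / PBS anatomy", {
  spec <- sim_family("E1", "ltr_retrotransposon", unit_length = 5000,
                     ltr_length = 400, copies = 10)
  lib <- make_ancestral_library(list(spec), seed = 3)
  el <- lib$sequence[["E1"]]
  expect_equal(nchar(el), 5000L)
  # both LTR copies start TG and end CA
  expect_equal(substr(el, 1, 2), "TG")
  expect_equal(substr(el, 399, 400), "CA")
  expect_equal(substr(el, 4601, 4602), "TG")
  expect_equal(substr(el, 4999, 5000), "CA")
  # the two LTRs are identical and the PBS sits 3 bp into the internal region
  expect_equal(substr(el, 1, 400), substr(el, 4601, 5000))
  expect_equal(substr(el, 404, 415), "TGGTATCAGAGC")
  # anatomy violations are rejected with the offending field named
  expect_error(sim_family("bad", "ltr_retrotransposon", unit_length = 700,
                          ltr_length = 400, copies = 1), "unit_length")
  # satellite monomer has the requested length
  sat <- make_ancestral_library(list(
    sim_family("S", "satellite", unit_length = 33, copies = 1)), seed = 1)
  expect_equal(nchar(sat$sequence[["S"]]), 33L)
})

test_that("library and genome generation are deterministic given the seed", {
  specs <- list(sim_family("E1", "ltr_retrotransposon", unit_length = 2000,
                           ltr_length = 250, copies = c(SIM = 20),
                           divergence = 0.05))
  l1 <- make_ancestral_library(specs, seed = 7)
  l2 <- make_ancestral_library(specs, seed = 7)
  expect_identical(l1$sequence, l2$sequence)
  g1 <- build_species_genome(l1, "SIM", 2e5, seed = 9)
  g2 <- build_species_genome(l2, "SIM", 2e5, seed = 9)
  expect_identical(g1$sequence, g2$sequence)
  expect_identical(g1$truth$insertions, g2$truth$insertions)
  r1 <- sample_reads(g1, 0.2, seed = 5)
  r2 <- sample_reads(g2, 0.2, seed = 5)
  expect_identical(r1$sequence, r2$sequence)
  expect_false(identical(sample_reads(g1, 0.2, seed = 6)$sequence,
                         r1$sequence))
})

test_that("truth table is conserved: family bp matches occupied genome bp", {
  specs <- list(
    sim_family("E1", "ltr_retrotransposon", unit_length = 1500,
               ltr_length = 200, copies = c(SIM = 15), solo_fraction = 0.4,
               divergence = 0.03),
    sim_family("S1", "satellite", unit_length = 120, copies = c(SIM = 300),
               divergence = 0.02, monomers_per_array = 100))
  lib <- make_ancestral_library(specs, seed = 2)
  g <- build_species_genome(lib, "SIM", 3e5, seed = 4)
  expect_equal(nchar(g$sequence), 3e5)
  ins <- g$truth$insertions
  fam <- g$truth$families
  # per-family bp equals the summed insertion lengths, exactly
  for (f in fam$family) {
    expect_equal(sum(ins$end[ins$family == f] - ins$start[ins$family == f]),
                 fam$bp[fam$family == f])
  }
  # family bp + background bp = genome length
  expect_equal(sum(fam$bp) + g$truth$background_bp, g$length)
  # inserted sequence really sits at the recorded coordinates: solo copies
  # start TG / end CA
  solos <- ins[ins$type == "solo", ]
  expect_gt(nrow(solos), 0)
  for (i in seq_len(nrow(solos))) {
    expect_equal(solos$end[i] - solos$start[i], 200)
  }
  # requested repeat content exceeding the genome is a sizing error
  expect_error(build_species_genome(lib, "SIM", 2e4, seed = 1),
               "does not fit")
})

test_that("solo_fraction 0 gives no solo-LTRs, divergence 0 identical copies", {
  specs <- list(sim_family("E1", "ltr_retrotransposon", unit_length = 1200,
                           ltr_length = 150, copies = c(SIM = 10),
                           solo_fraction = 0, divergence = 0))
  lib <- make_ancestral_library(specs, seed = 5)
  g <- build_species_genome(lib, "SIM", 1e5, seed = 6)
  expect_equal(g$truth$families$solo_count, 0L)
  ins <- g$truth$insertions
  el <- lib$sequence[["E1"]]
  for (i in seq_len(nrow(ins))) {
    expect_equal(substr(g$sequence, ins$start[i] + 1, ins$end[i]), el)
  }
})

test_that("copy divergence 0.05 yields ~90% mean pairwise identity", {
  # two independently mutated lineages at rate d agree per site with
  # probability (1-d)^2 + d^2/3 = 0.9033 at d = 0.05
  specs <- list(sim_family("D1", "dispersed_other", unit_length = 1000,
                           copies = c(SIM = 40), divergence = 0.05))
  lib <- make_ancestral_library(specs, seed = 8)
  g <- build_species_genome(lib, "SIM", 1e5, seed = 9)
  ins <- g$truth$insertions
  copies <- substring(g$sequence, ins$start + 1, ins$end)
  set.seed(10)
  ids <- replicate(200, {
    p <- sample.int(length(copies), 2)
    a <- strsplit(copies[p[1]], "")[[1]]
    b <- strsplit(copies[p[2]], "")[[1]]
    mean(a == b)
  })
  expect_gt(mean(ids), 0.89)
  expect_lt(mean(ids), 0.92)
})

test_that("read sampling honours counts, pairing, orientation and inserts", {
  set.seed(1)
  genome <- random_dna(1e6)
  reads <- sample_reads(genome, 0.1, seed = 3, error_rate = 0,
                        species_code = "SIM")
  expect_equal(nrow(reads), 1000L)  # 0.1 * 1e6 / 100, even
  # mates are symmetric
  dec <- decode_read_names(reads$read_id)
  expect_true(all(reads$mate_id == dec$mate_id))
  # error-free reads align back to the genome at 100% identity
  fwd <- reads[reads$strand == "+", ][1:20, ]
  expect_true(all(substring(genome, fwd$read_start, fwd$read_end) ==
                  fwd$sequence))
  rev <- reads[reads$strand == "-", ][1:20, ]
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(substring(genome, rev$read_start,
                                       rev$read_end))))
  expect_true(all(rc == rev$sequence))
  # mean insert ~300 over >= 1000 pairs
  big <- sample_reads(genome, 0.4, seed = 4, error_rate = 0)
  ins_len <- with(big[big$strand == "+", ], frag_end - frag_start + 1)
  expect_gt(length(ins_len), 1000)
  expect_lt(abs(mean(ins_len) - 300), 10)
  # coverage accuracy: sampled bases within 5% of requested coverage
  expect_lt(abs(sum(nchar(big$sequence)) / nchar(genome) - 0.4) / 0.4, 0.05)
  expect_error(sample_reads(genome, 0), "positive")
})

test_that("truth-based read annotation labels repeat and background reads", {
  specs <- list(sim_family("D1", "dispersed_other", unit_length = 2000,
                           copies = c(SIM = 20), divergence = 0))
  lib <- make_ancestral_library(specs, seed = 1)
  g <- build_species_genome(lib, "SIM", 2e5, seed = 2)
  reads <- sample_reads(g, 0.5, seed = 3, error_rate = 0)
  lab <- annotate_reads_by_truth(reads, g)
  frac <- mean(lab == "D1")
  expect_gt(frac, 0.15)  # ~20% of the genome is D1
  expect_lt(frac, 0.25)
  expect_true(all(lab %in% c("D1", "background")))
})
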