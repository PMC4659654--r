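# Similarity search, clustering, superclusters, filtering, contigs and
# graph export.

test_that("similarity thresholds behave exactly at the 55 bp boundary", {
  set.seed(2)
  core <- random_dna(55)
  # two reads sharing exactly 55 identical bp -> hit; 54 bp -> no hit
  a55 <- paste0(random_dna(45, gc = 0.2), core)
  b55 <- paste0(core, random_dna(45, gc = 0.8))
  r <- tagged_reads(c("S_0000001/0", "S_0000002/0"), "S", c(a55, b55))
  h <- find_similarity_hits(r)
  expect_equal(nrow(h), 1L)
  expect_equal(h$hit_length, 55L)
  expect_equal(h$identity, 100)
  core54 <- substr(core, 1, 54)
  a54 <- paste0(random_dna(46, gc = 0.2), core54)
  b54 <- paste0(core54, random_dna(46, gc = 0.8))
  r54 <- tagged_reads(c("S_0000001/0", "S_0000002/0"), "S", c(a54, b54))
  expect_equal(nrow(find_similarity_hits(r54)), 0L)
  # identical reads -> full-length 100% hit
  rid <- tagged_reads(c("S_0000001/0", "S_0000002/0"), "S",
                      c(a55, a55))
  hid <- find_similarity_hits(rid)
  expect_equal(hid$hit_length, 100L)
  expect_equal(hid$identity, 100)
  # reverse-complement partners are found with mapped spans
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(a55)))
  rrc <- tagged_reads(c("S_0000001/0", "S_0000002/0"), "S", c(a55, rc))
  hrc <- find_similarity_hits(rrc)
  expect_equal(hrc$orientation, "reverse")
  expect_equal(hrc$hit_length, 100L)
})

test_that("identity thresholding counts N as mismatch and respects 90%", {
  set.seed(3)
  base <- random_dna(100)
  # 10 substitutions in 100 -> exactly 90% -> hit
  mut10 <- substitute_at(base, seq(5, 95, by = 10))
  r <- tagged_reads(c("S_0000001/0", "S_0000002/0"), "S", c(base, mut10))
  h <- find_similarity_hits(r)
  expect_gte(nrow(h), 1L)
  expect_gte(max(h$identity), 90)
  # N never matches: poly-N read produces nothing
  rn <- tagged_reads(c("S_0000001/0", "S_0000002/0"), "S",
                     c(base, strrep("N", 100)))
  expect_equal(nrow(find_similarity_hits(rn)), 0L)
})

test_that("seeded search equals the exhaustive oracle on mixed reads", {
  # simulated repeat + background reads exercise both orientations and
  # diverged pairs near the 90%/55bp boundary
  specs <- list(sim_family("E", "ltr_retrotransposon", unit_length = 1500,
                           ltr_length = 200, copies = c(SIM = 30),
                           divergence = 0.06))
  lib <- make_ancestral_library(specs, seed = 31)
  g <- build_species_genome(lib, "SIM", 2e5, seed = 32)
  reads <- sample_reads(g, 0.08, seed = 33, error_rate = 0.01)
  expect_equal(hit_key(find_similarity_hits(reads)),
               hit_key(all_pairs_hits(reads)))
  # cross-check against an independent aligner on an unambiguous pair:
  # a perfect 70 bp overlap is recovered identically by Biostrings local
  # alignment under mismatch/gap-hostile scoring
  set.seed(34)
  core <- random_dna(70)
  two <- tagged_reads(c("S_0000001/0", "S_0000002/0"), "S",
                      c(paste0(random_dna(30, gc = 0.1), core),
                        paste0(core, random_dna(30, gc = 0.9))))
  row <- find_similarity_hits(two)
  pa <- Biostrings::pairwiseAlignment(
    two$sequence[1], two$sequence[2], type = "local", gapOpening = 1000,
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -9))
  expect_equal(Biostrings::nchar(Biostrings::pattern(pa)), row$hit_length)
  expect_equal(Biostrings::score(pa), row$hit_length)  # all matches
})

test_that("symmetric output mirrors spans", {
  set.seed(4)
  core <- random_dna(80)
  r <- tagged_reads(c("S_0000001/0", "S_0000002/0"), "S",
                    c(paste0(random_dna(20), core),
                      paste0(core, random_dna(20))))
  h <- find_similarity_hits(r, symmetric = TRUE)
  expect_equal(nrow(h), 2L)
  expect_equal(h$read_a, rev(h$read_b))
  expect_equal(h$start_a[1], h$start_b[2])
  expect_equal(h$end_b[1], h$end_a[2])
})

test_that("clusters are connected components numbered by size", {
  set.seed(5)
  # two families with zero cross-similarity -> exactly 2 clusters;
  # chain a-b, b-c with no a-c hit -> one cluster {a,b,c}
  t1 <- random_dna(160)
  fam1 <- c(substr(t1, 1, 100), substr(t1, 31, 130), substr(t1, 61, 160))
  t2 <- random_dna(120)
  fam2 <- c(substr(t2, 1, 100), substr(t2, 21, 120))
  reads <- tagged_reads(encode_read_name("SIM", 1:5, 0), "SIM",
                        c(fam1, fam2))
  h <- find_similarity_hits(reads)
  cl <- build_clusters(h, reads)
  expect_equal(nrow(cl$clusters), 2L)
  expect_equal(cl$clusters$n_reads, c(3L, 2L))       # numbered by size
  expect_equal(sort(cl$members[[1]]),
               sort(reads$read_id[1:3]))             # the chain is one cluster
  expect_equal(cl$clusters$proportion, c(0.6, 0.4))
  # partition property: every read in exactly one cluster or a singleton
  all_ids <- c(unlist(cl$members), cl$singletons)
  expect_equal(sort(all_ids), sort(reads$read_id))
  # hits naming unknown reads are a consistency error
  bad <- h
  bad$read_a[1] <- "GHOST_0000001/0"
  expect_error(build_clusters(bad, reads), "absent")
})

test_that("per-species counts sum to cluster sizes", {
  panel <- cached_panel()
  cl <- panel$clusters
  spcols <- paste0("n_", cl$species)
  expect_equal(unname(rowSums(as.matrix(cl$clusters[spcols]))),
               cl$clusters$n_reads)
  expect_equal(sum(cl$clusters$n_reads) + length(cl$singletons),
               cl$total_reads)
})

test_that("mate-pair links join split repeats into superclusters", {
  # one long element whose two halves share no sequence: reads cluster into
  # two clusters connected by mate pairs spanning the halves
  set.seed(6)
  partA <- random_dna(600)
  partB <- random_dna(600)
  spacer <- function() random_dna(250)
  genome <- paste0(random_dna(2000),
                   paste(replicate(40, paste0(partA, partB, spacer())),
                         collapse = ""),
                   random_dna(2000))
  reads <- sample_reads(genome, 0.6, seed = 7, error_rate = 0,
                        species_code = "SIM")
  h <- find_similarity_hits(reads)
  cl <- build_clusters(h, reads)
  expect_gte(nrow(cl$clusters), 2L)
  sc <- link_superclusters(cl, reads, min_shared_pairs = 2)
  # the two biggest clusters (A-half and B-half) share one supercluster
  expect_equal(sc$supercluster[1], sc$supercluster[2])
  # min_shared_pairs = Inf leaves every cluster alone
  sc_inf <- link_superclusters(cl, reads, min_shared_pairs = Inf)
  expect_equal(length(unique(sc_inf$supercluster)), nrow(cl$clusters))
})

test_that("cluster filtering applies the 0.01% / 0.005% thresholds", {
  cl <- fake_clusters(c(150, 80, 40, 2), total_reads = 1e6)
  gf <- filter_clusters(cl, "genome_fraction")
  expect_equal(gf$retained$clusters$cluster_id, 1L)   # only 0.015% >= 0.01%
  expect_equal(gf$n_discarded, 3L)
  rf <- filter_clusters(cl, "read_fraction")
  # 0.008% passes the 0.005% read threshold, 0.004% does not
  expect_equal(rf$retained$clusters$cluster_id, c(1L, 2L))
  expect_error(filter_clusters(cl, "bogus"))
  empty <- fake_clusters(integer(0), 100)
  expect_equal(filter_clusters(empty, "read_fraction")$n_retained, 0L)
})

test_that("contig assembly reconstructs an error-free template", {
  set.seed(8)
  template <- random_dna(500)
  starts <- round(seq(1, 401, length.out = 20))
  reads <- tagged_reads(encode_read_name("SIM", 1:20, 0), "SIM",
                        substring(template, starts, starts + 99))
  h <- find_similarity_hits(reads)
  contigs <- build_contigs(reads$read_id, reads, h)
  expect_equal(length(contigs), 1L)
  expect_equal(contigs[[1]]$consensus, template)
  lay <- contigs[[1]]$layout
  expect_equal(sort(lay$offset), sort(starts - 1L))
  expect_true(all(lay$core_start == 1L & lay$core_end == 100L))
  # two disjoint templates forced into one call -> 2 contigs
  t2 <- random_dna(300)
  reads2 <- tagged_reads(encode_read_name("SIM", 1:8, 0), "SIM",
                         c(substring(template, c(1, 41, 81, 121),
                                     c(100, 140, 180, 220)),
                           substring(t2, c(1, 41, 81, 121),
                                     c(100, 140, 180, 220))))
  h2 <- find_similarity_hits(reads2)
  contigs2 <- build_contigs(reads2$read_id, reads2, h2)
  expect_equal(length(contigs2), 2L)
})

test_that("reads leaving the repeat get masked tails on the contig", {
  set.seed(9)
  template <- random_dna(400)
  # 15 reads inside the template, 6 junction reads continuing into six
  # different flanks from position 301
  starts <- round(seq(1, 300, length.out = 15))
  inside <- substring(template, starts, starts + 99)
  junction <- vapply(1:6, function(i)
    paste0(substr(template, 241, 300), random_dna(40)), character(1))
  reads <- tagged_reads(encode_read_name("SIM", 1:21, 0), "SIM",
                        c(inside, junction))
  h <- find_similarity_hits(reads)
  contigs <- build_contigs(reads$read_id, reads, h)
  lay <- contigs[[1]]$layout
  jrows <- lay[match(encode_read_name("SIM", 16:21, 0), lay$read_id), ]
  # the flank part (40 bp) is masked: core ends ~60 bases into the read
  expect_true(all(abs(jrows$core_end - 60) <= 2, na.rm = TRUE))
})

test_that("graph export carries species attributes and community structure", {
  set.seed(10)
  core <- random_dna(90)
  reads <- tagged_reads(encode_read_name(c("AAA", "AAA", "BBB"), 1:3, 0),
                        c("AAA", "AAA", "BBB"),
                        c(paste0(core, random_dna(10)),
                          paste0(random_dna(10), core),
                          paste0(random_dna(5), core, random_dna(5))))
  h <- find_similarity_hits(reads)
  g <- export_graph(reads$read_id, h, reads)
  expect_equal(igraph::vcount(g), 3L)
  expect_equal(igraph::ecount(g), nrow(h))
  expect_equal(sort(unique(igraph::V(g)$species)), c("AAA", "BBB"))
  path <- tempfile(fileext = ".graphml")
  export_graph(reads$read_id, h, reads, path)
  expect_true(file.size(path) > 0)
  # two strongly diverged species variants of one family form two lobes
  # (here: disjoint communities of the similarity graph)
  specs <- list(sim_family("V", "dispersed_other", unit_length = 1000,
                           copies = c(SPA = 15, SPB = 15), divergence = 0.01,
                           lineage_divergence = 0.15))
  lib <- make_ancestral_library(specs, seed = 11)
  sim <- simulate_panel(specs, c(SPA = 5e4, SPB = 5e4), 0.4, seed = 12)
  hh <- find_similarity_hits(sim$reads)
  memb <- sim$reads$read_id[sim$reads$species == "SPA"][1]
  gg <- export_graph(sim$reads$read_id, hh, sim$reads)
  comm <- igraph::components(gg)
  # species variants do not cross-hit at 15% lineage divergence
  crossing <- sum(sim$reads$species[match(hh$read_a, sim$reads$read_id)] !=
                  sim$reads$species[match(hh$read_b, sim$reads$read_id)])
  expect_equal(crossing, 0L)
  expect_gte(comm$no, 2L)
})
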