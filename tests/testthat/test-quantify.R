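# Abundance arithmetic, class aggregation, replicate comparison and
# flow-cytometry conversions.

test_that("cluster abundance reproduces the published satellite figures", {
  # V. faba: 6.97% of a 13.41 Gbp genome is ~935 Mbp of satellite DNA
  vfb <- species_profiles("VFB", 13.41e9)
  rec <- cluster_abundance(69700, 1e6, vfb, "satellite")
  expect_equal(rec$mbp_per_1Cx, 934.677, tolerance = 1e-6)
  expect_lt(abs(rec$mbp_per_1Cx - 935) / 935, 0.01)
  # V. villosa: 12.3% of 2.04 Gbp is ~250 Mbp
  vvl <- species_profiles("VVL", 2.04e9)
  rec2 <- cluster_abundance(123000, 1e6, vvl, "satellite")
  expect_lt(abs(rec2$mbp_per_1Cx - 250) / 250, 0.01)
  expect_equal(rec2$percent_genome, 12.3)
  # zero reads -> zero everywhere
  rec0 <- cluster_abundance(0, 1e6, vfb)
  expect_equal(rec0$mbp_per_1Cx, 0)
  expect_error(cluster_abundance(1, 0, vfb), "positive")
})

test_that("unit consistency: percent and Mbp/1Cx agree through 1Cx", {
  set.seed(1)
  p <- species_profiles("AAA", 3.7e9)
  for (prop in runif(20)) {
    rec <- cluster_abundance(round(prop * 1e6), 1e6, p)
    expect_equal(rec$percent_genome / 100 * p$genome_size_1Cx / 1e6,
                 rec$mbp_per_1Cx, tolerance = 1e-12)
  }
  # monotone: more reads never decrease abundance
  recs <- vapply(seq(0, 1e5, by = 1e4), function(n)
    cluster_abundance(n, 1e6, p)$mbp_per_1Cx, numeric(1))
  expect_true(all(diff(recs) >= 0))
})

test_that("abundance tables close to 1 with the low-copy remainder", {
  panel <- cached_panel()
  profiles <- species_profiles(names(panel$scenario$species),
                               unlist(panel$scenario$species))
  cl <- panel$clusters
  tab <- abundance_table(cl, profiles, annotation = panel$cluster_annotation)
  for (sp in profiles$code) {
    expect_equal(sum(tab$proportion[tab$species == sp]), 1, tolerance = 1e-9)
  }
  expect_true("singletons/low-copy" %in% tab$repeat_class)
})

test_that("class aggregation conserves totals at every level", {
  rec <- rbind(
    abundance_record("A", "LTR/Ty3-gypsy/Ogre", 0.30, 2e9),
    abundance_record("A", "LTR/Ty3-gypsy/Tat", 0.05, 2e9),
    abundance_record("A", "LTR/Ty1-copia/Angela", 0.02, 2e9),
    abundance_record("A", "satellite/SatA", 0.08, 2e9))
  lvl2 <- aggregate_by_class(rec, 2)
  gypsy <- lvl2[lvl2$repeat_class == "LTR/Ty3-gypsy", ]
  expect_equal(gypsy$proportion, 0.35)       # Ogre + Tat at the lineage level
  lvl1 <- aggregate_by_class(rec, 1)
  expect_equal(sum(lvl1$proportion), sum(rec$proportion))   # conservation
  expect_equal(lvl1$proportion[lvl1$repeat_class == "LTR"], 0.37)
})

test_that("replicate comparison computes folds and flags singletons", {
  r1 <- rbind(abundance_record("A", "x", 0.2, 1e9),
              abundance_record("A", "y", 0.1, 1e9))
  # identical runs -> all folds 1
  ident <- compare_replicates(r1, r1)
  expect_true(all(ident$per_class$fold == 1))
  # abundances 2 and 8 (Mbp) -> fold 4
  r2 <- rbind(abundance_record("A", "x", 0.2 * 4, 1e9),
              abundance_record("A", "z", 0.05, 1e9))
  cmp <- compare_replicates(r1, r2)
  expect_equal(cmp$per_class$fold[cmp$per_class$repeat_class == "x"], 4)
  # class present in one run only -> infinite fold, excluded from the mean
  expect_true(is.infinite(
    cmp$per_class$fold[cmp$per_class$repeat_class == "y"]))
  expect_equal(cmp$mean_fold, 4)
})

test_that("flow-cytometry arithmetic matches the calibration formulas", {
  # sample peak 100, standard peak 200 against the 9.09 pg pea standard
  res <- genome_size_from_fcm(100, 200, 9.09)
  expect_equal(res$pg_2C, 4.545)
  # 1 pg DNA = 0.978e9 bp
  expect_equal(genome_size_from_fcm(1, 1, 1)$bp_2C, 0.978e9)
  # equal peaks -> sample 2C equals the standard
  expect_equal(genome_size_from_fcm(123, 123, 9.09)$pg_2C, 9.09)
  expect_error(genome_size_from_fcm(-1, 1, 1), "positive")
})

test_that("reference-library annotation labels clusters by best match", {
  set.seed(12)
  fam <- random_dna(600)
  starts <- round(seq(1, 500, length.out = 12))
  reads <- tagged_reads(encode_read_name("SIM", 1:12, 0), "SIM",
                        substring(fam, starts, starts + 99))
  h <- find_similarity_hits(reads)
  cl <- build_clusters(h, reads)
  lib <- c(FamRef = fam, Other = random_dna(600))
  ann <- annotate_clusters(cl, reads, lib,
                           library_classes = c(FamRef = "LTR/FamRef",
                                               Other = "DNA/Other"))
  expect_equal(ann$clusters$annotation[1], "LTR/FamRef")
})
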