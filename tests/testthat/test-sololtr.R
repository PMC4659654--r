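# Junction detection, validation, tag counting and the Rsf estimator.

# build a synthetic contig layout: reads of length 100 tiling a consensus,
# with `n_masked` reads whose alignment ends at `boundary` (0-based core end
# = boundary) while the read physically continues
synthetic_contig <- function(consensus, n_through = 10, n_masked = 6,
                             boundary = 200) {
  clen <- nchar(consensus)
  offs <- round(seq(0, clen - 100, length.out = n_through))
  lay1 <- data.frame(read_id = sprintf("SIM_%07d/0", seq_len(n_through)),
                     strand = "+", offset = offs, length = 100L,
                     core_start = 1L, core_end = 100L, core_identity = 100,
                     stringsAsFactors = FALSE)
  lay <- lay1
  if (n_masked > 0) {
    moffs <- boundary - round(seq(40, 80, length.out = n_masked))
    lay2 <- data.frame(read_id = sprintf("SIM_%07d/0",
                                         n_through + seq_len(n_masked)),
                       strand = "+", offset = moffs, length = 100L,
                       core_start = 1L, core_end = boundary - moffs,
                       core_identity = 100, stringsAsFactors = FALSE)
    lay <- rbind(lay1, lay2)
  }
  structure(list(consensus = consensus, layout = lay,
                 unplaced = character(0)), class = "contig_layout")
}

test_that("masked-fraction profiles yield junction candidates", {
  set.seed(1)
  cons <- random_dna(500)
  cg <- synthetic_contig(cons, n_through = 10, n_masked = 8, boundary = 200)
  cands <- detect_junction_candidates(cg)
  expect_equal(nrow(cands), 1L)
  expect_equal(cands$position, 201L)  # first downstream column
  # uniform contig without masking -> no candidates
  cg0 <- synthetic_contig(cons, n_through = 12, n_masked = 0)
  expect_equal(nrow(detect_junction_candidates(cg0)), 0L)
  # hard boundary: all reads masked from column k
  cgh <- synthetic_contig(cons, n_through = 4, n_masked = 10,
                          boundary = 300)
  ch <- detect_junction_candidates(cgh)
  expect_true(301 %in% ch$position)
})

test_that("junction validation demands CA terminus and a PBS motif", {
  set.seed(2)
  pbs <- "TGGTATCAGAGC"
  ltr_end <- paste0(random_dna(40), "TGTTA", "CA")
  good <- paste0(random_dna(60), ltr_end, "T", pbs, random_dna(60))
  b <- 60 + nchar(ltr_end) + 1  # first downstream column
  cg <- structure(list(consensus = good,
                       layout = data.frame(), unplaced = character(0)),
                  class = "contig_layout")
  m <- validate_junction(b, cg)
  expect_true(m$accepted)
  expect_true(m$tg_ca_ok && m$pbs_ok)
  expect_equal(nchar(m$ltr3end_tag), 30L)
  expect_equal(nchar(m$utr_tag), 30L)
  expect_equal(substr(m$ltr3end_tag, 29, 30), "CA")
  expect_equal(substr(good, b - 30, b - 1), m$ltr3end_tag)
  # GG instead of CA upstream -> rejected for the terminus
  bad_ca <- paste0(substr(good, 1, b - 3), "GG", substr(good, b, nchar(good)))
  cg2 <- structure(list(consensus = bad_ca, layout = data.frame(),
                        unplaced = character(0)), class = "contig_layout")
  m2 <- validate_junction(b, cg2, shift_tolerance = 0)
  expect_false(m2$accepted)
  expect_equal(m2$reason, "tg_ca")
  # CA present but no PBS within 30 bp -> rejected for the PBS
  no_pbs <- paste0(random_dna(60), ltr_end, random_dna(80, gc = 0.9))
  cg3 <- structure(list(consensus = no_pbs, layout = data.frame(),
                        unplaced = character(0)), class = "contig_layout")
  m3 <- validate_junction(b, cg3, shift_tolerance = 0)
  expect_false(m3$accepted)
  expect_equal(m3$reason, "pbs")
  # boundary too close to a contig end -> tag-untestable
  m4 <- validate_junction(10, cg, shift_tolerance = 0)
  expect_equal(m4$reason, "tag-untestable")
})

test_that("junction read counting follows the tag definitions", {
  set.seed(3)
  ltr_tag <- paste0(random_dna(28), "CA")
  utr_tag <- paste0("TGGTATCAGAGC", random_dna(18))
  model <- structure(list(element_label = "E", ltr3end_tag = ltr_tag,
                          utr_tag = utr_tag, boundary = NA, tg_ca_ok = TRUE,
                          pbs_ok = TRUE, accepted = TRUE, reason = ""),
                     class = "ltr_junction_model")
  lu_read <- paste0(random_dna(20), ltr_tag, utr_tag, random_dna(20))
  lx_read <- paste0(random_dna(20), ltr_tag, random_dna(50, gc = 0.9))
  short_read <- paste0(random_dna(50), ltr_tag, random_dna(20))  # 20 bp left
  none_read <- random_dna(100)
  reads <- tagged_reads(encode_read_name("SIM", 1:4, 0), "SIM",
                        c(lu_read, lx_read, short_read, none_read))
  cnt <- count_junction_reads(model, reads)
  expect_equal(cnt$LU, 1L)
  expect_equal(cnt$Lx, 1L)
  # reverse-complement reads are classified the same way
  rc <- tagged_reads(encode_read_name("SIM", 1:2, 0), "SIM",
                     as.character(Biostrings::reverseComplement(
                       Biostrings::DNAStringSet(c(lu_read, lx_read)))))
  cnt_rc <- count_junction_reads(model, rc)
  expect_equal(cnt_rc$LU, 1L)
  expect_equal(cnt_rc$Lx, 1L)
})

test_that("Rsf formula and the undefined flag", {
  expect_equal(compute_rsf(100, 100)$Rsf, 0)    # all full-length
  expect_equal(compute_rsf(100, 300)$Rsf, 2)
  r0 <- compute_rsf(0, 50)
  expect_true(is.na(r0$Rsf))
  expect_false(r0$defined)
})

test_that("full pipeline recovers a known solo:full ratio", {
  sc <- scenario_sololtr(1)
  lib <- make_ancestral_library(sc$specs, seed = 61)
  g <- build_species_genome(lib, "SIM", sc$species[["SIM"]], seed = 62)
  reads <- sample_reads(g, sc$coverage, error_rate = 0.005, seed = 63)
  res <- estimate_rsf(reads, cluster_sample = 2500)
  expect_gte(nrow(res), 1L)
  tt <- g$truth$families
  truth <- tt$solo_count / tt$full_count
  expect_lt(abs(res$Rsf[1] - truth), 0.35)  # single-seed sampling bound
  expect_gt(res$LU[1], 50)
})
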