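# Shared fixtures.  Heavy simulations are computed once per test run and
# cached, so several test files can reuse the same panel.

.fixture_cache <- new.env(parent = emptyenv())

# three-species comparative panel with similarity hits and per-read truth
# labels (computed once, ~30 s)
cached_panel <- function(seed = 42) {
  key <- paste0("panel_", seed)
  if (is.null(.fixture_cache[[key]])) {
    sc <- scenario_comparative_panel()
    sim <- simulate_panel(sc$specs, sc$species, sc$coverage, seed = seed)
    hits <- find_similarity_hits(sim$reads)
    labels <- character(0)
    for (code in names(sim$genomes)) {
      r <- sim$reads[sim$reads$species == code, ]
      labels <- c(labels, setNames(annotate_reads_by_truth(
        r, sim$genomes[[code]]), r$read_id))
    }
    clusters <- build_clusters(hits, sim$reads)
    ann <- vapply(clusters$members, function(m) {
      tb <- sort(table(labels[m]), decreasing = TRUE)
      names(tb)[1]
    }, character(1))
    .fixture_cache[[key]] <- list(scenario = sc, sim = sim, hits = hits,
                                  labels = labels, clusters = clusters,
                                  cluster_annotation = ann)
  }
  .fixture_cache[[key]]
}

# per-family recovered vs true genome proportions for one panel simulation
panel_recovery <- function(seed) {
  panel <- if (seed == 42) cached_panel() else {
    sc <- scenario_comparative_panel()
    sim <- simulate_panel(sc$specs, sc$species, sc$coverage, seed = seed)
    hits <- find_similarity_hits(sim$reads)
    labels <- character(0)
    for (code in names(sim$genomes)) {
      r <- sim$reads[sim$reads$species == code, ]
      labels <- c(labels, setNames(annotate_reads_by_truth(
        r, sim$genomes[[code]]), r$read_id))
    }
    clusters <- build_clusters(hits, sim$reads)
    ann <- vapply(clusters$members, function(m) {
      tb <- sort(table(labels[m]), decreasing = TRUE)
      names(tb)[1]
    }, character(1))
    list(sim = sim, clusters = clusters, cluster_annotation = ann)
  }
  out <- list()
  for (code in names(panel$sim$genomes)) {
    truth <- panel$sim$genomes[[code]]$truth$families
    n_sp <- sum(panel$sim$reads$species == code)
    rec <- vapply(truth$family, function(f)
      sum(panel$clusters$clusters[[paste0("n_", code)]][
        panel$cluster_annotation == f]) / n_sp, numeric(1))
    out[[code]] <- data.frame(species = code, family = truth$family,
                              truth_prop = truth$proportion,
                              recovered_prop = unname(rec),
                              stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# deterministic random reads (no repeat structure)
random_reads <- function(n, len = 100, seed = 1, species = "SIM") {
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i) random_dna(len), character(1))
  tagged_reads(encode_read_name(species, seq_len(n), 0L), species, seqs)
}

# canonical hit key for set comparisons
hit_key <- function(h) {
  sort(paste(h$read_a, h$read_b, h$orientation, h$identity, h$hit_length,
             h$start_a, h$end_a, h$start_b, h$end_b))
}

# mutate a sequence at an exact set of positions (always to a different base)
substitute_at <- function(seq, pos) {
  v <- strsplit(seq, "")[[1]]
  rot <- c(A = "C", C = "G", G = "T", T = "A", N = "A")
  v[pos] <- rot[v[pos]]
  paste(v, collapse = "")
}

# minimal read_clusters object for filter tests
fake_clusters <- function(sizes, total_reads) {
  members <- lapply(seq_along(sizes), function(i)
    sprintf("SIM_%03d%04d/0", i, seq_len(sizes[i])))
  cl <- data.frame(cluster_id = seq_along(sizes), n_reads = sizes,
                   proportion = sizes / total_reads,
                   n_SIM = sizes,
                   annotation = rep(NA_character_, length(sizes)),
                   stringsAsFactors = FALSE)
  structure(list(clusters = cl, members = members, singletons = character(0),
                 total_reads = total_reads, species = "SIM"),
            class = "read_clusters")
}
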