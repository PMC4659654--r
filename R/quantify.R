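# Repeat quantification: cluster read counts -> genome proportions and
# Mbp per monoploid genome (1Cx), class-level aggregation, replicate
# comparison and flow-cytometry genome-size arithmetic.

#' Abundance of one cluster in one species
#'
#' The number of reads in a cluster is proportional to the genomic abundance
#' of the corresponding repeat, so the genome proportion is the cluster's
#' per-species read count over the total analysed reads of that species, and
#' the absolute amount is that proportion times the monoploid genome size.
#'
#' @param per_species_count reads of this species in the cluster.
#' @param total_reads total analysed reads of the species.
#' @param profile one-row species profile (see [species_profile()]).
#' @param repeat_class optional class label carried through.
#' @return an `abundance_record` data frame row: `species`, `repeat_class`,
#'   `proportion`, `percent_genome`, `mbp_per_1Cx`.
#' @examples
#' p <- species_profiles("VFB", 13.41e9)
#' cluster_abundance(69700, 1e6, p)  # ~934.7 Mbp/1Cx
#' @export
cluster_abundance <- function(per_species_count, total_reads, profile,
                              repeat_class = NA_character_) {
  if (total_reads <= 0) stop("total_reads must be positive")
  proportion <- per_species_count / total_reads
  abundance_record(profile$code, repeat_class, proportion,
                   profile$genome_size_1Cx)
}

abundance_record <- function(species, repeat_class, proportion,
                             genome_size_1Cx) {
  data.frame(species = species, repeat_class = repeat_class,
             proportion = proportion,
             percent_genome = 100 * proportion,
             mbp_per_1Cx = proportion * genome_size_1Cx / 1e6,
             stringsAsFactors = FALSE)
}

#' Per-species abundance table from clustering results
#'
#' One row per (species, cluster annotation); clusters sharing an annotation
#' are summed.  The non-repeat remainder (reads outside retained clusters) is
#' emitted as the pseudo-class `"singletons/low-copy"` so that proportions
#' total 1 per species.
#'
#' @param clusters a `read_clusters` object with annotations assigned (see
#'   [annotate_clusters()]), or `annotation` supplied separately.
#' @param profiles `species_profiles` covering all tagged species.
#' @param total_reads named vector of analysed read counts per species
#'   (defaults to the per-species totals in the clustering).
#' @param annotation optional character vector of per-cluster class labels
#'   overriding `clusters$clusters$annotation`.
#' @return an abundance table (data frame of abundance records).
#' @export
abundance_table <- function(clusters, profiles, total_reads = NULL,
                            annotation = NULL) {
  cl <- clusters$clusters
  if (is.null(annotation)) annotation <- cl$annotation
  annotation[is.na(annotation)] <- "unclassified"
  species <- clusters$species
  if (is.null(total_reads)) {
    total_reads <- vapply(species, function(sp)
      sum(cl[[paste0("n_", sp)]]) , numeric(1)) # reads in clusters only
    # add singletons
    if (length(clusters$singletons)) {
      st <- table(sub("_.*$", "", clusters$singletons))
      total_reads[names(st)] <- total_reads[names(st)] + as.numeric(st)
    }
  }
  out <- list()
  for (sp in species) {
    prof <- species_profile(profiles, sp)
    counts <- tapply(cl[[paste0("n_", sp)]], annotation, sum)
    rec <- abundance_record(sp, names(counts),
                            as.numeric(counts) / total_reads[[sp]],
                            prof$genome_size_1Cx)
    rest <- 1 - sum(rec$proportion)
    rec <- rbind(rec, abundance_record(sp, "singletons/low-copy", rest,
                                       prof$genome_size_1Cx))
    out[[sp]] <- rec
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Annotate clusters against a reference repeat library
#'
#' Each cluster is labelled with the repeat class of the library family
#' accumulating the largest total hit length between member reads and the
#' family's reference sequence (nucleotide level); clusters with no library
#' hit, or tied best families, stay `"unclassified"`.
#'
#' @param clusters a `read_clusters` object.
#' @param reads the underlying `tagged_reads`.
#' @param library_seqs named character vector of reference sequences.
#' @param library_classes named character vector mapping library names to
#'   repeat-class labels (defaults to the library names themselves).
#' @param min_identity,min_overlap matching thresholds (default 80%/55 bp:
#'   annotation tolerates more divergence than clustering).
#' @param max_reads_per_cluster subsample cap per cluster (deterministic,
#'   evenly strided) to bound run time.
#' @return the `read_clusters` object with `annotation` filled in.
#' @export
annotate_clusters <- function(clusters, reads, library_seqs,
                              library_classes = NULL, min_identity = 80,
                              min_overlap = 55,
                              max_reads_per_cluster = 200) {
  if (is.null(library_classes))
    library_classes <- setNames(names(library_seqs), names(library_seqs))
  ann <- clusters$clusters$annotation
  for (i in seq_along(clusters$members)) {
    mem <- clusters$members[[i]]
    if (length(mem) > max_reads_per_cluster) {
      sel <- unique(round(seq(1, length(mem),
                              length.out = max_reads_per_cluster)))
      mem <- mem[sel]
    }
    sub <- reads[match(mem, reads$read_id), , drop = FALSE]
    combo <- tagged_reads(
      c(sub$read_id, paste0("LIB:", names(library_seqs))),
      c(sub$species, rep("LIB", length(library_seqs))),
      c(sub$sequence, unname(library_seqs)))
    h <- find_similarity_hits(combo, min_identity, min_overlap)
    lib_a <- startsWith(h$read_a, "LIB:")
    lib_b <- startsWith(h$read_b, "LIB:")
    h <- h[xor(lib_a, lib_b), , drop = FALSE]
    if (!nrow(h)) next
    fam <- ifelse(startsWith(h$read_a, "LIB:"),
                  sub("^LIB:", "", h$read_a), sub("^LIB:", "", h$read_b))
    tot <- tapply(h$hit_length, fam, sum)
    best <- which(tot == max(tot))
    if (length(best) == 1)
      ann[i] <- unname(library_classes[names(tot)[best]])
  }
  clusters$clusters$annotation <- ann
  clusters
}

#' Aggregate abundance records over the repeat-class tree
#'
#' Class labels are `/`-separated paths (e.g. `LTR/Ty3-gypsy/Ogre`);
#' aggregation at level `k` sums all records sharing their first `k` path
#' components, conserving totals.
#'
#' @param records an abundance table.
#' @param class_level tree depth to aggregate at (1 = top level).
#' @return aggregated abundance table.
#' @export
aggregate_by_class <- function(records, class_level = 1) {
  comp <- strsplit(records$repeat_class, "/", fixed = TRUE)
  lab <- vapply(comp, function(p)
    paste(p[seq_len(min(class_level, length(p)))], collapse = "/"),
    character(1))
  agg <- stats::aggregate(
    records[c("proportion", "percent_genome", "mbp_per_1Cx")],
    by = list(species = records$species, repeat_class = lab), FUN = sum)
  agg[order(agg$species, agg$repeat_class), , drop = FALSE]
}

#' Compare repeat abundances between replicate runs
#'
#' Per repeat class, the fold difference `max/min` between the two runs;
#' classes present in only one run are flagged with an infinite fold and
#' excluded from summary means.
#'
#' @param records_run1,records_run2 abundance tables for the same species and
#'   class tree.
#' @return list with `per_class` (data frame: `repeat_class`, `abundance_1`,
#'   `abundance_2`, `fold`) and `mean_fold` (mean over finite folds).
#' @export
compare_replicates <- function(records_run1, records_run2) {
  m <- merge(records_run1[c("species", "repeat_class", "mbp_per_1Cx")],
             records_run2[c("species", "repeat_class", "mbp_per_1Cx")],
             by = c("species", "repeat_class"), all = TRUE,
             suffixes = c("_1", "_2"))
  a1 <- m$mbp_per_1Cx_1
  a2 <- m$mbp_per_1Cx_2
  fold <- ifelse(is.na(a1) | is.na(a2) | pmin(a1, a2) == 0, Inf,
                 pmax(a1, a2) / pmin(a1, a2))
  per_class <- data.frame(species = m$species, repeat_class = m$repeat_class,
                          abundance_1 = a1, abundance_2 = a2, fold = fold,
                          stringsAsFactors = FALSE)
  list(per_class = per_class,
       mean_fold = mean(fold[is.finite(fold)]))
}

#' Genome size from flow-cytometry peak means
#'
#' `sample 2C DNA [pg] = sample G1 peak mean x standard 2C DNA [pg] /
#' standard G1 peak mean`, converted to base pairs with
#' 1 pg DNA = 0.978e9 bp.
#'
#' @param sample_g1_peak_mean G1 peak mean of the sample.
#' @param standard_g1_peak_mean G1 peak mean of the internal standard.
#' @param standard_2C_pg 2C DNA content of the standard in pg (e.g. 9.09 for
#'   the *Pisum sativum* cv. Ctirad standard).
#' @return list with `pg_2C` and `bp_2C`.
#' @export
genome_size_from_fcm <- function(sample_g1_peak_mean, standard_g1_peak_mean,
                                 standard_2C_pg) {
  if (any(c(sample_g1_peak_mean, standard_g1_peak_mean,
            standard_2C_pg) <= 0))
    stop("all flow-cytometry inputs must be positive")
  pg <- sample_g1_peak_mean * standard_2C_pg / standard_g1_peak_mean
  list(pg_2C = pg, bp_2C = pg * 0.978e9)
}
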