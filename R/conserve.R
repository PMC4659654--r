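# Cross-species sequence conservation: per-species average pairwise read
# similarity within clusters, and the per-read Hs/Ho intra- versus
# inter-specific hit-frequency ratio.

#' Average pairwise read similarity per species within a cluster
#'
#' For every species with at least two reads in the cluster, the mean over
#' read pairs of the adjusted similarity of their best-scoring ungapped local
#' hit (both orientations, match +5 / mismatch -4, hits shorter than
#' `min_hit_length` discarded).  When a hit ends before the read ends even
#' though the implied overlap continues, its similarity is rescaled by
#' `hit_length / maximal overlap` implied by the hit's diagonal: unmatched
#' overhang within the overlap counts as mismatch.
#'
#' @param members read ids of the cluster (or a `read_clusters` object with
#'   `cluster_id`).
#' @param reads the `tagged_reads`.
#' @param min_hit_length minimal hit length in bp (default 50).
#' @param max_pairs_per_species cap on evaluated pairs per species
#'   (deterministic, evenly strided subsample).
#' @param cluster_id cluster to use when `members` is a `read_clusters`.
#' @return data frame: `species`, `n_reads`, `n_pairs_hit`,
#'   `mean_similarity` (`NA` for species with fewer than 2 reads).
#' @export
species_pairwise_similarity <- function(members, reads, min_hit_length = 50,
                                        max_pairs_per_species = 20000,
                                        cluster_id = NULL) {
  if (inherits(members, "read_clusters")) {
    stopifnot(!is.null(cluster_id))
    members <- members$members[[cluster_id]]
  }
  sub <- reads[match(members, reads$read_id), , drop = FALSE]
  out <- list()
  for (sp in sort(unique(sub$species))) {
    ix <- which(sub$species == sp)
    if (length(ix) < 2) {
      out[[sp]] <- data.frame(species = sp, n_reads = length(ix),
                              n_pairs_hit = 0L, mean_similarity = NA_real_,
                              stringsAsFactors = FALSE)
      next
    }
    pr <- utils::combn(ix, 2)
    if (ncol(pr) > max_pairs_per_species) {
      sel <- unique(round(seq(1, ncol(pr),
                              length.out = max_pairs_per_species)))
      pr <- pr[, sel, drop = FALSE]
    }
    bh <- cpp_best_overlap_hits(sub$sequence, pr[1, ], pr[2, ],
                                5L, 4L, as.integer(min_hit_length))
    ok <- bh$found
    out[[sp]] <- data.frame(
      species = sp, n_reads = length(ix), n_pairs_hit = sum(ok),
      mean_similarity = if (any(ok)) mean(bh$adjusted_similarity[ok])
                        else NA_real_,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-read Hs/Ho intra- versus inter-specific hit-frequency ratios
#'
#' Within each repeat group (reads pooled from clusters sharing an
#' annotation), each read's `Hs` is the number of distinct same-species reads
#' it hits divided by the number of same-species reads in the group excluding
#' itself, and `Ho` is the number of distinct other-species reads it hits
#' divided by the number of other-species reads in the group.  Dividing hit
#' counts by group sizes normalizes for varying repeat copy numbers between
#' species, so conserved repeats give ratios near 1 (0 on the log10 scale)
#' and species-private variants give ratios far above 1.  Hits are counted as
#' distinct partner reads, and self-hits are excluded throughout.
#'
#' @param groups named list: repeat group -> character vector of read ids.
#' @param hits `similarity_hits` computed over all pooled reads at the
#'   comparative thresholds (90% / 55 bp).
#' @param reads the `tagged_reads` (for species tags).
#' @param species_subset optional character vector restricting both the reads
#'   considered and the species against which `Ho` is computed.
#' @return a `hs_ho_records` data frame: `read_id`, `species`,
#'   `repeat_group`, `Hs`, `Ho`, `log10_ratio` (defined only when both are
#'   positive).
#' @export
hs_ho <- function(groups, hits, reads, species_subset = NULL) {
  spec_of <- setNames(reads$species, reads$read_id)
  if (!is.null(species_subset)) {
    if (length(species_subset) < 2)
      stop("species_subset must contain at least 2 species")
  }
  # symmetric partner table once
  pa <- c(hits$read_a, hits$read_b)
  pb <- c(hits$read_b, hits$read_a)
  keep <- pa != pb
  pa <- pa[keep]; pb <- pb[keep]
  out <- list()
  for (g in names(groups)) {
    ids <- groups[[g]]
    sp <- spec_of[ids]
    if (!is.null(species_subset)) {
      ids <- ids[sp %in% species_subset]
      sp <- spec_of[ids]
    }
    if (length(ids) == 0) next
    n_by_sp <- table(sp)
    if (length(n_by_sp) < 2)
      warning("group '", g, "' has a single species; Ho undefined")
    in_g <- pa %in% ids & pb %in% ids
    ga <- pa[in_g]; gb <- pb[in_g]
    pkey <- !duplicated(paste(ga, gb))
    ga <- ga[pkey]; gb <- gb[pkey]
    same <- spec_of[ga] == spec_of[gb]
    hs_cnt <- table(factor(ga[same], levels = ids))
    ho_cnt <- table(factor(ga[!same], levels = ids))
    n_same <- as.numeric(n_by_sp[sp]) - 1
    n_other <- length(ids) - as.numeric(n_by_sp[sp])
    Hs <- ifelse(n_same > 0, as.numeric(hs_cnt) / n_same, NA_real_)
    Ho <- ifelse(n_other > 0, as.numeric(ho_cnt) / n_other, NA_real_)
    lr <- ifelse(!is.na(Hs) & !is.na(Ho) & Hs > 0 & Ho > 0,
                 log10(Hs / Ho), NA_real_)
    out[[g]] <- data.frame(read_id = ids, species = unname(sp),
                           repeat_group = g, Hs = Hs, Ho = Ho,
                           log10_ratio = lr, stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(read_id = character(0), species = character(0),
               repeat_group = character(0), Hs = numeric(0), Ho = numeric(0),
               log10_ratio = numeric(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("hs_ho_records", "data.frame")
  res
}

#' Hs/Ho computation restricted to a subset of species
#'
#' Identical to [hs_ho()] with reads of other species removed and `Ho`
#' computed only against the subset; used to compare repeats within groups
#' of phylogenetically closely related species.
#'
#' @inheritParams hs_ho
#' @export
hs_ho_restricted <- function(groups, hits, reads, species_subset) {
  if (length(species_subset) < 2)
    stop("species_subset must contain at least 2 species")
  hs_ho(groups, hits, reads, species_subset = species_subset)
}

#' Histogram of log10(Hs/Ho) ratios per repeat group
#'
#' Fixed bins of width 0.1 over \[-1, 4\]; out-of-range values are clamped
#' into the edge bins and reported.  Reads with `Hs = 0` or `Ho = 0` are
#' excluded from the histogram and counted separately.
#'
#' @param records `hs_ho_records` from [hs_ho()].
#' @param bin_width bin width in log10 units.
#' @param range histogram range (log10 units).
#' @return list per group: `breaks`, `counts`, `n_defined`, `n_hs_zero`,
#'   `n_ho_zero`, `n_clamped`.
#' @export
hs_ho_histogram <- function(records, bin_width = 0.1, range = c(-1, 4)) {
  out <- list()
  for (g in unique(records$repeat_group)) {
    r <- records[records$repeat_group == g, , drop = FALSE]
    lr <- r$log10_ratio
    defined <- !is.na(lr)
    x <- lr[defined]
    n_clamped <- sum(x < range[1] | x > range[2])
    x <- pmin(pmax(x, range[1]), range[2])
    breaks <- seq(range[1], range[2], by = bin_width)
    counts <- as.integer(table(cut(x, breaks, include.lowest = TRUE)))
    out[[g]] <- list(breaks = breaks, counts = counts,
                     n_defined = sum(defined),
                     n_hs_zero = sum(!is.na(r$Hs) & r$Hs == 0),
                     n_ho_zero = sum(!is.na(r$Ho) & r$Ho == 0 &
                                     !is.na(r$Hs) & r$Hs > 0),
                     n_clamped = n_clamped)
  }
  out
}
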