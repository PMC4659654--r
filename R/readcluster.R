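# Graph-based read clustering: all-to-all similarity search, connected
# components, mate-pair superclusters, cluster filtering, and greedy
# overlap-layout-consensus contigs with per-read masking.

#' All-to-all read similarity search
#'
#' Finds every read pair whose best ungapped local alignment (both
#' orientations) reaches at least `min_identity` percent identity over at
#' least `min_overlap` aligned columns.  Candidate diagonals are located with
#' exact-match k-mer seeds and evaluated exactly; with the default
#' `seed_length = 8` the seeded search provably returns the same hit set as
#' the exhaustive all-diagonal scan for the default 90%/55 bp criterion
#' (a qualifying segment of length L carries at most `floor(L/10)` mismatches
#' and therefore contains an exact match run of at least
#' `ceiling((L - m)/(m + 1)) >= 8` bases for all `L <= 100`).
#'
#' Identity is computed as matches over alignment columns; `N` bases never
#' match.  Per pair and orientation the longest qualifying segment is
#' reported (ties: smallest diagonal, then smallest start).
#'
#' @param reads a `tagged_reads` data frame.
#' @param min_identity minimum percent identity in (0, 100].
#' @param min_overlap minimum alignment length in bp.
#' @param seed_length k-mer seed length (1--15).
#' @param symmetric if `TRUE`, every hit is also reported with the reads
#'   swapped (mirrored spans); default reports each unordered pair once.
#' @return a `similarity_hits` data frame: `read_a`, `read_b`, `orientation`
#'   (`"same"`/`"reverse"`), `identity`, `hit_length` and the 1-based
#'   inclusive spans `start_a`, `end_a`, `start_b`, `end_b` (B spans are on
#'   the forward strand of B).
#' @export
find_similarity_hits <- function(reads, min_identity = 90, min_overlap = 55,
                                 seed_length = 8, symmetric = FALSE) {
  stopifnot(min_identity > 0, min_identity <= 100, min_overlap > 0)
  if (nrow(reads) == 0) return(empty_hits(character(0)))
  df <- cpp_find_hits(reads$sequence, min_identity, as.integer(min_overlap),
                      as.integer(seed_length))
  hits_from_cpp(df, reads$read_id, symmetric)
}

#' Exhaustive all-pairs similarity search (reference implementation)
#'
#' Enumerates every diagonal of every read pair in both orientations and
#' applies the identity/length criterion directly.  Quadratic in segment
#' length per diagonal and therefore only practical for small read sets; it
#' serves as the independent reference that the seeded search is validated
#' against.
#'
#' @inheritParams find_similarity_hits
#' @return see [find_similarity_hits()].
#' @export
all_pairs_hits <- function(reads, min_identity = 90, min_overlap = 55,
                           symmetric = FALSE) {
  stopifnot(min_identity > 0, min_identity <= 100, min_overlap > 0)
  if (nrow(reads) == 0) return(empty_hits(character(0)))
  df <- cpp_all_hits_bruteforce(reads$sequence, min_identity,
                                as.integer(min_overlap))
  hits_from_cpp(df, reads$read_id, symmetric)
}

empty_hits <- function(ids) {
  df <- data.frame(read_a = character(0), read_b = character(0),
                   orientation = character(0), identity = numeric(0),
                   hit_length = integer(0), start_a = integer(0),
                   end_a = integer(0), start_b = integer(0),
                   end_b = integer(0), stringsAsFactors = FALSE)
  class(df) <- c("similarity_hits", "data.frame")
  df
}

hits_from_cpp <- function(df, ids, symmetric) {
  out <- data.frame(read_a = ids[df$a], read_b = ids[df$b],
                    orientation = df$orientation, identity = df$identity,
                    hit_length = df$hit_length, start_a = df$start_a,
                    end_a = df$end_a, start_b = df$start_b, end_b = df$end_b,
                    stringsAsFactors = FALSE)
  if (symmetric && nrow(out)) {
    mirror <- data.frame(read_a = out$read_b, read_b = out$read_a,
                         orientation = out$orientation,
                         identity = out$identity,
                         hit_length = out$hit_length, start_a = out$start_b,
                         end_a = out$end_b, start_b = out$start_a,
                         end_b = out$end_a, stringsAsFactors = FALSE)
    out <- rbind(out, mirror)
  }
  class(out) <- c("similarity_hits", "data.frame")
  out
}

#' Cluster reads as connected components of the similarity graph
#'
#' Clusters are numbered by decreasing size (1 = largest); ties are broken by
#' the lexicographically smallest member read id.  Reads without any hit are
#' reported separately as singletons.  Per-species read counts are derived
#' from the species tags.
#'
#' @param hits a `similarity_hits` data frame over `reads`.
#' @param reads the `tagged_reads` the hits were computed from.
#' @return a `read_clusters` object: list with `clusters` (data frame with
#'   `cluster_id`, `n_reads`, `proportion` and one `n_<code>` count column
#'   per species), `members` (list of read-id vectors per cluster),
#'   `singletons`, `total_reads` and `annotation` (`NA` until assigned).
#' @export
build_clusters <- function(hits, reads) {
  unknown <- setdiff(unique(c(hits$read_a, hits$read_b)), reads$read_id)
  if (length(unknown))
    stop("hits reference reads absent from the read set: ",
         paste(head(unknown, 5), collapse = ", "))
  idx <- seq_len(nrow(reads))
  names(idx) <- reads$read_id
  g <- igraph::make_empty_graph(n = nrow(reads), directed = FALSE)
  if (nrow(hits))
    g <- igraph::add_edges(g, rbind(idx[hits$read_a], idx[hits$read_b]))
  comp <- igraph::components(g)
  sizes <- comp$csize
  clustered <- which(sizes[comp$membership] >= 2)
  singleton_ids <- reads$read_id[sizes[comp$membership] == 1]

  keep <- which(sizes >= 2)
  # deterministic numbering: size desc, then smallest member read id
  min_member <- vapply(keep, function(k)
    min(reads$read_id[comp$membership == k]), character(1))
  ord <- keep[order(-sizes[keep], min_member)]
  members <- lapply(ord, function(k)
    sort(reads$read_id[comp$membership == k]))
  n_cl <- length(members)
  species <- sort(unique(reads$species))
  counts <- matrix(0L, nrow = n_cl, ncol = length(species),
                   dimnames = list(NULL, species))
  spec_by_read <- setNames(reads$species, reads$read_id)
  for (i in seq_len(n_cl)) {
    tab <- table(spec_by_read[members[[i]]])
    counts[i, names(tab)] <- as.integer(tab)
  }
  clusters <- data.frame(cluster_id = seq_len(n_cl),
                         n_reads = lengths(members),
                         proportion = lengths(members) / nrow(reads),
                         stringsAsFactors = FALSE)
  for (sp in species) clusters[[paste0("n_", sp)]] <- counts[, sp]
  clusters$annotation <- NA_character_
  structure(list(clusters = clusters, members = members,
                 singletons = singleton_ids, total_reads = nrow(reads),
                 species = species),
            class = "read_clusters")
}

#' @export
print.read_clusters <- function(x, ...) {
  cat("read_clusters:", nrow(x$clusters), "clusters,",
      length(x$singletons), "singletons,", x$total_reads, "reads\n")
  print(head(x$clusters, 10), ...)
  invisible(x)
}

#' Join clusters into superclusters via mate-pair links
#'
#' Clusters are merged (union-find closure) whenever at least
#' `min_shared_pairs` read pairs have one mate in each cluster, identifying
#' repeats whose parts were split between clusters.
#'
#' @param clusters a `read_clusters` object.
#' @param reads the underlying `tagged_reads` (mate metadata required).
#' @param min_shared_pairs minimum number of spanning pairs (use `Inf` to
#'   disable merging).
#' @return data frame with `cluster_id` and `supercluster` (1-based ids,
#'   numbered by decreasing total read count).
#' @export
link_superclusters <- function(clusters, reads, min_shared_pairs = 2) {
  cl_of <- cluster_membership(clusters)
  n_cl <- nrow(clusters$clusters)
  mates <- reads[!is.na(reads$mate_id), c("read_id", "mate_id")]
  ca <- cl_of[mates$read_id]
  cb <- cl_of[mates$mate_id]
  ok <- !is.na(ca) & !is.na(cb) & ca != cb
  g <- igraph::make_empty_graph(n = n_cl, directed = FALSE)
  if (any(ok) && is.finite(min_shared_pairs)) {
    lo <- pmin(ca[ok], cb[ok])
    hi <- pmax(ca[ok], cb[ok])
    tab <- table(paste(lo, hi))  # each pair counted twice (both mates)
    npairs <- as.integer(tab) / 2
    linked <- names(tab)[npairs >= min_shared_pairs]
    if (length(linked)) {
      ends <- do.call(rbind, strsplit(linked, " "))
      g <- igraph::add_edges(g, rbind(as.integer(ends[, 1]),
                                      as.integer(ends[, 2])))
    }
  }
  comp <- igraph::components(g)
  # number superclusters by decreasing summed read count, ties by smallest
  # member cluster id
  size_by_sc <- tapply(clusters$clusters$n_reads, comp$membership, sum)
  min_cl <- tapply(clusters$clusters$cluster_id, comp$membership, min)
  ord <- order(-as.numeric(size_by_sc), as.integer(min_cl))
  renum <- integer(length(size_by_sc))
  renum[as.integer(names(size_by_sc))[ord]] <- seq_along(ord)
  data.frame(cluster_id = clusters$clusters$cluster_id,
             supercluster = renum[comp$membership],
             stringsAsFactors = FALSE)
}

cluster_membership <- function(clusters) {
  ids <- rep(clusters$clusters$cluster_id, lengths(clusters$members))
  setNames(ids, unlist(clusters$members))
}

#' Filter clusters by abundance
#'
#' Two modes mirror the two analysis designs: per-species runs retain
#' clusters representing at least 0.01% of the genome (`genome_fraction`),
#' comparative runs retain clusters holding at least 0.005% of the analysed
#' reads (`read_fraction`).  Cluster proportions of analysed reads are used
#' as the genome-proportion proxy.
#'
#' @param clusters a `read_clusters` object.
#' @param mode `"genome_fraction"` or `"read_fraction"`.
#' @param genome_threshold retention threshold for `genome_fraction` mode
#'   (default 1e-4, i.e. 0.01%).
#' @param read_threshold retention threshold for `read_fraction` mode
#'   (default 5e-5, i.e. 0.005%).
#' @return list with `retained` (a `read_clusters` object), `n_retained` and
#'   `n_discarded`.
#' @export
filter_clusters <- function(clusters,
                            mode = c("genome_fraction", "read_fraction"),
                            genome_threshold = 1e-4, read_threshold = 5e-5) {
  mode <- match.arg(mode)
  thr <- if (mode == "genome_fraction") genome_threshold else read_threshold
  keep <- clusters$clusters$proportion >= thr
  retained <- clusters
  retained$clusters <- clusters$clusters[keep, , drop = FALSE]
  rownames(retained$clusters) <- NULL
  retained$members <- clusters$members[keep]
  list(retained = retained, n_retained = sum(keep),
       n_discarded = sum(!keep))
}

# ---------------------------------------------------------------------------
# Greedy overlap-layout-consensus contigs

#' Assemble cluster reads into contig layouts
#'
#' Greedy overlap-layout-consensus: the read with most hits seeds the layout,
#' remaining reads are placed breadth-first at the offset and strand implied
#' by their best similarity hit to an already placed read, and the consensus
#' is the per-column majority base.  Each read's longest segment agreeing
#' with the consensus at `min_identity` is its aligned core; the remainder is
#' recorded as masked.  Masked read tails mark positions where reads leave
#' the repeat (e.g. element/flank junctions).  Deterministic for a fixed
#' read ordering.
#'
#' @param members read ids of one cluster (>= 2 reads), or a `read_clusters`
#'   object together with `cluster_id`.
#' @param reads the `tagged_reads`.
#' @param hits `similarity_hits` covering the cluster (only intra-cluster
#'   hits are used).
#' @param cluster_id cluster to assemble when `members` is a `read_clusters`.
#' @param min_identity identity threshold for the aligned core.
#' @param min_core minimum core length; reads without a qualifying core are
#'   reported unplaced.
#' @return list of `contig_layout` objects, largest first.  Each has
#'   `consensus` (character), `layout` (data frame: `read_id`, `strand`,
#'   `offset` 0-based, `length`, `core_start`, `core_end`, `core_identity`;
#'   core coordinates are 1-based in contig-oriented read space) and
#'   `unplaced` (read ids).
#' @export
build_contigs <- function(members, reads, hits, cluster_id = NULL,
                          min_identity = 90, min_core = 20) {
  if (inherits(members, "read_clusters")) {
    stopifnot(!is.null(cluster_id))
    members <- members$members[[cluster_id]]
  }
  if (length(members) < 2) stop("a cluster needs at least 2 reads")
  sub <- reads[match(members, reads$read_id), , drop = FALSE]
  h <- hits[hits$read_a %in% members & hits$read_b %in% members, ,
            drop = FALSE]
  idx <- setNames(seq_along(members), members)
  la <- nchar(sub$sequence)

  # edge list with placement geometry, deduplicated per unordered pair
  # (keep the longest hit per pair)
  if (nrow(h)) {
    ai <- idx[h$read_a]
    bi <- idx[h$read_b]
    key <- paste(pmin(ai, bi), pmax(ai, bi))
    h <- h[order(key, -h$hit_length), , drop = FALSE]
    ai <- idx[h$read_a]; bi <- idx[h$read_b]
    dup <- duplicated(paste(pmin(ai, bi), pmax(ai, bi)))
    h <- h[!dup, , drop = FALSE]
    ai <- idx[h$read_a]; bi <- idx[h$read_b]
  } else {
    ai <- bi <- integer(0)
  }

  n <- length(members)
  adj <- vector("list", n)
  if (length(ai)) {
    ec <- seq_along(ai)
    for (lst in split(ec, ai)) adj[[ai[lst[1]]]] <-
        c(adj[[ai[lst[1]]]], lst)
    for (lst in split(ec, bi)) adj[[bi[lst[1]]]] <-
        c(adj[[bi[lst[1]]]], lst)
  }
  deg <- lengths(adj)

  placed <- rep(NA_integer_, n)   # contig index
  offset <- rep(NA_integer_, n)   # 0-based contig column of oriented pos 1
  strand <- rep(NA_integer_, n)   # +1 forward, -1 reverse-complement
  contigs <- list()
  remaining <- which(deg > 0)

  while (length(remaining)) {
    seed <- remaining[order(-deg[remaining], members[remaining])][1]
    ci <- length(contigs) + 1L
    placed[seed] <- ci
    offset[seed] <- 0L
    strand[seed] <- 1L
    queue <- seed
    comp <- seed
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      for (e in adj[[v]]) {
        u <- if (ai[e] == v) bi[e] else ai[e]
        if (!is.na(placed[u])) next
        # geometry: oriented start of the hit on each side
        same <- h$orientation[e] == "same"
        if (ai[e] == v) {
          sv <- h$start_a[e]; ev <- h$end_a[e]
          su <- h$start_b[e]; eu <- h$end_b[e]
        } else {
          sv <- h$start_b[e]; ev <- h$end_b[e]
          su <- h$start_a[e]; eu <- h$end_a[e]
        }
        s_u <- if (same) strand[v] else -strand[v]
        qv <- if (strand[v] == 1L) sv else la[v] - ev + 1L
        qu <- if (s_u == 1L) su else la[u] - eu + 1L
        placed[u] <- ci
        strand[u] <- s_u
        offset[u] <- offset[v] + (qv - qu)
        queue <- c(queue, u)
        comp <- c(comp, u)
      }
    }
    remaining <- setdiff(remaining, comp)
    contigs[[ci]] <- sort(comp)
  }
  unplaced <- members[is.na(placed)]

  out <- list()
  for (ci in seq_along(contigs)) {
    ix <- contigs[[ci]]
    off <- offset[ix] - min(offset[ix])
    lens <- la[ix]
    clen <- max(off + lens)
    seqs <- sub$sequence[ix]
    strands <- strand[ix]
    ones <- rep(1L, length(ix))
    cons1 <- cpp_consensus(seqs, off, strands, ones, lens, clen)
    cores <- cpp_core_spans(cons1, seqs, off, strands, min_identity,
                            as.integer(min_core))
    cons2 <- cpp_consensus(seqs, off, strands,
                           pmax(cores$core_start, 1L), cores$core_end, clen)
    cores2 <- cpp_core_spans(cons2, seqs, off, strands, min_identity,
                             as.integer(min_core))
    # trim columns never covered by a core
    covered <- rep(FALSE, clen)
    for (i in seq_along(ix)) {
      if (cores2$core_end[i] >= cores2$core_start[i] &&
          cores2$core_start[i] >= 1) {
        c0 <- off[i] + cores2$core_start[i]
        c1 <- off[i] + cores2$core_end[i]
        covered[max(1, c0):min(clen, c1)] <- TRUE
      }
    }
    if (any(covered)) {
      first <- which(covered)[1]
      last <- max(which(covered))
      cons2 <- substr(cons2, first, last)
      off <- off - (first - 1L)
    }
    layout <- data.frame(read_id = members[ix],
                         strand = ifelse(strands == 1L, "+", "-"),
                         offset = off, length = lens,
                         core_start = cores2$core_start,
                         core_end = cores2$core_end,
                         core_identity = cores2$core_identity,
                         stringsAsFactors = FALSE)
    out[[ci]] <- structure(list(consensus = cons2, layout = layout,
                                unplaced = character(0)),
                           class = "contig_layout")
  }
  ord <- order(-vapply(out, function(cg) nrow(cg$layout), integer(1)))
  out <- out[ord]
  if (length(out)) out[[1]]$unplaced <- unplaced
  out
}

#' Export a cluster's similarity graph
#'
#' Nodes are reads (with a `species` attribute), edges are similarity hits
#' (with an `identity` attribute); written as GraphML for external viewers.
#'
#' @param members read ids of the cluster, or a `read_clusters` object with
#'   `cluster_id`.
#' @param hits `similarity_hits` over the reads.
#' @param reads the `tagged_reads`.
#' @param path output file; when `NULL` the igraph object is returned.
#' @param cluster_id cluster to export when `members` is a `read_clusters`.
#' @return the igraph object, invisibly when written to file.
#' @export
export_graph <- function(members, hits, reads, path = NULL,
                         cluster_id = NULL) {
  if (inherits(members, "read_clusters")) {
    stopifnot(!is.null(cluster_id))
    members <- members$members[[cluster_id]]
  }
  if (length(members) == 0) stop("cluster is empty")
  sub <- reads[match(members, reads$read_id), , drop = FALSE]
  h <- hits[hits$read_a %in% members & hits$read_b %in% members, ,
            drop = FALSE]
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = h$read_a, to = h$read_b,
                   identity = h$identity, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = sub$read_id, species = sub$species,
                          stringsAsFactors = FALSE))
  if (is.null(path)) return(g)
  igraph::write_graph(g, path, format = "graphml")
  invisible(g)
}
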