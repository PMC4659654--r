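# Solo-LTR estimation: detect LTR_3'end/5'UTR junctions in cluster contigs,
# validate them (TG/CA terminus, PBS motif), extract 30 nt tags, count
# junction-spanning reads and compute Rsf = (Lx - LU)/LU.
#
# Accounting: every full-length element contributes one LTR_3'end/5'UTR
# junction (counted in LU) via its 5' LTR and one LTR_3'end/flank junction
# (counted in Lx) via its 3' LTR; a solo-LTR contributes one flank junction
# only.  Hence E[Lx] ~ N_full + N_solo, E[LU] ~ N_full and
# E[Rsf] ~ N_solo/N_full, with Rsf = 0 when all elements are full length.

#' Detect junction candidates from contig masking profiles
#'
#' Insertion sites of mobile elements into unrelated sequence appear in
#' cluster contigs as abrupt increases in the proportion of masked read
#' tails: reads physically continue past the boundary but their alignment to
#' the consensus ends there.  For each contig column the masked fraction is
#' the number of reads whose masked suffix starts within `window` columns of
#' the column, over the number of reads covering it; a candidate boundary is
#' called at the modal onset column of every region where this fraction
#' reaches `high` after staying below `low` upstream.
#'
#' The default `high = 0.25` reflects the layout geometry of LTR elements:
#' reads continuing into the 5'UTR keep aligning while reads continuing into
#' insertion-site flanks are masked, and with the two LTRs of full-length
#' elements either collapsed onto one contig locus or unrolled into two, the
#' flank-read mass at one LTR-end locus is at least about a quarter of the
#' local depth, while background columns stay near zero.
#'
#' @param contig a `contig_layout` from [build_contigs()].
#' @param low,high masked-fraction thresholds.
#' @param window half-width in columns of the onset-mass window.
#' @param min_coverage minimum covering reads at the candidate column.
#' @param min_masked_tail a read's tail counts as masked only if at least
#'   this many masked bases follow its core.
#' @param min_onset_reads minimum reads whose mask starts at the modal
#'   boundary column.
#' @return data frame: `position` (contig column directly after the
#'   boundary, 1-based), `masked_fraction`, `coverage`, `onset_reads`.
#' @export
detect_junction_candidates <- function(contig, low = 0.08, high = 0.25,
                                       window = 5, min_coverage = 5,
                                       min_masked_tail = 10,
                                       min_onset_reads = 3) {
  lay <- contig$layout
  clen <- nchar(contig$consensus)
  empty <- data.frame(position = integer(0), masked_fraction = numeric(0),
                      coverage = integer(0), onset_reads = integer(0))
  placed <- lay$core_end >= lay$core_start & lay$core_start >= 1
  lay <- lay[placed, , drop = FALSE]
  if (nrow(lay) == 0 || clen == 0) return(empty)
  # physical span of each read on the contig (0-based half-open columns)
  sp0 <- lay$offset
  sp1 <- lay$offset + lay$length
  cover <- integer(clen + 1L)
  from <- pmax(sp0, 0L) + 1L
  to <- pmin(sp1, clen)
  okc <- from <= to
  for (i in which(okc)) {
    cover[from[i]] <- cover[from[i]] + 1L
    cover[to[i] + 1L] <- cover[to[i] + 1L] - 1L
  }
  coverage <- cumsum(cover)[seq_len(clen)]
  # masked-suffix onset per read: core_end is in oriented read coordinates,
  # so the first masked base sits at 1-based contig column offset + core_end
  # + 1
  tail_len <- lay$length - lay$core_end
  onset <- lay$offset + lay$core_end + 1L
  onset <- onset[tail_len >= min_masked_tail]
  onset <- onset[onset >= 1 & onset <= clen]
  if (!length(onset)) return(empty)
  onsets <- tabulate(onset, nbins = clen)
  cs <- cumsum(onsets)
  winsum <- function(a, b) {  # inclusive 1-based range sums, clipped
    a <- pmax(a, 1L); b <- pmin(b, clen)
    out <- numeric(length(a))
    ok <- b >= a
    out[ok] <- cs[b[ok]] - c(0, cs)[a[ok]]
    out
  }
  cols <- seq_len(clen)
  mass <- winsum(cols - window, cols + window)
  frac <- ifelse(coverage > 0, mass / coverage, 0)
  before <- winsum(cols - 3L * window, cols - window - 1L) /
    pmax(coverage, 1L)
  hot <- which(frac >= high & coverage >= min_coverage & before <= low)
  if (!length(hot)) return(empty)
  # group nearby hot columns into regions; boundary = modal onset column
  grp <- cumsum(c(TRUE, diff(hot) > 2L * window))
  out <- lapply(split(hot, grp), function(region) {
    lo <- max(1L, min(region) - window)
    hi <- min(clen, max(region) + window)
    o <- onsets[lo:hi]
    b <- lo + which.max(o) - 1L
    data.frame(position = b, masked_fraction = frac[b],
               coverage = coverage[b], onset_reads = max(o))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[res$onset_reads >= min_onset_reads, , drop = FALSE]
}

#' Reverse-complement a contig layout
#'
#' Junctions present themselves as masked read suffixes only in the contig
#' orientation that matches the element's forward strand; scanning both the
#' contig and its reverse complement covers either case.
#'
#' @param contig a `contig_layout`.
#' @return the reverse-complemented `contig_layout`.
#' @export
flip_contig <- function(contig) {
  clen <- nchar(contig$consensus)
  lay <- contig$layout
  new <- lay
  new$strand <- ifelse(lay$strand == "+", "-", "+")
  new$offset <- clen - (lay$offset + lay$length)
  has_core <- lay$core_end >= lay$core_start & lay$core_start >= 1
  new$core_start <- ifelse(has_core, lay$length - lay$core_end + 1L, 0L)
  new$core_end <- ifelse(has_core, lay$length - lay$core_start + 1L, 0L)
  structure(list(consensus = revcomp(contig$consensus), layout = new,
                 unplaced = contig$unplaced),
            class = "contig_layout")
}

#' Validate a junction candidate and extract 30 nt tags
#'
#' A candidate boundary is accepted as an LTR_3'end/5'UTR junction only if
#' (i) the consensus carries the conserved LTR terminal dinucleotide `CA`
#' directly 5' of the boundary and (ii) a primer-binding-site motif (reverse
#' complement of a tRNA 3' end, at least `pbs_min_match` of 12 positions)
#' occurs within the first `pbs_window` bp of the downstream consensus.
#' Thirty-nucleotide tags are extracted directly adjacent to the boundary:
#' the LTR_3'end tag ends with the `CA` terminus and the 5'UTR tag starts
#' the downstream region.
#'
#' @param candidate_position contig column directly after the boundary
#'   (1-based), as returned by [detect_junction_candidates()].
#' @param contig the `contig_layout`.
#' @param trna_motifs character vector of tRNA 3'-end 12-mers (default: the
#'   bundled initiator-Met motif, matching the simulator's PBS).
#' @param tag_length tag length in nt (default 30).
#' @param pbs_window search window for the PBS in bp.
#' @param pbs_min_match minimum matching positions of the 12-mer.
#' @param shift_tolerance candidate boundaries are allowed to be off by up to
#'   this many columns; the nearest shifted position passing both criteria
#'   is used (masking onsets scatter by a base or two around the true
#'   boundary under sequencing errors).
#' @param element_label label carried into the model.
#' @return an `ltr_junction_model` list (`element_label`, `ltr3end_tag`,
#'   `utr_tag`, `boundary`, `tg_ca_ok`, `pbs_ok`, `accepted`, `reason`).
#'   Models are accepted only when both criteria hold and both tags are
#'   extractable ("tag-untestable" otherwise).
#' @export
validate_junction <- function(candidate_position, contig,
                              trna_motifs = DEFAULT_TRNA_MOTIFS,
                              tag_length = 30, pbs_window = 30,
                              pbs_min_match = 10, shift_tolerance = 2,
                              element_label = NA_character_) {
  cons <- contig$consensus
  shifts <- c(0, as.vector(rbind(seq_len(shift_tolerance),
                                 -seq_len(shift_tolerance))))
  model <- NULL
  for (s in shifts) {
    m <- validate_junction_at(candidate_position + s, cons, trna_motifs,
                              tag_length, pbs_window, pbs_min_match,
                              element_label)
    if (is.null(model)) model <- m
    if (m$accepted) return(m)
  }
  model
}

validate_junction_at <- function(b, cons, trna_motifs, tag_length,
                                 pbs_window, pbs_min_match, element_label) {
  model <- list(element_label = element_label, ltr3end_tag = NA_character_,
                utr_tag = NA_character_, boundary = b, tg_ca_ok = FALSE,
                pbs_ok = FALSE, accepted = FALSE, reason = "")
  class(model) <- "ltr_junction_model"
  if (b - tag_length < 1 || b + tag_length - 1 > nchar(cons)) {
    model$reason <- "tag-untestable"
    return(model)
  }
  model$tg_ca_ok <- substr(cons, b - 2, b - 1) == "CA"
  down <- substr(cons, b, b + pbs_window - 1)
  model$pbs_ok <- any(vapply(trna_motifs, function(m)
    motif_best_match(revcomp(m), down) >= pbs_min_match, logical(1)))
  if (!model$tg_ca_ok) {
    model$reason <- "tg_ca"
    return(model)
  }
  if (!model$pbs_ok) {
    model$reason <- "pbs"
    return(model)
  }
  model$ltr3end_tag <- substr(cons, b - tag_length, b - 1)
  model$utr_tag <- substr(cons, b, b + tag_length - 1)
  model$accepted <- TRUE
  model
}

# best ungapped match count of `motif` over all placements inside `window`
motif_best_match <- function(motif, window) {
  lm <- nchar(motif)
  lw <- nchar(window)
  if (lw < lm) return(0L)
  mv <- strsplit(motif, "")[[1]]
  wv <- strsplit(window, "")[[1]]
  best <- 0L
  for (o in 0:(lw - lm)) {
    m <- sum(mv == wv[(o + 1):(o + lm)])
    if (m > best) best <- m
  }
  best
}

#' Extract validated junction models from contigs
#'
#' Runs candidate detection and validation over a list of contigs, scanning
#' both contig orientations (the orientation of an assembled repeat relative
#' to the element is arbitrary), and deduplicates models with identical tag
#' pairs (the two LTR loci of one element yield the same tags).
#'
#' @param contigs list of `contig_layout` objects.
#' @param ... passed to [detect_junction_candidates()] and
#'   [validate_junction()] (matched by name).
#' @param element_label label for the models.
#' @param trna_motifs tRNA 3'-end motifs for PBS validation.
#' @return list with `models` (accepted `ltr_junction_model`s) and
#'   `rejected` (data frame of rejected candidates with reasons).
#' @export
extract_junction_models <- function(contigs, element_label = NA_character_,
                                    trna_motifs = DEFAULT_TRNA_MOTIFS, ...) {
  dots <- list(...)
  det_args <- dots[names(dots) %in%
    names(formals(detect_junction_candidates))]
  val_args <- dots[names(dots) %in% names(formals(validate_junction))]
  models <- list()
  rejected <- list()
  for (ci in seq_along(contigs)) {
    for (ori in c("+", "-")) {
      cg <- if (ori == "+") contigs[[ci]] else flip_contig(contigs[[ci]])
      cands <- do.call(detect_junction_candidates, c(list(cg), det_args))
      for (k in seq_len(nrow(cands))) {
        m <- do.call(validate_junction,
                     c(list(cands$position[k], cg,
                            trna_motifs = trna_motifs,
                            element_label = element_label), val_args))
        if (m$accepted) {
          models[[length(models) + 1L]] <- m
        } else {
          rejected[[length(rejected) + 1L]] <- data.frame(
            contig = ci, orientation = ori, position = cands$position[k],
            reason = m$reason, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(models)) {
    keys <- vapply(models, function(m) paste(m$ltr3end_tag, m$utr_tag),
                   character(1))
    models <- models[!duplicated(keys)]
  }
  list(models = models,
       rejected = if (length(rejected)) do.call(rbind, rejected) else
         data.frame(contig = integer(0), orientation = character(0),
                    position = integer(0), reason = character(0),
                    stringsAsFactors = FALSE))
}

#' Count junction-spanning reads for one junction model
#'
#' A read is classified when it has a significant hit (at least
#' `min_identity` percent over `min_hit` bp) to the LTR_3'end tag and at
#' least `lx_flank` bp of read remain downstream of the tag: it counts in
#' `LU` when the 5'UTR tag matches directly adjacent in proper order and
#' orientation, and in `Lx` when that downstream region has no similarity to
#' the 5'UTR tag.  Demanding the same downstream window for both categories
#' makes LTR/5'UTR junctions and LTR/insertion-site junctions equally
#' detectable per read, so expected counts satisfy
#' `E[Lx]/E[LU] = (N_full + N_solo)/N_full`.  Reverse-complement reads are
#' handled by orientation normalization; each read counts at most once, with
#' LU taking precedence.
#'
#' @param model an accepted `ltr_junction_model`.
#' @param reads `tagged_reads` of one species.
#' @param min_identity percent identity threshold (default 90).
#' @param min_hit minimum hit length in bp (default 27).
#' @param lx_flank minimum downstream region for Lx calls (default 30).
#' @return list with integer counts `LU` and `Lx`.
#' @export
count_junction_reads <- function(model, reads, min_identity = 90,
                                 min_hit = 27, lx_flank = 30) {
  if (!isTRUE(model$accepted)) stop("model was not accepted")
  cat_ <- cpp_tag_scan(reads$sequence, model$ltr3end_tag, model$utr_tag,
                       min_identity, as.integer(min_hit),
                       as.integer(lx_flank), 3L)
  list(LU = sum(cat_ == 1L), Lx = sum(cat_ == 2L))
}

#' Solo-LTR to full-length ratio from junction read counts
#'
#' `Rsf = (Lx - LU) / LU`.  0 indicates that all elements are full length;
#' values above 0 reflect an excess of LTR_3'end insertion-site reads over
#' LTR/5'UTR junction reads, i.e. the presence of solo-LTRs.  Undefined
#' (flagged, `Rsf = NA`) when `LU = 0`.
#'
#' @param LU count of LTR_3'end/5'UTR junction reads.
#' @param Lx count of LTR_3'end insertion-site reads.
#' @param species_code,element_label labels carried through.
#' @return data frame: `species`, `element`, `LU`, `Lx`, `Rsf`, `defined`.
#' @export
compute_rsf <- function(LU, Lx, species_code = NA_character_,
                        element_label = NA_character_) {
  defined <- LU > 0
  data.frame(species = species_code, element = element_label,
             LU = as.integer(LU), Lx = as.integer(Lx),
             Rsf = ifelse(defined, (Lx - LU) / LU, NA_real_),
             defined = defined, stringsAsFactors = FALSE)
}

#' End-to-end Rsf estimation from a read set
#'
#' Clusters a subsample of the reads, assembles the largest clusters,
#' extracts validated LTR_3'end/5'UTR junction models and counts junction
#' reads over the full read set.  One result row per junction model per
#' species; with several models the row with the largest LU per species is
#' first.
#'
#' @param reads `tagged_reads` (one or more species).
#' @param cluster_sample number of reads used for junction-model discovery.
#' @param n_clusters number of largest clusters assembled.
#' @param min_identity,min_overlap,seed_length clustering thresholds.
#' @param element_label label for the discovered models.
#' @param ... passed to [extract_junction_models()].
#' @return data frame of [compute_rsf()] rows (empty when no model was
#'   validated).
#' @export
estimate_rsf <- function(reads, cluster_sample = 1500, n_clusters = 2,
                         min_identity = 90, min_overlap = 55,
                         seed_length = 8, element_label = "LTR_element",
                         ...) {
  n <- nrow(reads)
  sel <- if (n > cluster_sample)
    unique(round(seq(1, n, length.out = cluster_sample))) else seq_len(n)
  sub <- reads[sel, , drop = FALSE]
  hits <- find_similarity_hits(sub, min_identity, min_overlap, seed_length)
  clusters <- build_clusters(hits, sub)
  n_cl <- min(n_clusters, nrow(clusters$clusters))
  models <- list()
  for (k in seq_len(n_cl)) {
    contigs <- build_contigs(clusters, sub, hits, cluster_id = k,
                             min_identity = min_identity)
    em <- extract_junction_models(contigs, element_label = element_label,
                                  ...)
    models <- c(models, em$models)
  }
  if (length(models)) {
    keys <- vapply(models, function(m) paste(m$ltr3end_tag, m$utr_tag),
                   character(1))
    models <- models[!duplicated(keys)]
  }
  out <- list()
  for (sp in sort(unique(reads$species))) {
    rsp <- reads[reads$species == sp, , drop = FALSE]
    rows <- lapply(models, function(m) {
      cnt <- count_junction_reads(m, rsp)
      compute_rsf(cnt$LU, cnt$Lx, sp, m$element_label)
    })
    if (length(rows)) {
      rows <- do.call(rbind, rows)
      rows <- rows[order(-rows$LU), , drop = FALSE]
      out[[sp]] <- rows
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(species = character(0), element = character(0),
               LU = integer(0), Lx = integer(0), Rsf = numeric(0),
               defined = logical(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}
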