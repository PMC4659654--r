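# Multi-species repeat-genome simulator: the ground-truth harness for every
# estimator in the package.  Substitution-only evolution keeps all best local
# alignments gap-free, so alignment-based oracles stay exact.

DEFAULT_PBS <- "TGGTATCAGAGC"  # primer binding site, complementary to the
                               # 3' end of an initiator-Met tRNA
DEFAULT_TRNA_MOTIFS <- c(iMet = "GCTCTGATACCA")  # revcomp(DEFAULT_PBS)

#' Random DNA sequence
#' @param n length in bp.
#' @param gc GC content (default 0.4).
#' @return a single character string.
#' @export
random_dna <- function(n, gc = 0.4) {
  if (n <= 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)  # A C G T
  idx <- sample.int(4L, n, replace = TRUE, prob = p)
  rawToChar(as.raw(c(65L, 67L, 71L, 84L))[idx])
}

# apply random substitutions at a per-site rate; each hit site is replaced by
# a base drawn uniformly from the three alternatives
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  n <- nchar(seq)
  k <- rbinom(1L, n, rate)
  if (k == 0L) return(seq)
  pos <- sample.int(n, k)
  r <- charToRaw(seq)
  bases <- as.raw(c(65L, 67L, 71L, 84L))
  for (i in seq_len(k)) {
    old <- r[pos[i]]
    alt <- bases[bases != old]
    r[pos[i]] <- alt[sample.int(3L, 1L)]
  }
  rawToChar(r)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# resolve a per-species scalar-or-named-vector field
.per_species <- function(x, code, default = 0) {
  if (is.null(x)) return(default)
  if (is.null(names(x))) return(unname(x[1]))
  if (code %in% names(x)) return(unname(x[[code]]))
  default
}

#' Specify a simulated repeat family
#'
#' @param family_id unique family name.
#' @param kind `"ltr_retrotransposon"`, `"satellite"` or `"dispersed_other"`.
#' @param unit_length element length (ltr/dispersed kinds) or satellite
#'   monomer length, in bp.
#' @param ltr_length LTR length in bp (ltr kind only); must satisfy
#'   `unit_length > 2 * ltr_length`.
#' @param copies integer copy number, a scalar or a named vector per species
#'   code.  For satellites this is the number of monomers.
#' @param solo_fraction probability that an inserted LTR element is reduced to
#'   a solo-LTR (single LTR retained, internal region and second LTR excised);
#'   scalar or named per species.  Only meaningful for the ltr kind.
#' @param divergence expected per-site substitution fraction applied
#'   independently to every copy (scalar or named per species), in \[0, 0.3\].
#' @param lineage_divergence substitutions applied once per species to the
#'   family consensus before per-copy divergence; models species-private
#'   sequence variants shared by all copies within a species.
#' @param monomers_per_array for satellites, the expected number of tandem
#'   monomers per array (copies are grouped into
#'   `ceiling(copies / monomers_per_array)` arrays).
#' @param repeat_class hierarchical class label (default derived from kind),
#'   e.g. `"LTR/Ty3-gypsy/OgreLike"` or `"satellite/SatA"`.
#' @param pbs primer-binding-site sequence placed 3 bp downstream of the
#'   5' LTR (ltr kind).
#' @return a `sim_family` specification list.
#' @export
sim_family <- function(family_id,
                       kind = c("ltr_retrotransposon", "satellite",
                                "dispersed_other"),
                       unit_length, ltr_length = NULL, copies = 100,
                       solo_fraction = 0, divergence = 0.02,
                       lineage_divergence = 0, monomers_per_array = 500,
                       repeat_class = NULL, pbs = DEFAULT_PBS) {
  kind <- match.arg(kind)
  if (kind == "ltr_retrotransposon") {
    if (is.null(ltr_length)) stop("ltr_length required for ltr kind")
    if (unit_length <= 2 * ltr_length)
      stop("invalid family '", family_id,
           "': unit_length must exceed 2 * ltr_length")
    if (unit_length - 2 * ltr_length < nchar(pbs) + 6)
      stop("internal region too short for the PBS")
  }
  if (any(divergence < 0 | divergence > 0.3))
    stop("divergence must be in [0, 0.3]")
  if (any(solo_fraction < 0 | solo_fraction > 1))
    stop("solo_fraction must be in [0, 1]")
  if (is.null(repeat_class)) {
    repeat_class <- switch(kind,
      ltr_retrotransposon = paste0("LTR/", family_id),
      satellite = paste0("satellite/", family_id),
      dispersed_other = paste0("DNA/", family_id))
  }
  structure(list(family_id = family_id, kind = kind,
                 unit_length = as.integer(unit_length),
                 ltr_length = if (is.null(ltr_length)) NA_integer_
                              else as.integer(ltr_length),
                 copies = copies, solo_fraction = solo_fraction,
                 divergence = divergence,
                 lineage_divergence = lineage_divergence,
                 monomers_per_array = monomers_per_array,
                 repeat_class = repeat_class, pbs = pbs),
            class = "sim_family")
}

#' Generate the ancestral repeat library
#'
#' Each LTR element is built as `LTR + internal + LTR` with identical LTRs
#' starting with `TG` and ending with `CA`, and a PBS motif placed 3 bp
#' downstream of the 5' LTR; satellite and dispersed families are random
#' sequences of the requested unit length.  Deterministic given the seed.
#'
#' @param specs list of [sim_family()] specifications.
#' @param seed integer RNG seed.
#' @return a `repeat_library`: named list with elements `sequence` (ancestral
#'   consensus per family) and `specs`.
#' @export
make_ancestral_library <- function(specs, seed = 1L) {
  if (inherits(specs, "sim_family")) specs <- list(specs)
  ids <- vapply(specs, `[[`, character(1), "family_id")
  if (anyDuplicated(ids)) stop("family_ids must be unique")
  set.seed(seed)
  seqs <- setNames(vector("list", length(specs)), ids)
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    if (sp$kind == "ltr_retrotransposon") {
      ltr <- paste0("TG", random_dna(sp$ltr_length - 4L), "CA")
      internal_len <- sp$unit_length - 2L * sp$ltr_length
      internal <- paste0(random_dna(3L), sp$pbs,
                         random_dna(internal_len - 3L - nchar(sp$pbs)))
      seqs[[i]] <- paste0(ltr, internal, ltr)
    } else {
      seqs[[i]] <- random_dna(sp$unit_length)
    }
  }
  structure(list(sequence = seqs, specs = setNames(specs, ids)),
            class = "repeat_library")
}

#' Build one simulated species genome with known repeat composition
#'
#' Every copy of each family is independently mutated at the family's
#' divergence rate (substitutions only); LTR-element copies become solo-LTRs
#' with the specified probability (one LTR retained, internal region and the
#' second LTR cleanly excised); satellite monomer copies are grouped into
#' tandem arrays.  All repeat units are inserted at uniform random positions
#' into random background sequence so that every element has flanking
#' sequence, and exact insertion coordinates and LTR junction positions are
#' recorded as ground truth.
#'
#' @param library a `repeat_library` from [make_ancestral_library()].
#' @param species_code code of the species to build.
#' @param target_length total genome length in bp; must exceed the summed
#'   repeat length.
#' @param seed integer RNG seed.
#' @param gc background GC content.
#' @return a `sim_genome` list: `sequence`, `species`, `length`, and `truth`
#'   with components `families` (per-family full/solo counts, bp, genome
#'   proportion), `insertions` (0-based half-open coordinates) and
#'   `junctions` (genome positions of LTR_3'end boundaries, typed
#'   `LU` for LTR/5'UTR junctions and `Lx` for LTR/flank junctions).
#' @export
build_species_genome <- function(library, species_code, target_length,
                                 seed = 1L, gc = 0.4) {
  set.seed(seed)
  specs <- library$specs
  units <- list()   # character sequences to insert
  meta <- list()    # per-unit metadata
  fam_rows <- list()
  for (fid in names(specs)) {
    sp <- specs[[fid]]
    n <- as.integer(round(.per_species(sp$copies, species_code, 0)))
    if (n <= 0) next
    div <- .per_species(sp$divergence, species_code, 0)
    ldiv <- .per_species(sp$lineage_divergence, species_code, 0)
    consensus <- library$sequence[[fid]]
    if (ldiv > 0) consensus <- mutate_seq(consensus, ldiv)
    if (sp$kind == "ltr_retrotransposon") {
      sfrac <- .per_species(sp$solo_fraction, species_code, 0)
      is_solo <- runif(n) < sfrac
      ltr <- substr(consensus, 1L, sp$ltr_length)
      copies <- character(n)
      for (i in seq_len(n)) {
        base <- if (is_solo[i]) ltr else consensus
        copies[i] <- mutate_seq(base, div)
      }
      units <- c(units, as.list(copies))
      meta <- c(meta, lapply(seq_len(n), function(i) {
        list(family = fid, type = if (is_solo[i]) "solo" else "full",
             ltr_length = sp$ltr_length, unit_length = sp$unit_length)
      }))
      fam_rows[[fid]] <- data.frame(
        family = fid, kind = sp$kind, repeat_class = sp$repeat_class,
        full_count = sum(!is_solo), solo_count = sum(is_solo),
        bp = sum(nchar(copies)), stringsAsFactors = FALSE)
    } else if (sp$kind == "satellite") {
      n_arrays <- max(1L, as.integer(ceiling(n / sp$monomers_per_array)))
      per_array <- diff(round(seq(0, n, length.out = n_arrays + 1L)))
      arrays <- vapply(per_array, function(m) {
        paste0(vapply(seq_len(m), function(j) mutate_seq(consensus, div),
                      character(1)), collapse = "")
      }, character(1))
      arrays <- arrays[nchar(arrays) > 0]
      units <- c(units, as.list(arrays))
      meta <- c(meta, lapply(arrays, function(a)
        list(family = fid, type = "array", ltr_length = NA_integer_,
             unit_length = sp$unit_length)))
      fam_rows[[fid]] <- data.frame(
        family = fid, kind = sp$kind, repeat_class = sp$repeat_class,
        full_count = n, solo_count = 0L, bp = sum(nchar(arrays)),
        stringsAsFactors = FALSE)
    } else {
      copies <- vapply(seq_len(n), function(i) mutate_seq(consensus, div),
                       character(1))
      units <- c(units, as.list(copies))
      meta <- c(meta, lapply(copies, function(cp)
        list(family = fid, type = "dispersed", ltr_length = NA_integer_,
             unit_length = sp$unit_length)))
      fam_rows[[fid]] <- data.frame(
        family = fid, kind = sp$kind, repeat_class = sp$repeat_class,
        full_count = n, solo_count = 0L, bp = sum(nchar(copies)),
        stringsAsFactors = FALSE)
    }
  }
  repeat_bp <- sum(vapply(units, nchar, integer(1)))
  bg_len <- target_length - repeat_bp
  if (bg_len < length(units) + 1L)
    stop("requested repeat content (", repeat_bp,
         " bp) does not fit the target genome length (", target_length, " bp)")
  background <- random_dna(bg_len, gc = gc)

  nu <- length(units)
  if (nu > 0) {
    ins_at <- sort(sample.int(bg_len - 1L, nu, replace = TRUE))  # after pos
    order_units <- sample.int(nu)  # shuffle family interleaving
    units <- units[order_units]
    meta <- meta[order_units]
    lens <- vapply(units, nchar, integer(1))
    starts0 <- ins_at + cumsum(c(0L, lens[-nu]))  # 0-based start in genome
    pieces <- character(2L * nu + 1L)
    prev <- 0L
    for (i in seq_len(nu)) {
      pieces[2L * i - 1L] <- substr(background, prev + 1L, ins_at[i])
      pieces[2L * i] <- units[[i]]
      prev <- ins_at[i]
    }
    pieces[2L * nu + 1L] <- substr(background, prev + 1L, bg_len)
    genome <- paste0(pieces, collapse = "")
  } else {
    genome <- background
    starts0 <- integer(0)
    lens <- integer(0)
  }

  insertions <- data.frame(
    family = vapply(meta, `[[`, character(1), "family"),
    type = vapply(meta, `[[`, character(1), "type"),
    start = starts0, end = starts0 + lens, stringsAsFactors = FALSE)

  jl <- list()
  for (i in seq_along(meta)) {
    m <- meta[[i]]
    if (m$type == "full") {
      jl[[length(jl) + 1L]] <- data.frame(
        family = m$family, type = c("LU", "Lx"),
        position = c(starts0[i] + m$ltr_length, starts0[i] + m$unit_length),
        stringsAsFactors = FALSE)
    } else if (m$type == "solo") {
      jl[[length(jl) + 1L]] <- data.frame(
        family = m$family, type = "Lx", position = starts0[i] + m$ltr_length,
        stringsAsFactors = FALSE)
    }
  }
  junctions <- if (length(jl)) do.call(rbind, jl) else
    data.frame(family = character(0), type = character(0),
               position = integer(0), stringsAsFactors = FALSE)

  families <- if (length(fam_rows)) do.call(rbind, fam_rows) else
    data.frame(family = character(0), kind = character(0),
               repeat_class = character(0), full_count = integer(0),
               solo_count = integer(0), bp = integer(0),
               stringsAsFactors = FALSE)
  rownames(families) <- NULL
  families$proportion <- families$bp / nchar(genome)

  structure(list(sequence = genome, species = species_code,
                 length = nchar(genome),
                 truth = list(families = families, insertions = insertions,
                              junctions = junctions,
                              background_bp = bg_len)),
            class = "sim_genome")
}

#' Sample tagged paired-end reads from a genome
#'
#' Fragments of uniformly distributed length (`insert_min`--`insert_max`) are
#' drawn with uniform start positions; both 100 nt mates are emitted, the
#' second in reverse-complement orientation.  Sequencing errors are random
#' substitutions at `error_rate` per base.  The read count equals
#' [reads_for_coverage()] rounded to an even number.
#'
#' @param genome a `sim_genome` or a plain character genome sequence.
#' @param coverage fold coverage (> 0).
#' @param read_length read length in nt (default 100).
#' @param insert_min,insert_max fragment length range in bp.
#' @param error_rate per-base substitution error rate.
#' @param seed integer RNG seed.
#' @param species_code species tag; defaults to the `sim_genome` species.
#' @return a `tagged_reads` data frame with provenance columns `frag_start`,
#'   `frag_end` (1-based genome coordinates of the fragment) and `strand`.
#' @export
sample_reads <- function(genome, coverage, read_length = 100L,
                         insert_min = 200L, insert_max = 400L,
                         error_rate = 0.01, seed = 1L, species_code = NULL) {
  if (inherits(genome, "sim_genome")) {
    if (is.null(species_code)) species_code <- genome$species
    genome <- genome$sequence
  }
  if (is.null(species_code)) species_code <- "SIM"
  if (coverage <= 0) stop("coverage must be positive")
  glen <- nchar(genome)
  if (glen <= insert_max) stop("genome length must exceed the maximum insert")
  set.seed(seed)
  n_reads <- reads_for_coverage(glen, coverage, read_length)
  n_pairs <- ceiling(n_reads / 2)
  inserts <- sample.int(insert_max - insert_min + 1L, n_pairs,
                        replace = TRUE) + insert_min - 1L
  starts <- vapply(inserts, function(ins)
    sample.int(glen - ins + 1L, 1L), integer(1))
  fwd <- substring(genome, starts, starts + read_length - 1L)
  rev_src <- substring(genome, starts + inserts - read_length,
                       starts + inserts - 1L)
  rev <- revcomp(rev_src)
  seqs <- c(fwd, rev)
  if (error_rate > 0)
    seqs <- vapply(seqs, mutate_seq, character(1), rate = error_rate,
                   USE.NAMES = FALSE)
  ids <- c(encode_read_name(species_code, seq_len(n_pairs), 1L),
           encode_read_name(species_code, seq_len(n_pairs), 2L))
  mates <- c(encode_read_name(species_code, seq_len(n_pairs), 2L),
             encode_read_name(species_code, seq_len(n_pairs), 1L))
  reads <- tagged_reads(ids, species_code, seqs, mates)
  reads$frag_start <- c(starts, starts)
  reads$frag_end <- c(starts + inserts - 1L, starts + inserts - 1L)
  reads$read_start <- c(starts, starts + inserts - read_length)
  reads$read_end <- c(starts + read_length - 1L, starts + inserts - 1L)
  reads$strand <- rep(c("+", "-"), each = n_pairs)
  reads
}

#' Label reads by the simulator's ground truth
#'
#' Each read is assigned the family whose inserted interval overlaps the
#' largest part of the read span (`"background"` when less than half of the
#' read lies inside any insertion).  Used to annotate clusters in test mode.
#'
#' @param reads reads from [sample_reads()] (provenance columns required).
#' @param genome the `sim_genome` the reads were sampled from.
#' @return character vector of family labels, one per read.
#' @export
annotate_reads_by_truth <- function(reads, genome) {
  ins <- genome$truth$insertions
  if (!all(c("read_start", "read_end") %in% names(reads)))
    stop("reads lack provenance columns; use sample_reads() output")
  n <- nrow(reads)
  labels <- rep("background", n)
  if (nrow(ins) == 0) return(labels)
  ins <- ins[order(ins$start), , drop = FALSE]
  # insertions are disjoint; locate candidate intervals around each read
  idx <- findInterval(reads$read_start - 1L, ins$start)
  rl <- reads$read_end - reads$read_start + 1L
  for (k in c(0L, 1L)) {
    j <- idx + k
    valid <- j >= 1L & j <= nrow(ins)
    ov <- rep(0L, n)
    ov[valid] <- pmax(0L, pmin(reads$read_end[valid], ins$end[j[valid]]) -
                            pmax(reads$read_start[valid] - 1L,
                                 ins$start[j[valid]]))
    better <- ov > rl / 2
    labels[better] <- ins$family[j[better]]
  }
  labels
}

#' Simulate a multi-species panel and pool tagged reads
#'
#' Convenience wrapper: builds one genome per species from a shared ancestral
#' library and samples reads at the given coverage for each, pooling them
#' with species tags.
#'
#' @param specs list of [sim_family()] specifications.
#' @param species named numeric vector of target genome lengths (names are
#'   species codes).
#' @param coverage per-species fold coverage.
#' @param seed integer RNG seed.
#' @param ... further arguments passed to [sample_reads()].
#' @return list with `reads` (pooled `tagged_reads`), `genomes` (named list of
#'   `sim_genome`) and `library`.
#' @export
simulate_panel <- function(specs, species, coverage, seed = 1L, ...) {
  lib <- make_ancestral_library(specs, seed = seed)
  genomes <- list()
  reads <- list()
  for (i in seq_along(species)) {
    code <- names(species)[i]
    genomes[[code]] <- build_species_genome(lib, code, species[[i]],
                                            seed = seed + 1000L * i)
    reads[[code]] <- sample_reads(genomes[[code]], coverage,
                                  seed = seed + 1000L * i + 1L, ...)
  }
  pooled <- do.call(rbind, reads)
  rownames(pooled) <- NULL
  class(pooled) <- c("tagged_reads", "data.frame")
  list(reads = pooled, genomes = genomes, library = lib)
}
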