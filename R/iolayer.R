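#' @useDynLib repeatome, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats lm pf rbinom runif setNames median complete.cases
#' @importFrom utils read.delim write.table combn head
NULL

# ---------------------------------------------------------------------------
# Species profiles

#' Build a table of species profiles
#'
#' A species profile holds the short species code used in read-name tags, the
#' holoploid genome size (1C, in bp), the ploidy level and, derived from them,
#' the monoploid genome size (1Cx = 1C / (ploidy/2)).  1Cx is the
#' normalization constant for all abundance arithmetic; for diploids
#' 1Cx equals 1C exactly.
#'
#' @param code character vector of unique species codes; must not contain the
#'   tag separator `"_"`.
#' @param genome_size_1C numeric, holoploid genome size in bp.
#' @param ploidy integer ploidy level (>= 1), default 2 (diploid).
#' @param chromosome_number optional integer chromosome counts.
#' @return a `data.frame` of class `species_profiles` with columns `code`,
#'   `genome_size_1C`, `ploidy`, `chromosome_number` and `genome_size_1Cx`.
#' @examples
#' species_profiles(c("AAA", "BBB"), c(2e9, 4e9))
#' @export
species_profiles <- function(code, genome_size_1C, ploidy = 2L,
                             chromosome_number = NA_integer_) {
  code <- as.character(code)
  if (anyDuplicated(code)) stop("species codes must be unique")
  if (any(grepl("_", code, fixed = TRUE)))
    stop("species codes must not contain the tag separator '_'")
  if (any(genome_size_1C <= 0)) stop("genome_size_1C must be positive")
  ploidy <- as.integer(rep_len(ploidy, length(code)))
  if (any(ploidy < 1L)) stop("ploidy must be >= 1")
  df <- data.frame(
    code = code,
    genome_size_1C = as.numeric(genome_size_1C),
    ploidy = ploidy,
    chromosome_number = rep_len(as.integer(chromosome_number), length(code)),
    stringsAsFactors = FALSE
  )
  df$genome_size_1Cx <- df$genome_size_1C / (df$ploidy / 2)
  class(df) <- c("species_profiles", "data.frame")
  df
}

#' Read a species table from TSV
#'
#' Expected columns: `code`, `1C_bp` (or `genome_size_1C`), `ploidy` and
#' optionally `chromosomes`.  Any further columns are carried through
#' unchanged (e.g. sequencing-run read counts).
#'
#' @param path path to a tab-delimited file with a header line.
#' @return a `species_profiles` data frame.
#' @export
read_species_table <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  size_col <- intersect(c("1C_bp", "genome_size_1C"), names(raw))
  if (!("code" %in% names(raw)) || length(size_col) == 0)
    stop("species table needs columns 'code' and '1C_bp'")
  prof <- species_profiles(
    code = raw$code,
    genome_size_1C = raw[[size_col[1]]],
    ploidy = if ("ploidy" %in% names(raw)) raw$ploidy else 2L,
    chromosome_number = if ("chromosomes" %in% names(raw)) raw$chromosomes
                        else NA_integer_
  )
  extra <- setdiff(names(raw), c("code", size_col, "ploidy", "chromosomes"))
  for (cl in extra) prof[[cl]] <- raw[[cl]]
  prof
}

#' Look up one species profile
#' @param profiles a `species_profiles` data frame.
#' @param code species code.
#' @return a one-row data frame.
#' @export
species_profile <- function(profiles, code) {
  i <- match(code, profiles$code)
  if (is.na(i))
    stop("unknown species code '", code, "'; known codes: ",
         paste(profiles$code, collapse = ", "))
  profiles[i, , drop = FALSE]
}

# ---------------------------------------------------------------------------
# Read-name tag codec:  <CODE>_<serial>/<mate>
# The species of origin is recoverable from the name prefix; the serial
# groups the two mates of a pair.

#' Encode a tagged read name
#'
#' Read names follow `<CODE>_<serial>/<mate>`; the species code is the prefix
#' before the first underscore, the serial identifies the fragment (shared by
#' both mates) and the mate index is 1 or 2 (0 for unpaired reads).
#'
#' @param species_code species code (no underscores).
#' @param serial integer fragment serial.
#' @param mate mate index (0, 1 or 2).
#' @return character vector of read names.
#' @examples
#' encode_read_name("VSA", 1, 1)  # "VSA_0000001/1"
#' @export
encode_read_name <- function(species_code, serial, mate = 0L) {
  if (any(grepl("_", species_code, fixed = TRUE)))
    stop("species codes must not contain '_'")
  sprintf("%s_%07d/%d", species_code, as.integer(serial), as.integer(mate))
}

#' Decode tagged read names
#'
#' @param names character vector of read names.
#' @return data frame with columns `read_id`, `species`, `serial`, `mate` and
#'   `mate_id` (the name of the paired read, `NA` for unpaired reads).
#'   Species is `NA` for names that do not follow the codec.
#' @export
decode_read_names <- function(names) {
  m <- regmatches(names, regexec("^([^_]+)_([0-9]+)/([0-9])$", names))
  ok <- lengths(m) == 4L
  species <- rep(NA_character_, length(names))
  serial <- rep(NA_integer_, length(names))
  mate <- rep(NA_integer_, length(names))
  if (any(ok)) {
    parts <- do.call(rbind, m[ok])
    species[ok] <- parts[, 2]
    serial[ok] <- as.integer(parts[, 3])
    mate[ok] <- as.integer(parts[, 4])
  }
  mate_id <- rep(NA_character_, length(names))
  paired <- ok & mate %in% c(1L, 2L)
  if (any(paired))
    mate_id[paired] <- sprintf("%s_%07d/%d", species[paired], serial[paired],
                               3L - mate[paired])
  data.frame(read_id = names, species = species, serial = serial, mate = mate,
             mate_id = mate_id, stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# Sequence I/O

#' Read tagged sequences from FASTA or FASTQ
#'
#' Every record becomes one tagged read; the species tag is decoded from the
#' read name when present, otherwise `default_species` is used.  Lowercase
#' bases are upper-cased (with a message); characters outside `A,C,G,T,N` are
#' treated as `N` by all downstream alignment.
#'
#' @param path input file.
#' @param format `"fasta"` or `"fastq"` (default guessed from the extension).
#' @param default_species species code assigned to untagged reads.
#' @param known_species optional character vector; decoded tags outside this
#'   set raise an error listing the known codes.
#' @return a `tagged_reads` data frame with columns `read_id`, `species`,
#'   `sequence`, `mate_id`.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq"),
                           default_species = NA_character_,
                           known_species = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = format),
    error = function(e) stop("failed to parse '", path, "' as ", format, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  seqs <- as.character(set)
  ids <- sub("\\s.*$", "", names(set))
  if (any(grepl("[acgtn]", seqs))) {
    message("lowercase bases found in '", path, "'; upper-casing")
    seqs <- toupper(seqs)
  }
  dec <- decode_read_names(ids)
  dec$species[is.na(dec$species)] <- default_species
  if (!is.null(known_species)) {
    bad <- setdiff(unique(dec$species), c(known_species, NA_character_))
    if (length(bad))
      stop("unknown species tag(s): ", paste(bad, collapse = ", "),
           "; known codes: ", paste(known_species, collapse = ", "))
  }
  tagged_reads(ids, dec$species, unname(seqs), dec$mate_id)
}

#' Construct a tagged-reads table
#'
#' @param read_id unique read identifiers.
#' @param species species code per read.
#' @param sequence nucleotide sequences over `A,C,G,T,N`.
#' @param mate_id optional identifier of the paired read (`NA` if unpaired).
#' @return a data frame of class `tagged_reads`.
#' @export
tagged_reads <- function(read_id, species, sequence, mate_id = NA_character_) {
  if (anyDuplicated(read_id)) stop("read_id values must be unique")
  df <- data.frame(read_id = as.character(read_id),
                   species = as.character(species),
                   sequence = toupper(as.character(sequence)),
                   mate_id = rep_len(as.character(mate_id), length(read_id)),
                   stringsAsFactors = FALSE)
  class(df) <- c("tagged_reads", "data.frame")
  df
}

#' Write tagged reads to FASTA or FASTQ
#'
#' FASTQ output carries a constant quality of `"I"` (Phred 40); provenance
#' columns beyond the read name are not serialized.
#'
#' @param reads a `tagged_reads` data frame.
#' @param path output file.
#' @param format `"fasta"` or `"fastq"`.
#' @export
write_sequences <- function(reads, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  set <- Biostrings::DNAStringSet(reads$sequence)
  names(set) <- reads$read_id
  if (format == "fasta") {
    Biostrings::writeXStringSet(set, path)
  } else {
    quals <- Biostrings::BStringSet(vapply(nchar(reads$sequence), function(n)
      strrep("I", n), character(1)))
    Biostrings::writeXStringSet(set, path, format = "fastq", qualities = quals)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Result tables: TSV with a JSON mirror

#' Write a result table to TSV or JSON
#'
#' TSV files are tab-delimited with `"."` as the decimal mark and a header
#' row; JSON files are written with full numeric precision so that a
#' round-trip read returns identical values.
#'
#' @param records a data frame.
#' @param path output file.
#' @param format `"tsv"` or `"json"`.
#' @export
write_result_table <- function(records, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  records <- as.data.frame(records)
  if (format == "tsv") {
    utils::write.table(records, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, dec = ".")
  } else {
    jsonlite::write_json(records, path, dataframe = "rows", digits = NA,
                         na = "null")
  }
  invisible(path)
}

#' Read back a result table written by [write_result_table()]
#' @param path input file.
#' @param format `"tsv"` or `"json"`.
#' @return a data frame.
#' @export
read_result_table <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::read.delim(path, stringsAsFactors = FALSE)
  } else {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  }
}

# ---------------------------------------------------------------------------
# Coverage arithmetic

#' Number of reads representing a given genome coverage
#'
#' `count = round(genome_size * coverage / read_length)`, the read count whose
#' summed length equals `coverage` times the genome.  Used, for example, to
#' downsample each species to 0.01x coverage before pooled comparative
#' clustering.
#'
#' @param genome_size genome size in bp.
#' @param coverage fold coverage (>= 0).
#' @param read_length read length in nt.
#' @return integer read count.
#' @examples
#' reads_for_coverage(1e9, 0.01, 100)  # 100000
#' @export
reads_for_coverage <- function(genome_size, coverage, read_length = 100) {
  if (any(read_length <= 0)) stop("read_length must be positive")
  if (any(genome_size <= 0)) stop("genome_size must be positive")
  if (any(coverage < 0)) stop("coverage must be non-negative")
  as.integer(round(genome_size * coverage / read_length))
}

#' Fold coverage represented by a read count
#' @param n_reads number of reads.
#' @param genome_size genome size in bp.
#' @param read_length read length in nt.
#' @return fold coverage.
#' @export
coverage_for_reads <- function(n_reads, genome_size, read_length = 100) {
  if (any(genome_size <= 0)) stop("genome_size must be positive")
  n_reads * read_length / genome_size
}
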