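# Domain types shared by the whole toolkit. Sequences are plain character
# strings wrapped with an identifier; hits are rows of a classed data.frame so
# they can be filtered, sorted and written with ordinary data.frame tools.

IUPAC_RNA <- c("A", "C", "G", "U",
               "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")

#' Normalize a nucleotide string to canonical RNA
#'
#' Strips whitespace, upper-cases, and converts DNA to RNA (`T` to `U`).
#' IUPAC ambiguity codes (R, Y, S, W, K, M, B, D, H, V, N) are accepted and
#' preserved; any other character is an error reporting its position.
#'
#' @param raw Character scalar: the sequence, possibly mixed-case DNA.
#' @param identifier Optional label kept with the sequence.
#' @return An object of class `rna_sequence`: a list with elements
#'   `identifier` and `residues`.
#' @examples
#' normalize_sequence("atgc")$residues  # "AUGC"
#' @export
normalize_sequence <- function(raw, identifier = "query") {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw)) {
    stop_rfam("empty_sequence", "sequence must be a single character string")
  }
  raw <- as.vector(raw, mode = "character")  # drop classes/attributes (e.g. seqinr's)
  residues <- toupper(gsub("[[:space:]]", "", raw))
  if (nchar(residues) == 0L) {
    stop_rfam("empty_sequence", "sequence is empty after whitespace removal")
  }
  residues <- gsub("T", "U", residues, fixed = TRUE)
  chars <- strsplit(residues, "", fixed = TRUE)[[1L]]
  bad <- which(!(chars %in% IUPAC_RNA))
  if (length(bad) > 0L) {
    stop_rfam("illegal_residue",
              sprintf("illegal residue '%s' at position %d", chars[bad[1L]], bad[1L]),
              position = bad[1L], residue = chars[bad[1L]])
  }
  structure(list(identifier = identifier, residues = residues),
            class = "rna_sequence")
}

#' @export
print.rna_sequence <- function(x, ...) {
  cat(sprintf("<rna_sequence> %s (%d nt)\n", x$identifier, nchar(x$residues)))
  invisible(x)
}

#' Classify a token as an Rfam accession or a family ID
#'
#' Rfam family accessions match `RF` followed by five digits (e.g. `RF00005`);
#' anything else is treated as a candidate family ID (e.g. `tRNA`).
#'
#' @param token Non-empty character scalar.
#' @return `"accession"` or `"id"`.
#' @export
validate_accession <- function(token) {
  if (!is.character(token) || length(token) != 1L || is.na(token) || !nzchar(token)) {
    stop_rfam("bad_token", "family accession/ID must be a non-empty string")
  }
  if (grepl("^RF[0-9]{5}$", token)) "accession" else "id"
}

#' Construct a table of Rfam homology hits
#'
#' One row per hit on a query sequence. Coordinates are 1-based inclusive on
#' the query's plus strand. Server-side minus-strand hits reported with
#' `start > end` are normalized here to `start <= end` with `strand = "minus"`
#' so that all downstream interval arithmetic is uniform.
#'
#' @param rfam_accession Family accessions (`RFxxxxx`).
#' @param rfam_id Family mnemonics (e.g. `Corona_FSE`).
#' @param query_start,query_end 1-based inclusive coordinates.
#' @param strand `"plus"` or `"minus"` (recycled; default `"plus"`).
#' @param bit_score,e_value Hit scores; e-values must be positive.
#' @param alignment Optional per-hit alignment block (character, or NA).
#' @return A `data.frame` of class `rfam_hits`.
#' @export
rfam_hits <- function(rfam_accession = character(), rfam_id = character(),
                      query_start = integer(), query_end = integer(),
                      strand = "plus", bit_score = numeric(),
                      e_value = numeric(), alignment = NA_character_) {
  n <- length(rfam_accession)
  stopifnot(length(rfam_id) == n, length(query_start) == n,
            length(query_end) == n, length(bit_score) == n,
            length(e_value) == n)
  strand <- rep_len(as.character(strand), n)
  alignment <- rep_len(as.character(alignment), n)
  if (n > 0L) {
    if (any(!grepl("^RF[0-9]{5}$", rfam_accession))) {
      stop_rfam("bad_hit", "rfam_accession must match RF followed by 5 digits")
    }
    if (any(!(strand %in% c("plus", "minus")))) {
      stop_rfam("bad_hit", "strand must be 'plus' or 'minus'")
    }
    if (any(!is.finite(e_value)) || any(e_value <= 0)) {
      stop_rfam("bad_hit", "e_value must be positive")
    }
    # minus-strand ingestion: swap reversed coordinates
    rev <- query_start > query_end
    if (any(rev)) {
      tmp <- query_start[rev]
      query_start[rev] <- query_end[rev]
      query_end[rev] <- tmp
      strand[rev] <- "minus"
    }
  }
  out <- data.frame(rfam_accession = as.character(rfam_accession),
                    rfam_id = as.character(rfam_id),
                    query_start = as.integer(query_start),
                    query_end = as.integer(query_end),
                    strand = strand,
                    bit_score = as.numeric(bit_score),
                    e_value = as.numeric(e_value),
                    alignment = alignment,
                    stringsAsFactors = FALSE)
  class(out) <- c("rfam_hits", "data.frame")
  out
}

#' @export
print.rfam_hits <- function(x, ...) {
  cat(sprintf("Rfam hits: %d\n", nrow(x)))
  if (nrow(x) > 0L) print.data.frame(x[, setdiff(names(x), "alignment")], row.names = FALSE)
  invisible(x)
}

#' Search options for [rfam_sequence_search()]
#'
#' @param fragments_overlap Overlap in nucleotides between consecutive
#'   fragments when a query longer than `window` is split (default 1000).
#' @param clan_competition_filter Apply clan-competition filtering of
#'   overlapping same-clan hits (default `FALSE`).
#' @param clan_overlap_threshold Minimum overlap, as a fraction of the shorter
#'   hit, for two same-clan hits to compete (default 0.5).
#' @param window Maximum fragment length accepted by the search service
#'   (default 10000 nt).
#' @return An object of class `search_options`.
#' @export
search_options <- function(fragments_overlap = 1000,
                           clan_competition_filter = FALSE,
                           clan_overlap_threshold = 0.5,
                           window = 10000) {
  fragments_overlap <- as.integer(fragments_overlap)
  window <- as.integer(window)
  if (is.na(fragments_overlap) || fragments_overlap < 0L) {
    stop_rfam("bad_options", "fragments_overlap must be a non-negative integer")
  }
  if (fragments_overlap >= window) {
    stop_rfam("bad_overlap", "fragments_overlap must be smaller than the window size")
  }
  if (!is.numeric(clan_overlap_threshold) || clan_overlap_threshold <= 0 ||
      clan_overlap_threshold > 1) {
    stop_rfam("bad_options", "clan_overlap_threshold must lie in (0, 1]")
  }
  structure(list(fragments_overlap = fragments_overlap,
                 clan_competition_filter = isTRUE(clan_competition_filter),
                 clan_overlap_threshold = clan_overlap_threshold,
                 window = window),
            class = "search_options")
}

#' Read a clan assignment table
#'
#' Two-column tab-separated file mapping family accession to clan accession;
#' lines starting with `#` are comments. Families absent from the table belong
#' to no clan. A bundled snapshot ships with the package.
#'
#' @param file Path to the TSV snapshot; default is the bundled copy.
#' @return Named character vector: names are family accessions, values clans.
#' @export
read_clan_table <- function(file = system.file("extdata", "clans.tsv",
                                               package = "rfamtools")) {
  tab <- utils::read.table(file, header = FALSE, sep = "\t", comment.char = "#",
                           col.names = c("family", "clan"),
                           colClasses = "character")
  if (anyDuplicated(tab$family)) {
    stop_rfam("bad_clan_table", "a family accession maps to more than one clan")
  }
  stats::setNames(tab$clan, tab$family)
}

#' Consensus sequence plus secondary-structure record
#'
#' @param sequence Consensus sequence string (may carry case/ambiguity markup).
#' @param structure Structure string of the same length.
#' @param notation `"DB"` (extended dot-bracket) or `"WUSS"`.
#' @return An object of class `consensus_structure`.
#' @export
consensus_structure <- function(sequence, structure, notation = c("DB", "WUSS")) {
  notation <- match.arg(notation)
  stopifnot(is.character(sequence), length(sequence) == 1L,
            is.character(structure), length(structure) == 1L)
  if (nchar(sequence) != nchar(structure)) {
    stop_rfam("length_mismatch", "sequence and structure must have equal length")
  }
  if (nchar(sequence) == 0L) {
    stop_rfam("empty_sequence", "consensus record is empty")
  }
  structure_pairs(structure)  # errors if brackets are unbalanced
  structure(list(sequence = sequence, structure = structure, notation = notation),
            class = "consensus_structure")
}

#' @export
print.consensus_structure <- function(x, ...) {
  cat(sprintf("<consensus_structure> %s, %d positions\n", x$notation, nchar(x$sequence)))
  cat(x$sequence, "\n", x$structure, "\n", sep = "")
  invisible(x)
}

#' Seed alignment container
#'
#' A gapped multiple alignment with Stockholm-style annotations: per-file
#' (`#=GF`), per-column (`#=GC`, e.g. the consensus structure `SS_cons`), and
#' per-row (`#=GR`) lines.
#'
#' @param rows Named character vector of gapped sequences (names unique).
#' @param column_annotations Named character vector; each string as long as the
#'   alignment.
#' @param file_annotations Named list of character vectors.
#' @param row_annotations Named list (by row) of named character vectors
#'   (by tag), each as long as the alignment.
#' @return An object of class `seed_alignment`.
#' @export
seed_alignment <- function(rows, column_annotations = character(),
                           file_annotations = list(), row_annotations = list()) {
  if (length(rows) == 0L) stop_rfam("bad_alignment", "alignment has no rows")
  if (is.null(names(rows)) || any(!nzchar(names(rows)))) {
    stop_rfam("bad_alignment", "every alignment row must be named")
  }
  if (anyDuplicated(names(rows))) {
    stop_rfam("bad_alignment", "alignment row names must be unique")
  }
  width <- unique(nchar(rows))
  if (length(width) != 1L) {
    stop_rfam("ragged_alignment", "alignment rows have unequal lengths")
  }
  if (length(column_annotations) > 0L && any(nchar(column_annotations) != width)) {
    stop_rfam("ragged_alignment", "column annotation length differs from alignment width")
  }
  for (ra in row_annotations) {
    if (any(nchar(ra) != width)) {
      stop_rfam("ragged_alignment", "row annotation length differs from alignment width")
    }
  }
  structure(list(rows = rows,
                 column_annotations = column_annotations,
                 file_annotations = file_annotations,
                 row_annotations = row_annotations),
            class = "seed_alignment")
}

#' @export
print.seed_alignment <- function(x, ...) {
  cat(sprintf("<seed_alignment> %d rows x %d columns, %d column annotation(s)\n",
              length(x$rows), nchar(x$rows[[1L]]), length(x$column_annotations)))
  invisible(x)
}

#' @export
length.seed_alignment <- function(x) length(x$rows)

# Member sequence regions of a family: plain data.frame with fixed columns.
region_table <- function(genbank_accession = character(), region_start = integer(),
                         region_end = integer(), description = character(),
                         species = character()) {
  stopifnot(all(region_start >= 1L), all(region_end >= 1L))
  data.frame(genbank_accession = as.character(genbank_accession),
             region_start = as.integer(region_start),
             region_end = as.integer(region_end),
             description = as.character(description),
             species = as.character(species),
             stringsAsFactors = FALSE)
}

# PDB structure <-> covariance model residue correspondences.
pdb_table <- function(pdb_id = character(), chain = character(),
                      pdb_residue_start = integer(), pdb_residue_end = integer(),
                      cm_position_start = integer(), cm_position_end = integer()) {
  if (length(pdb_id) > 0L && any(nchar(pdb_id) != 4L)) {
    stop_rfam("bad_pdb", "PDB identifiers must be 4 characters")
  }
  data.frame(pdb_id = as.character(pdb_id), chain = as.character(chain),
             pdb_residue_start = as.integer(pdb_residue_start),
             pdb_residue_end = as.integer(pdb_residue_end),
             cm_position_start = as.integer(cm_position_start),
             cm_position_end = as.integer(cm_position_end),
             stringsAsFactors = FALSE)
}
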