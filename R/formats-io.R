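# Opaque payload pass-through (Infernal CM, SVG) and tab-delimited exports.
# CM and SVG payloads are never interpreted beyond a sanity check of their
# header; they are written byte-for-byte.

#' Validate and pass through an Infernal covariance-model payload
#'
#' The payload is only checked to start with the `INFERNAL` header token and
#' otherwise written verbatim.
#'
#' @param payload Character scalar or raw vector as fetched.
#' @param file Optional path to write the payload to.
#' @return The payload, invisibly when written to a file.
#' @export
passthrough_cm <- function(payload, file = NULL) {
  txt <- payload_text(payload)
  if (!startsWith(txt, "INFERNAL")) {
    stop_rfam("not_a_covariance_model",
              "payload does not start with the Infernal header token")
  }
  write_payload(payload, file)
}

#' Validate and pass through an SVG payload
#'
#' Checked only to contain an XML `<svg` root element; written verbatim.
#'
#' @inheritParams passthrough_cm
#' @return The payload, invisibly when written to a file.
#' @export
passthrough_svg <- function(payload, file = NULL) {
  txt <- payload_text(payload)
  if (!grepl("<svg[\\s>]", txt, perl = TRUE)) {
    stop_rfam("not_an_svg", "payload does not contain an <svg> root element")
  }
  write_payload(payload, file)
}

payload_text <- function(payload) {
  if (is.raw(payload)) rawToChar(payload) else paste(payload, collapse = "\n")
}

write_payload <- function(payload, file) {
  if (is.null(file)) return(payload)
  if (is.raw(payload)) {
    writeBin(payload, file)
  } else {
    writeChar(paste(payload, collapse = "\n"), file, eos = NULL)
  }
  invisible(payload)
}

# Tab and newline escaping so arbitrary description fields survive TSV.
escape_tsv_field <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  gsub("\n", "\\n", x, fixed = TRUE)
}

unescape_tsv_field <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    chars <- strsplit(x[i], "", fixed = TRUE)[[1L]]
    res <- character(0)
    j <- 1L
    while (j <= length(chars)) {
      if (chars[j] == "\\" && j < length(chars)) {
        res <- c(res, switch(chars[j + 1L], t = "\t", n = "\n", "\\" = "\\",
                             chars[j + 1L]))
        j <- j + 2L
      } else {
        res <- c(res, chars[j])
        j <- j + 1L
      }
    }
    out[i] <- paste(res, collapse = "")
  }
  out
}

format_tsv <- function(df) {
  if (nrow(df) == 0L) {
    body <- character(0)
  } else {
    esc <- vapply(df, function(col) escape_tsv_field(as.character(col)),
                  character(nrow(df)))
    if (nrow(df) == 1L) esc <- matrix(esc, nrow = 1L)
    body <- apply(esc, 1L, paste, collapse = "\t")
  }
  paste0(paste(c(paste(names(df), collapse = "\t"), body), collapse = "\n"), "\n")
}

parse_tsv <- function(text) {
  lines <- strsplit(sub("\n$", "", text), "\n", fixed = TRUE)[[1L]]
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (length(lines) == 1L) {
    df <- as.data.frame(stats::setNames(rep(list(character()), length(header)), header),
                        stringsAsFactors = FALSE)
    return(df)
  }
  cells <- lapply(lines[-1L], function(l) {
    unescape_tsv_field(strsplit(l, "\t", fixed = TRUE)[[1L]])
  })
  df <- as.data.frame(do.call(rbind, cells), stringsAsFactors = FALSE)
  names(df) <- header
  df
}

#' Write member sequence regions as tab-delimited text
#'
#' Header plus one row per region (GenBank accession, 1-based coordinates,
#' description, species). Embedded tabs/newlines in fields are escaped.
#'
#' @param regions A data.frame as returned by [rfam_sequence_regions()].
#' @param file Optional output path.
#' @return The TSV text, invisibly when written to a file.
#' @export
write_regions_tsv <- function(regions, file = NULL) {
  txt <- format_tsv(regions)
  if (is.null(file)) return(txt)
  writeChar(txt, file, eos = NULL)
  invisible(txt)
}

#' Write PDB-to-covariance-model correspondences as tab-delimited text
#'
#' @param rows A data.frame as returned by [rfam_pdb_mapping()].
#' @inheritParams write_regions_tsv
#' @return The TSV text, invisibly when written to a file.
#' @export
write_pdb_tsv <- function(rows, file = NULL) {
  txt <- format_tsv(rows)
  if (is.null(file)) return(txt)
  writeChar(txt, file, eos = NULL)
  invisible(txt)
}

#' Write a hit table as tab-delimited text
#'
#' Columns: rfam_accession, rfam_id, query_start, query_end, strand,
#' bit_score, e_value.
#'
#' @param hits An [rfam_hits()] table.
#' @inheritParams write_regions_tsv
#' @return The TSV text, invisibly when written to a file.
#' @export
write_hits_tsv <- function(hits, file = NULL) {
  cols <- c("rfam_accession", "rfam_id", "query_start", "query_end",
            "strand", "bit_score", "e_value")
  txt <- format_tsv(as.data.frame(hits)[, cols, drop = FALSE])
  if (is.null(file)) return(txt)
  writeChar(txt, file, eos = NULL)
  invisible(txt)
}

#' Read a query sequence from a FASTA file
#'
#' Reads the first record of a FASTA file (via \pkg{seqinr}) and normalizes it
#' to canonical RNA with [normalize_sequence()].
#'
#' @param file Path to a FASTA file.
#' @return An `rna_sequence` object.
#' @export
read_fasta_sequence <- function(file) {
  recs <- seqinr::read.fasta(file, seqtype = "DNA", as.string = TRUE)
  if (length(recs) == 0L) stop_rfam("empty_sequence", "FASTA file has no records")
  normalize_sequence(unlist(recs[[1L]]), identifier = names(recs)[1L])
}
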