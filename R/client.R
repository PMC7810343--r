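# High-level family-data retrieval: one function per Rfam endpoint, each
# accepting either a family accession (RFxxxxx) or a family ID. IDs are
# resolved to accessions through the transport's lookup endpoint first, so
# every downstream request is keyed by accession.

resolve_accession <- function(conn, rfam_family) {
  if (validate_accession(rfam_family) == "accession") return(rfam_family)
  lookup_id(conn, rfam_family)$accession
}

#' Convert a family accession to the corresponding family ID
#'
#' @param conn An [rfam_connection()].
#' @param rfam_family_accession Accession, e.g. `"RF00005"`.
#' @return The family ID (e.g. `"tRNA"`).
#' @export
rfam_accession_to_id <- function(conn, rfam_family_accession) {
  lookup_id(conn, rfam_family_accession)$id
}

#' Convert a family ID to the corresponding accession
#'
#' @param conn An [rfam_connection()].
#' @param rfam_family_id Family ID, e.g. `"tRNA"`.
#' @return The family accession (e.g. `"RF00005"`).
#' @export
rfam_id_to_accession <- function(conn, rfam_family_id) {
  lookup_id(conn, rfam_family_id)$accession
}

#' Keyword search returning matching family accessions
#'
#' @param conn An [rfam_connection()].
#' @param query Keyword matched against family IDs, summaries, descriptions.
#' @return Character vector of family accessions.
#' @export
rfam_text_search <- function(conn, query) text_search(conn, query)

#' Brief descriptive summary of a family
#'
#' @param conn An [rfam_connection()].
#' @param rfam_family Family accession or ID.
#' @return A list of class `family_summary`: `accession`, `id`,
#'   `description`, `number_of_sequences`, plus any further metadata fields.
#' @export
rfam_family_summary <- function(conn, rfam_family) {
  acc <- resolve_accession(conn, rfam_family)
  res <- fetch(conn, endpoint_request("summary", acc))
  rec <- jsonlite::fromJSON(res$body)
  if (is.null(rec$accession) || is.null(rec$id) ||
      !nzchar(rec$accession) || !nzchar(rec$id)) {
    stop_rfam("bad_response", "summary record lacks accession or id")
  }
  structure(rec, class = "family_summary")
}

#' @export
print.family_summary <- function(x, ...) {
  cat(sprintf("%s (%s): %s\n", x$accession, x$id, x$description))
  if (!is.null(x$number_of_sequences)) {
    cat(sprintf("  sequences: %d\n", as.integer(x$number_of_sequences)))
  }
  invisible(x)
}

#' Consensus sequence and secondary structure of a family
#'
#' The structure is returned in extended dot-bracket (`"DB"`, default) or
#' WUSS notation; dot-bracket is derived from the WUSS annotation with
#' [wuss_to_dotbracket()], which preserves the base-pair set exactly.
#'
#' @param conn An [rfam_connection()].
#' @param rfam_family Family accession or ID.
#' @param format `"DB"` or `"WUSS"`.
#' @param filename Optional path: writes the two-line record of
#'   [write_consensus_file()], directly readable by helix-plot tools.
#' @return A [consensus_structure()] object.
#' @export
rfam_consensus_structure <- function(conn, rfam_family, format = c("DB", "WUSS"),
                                     filename = NULL) {
  format <- match.arg(format)
  acc <- resolve_accession(conn, rfam_family)
  res <- fetch(conn, endpoint_request("secondary_structure", acc))
  rec <- jsonlite::fromJSON(res$body)
  ss <- if (format == "WUSS") rec$wuss else wuss_to_dotbracket(rec$wuss)
  cs <- consensus_structure(rec$sequence, ss, notation = format)
  if (!is.null(filename)) write_consensus_file(cs, filename)
  cs
}

#' Seed multiple sequence alignment of a family
#'
#' @param conn An [rfam_connection()].
#' @param rfam_family Family accession or ID.
#' @param format Export format for `filename`: `"stockholm"`, `"pfam"`,
#'   `"fasta"` (gapped) or `"fastau"` (ungapped).
#' @param filename Optional output path.
#' @return A [seed_alignment()] object.
#' @export
rfam_seed_alignment <- function(conn, rfam_family,
                                format = c("stockholm", "pfam", "fasta", "fastau"),
                                filename = NULL) {
  format <- match.arg(format)
  acc <- resolve_accession(conn, rfam_family)
  res <- fetch(conn, endpoint_request("seed_alignment", acc))
  aln <- parse_stockholm(res$body)
  if (!is.null(filename)) write_alignment(aln, format, file = filename)
  aln
}

#' Phylogenetic tree of a family's seed alignment (NHX format)
#'
#' @param conn An [rfam_connection()].
#' @param rfam_family Family accession or ID.
#' @param filename Optional path; the raw NHX text is written verbatim.
#' @return A [parse_nhx()] tree summary.
#' @export
rfam_seed_tree <- function(conn, rfam_family, filename = NULL) {
  acc <- resolve_accession(conn, rfam_family)
  res <- fetch(conn, endpoint_request("seed_tree", acc))
  if (!is.null(filename)) writeChar(res$body, filename, eos = NULL)
  parse_nhx(res$body)
}

#' Rendered image of the seed-alignment tree
#'
#' The image is fetched as an opaque payload and written verbatim.
#'
#' @param conn An [rfam_connection()].
#' @param rfam_family Family accession or ID.
#' @param label `"species"` (species names) or `"acc"` (sequence accessions).
#' @param filename Optional output path.
#' @return The payload, invisibly when written to a file.
#' @export
rfam_seed_tree_image <- function(conn, rfam_family, label = c("species", "acc"),
                                 filename = NULL) {
  label <- match.arg(label)
  acc <- resolve_accession(conn, rfam_family)
  res <- fetch(conn, endpoint_request("seed_tree_image", acc,
                                      params = list(label = label)))
  write_payload(res$body, filename)
}

PLOT_TYPES <- c("norm", "cons", "fcbp", "cov", "ent", "maxcm", "rscape", "rscape-cyk")

#' Secondary-structure diagram of a family
#'
#' Fetches the rendered diagram as an opaque payload. Plot types: `norm`
#' (plain), `cons` (sequence conservation), `fcbp` (basepair conservation),
#' `cov` (covariation), `ent` (relative entropy), `maxcm` (maximum covariance
#' model parse), `rscape` (R-scape analysis), `rscape-cyk` (R-scape predicted
#' structure).
#'
#' @param conn An [rfam_connection()].
#' @param rfam_family Family accession or ID.
#' @param plot_type One of the eight diagram types.
#' @param filename Optional output path.
#' @return The payload, invisibly when written to a file.
#' @export
rfam_structure_plot <- function(conn, rfam_family, plot_type = PLOT_TYPES,
                                filename = NULL) {
  plot_type <- match.arg(plot_type)
  acc <- resolve_accession(conn, rfam_family)
  res <- fetch(conn, endpoint_request("structure_image", acc,
                                      params = list(plot_type = plot_type)))
  write_payload(res$body, filename)
}

#' Secondary-structure diagram as SVG (XML)
#'
#' Same diagram types as [rfam_structure_plot()], but the payload is checked
#' to be an SVG document before being written, so the result is directly
#' editable as vector graphics.
#'
#' @inheritParams rfam_structure_plot
#' @return The SVG text, invisibly when written to a file.
#' @export
rfam_structure_svg <- function(conn, rfam_family, plot_type = PLOT_TYPES,
                               filename = NULL) {
  plot_type <- match.arg(plot_type)
  acc <- resolve_accession(conn, rfam_family)
  res <- fetch(conn, endpoint_request("structure_image", acc,
                                      params = list(plot_type = plot_type,
                                                    media = "svg")))
  passthrough_svg(res$body, filename)
}

#' Covariance model of a family (Infernal format)
#'
#' The model text is passed through verbatim after checking the Infernal
#' header.
#'
#' @param conn An [rfam_connection()].
#' @param rfam_family Family accession or ID.
#' @param filename Optional output path.
#' @return The CM text, invisibly when written to a file.
#' @export
rfam_covariance_model <- function(conn, rfam_family, filename = NULL) {
  acc <- resolve_accession(conn, rfam_family)
  res <- fetch(conn, endpoint_request("covariance_model", acc))
  passthrough_cm(res$body, filename)
}

#' All sequence regions annotated as members of a family
#'
#' @param conn An [rfam_connection()].
#' @param rfam_family Family accession or ID.
#' @param filename Optional path for a tab-delimited export
#'   ([write_regions_tsv()]).
#' @return A data.frame with columns `genbank_accession`, `region_start`,
#'   `region_end`, `description`, `species`.
#' @export
rfam_sequence_regions <- function(conn, rfam_family, filename = NULL) {
  acc <- resolve_accession(conn, rfam_family)
  res <- fetch(conn, endpoint_request("regions", acc))
  recs <- jsonlite::fromJSON(res$body, simplifyVector = FALSE)
  regions <- region_table(
    genbank_accession = vapply(recs, `[[`, "", "genbank_accession"),
    region_start = vapply(recs, function(r) as.integer(r$region_start), 1L),
    region_end = vapply(recs, function(r) as.integer(r$region_end), 1L),
    description = vapply(recs, `[[`, "", "description"),
    species = vapply(recs, `[[`, "", "species"))
  if (!is.null(filename)) write_regions_tsv(regions, filename)
  regions
}

#' PDB structures of family members, mapped onto the covariance model
#'
#' @param conn An [rfam_connection()].
#' @param rfam_family Family accession or ID.
#' @param filename Optional path for a tab-delimited export
#'   ([write_pdb_tsv()]).
#' @return A data.frame with PDB id/chain and residue-to-CM-position ranges.
#' @export
rfam_pdb_mapping <- function(conn, rfam_family, filename = NULL) {
  acc <- resolve_accession(conn, rfam_family)
  res <- fetch(conn, endpoint_request("pdb_mapping", acc))
  recs <- jsonlite::fromJSON(res$body, simplifyVector = FALSE)
  rows <- pdb_table(
    pdb_id = vapply(recs, `[[`, "", "pdb_id"),
    chain = vapply(recs, `[[`, "", "chain"),
    pdb_residue_start = vapply(recs, function(r) as.integer(r$pdb_residue_start), 1L),
    pdb_residue_end = vapply(recs, function(r) as.integer(r$pdb_residue_end), 1L),
    cm_position_start = vapply(recs, function(r) as.integer(r$cm_position_start), 1L),
    cm_position_end = vapply(recs, function(r) as.integer(r$cm_position_end), 1L))
  if (!is.null(filename)) write_pdb_tsv(rows, filename)
  rows
}
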