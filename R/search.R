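# Long-sequence search orchestration. The Rfam search service accepts queries
# of at most 10,000 nt, so longer queries are split into overlapping windows,
# searched fragment by fragment, and the hits are remapped onto the original
# coordinates. A hit inside an overlap region is found by both neighbouring
# fragments; deduplication collapses those exact duplicates.

#' Plan the fragmentation of a long query
#'
#' A query of length at most `window` yields a single fragment `[1, L]`.
#' Longer queries produce fragments starting at `1, 1 + (window - overlap),
#' 1 + 2*(window - overlap), ...`; every fragment except possibly the last is
#' exactly `window` nt, the last ends exactly at `L`, and consecutive
#' fragments share exactly `overlap` positions (the last pair may share more).
#'
#' @param sequence_length Query length in nucleotides.
#' @param window Maximum fragment length (default 10000).
#' @param overlap Overlap between consecutive fragments; must be < `window`.
#' @return A data.frame of class `fragment_plan` with columns `parent_start`,
#'   `parent_end`; the window and overlap are kept as attributes.
#' @examples
#' plan_fragments(29903, 10000, 3000)
#' @export
plan_fragments <- function(sequence_length, window = RFAM_SEARCH_WINDOW, overlap = 1000) {
  sequence_length <- as.integer(sequence_length)
  window <- as.integer(window)
  overlap <- as.integer(overlap)
  if (is.na(overlap) || overlap < 0L || overlap >= window) {
    stop_rfam("bad_overlap", "overlap must satisfy 0 <= overlap < window")
  }
  if (is.na(sequence_length) || sequence_length < 1L) {
    stop_rfam("bad_request", "sequence_length must be >= 1")
  }
  if (sequence_length <= window) {
    starts <- 1L
    ends <- sequence_length
  } else {
    step <- window - overlap
    starts <- 1L
    ends <- window
    while (ends[length(ends)] < sequence_length) {
      s <- starts[length(starts)] + step
      starts <- c(starts, s)
      ends <- c(ends, min(s + window - 1L, sequence_length))
    }
  }
  out <- data.frame(parent_start = starts, parent_end = ends)
  attr(out, "window") <- window
  attr(out, "overlap") <- overlap
  class(out) <- c("fragment_plan", "data.frame")
  out
}

#' Cut a query sequence into the planned fragments
#'
#' @param seq An `rna_sequence` (see [normalize_sequence()]).
#' @param plan A [plan_fragments()] plan for `nchar(seq$residues)`.
#' @return A list of `sequence_fragment` objects, each holding `parent_id`,
#'   `parent_start`, `parent_end` (1-based inclusive) and `residues`.
#' @export
extract_fragments <- function(seq, plan) {
  stopifnot(inherits(seq, "rna_sequence"), inherits(plan, "fragment_plan"))
  L <- nchar(seq$residues)
  if (plan$parent_end[nrow(plan)] != L) {
    stop_rfam("bad_request", "fragment plan does not match the sequence length")
  }
  lapply(seq_len(nrow(plan)), function(i) {
    structure(list(parent_id = seq$identifier,
                   parent_start = plan$parent_start[i],
                   parent_end = plan$parent_end[i],
                   residues = substr(seq$residues, plan$parent_start[i],
                                     plan$parent_end[i])),
              class = "sequence_fragment")
  })
}

#' Remap a fragment-local hit to parent coordinates
#'
#' @param local_hit A one-row [rfam_hits()] table with coordinates local to
#'   `fragment` (1-based).
#' @param fragment The `sequence_fragment` the hit was found on.
#' @return The hit with `query_start`/`query_end` shifted by
#'   `fragment$parent_start - 1`; strand and scores unchanged.
#' @export
map_hit_to_parent <- function(local_hit, fragment) {
  stopifnot(inherits(fragment, "sequence_fragment"))
  flen <- fragment$parent_end - fragment$parent_start + 1L
  if (any(local_hit$query_start < 1L) || any(local_hit$query_end > flen)) {
    stop_rfam("coordinate_out_of_range",
              "hit coordinates fall outside the fragment")
  }
  offset <- fragment$parent_start - 1L
  local_hit$query_start <- local_hit$query_start + offset
  local_hit$query_end <- local_hit$query_end + offset
  local_hit
}

#' Collapse duplicate hits reported by overlapping fragments
#'
#' Two hits are duplicates iff they agree on family accession, parent
#' coordinates and strand; of a duplicate group the hit with the lowest
#' e-value survives. The result is sorted by (query_start, query_end,
#' accession), making the operation idempotent and order-insensitive.
#'
#' @param hits An [rfam_hits()] table in parent coordinates.
#' @return The deduplicated, sorted [rfam_hits()] table.
#' @export
deduplicate_hits <- function(hits) {
  stopifnot(inherits(hits, "rfam_hits"))
  if (nrow(hits) == 0L) return(hits)
  key <- paste(hits$rfam_accession, hits$query_start, hits$query_end,
               hits$strand, sep = "\r")
  best <- tapply(seq_len(nrow(hits)), key, function(idx) {
    idx[which.min(hits$e_value[idx])]
  })
  out <- hits[sort(as.integer(best)), , drop = FALSE]
  out <- out[order(out$query_start, out$query_end, out$rfam_accession), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("rfam_hits", "data.frame")
  out
}

# Raw hit records from a job payload -> rfam_hits (fragment-local coords).
parse_hit_payload <- function(records) {
  if (length(records) == 0L) return(rfam_hits())
  get_field <- function(field, default = NA) {
    vapply(records, function(r) {
      v <- r[[field]]
      if (is.null(v)) default else v
    }, default)
  }
  rfam_hits(rfam_accession = get_field("accession", NA_character_),
            rfam_id = get_field("id", NA_character_),
            query_start = as.integer(get_field("start", NA_real_)),
            query_end = as.integer(get_field("end", NA_real_)),
            strand = get_field("strand", "plus"),
            bit_score = as.numeric(get_field("bit_score", NA_real_)),
            e_value = as.numeric(get_field("e_value", NA_real_)),
            alignment = get_field("alignment", NA_character_))
}

#' Search a sequence of any length against the Rfam families
#'
#' Mirrors the full search pipeline: normalization, fragmentation into
#' overlapping windows, per-fragment remote search, remapping of hits to the
#' original coordinates, deduplication, and (optionally) clan-competition
#' filtering. A failure on any fragment aborts the whole search -- no silent
#' partial results.
#'
#' @param sequence Character string, or an `rna_sequence`.
#' @param conn An [rfam_connection()].
#' @param options A [search_options()] object.
#' @param clans Clan assignment (named character vector, see
#'   [read_clan_table()]); used only when the clan filter is enabled.
#' @return An [rfam_hits()] table sorted by query coordinates.
#' @export
rfam_sequence_search <- function(sequence, conn,
                                 options = search_options(),
                                 clans = read_clan_table()) {
  seq <- if (inherits(sequence, "rna_sequence")) sequence else normalize_sequence(sequence)
  stopifnot(inherits(options, "search_options"))
  plan <- plan_fragments(nchar(seq$residues), options$window,
                         options$fragments_overlap)
  fragments <- extract_fragments(seq, plan)
  per_fragment <- lapply(fragments, function(frag) {
    tryCatch({
      handle <- submit_search(conn, frag)
      res <- await_search(conn, handle)
      local_hits <- parse_hit_payload(res$hits)
      map_hit_to_parent(local_hits, frag)
    }, rfamtools_error = function(e) {
      stop_rfam("fragment_search_failed",
                sprintf("search failed on fragment %d-%d: %s",
                        frag$parent_start, frag$parent_end, conditionMessage(e)),
                parent_condition = e)
    })
  })
  hits <- do.call(rbind, per_fragment)
  class(hits) <- c("rfam_hits", "data.frame")
  hits <- deduplicate_hits(hits)
  if (options$clan_competition_filter) {
    hits <- clan_competition(hits, clans, options$clan_overlap_threshold)
  }
  hits
}
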