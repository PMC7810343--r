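# Clan competition: Rfam groups evolutionarily related families into clans,
# and two hits from the same clan covering the same region are redundant.
# The filter keeps, per group of overlapping same-clan hits, only the
# best-ranked hit (lowest e-value; ties broken by higher bit score, then by
# accession), where "overlapping" means the shared interval covers at least a
# threshold fraction of the shorter hit (default 50%).

#' Overlap between two hits, as a fraction of the shorter one
#'
#' Intervals are 1-based inclusive, so the overlap length is
#' `max(0, min(end_a, end_b) - max(start_a, start_b) + 1)` and the fraction
#' divides by the shorter hit's length. The report is symmetric in its
#' arguments, and containment always yields fraction 1.
#'
#' @param a,b Hits: one-row [rfam_hits()] tables or list-like objects with
#'   `query_start`/`query_end`.
#' @return A list of class `overlap_report` with `overlap_nt` and
#'   `fraction_of_shortest`.
#' @export
overlap_fraction <- function(a, b) {
  ov <- overlap_nt(a$query_start, a$query_end, b$query_start, b$query_end)
  shortest <- min(a$query_end - a$query_start + 1L, b$query_end - b$query_start + 1L)
  structure(list(overlap_nt = ov, fraction_of_shortest = ov / shortest),
            class = "overlap_report")
}

overlap_nt <- function(start_a, end_a, start_b, end_b) {
  max(0L, min(end_a, end_b) - max(start_a, start_b) + 1L)
}

# Total rank order used by the filter: ascending e-value, descending bit
# score, ascending accession. Returns a permutation of row indices.
hit_rank_order <- function(hits) {
  order(hits$e_value, -hits$bit_score, hits$rfam_accession, hits$query_start,
        hits$query_end)
}

#' Clan-competition filtering of overlapping hits
#'
#' Greedy by rank: walk the hits from best to worst; keep a hit unless its
#' family shares a clan with an already-kept hit on the same strand whose
#' overlap covers at least `threshold` of the shorter of the two. Hits whose
#' family belongs to no clan are always kept. The retained set is independent
#' of the input order and the filter is idempotent.
#'
#' @param hits An [rfam_hits()] table with normalized coordinates.
#' @param clans Named character vector mapping family accession to clan
#'   (see [read_clan_table()]); families absent from it have no clan.
#' @param threshold Minimum overlap fraction in (0, 1] (default 0.5).
#' @return The retained hits, sorted by query coordinates.
#' @export
clan_competition <- function(hits, clans = read_clan_table(), threshold = 0.5) {
  stopifnot(inherits(hits, "rfam_hits"))
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop_rfam("bad_options", "threshold must lie in (0, 1]")
  }
  if (nrow(hits) <= 1L) return(sort_hits(hits))
  clan_of <- unname(clans[hits$rfam_accession])
  kept <- integer(0)
  for (i in hit_rank_order(hits)) {
    cl <- clan_of[i]
    competes <- FALSE
    if (!is.na(cl)) {
      for (j in kept) {
        if (is.na(clan_of[j]) || clan_of[j] != cl) next
        if (hits$strand[j] != hits$strand[i]) next
        ov <- overlap_fraction(hits[i, ], hits[j, ])
        if (ov$fraction_of_shortest >= threshold) {
          competes <- TRUE
          break
        }
      }
    }
    if (!competes) kept <- c(kept, i)
  }
  sort_hits(hits[sort(kept), , drop = FALSE])
}

sort_hits <- function(hits) {
  out <- hits[order(hits$query_start, hits$query_end, hits$rfam_accession), ,
              drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("rfam_hits", "data.frame")
  out
}
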