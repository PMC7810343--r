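# Deterministic synthetic data and replay-store generation. Everything the
# toolkit can fetch remotely can also be generated locally: synthetic worlds
# (random genomes with planted family motifs plus the recorded per-fragment
# search responses an exact-match search service would return) and the
# SARS-CoV-2 case-study fixture, whose seven hits sit at the published
# coordinates on a synthetic 29,903-nt genome. The genome background is
# random; it stands in for the real NC_045512.2 sequence, which is not
# bundled.

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# Record the submit + poll responses an exact-match search service would give
# for every fragment of `fragments`, taking the ground truth `truth` (parent
# coordinates) as the authoritative hit set. A hit is reported by every
# fragment that fully contains it, with fragment-local coordinates.
record_search_responses <- function(replay_dir, fragments, truth,
                                    job_prefix = "job") {
  for (i in seq_along(fragments)) {
    frag <- fragments[[i]]
    job_id <- sprintf("%s-%d", job_prefix, i)
    record_response(replay_dir,
                    endpoint_request("search_submit",
                                     params = list(seq_digest = md5_string(toupper(frag$residues)))),
                    jsonlite::toJSON(list(job_id = job_id), auto_unbox = TRUE))
    inside <- truth[truth$start >= frag$parent_start &
                    truth$end <= frag$parent_end, , drop = FALSE]
    hits <- lapply(seq_len(nrow(inside)), function(k) {
      list(accession = inside$accession[k], id = inside$id[k],
           start = inside$start[k] - frag$parent_start + 1L,
           end = inside$end[k] - frag$parent_start + 1L,
           strand = inside$strand[k], bit_score = inside$bit_score[k],
           e_value = inside$e_value[k])
    })
    record_response(replay_dir,
                    endpoint_request("search_poll", params = list(job_id = job_id)),
                    jsonlite::toJSON(list(status = "done", hits = hits),
                                     auto_unbox = TRUE, digits = NA))
  }
  invisible(replay_dir)
}

#' Generate a synthetic world: families, a genome with planted motifs, and
#' the matching replay store
#'
#' Families get literal motifs (30-60 nt) planted at random non-overlapping
#' genome positions (one or two copies each); the replay store records the
#' per-fragment search responses an exact-match service would return, so
#' [rfam_sequence_search()] against it must recover the planted annotations
#' exactly. Fully reproducible for a fixed seed.
#'
#' @param seed Integer RNG seed.
#' @param n_families Number of synthetic families (>= 1).
#' @param genome_length Genome length in nt (default 25000).
#' @param window,overlap Fragmentation parameters used for the recorded
#'   responses (defaults 10000/1000).
#' @param replay_dir Directory for the replay store (default: fresh tempdir).
#' @return A list: `genome` (`rna_sequence`), `families` (data.frame),
#'   `truth` (data.frame of planted hits in parent coordinates),
#'   `replay_dir`, `options` (matching [search_options()]).
#' @export
generate_world <- function(seed, n_families = 3L, genome_length = 25000L,
                           window = 10000L, overlap = 1000L,
                           replay_dir = tempfile("world")) {
  stopifnot(n_families >= 1L)
  set.seed(seed)
  genome <- random_rna(genome_length)
  accession <- sprintf("RF9%04d", seq_len(n_families))
  id <- sprintf("SYN_fam%d", seq_len(n_families))
  motif_len <- sample(30:60, n_families, replace = TRUE)
  motifs <- vapply(motif_len, random_rna, "")
  e_value <- 10^stats::runif(n_families, -20, -5)
  bit_score <- round(stats::runif(n_families, 25, 150), 1)
  families <- data.frame(accession = accession, id = id, motif = motifs,
                         e_value = e_value, bit_score = bit_score,
                         stringsAsFactors = FALSE)
  # plant each motif 1-2 times at non-overlapping positions
  occupied <- matrix(integer(0), ncol = 2)
  truth <- NULL
  for (f in seq_len(n_families)) {
    for (copy in seq_len(sample(1:2, 1L))) {
      for (try in 1:200) {
        s <- sample.int(genome_length - motif_len[f] + 1L, 1L)
        e <- s + motif_len[f] - 1L
        clash <- nrow(occupied) > 0L &&
          any(pmax(occupied[, 1], s) <= pmin(occupied[, 2], e))
        if (!clash) break
      }
      if (clash) next
      occupied <- rbind(occupied, c(s, e))
      substr(genome, s, e) <- motifs[f]
      truth <- rbind(truth, data.frame(accession = accession[f], id = id[f],
                                       start = s, end = e, strand = "plus",
                                       bit_score = bit_score[f],
                                       e_value = e_value[f],
                                       stringsAsFactors = FALSE))
    }
  }
  truth <- truth[order(truth$start, truth$end, truth$accession), , drop = FALSE]
  rownames(truth) <- NULL
  seq <- normalize_sequence(genome, identifier = sprintf("synthetic_world_%d", seed))
  plan <- plan_fragments(genome_length, window, overlap)
  fragments <- extract_fragments(seq, plan)
  record_search_responses(replay_dir, fragments, truth,
                          job_prefix = sprintf("world%d", seed))
  list(genome = seq, families = families, truth = truth,
       replay_dir = replay_dir,
       options = search_options(fragments_overlap = overlap, window = window))
}

# ---- SARS-CoV-2 case study -------------------------------------------------

#' The seven published SARS-CoV-2 hits, with clans and synthetic scores
#'
#' The seven non-coding RNA elements found in the 29,903-nt SARS-CoV-2
#' genome, with their published genome coordinates. Clan groupings follow the
#' case-study description: the two 5'-UTR families form one clan, the two
#' 3'-UTR families plus the 3'-UTR pseudoknot (Corona_pk3) and s2m another,
#' and the frameshifting element (Corona_FSE) belongs to no clan. Bit scores
#' and e-values are synthetic, fixed so that the Sarbecovirus-specific hit
#' ranks best within each clan.
#'
#' @return A data.frame with columns `accession`, `id`, `start`, `end`,
#'   `strand`, `bit_score`, `e_value`, `clan` (NA = unclanned).
#' @export
case_study_table <- function() {
  data.frame(
    accession = c("RF03117", "RF03120", "RF00507", "RF03122", "RF03125",
                  "RF00165", "RF00164"),
    id = c("bCoV-5UTR", "Sarbecovirus-5UTR", "Corona_FSE", "bCoV-3UTR",
           "Sarbecovirus-3UTR", "Corona_pk3", "s2m"),
    start = c(2L, 2L, 13470L, 29519L, 29537L, 29604L, 29728L),
    end = c(300L, 300L, 13551L, 29871L, 29871L, 29663L, 29770L),
    strand = "plus",
    bit_score = c(90.1, 141.8, 67.4, 85.2, 120.6, 38.5, 41.2),
    e_value = c(2.4e-26, 1.1e-38, 1.6e-17, 3.0e-24, 5.0e-33, 2.1e-9, 6.8e-8),
    clan = c("CL00116", "CL00116", NA, "CL00117", "CL00117", "CL00117",
             "CL00117"),
    stringsAsFactors = FALSE)
}

#' The case-study hit table as an [rfam_hits()] object
#' @return An [rfam_hits()] table of the seven published hits.
#' @export
case_study_hits <- function() {
  tab <- case_study_table()
  rfam_hits(rfam_accession = tab$accession, rfam_id = tab$id,
            query_start = tab$start, query_end = tab$end,
            strand = tab$strand, bit_score = tab$bit_score,
            e_value = tab$e_value)
}

#' Clan assignment of the case-study families
#' @return Named character vector (family accession -> clan accession).
#' @export
case_study_clans <- function() {
  tab <- case_study_table()
  tab <- tab[!is.na(tab$clan), ]
  stats::setNames(tab$clan, tab$accession)
}

#' Build the SARS-CoV-2 case-study fixture and its replay store
#'
#' A synthetic 29,903-nt genome (random background standing in for the real
#' reference sequence) together with a replay store whose per-fragment search
#' responses place the seven published hits at their exact genome
#' coordinates. Searching this fixture with the 10,000-nt window and a
#' 3,000-nt fragment overlap reproduces the seven hits with the clan filter
#' off, and the three surviving hits (Sarbecovirus-5UTR, Corona_FSE,
#' Sarbecovirus-3UTR) with the filter on.
#'
#' @param replay_dir Directory for the replay store (default: fresh tempdir).
#' @param seed Seed for the random genome background.
#' @return A list: `genome` (`rna_sequence`, 29,903 nt), `hits`
#'   ([rfam_hits()], the published 7-hit table), `clans`, `replay_dir`,
#'   `options` (overlap 3000, clan filter off).
#' @export
build_case_study <- function(replay_dir = tempfile("casestudy"), seed = 1L) {
  set.seed(seed)
  genome_length <- 29903L
  genome <- random_rna(genome_length)
  seq <- normalize_sequence(genome, identifier = "synthetic_sars_cov_2")
  tab <- case_study_table()
  truth <- data.frame(accession = tab$accession, id = tab$id,
                      start = tab$start, end = tab$end, strand = tab$strand,
                      bit_score = tab$bit_score, e_value = tab$e_value,
                      stringsAsFactors = FALSE)
  plan <- plan_fragments(genome_length, RFAM_SEARCH_WINDOW, 3000L)
  fragments <- extract_fragments(seq, plan)
  record_search_responses(replay_dir, fragments, truth, job_prefix = "casestudy")
  list(genome = seq, hits = case_study_hits(), clans = case_study_clans(),
       replay_dir = replay_dir,
       options = search_options(fragments_overlap = 3000L))
}

# ---- family-endpoint fixtures ---------------------------------------------

#' Record synthetic family-endpoint responses into a replay store
#'
#' Populates a replay store with deterministic synthetic responses for two
#' families -- RF00005 (tRNA) and RF03120 (Sarbecovirus-5UTR) -- covering
#' every retrieval endpoint: ID lookups, summaries, consensus structures,
#' seed alignments (Stockholm), seed trees (NHX; the RF03120 tree has 19 tips
#' and 17 internal nodes), covariance models, SVG diagrams, tree images,
#' member regions, PDB mappings and keyword searches. Also records a 404 for
#' RF99999, a transient 503 for RF88888, and a permanently pending search
#' job (`job-pending`). All payloads are synthetic stand-ins generated here,
#' not downloaded data.
#'
#' @param replay_dir Directory for the replay store (default: fresh tempdir).
#' @return `replay_dir`, invisibly.
#' @export
build_family_fixtures <- function(replay_dir = tempfile("families")) {
  set.seed(7L)
  json <- function(x) jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)

  pairs <- list(list(accession = "RF00005", id = "tRNA"),
                list(accession = "RF03120", id = "Sarbecovirus-5UTR"))
  for (p in pairs) {
    record_response(replay_dir, endpoint_request("id_lookup", p$accession), json(p))
    record_response(replay_dir, endpoint_request("id_lookup", p$id), json(p))
  }

  record_response(replay_dir, endpoint_request("summary", "RF00005"),
                  json(list(accession = "RF00005", id = "tRNA",
                            description = "Transfer RNA (tRNA), the adaptor molecule of translation",
                            number_of_sequences = 954L,
                            rna_type = "Gene; tRNA")))
  record_response(replay_dir, endpoint_request("summary", "RF03120"),
                  json(list(accession = "RF03120", id = "Sarbecovirus-5UTR",
                            description = "Sarbecovirus 5' UTR: the SARS beta-coronavirus 5'-UTR structured element",
                            number_of_sequences = 19L,
                            rna_type = "Cis-reg")))
  record_response(replay_dir, endpoint_request("summary", "RF99999"),
                  "not found", status = 404L, content_kind = "text")
  record_response(replay_dir, endpoint_request("summary", "RF88888"),
                  "upstream overloaded", status = 503L, content_kind = "text")

  # consensus sequence + WUSS structure (synthetic, balanced by construction)
  record_response(replay_dir, endpoint_request("secondary_structure", "RF00005"),
                  json(list(sequence = "GCCGAAAUAGCUCAGUUGGGAGAGCGCC",
                            wuss = "<<<<<<<___<<<<___>>>>>>>>>>>")))
  record_response(replay_dir, endpoint_request("secondary_structure", "RF03120"),
                  json(list(sequence = "AUAUUAGGUUUUUACCUACCCAGGAAAAGCCAACCAACCUCGAUCUCUUGUAGAUCUGUU",
                            wuss = "::<<<<<<<.<<<___>>>.>>>>>>>::((((<<<<____>>>>,,,,))))::~~~~~")))

  # seed alignments: small synthetic Stockholm records
  record_response(replay_dir, endpoint_request("seed_alignment", "RF00005"),
                  synthetic_stockholm("RF00005", "tRNA", n_rows = 5L, width = 28L,
                                      ss = "<<<<<<<___<<<<___>>>>>>>>>>>"),
                  content_kind = "stockholm")
  record_response(replay_dir, endpoint_request("seed_alignment", "RF03120"),
                  synthetic_stockholm("RF03120", "Sarbecovirus-5UTR", n_rows = 19L,
                                      width = 60L,
                                      ss = "::<<<<<<<.<<<___>>>.>>>>>>>::((((<<<<____>>>>,,,,))))::~~~~~"),
                  content_kind = "stockholm")

  # seed trees: unrooted binary NHX trees (n tips -> n-2 internal nodes)
  record_response(replay_dir, endpoint_request("seed_tree", "RF00005"),
                  synthetic_nhx_tree(5L, "tRNA"), content_kind = "nhx")
  record_response(replay_dir, endpoint_request("seed_tree", "RF03120"),
                  synthetic_nhx_tree(19L, "SARSCoV"), content_kind = "nhx")

  for (p in pairs) {
    record_response(replay_dir, endpoint_request("covariance_model", p$accession),
                    paste0("INFERNAL1/a [1.1.4 | Dec 2020]\nNAME     ", p$id,
                           "\nACC      ", p$accession,
                           "\nSTATES   120\nNODES    40\n//\n"),
                    content_kind = "cm")
    svg <- function(kind) {
      paste0("<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
             "<svg xmlns=\"http://www.w3.org/2000/svg\" width=\"10\" height=\"10\">",
             "<title>", p$accession, " ", kind, "</title><circle r=\"4\"/></svg>\n")
    }
    for (pt in PLOT_TYPES) {
      record_response(replay_dir,
                      endpoint_request("structure_image", p$accession,
                                       params = list(plot_type = pt)),
                      svg(pt), content_kind = "svg")
      record_response(replay_dir,
                      endpoint_request("structure_image", p$accession,
                                       params = list(plot_type = pt, media = "svg")),
                      svg(pt), content_kind = "svg")
    }
    for (lab in c("species", "acc")) {
      record_response(replay_dir,
                      endpoint_request("seed_tree_image", p$accession,
                                       params = list(label = lab)),
                      svg(paste0("tree-", lab)), content_kind = "svg")
    }
  }

  record_response(replay_dir, endpoint_request("regions", "RF00005"),
                  json(list(
                    list(genbank_accession = "SYNBANK01.1", region_start = 101L,
                         region_end = 172L,
                         description = "tRNA-Phe, synthetic locus",
                         species = "Synthetica exempli"),
                    list(genbank_accession = "SYNBANK02.1", region_start = 55L,
                         region_end = 126L,
                         description = "tRNA with\ttab in description",
                         species = "Synthetica altera"))))
  record_response(replay_dir, endpoint_request("pdb_mapping", "RF00005"),
                  json(list(
                    list(pdb_id = "1EHZ", chain = "A", pdb_residue_start = 1L,
                         pdb_residue_end = 76L, cm_position_start = 1L,
                         cm_position_end = 71L))))

  record_response(replay_dir, endpoint_request("text_search", params = list(q = "tRNA")),
                  json(list("RF00005", "RF00005")))
  record_response(replay_dir,
                  endpoint_request("text_search", params = list(q = "coronavirus")),
                  json(list("RF03120")))
  record_response(replay_dir,
                  endpoint_request("text_search", params = list(q = "zzzz-no-such-term")),
                  json(list()))

  record_response(replay_dir,
                  endpoint_request("search_poll", params = list(job_id = "job-pending")),
                  json(list(status = "pending")))
  invisible(replay_dir)
}

# Random gapped Stockholm record with a consensus-structure line.
synthetic_stockholm <- function(accession, id, n_rows, width, ss) {
  stopifnot(nchar(ss) == width)
  rows <- vapply(seq_len(n_rows), function(i) {
    chars <- sample(c("A", "C", "G", "U"), width, replace = TRUE)
    gaps <- sample.int(width, max(1L, width %/% 10L))
    chars[gaps] <- "-"
    paste(chars, collapse = "")
  }, "")
  names(rows) <- sprintf("SYNSEQ%02d.1/1-%d", seq_len(n_rows), width)
  aln <- seed_alignment(rows,
                        column_annotations = c(SS_cons = ss),
                        file_annotations = list(AC = accession, ID = id))
  write_alignment(aln, "stockholm")
}

# Unrooted binary tree with NHX support-value comments on a node.
synthetic_nhx_tree <- function(n_tips, label_prefix) {
  phy <- ape::rtree(n_tips, rooted = FALSE,
                    tip.label = sprintf("_%s%02d.1/1-300", label_prefix,
                                        seq_len(n_tips)))
  newick <- ape::write.tree(phy)
  sub(";$", "[&&NHX:S=synthetic];", newick)
}
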