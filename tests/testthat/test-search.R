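test_that("fragment planning covers short, boundary and long queries", {
  p1 <- plan_fragments(5000, 10000, 3000)
  expect_equal(nrow(p1), 1L)
  expect_equal(c(p1$parent_start, p1$parent_end), c(1L, 5000L))
  p2 <- plan_fragments(10000, 10000, 3000)
  expect_equal(c(p2$parent_start, p2$parent_end), c(1L, 10000L))
  p3 <- plan_fragments(29903, 10000, 3000)
  expect_equal(p3$parent_start, c(1L, 7001L, 14001L, 21001L))
  expect_equal(p3$parent_end, c(10000L, 17000L, 24000L, 29903L))
  expect_error(plan_fragments(100, 10000, 10000), class = "rfamtools_bad_overlap")
  expect_error(plan_fragments(0, 10000, 100), class = "rfamtools_bad_request")
})

test_that("fragment plans cover the parent with the stated overlaps", {
  set.seed(11)
  for (i in 1:50) {
    window <- sample(50:500, 1L)
    overlap <- sample(0:(window - 1L), 1L)
    L <- sample(1:2000, 1L)
    p <- plan_fragments(L, window, overlap)
    expect_equal(p$parent_start[1L], 1L)
    expect_equal(p$parent_end[nrow(p)], L)
    expect_true(all(p$parent_end - p$parent_start + 1L <= window))
    expect_true(all(diff(p$parent_start) > 0L))
    if (nrow(p) > 1L) {
      shared <- p$parent_end[-nrow(p)] - p$parent_start[-1L] + 1L
      expect_true(all(shared[-length(shared)] == overlap))
      expect_true(shared[length(shared)] >= overlap)  # extended last pair
    }
  }
})

test_that("fragment residues reconstruct the parent sequence exactly", {
  set.seed(12)
  for (i in 1:25) {
    L <- sample(200:3000, 1L)
    window <- sample(100:800, 1L)
    overlap <- sample(0:(window - 1L), 1L)
    seq <- normalize_sequence(paste(sample(c("A", "C", "G", "U"), L, TRUE),
                                    collapse = ""))
    frags <- extract_fragments(seq, plan_fragments(L, window, overlap))
    expect_identical(reconstruct_from_fragments(frags), seq$residues)
  }
})

test_that("hit remapping shifts by the fragment offset and validates bounds", {
  frag <- structure(list(parent_id = "g", parent_start = 7001L,
                         parent_end = 17000L, residues = strrep("A", 10000L)),
                    class = "sequence_fragment")
  local <- rfam_hits("RF00507", "Corona_FSE", 6470L, 6551L,
                     bit_score = 67.4, e_value = 1.6e-17)
  mapped <- map_hit_to_parent(local, frag)
  expect_equal(c(mapped$query_start, mapped$query_end), c(13470L, 13551L))
  expect_equal(mapped$strand, local$strand)
  expect_equal(mapped$e_value, local$e_value)
  frag1 <- structure(list(parent_id = "g", parent_start = 1L, parent_end = 400L,
                          residues = strrep("A", 400L)),
                     class = "sequence_fragment")
  id1 <- map_hit_to_parent(rfam_hits("RF00001", "x", 1L, 1L, bit_score = 1,
                                     e_value = 1e-3), frag1)
  expect_equal(c(id1$query_start, id1$query_end), c(1L, 1L))
  b <- map_hit_to_parent(rfam_hits("RF03117", "bCoV-5UTR", 2L, 300L,
                                   bit_score = 90.1, e_value = 2.4e-26), frag1)
  expect_equal(c(b$query_start, b$query_end), c(2L, 300L))
  expect_error(map_hit_to_parent(rfam_hits("RF00001", "x", 390L, 401L,
                                           bit_score = 1, e_value = 1e-3), frag1),
               class = "rfamtools_coordinate_out_of_range")
})

test_that("deduplication keeps the lower e-value copy and sorts stably", {
  dup <- rfam_hits(rep("RF00507", 2), rep("Corona_FSE", 2),
                   query_start = c(13470L, 13470L), query_end = c(13551L, 13551L),
                   bit_score = c(67, 67), e_value = c(1e-8, 1e-10))
  out <- deduplicate_hits(dup)
  expect_equal(nrow(out), 1L)
  expect_equal(out$e_value, 1e-10)
  expect_equal(nrow(deduplicate_hits(rfam_hits())), 0L)
})

test_that("deduplication is idempotent and order-insensitive", {
  set.seed(13)
  for (i in 1:30) {
    base <- random_hit_instance()$hits
    dups <- base[sample.int(nrow(base), nrow(base), replace = TRUE), ]
    class(dups) <- c("rfam_hits", "data.frame")
    once <- deduplicate_hits(dups)
    expect_identical(deduplicate_hits(once), once)
    perm <- dups[sample.int(nrow(dups)), ]
    class(perm) <- c("rfam_hits", "data.frame")
    out_perm <- deduplicate_hits(perm)
    expect_identical(out_perm[, names(out_perm) != "alignment"],
                     once[, names(once) != "alignment"])
  }
})

test_that("a single-fragment search equals the direct fragment search", {
  dir <- withr::local_tempdir()
  seq <- normalize_sequence(paste(rep("ACGU", 200), collapse = ""), "short")
  truth <- data.frame(accession = "RF91111", id = "SYN_one", start = 101L,
                      end = 140L, strand = "plus", bit_score = 50,
                      e_value = 1e-9, stringsAsFactors = FALSE)
  frags <- extract_fragments(seq, plan_fragments(800, 10000, 1000))
  rfamtools:::record_search_responses(dir, frags, truth, "single")
  conn <- rfam_connection("replay", replay_dir = dir)
  via_pipeline <- rfam_sequence_search(seq, conn, search_options(), clans = character())
  handle <- submit_search(conn, frags[[1L]])
  direct <- rfamtools:::parse_hit_payload(poll_search(conn, handle)$hits)
  expect_equal(as.data.frame(via_pipeline), as.data.frame(direct))
})

test_that("an empty recorded response yields an empty hit table", {
  dir <- withr::local_tempdir()
  seq <- normalize_sequence(strrep("ACGU", 125), "tiny")
  frags <- extract_fragments(seq, plan_fragments(500, 10000, 1000))
  rfamtools:::record_search_responses(dir, frags, data.frame(
    accession = character(), id = character(), start = integer(),
    end = integer(), strand = character(), bit_score = numeric(),
    e_value = numeric()), "empty")
  conn <- rfam_connection("replay", replay_dir = dir)
  hits <- rfam_sequence_search(seq, conn, search_options(), clans = character())
  expect_s3_class(hits, "rfam_hits")
  expect_equal(nrow(hits), 0L)
})

test_that("a failing fragment aborts the whole search", {
  dir <- withr::local_tempdir()
  w <- generate_world(9L, genome_length = 15000L, replay_dir = dir)
  # remove the second fragment's poll entry: its search can no longer finish
  poll2 <- endpoint_request("search_poll", params = list(job_id = "world9-2"))
  id <- rfamtools:::request_entry_id(poll2)
  file.remove(file.path(dir, paste0(id, c(".json", ".body"))))
  conn <- rfam_connection("replay", replay_dir = dir)
  expect_error(rfam_sequence_search(w$genome, conn, w$options, character()),
               class = "rfamtools_fragment_search_failed")
})

test_that("planted motifs remap to their parent coordinates from any fragment", {
  # a motif inside the fragment overlap is reported by both fragments and must
  # come back once, at the planted position
  dir <- withr::local_tempdir()
  set.seed(14)
  L <- 12000L
  genome <- paste(sample(c("A", "C", "G", "U"), L, TRUE), collapse = "")
  truth <- data.frame(accession = "RF92222", id = "SYN_straddle",
                      start = 9200L, end = 9240L, strand = "plus",
                      bit_score = 60, e_value = 1e-12, stringsAsFactors = FALSE)
  seq <- normalize_sequence(genome, "straddle")
  frags <- extract_fragments(seq, plan_fragments(L, 10000L, 1000L))
  # the motif lies in [9001, 10000], the overlap shared by both fragments
  expect_true(truth$start >= frags[[2L]]$parent_start &&
                truth$end <= frags[[1L]]$parent_end)
  rfamtools:::record_search_responses(dir, frags, truth, "straddle")
  conn <- rfam_connection("replay", replay_dir = dir)
  hits <- rfam_sequence_search(seq, conn,
                               search_options(fragments_overlap = 1000L),
                               clans = character())
  expect_equal(nrow(hits), 1L)
  expect_equal(c(hits$query_start, hits$query_end), c(9200L, 9240L))
})
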