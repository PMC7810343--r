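test_that("sequence normalization case-folds, converts DNA and is idempotent", {
  expect_equal(normalize_sequence("acguACGU")$residues, "ACGUACGU")
  expect_equal(normalize_sequence("atgc")$residues, "AUGC")
  expect_equal(normalize_sequence(" a c\ngu\t")$residues, "ACGU")
  once <- normalize_sequence("atgcRYN")$residues
  expect_equal(normalize_sequence(once)$residues, once)  # idempotent
  expect_equal(once, "AUGCRYN")  # IUPAC ambiguity codes preserved
})

test_that("sequence normalization rejects empty and illegal input", {
  expect_error(normalize_sequence(""), class = "rfamtools_empty_sequence")
  expect_error(normalize_sequence("   \n"), class = "rfamtools_empty_sequence")
  err <- tryCatch(normalize_sequence("ACX"), error = identity)
  expect_s3_class(err, "rfamtools_illegal_residue")
  expect_equal(err$position, 3L)
  expect_equal(err$residue, "X")
})

test_that("accession classification separates RFxxxxx from IDs", {
  expect_equal(validate_accession("RF00005"), "accession")
  expect_equal(validate_accession("tRNA"), "id")
  expect_equal(validate_accession("RF0005"), "id")    # wrong digit count
  expect_equal(validate_accession("RF000051"), "id")
  expect_error(validate_accession(""), class = "rfamtools_bad_token")
})

test_that("hit construction validates scores and normalizes minus-strand coordinates", {
  h <- rfam_hits("RF00001", "fam", query_start = 120L, query_end = 80L,
                 bit_score = 10, e_value = 1e-5)
  expect_equal(h$query_start, 80L)
  expect_equal(h$query_end, 120L)
  expect_equal(h$strand, "minus")
  expect_error(rfam_hits("RF1", "x", 1L, 2L, bit_score = 1, e_value = 1e-3),
               class = "rfamtools_bad_hit")
  expect_error(rfam_hits("RF00001", "x", 1L, 2L, bit_score = 1, e_value = 0),
               class = "rfamtools_bad_hit")
})

test_that("search options enforce the overlap/window and threshold invariants", {
  opts <- search_options(fragments_overlap = 3000)
  expect_equal(opts$window, 10000L)
  expect_false(opts$clan_competition_filter)
  expect_error(search_options(fragments_overlap = 10000),
               class = "rfamtools_bad_overlap")
  expect_error(search_options(clan_overlap_threshold = 0),
               class = "rfamtools_bad_options")
  expect_error(search_options(clan_overlap_threshold = 1.2),
               class = "rfamtools_bad_options")
})

test_that("consensus-structure records require equal lengths and balanced brackets", {
  cs <- consensus_structure("ACGU", "<..>")
  expect_equal(cs$notation, "DB")
  expect_error(consensus_structure("ACGU", "<.>"),
               class = "rfamtools_length_mismatch")
  expect_error(consensus_structure("ACGUA", "<<(>>"),
               class = "rfamtools_unbalanced_structure")
})

test_that("seed alignments reject ragged rows and duplicate names", {
  expect_error(seed_alignment(c(a = "AC-G", b = "ACG")),
               class = "rfamtools_ragged_alignment")
  expect_error(seed_alignment(stats::setNames(c("ACGU", "ACGU"), c("a", "a"))),
               class = "rfamtools_bad_alignment")
  expect_error(seed_alignment(c(a = "ACGU"), column_annotations = c(SS = "...")),
               class = "rfamtools_ragged_alignment")
})

test_that("the clan snapshot loads as a one-to-one accession map", {
  clans <- read_clan_table()
  expect_true(length(clans) >= 7L)
  expect_false(anyDuplicated(names(clans)) > 0L)
  expect_equal(unname(clans["RF03120"]), "CL00116")
})
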