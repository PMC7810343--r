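test_that("replay fetch returns recorded bodies verbatim and deterministically", {
  dir <- withr::local_tempdir()
  req <- endpoint_request("summary", "RF12345")
  body <- "{\"accession\":\"RF12345\",\"id\":\"toy\",\"description\":\"toy family\"}"
  record_response(dir, req, body)
  conn <- rfam_connection("replay", replay_dir = dir)
  res1 <- fetch(conn, req)
  res2 <- fetch(conn, req)
  expect_identical(res1$body, body)
  expect_identical(res1, res2)  # referential transparency under replay
})

test_that("request canonicalization ignores parameter order", {
  a <- endpoint_request("structure_image", "RF00005",
                        params = list(plot_type = "cons", media = "svg"))
  b <- endpoint_request("structure_image", "RF00005",
                        params = list(media = "svg", plot_type = "cons"))
  expect_identical(rfamtools:::request_entry_id(a),
                   rfamtools:::request_entry_id(b))
  expect_error(endpoint_request("not_a_kind"), class = "rfamtools_bad_request")
})

test_that("unrecorded requests are loud replay misses, never silent calls", {
  dir <- withr::local_tempdir()
  conn <- rfam_connection("replay", replay_dir = dir)
  expect_error(fetch(conn, endpoint_request("summary", "RF00001")),
               class = "rfamtools_replay_miss")
})

test_that("a recorded 404 maps to the family-not-found condition", {
  conn <- family_conn()
  expect_error(fetch(conn, endpoint_request("summary", "RF99999")),
               class = "rfamtools_family_not_found")
})

test_that("transient failures are retried with capped, non-decreasing backoff", {
  slept <- numeric()
  conn <- rfam_connection("replay", replay_dir = family_store,
                          max_retries = 3L, backoff_initial = 0.01,
                          backoff_multiplier = 2, backoff_cap = 0.03,
                          sleep_fn = function(s) slept <<- c(slept, s))
  expect_error(fetch(conn, endpoint_request("summary", "RF88888")),
               class = "rfamtools_service_unavailable")
  expect_length(slept, 3L)                  # retry count == configured cap
  expect_true(all(diff(slept) >= 0))        # monotone non-decreasing
  expect_true(all(slept <= 0.03))           # capped
  expect_equal(slept, c(0.01, 0.02, 0.03))
})

test_that("fragment submission enforces the 10,000-nt service limit", {
  conn <- family_conn()
  frag_of <- function(n) {
    structure(list(parent_id = "q", parent_start = 1L, parent_end = n,
                   residues = strrep("A", n)),
              class = "sequence_fragment")
  }
  expect_error(submit_search(conn, frag_of(10001L)),
               class = "rfamtools_fragment_too_long")
  # a recorded submission round-trips to its recorded handle
  dir <- withr::local_tempdir()
  frag <- frag_of(9999L)
  record_response(dir,
                  endpoint_request("search_submit",
                                   params = list(seq_digest = rfamtools:::md5_string(frag$residues))),
                  "{\"job_id\":\"job-77\"}")
  conn2 <- rfam_connection("replay", replay_dir = dir)
  handle <- submit_search(conn2, frag)
  expect_equal(handle$job_id, "job-77")
})

test_that("polling distinguishes pending, done and expired jobs", {
  conn <- family_conn()
  pending <- structure(list(job_id = "job-pending", fragment = NULL),
                       class = "job_handle")
  expect_equal(poll_search(conn, pending)$status, "pending")
  # pending results never mutate
  expect_equal(poll_search(conn, pending)$status, "pending")
  unknown <- structure(list(job_id = "job-unknown", fragment = NULL),
                       class = "job_handle")
  expect_error(poll_search(conn, unknown), class = "rfamtools_job_expired")
  w <- generate_world(3L, replay_dir = withr::local_tempdir())
  done <- structure(list(job_id = "world3-1", fragment = NULL),
                    class = "job_handle")
  res <- poll_search(rfam_connection("replay", replay_dir = w$replay_dir), done)
  expect_equal(res$status, "done")
  expect_true(length(res$hits) >= 0L)
})

test_that("accession/ID lookup is a bijection on fixture families", {
  conn <- family_conn()
  pair <- lookup_id(conn, "RF00005")
  expect_equal(pair$id, "tRNA")
  expect_equal(lookup_id(conn, "tRNA")$accession, "RF00005")
  expect_equal(lookup_id(conn, lookup_id(conn, "RF03120")$id)$accession, "RF03120")
})

test_that("keyword search de-duplicates and handles empty results", {
  conn <- family_conn()
  expect_equal(rfam_text_search(conn, "tRNA"), "RF00005")  # dup rows collapsed
  expect_equal(rfam_text_search(conn, "zzzz-no-such-term"), character(0))
  expect_error(rfam_text_search(conn, ""), class = "rfamtools_bad_request")
})
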