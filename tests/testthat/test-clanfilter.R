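hit_row <- function(acc, start, end, e_value = 1e-10, bit = 50,
                    strand = "plus", id = acc) {
  rfam_hits(acc, id, as.integer(start), as.integer(end), strand = strand,
            bit_score = bit, e_value = e_value)
}

bind_hits <- function(...) {
  out <- do.call(rbind, list(...))
  class(out) <- c("rfam_hits", "data.frame")
  out
}

test_that("overlap fraction is symmetric, interval-exact and containment-aware", {
  a <- hit_row("RF03117", 2, 300)
  b <- hit_row("RF03120", 2, 300)
  expect_equal(overlap_fraction(a, b)$fraction_of_shortest, 1.0)
  u3 <- hit_row("RF03125", 29537, 29871)
  pk <- hit_row("RF00165", 29604, 29663)
  rep1 <- overlap_fraction(u3, pk)
  expect_equal(rep1$overlap_nt, 60L)       # the pseudoknot is fully contained
  expect_equal(rep1$fraction_of_shortest, 1.0)
  expect_equal(overlap_fraction(pk, u3)$overlap_nt, rep1$overlap_nt)
  expect_equal(overlap_fraction(hit_row("RF00001", 1, 100),
                                hit_row("RF00002", 200, 300))$fraction_of_shortest, 0)
  # partial overlap: 50 shared positions over a 100-nt shorter hit
  expect_equal(overlap_fraction(hit_row("RF00001", 1, 100),
                                hit_row("RF00002", 51, 250))$fraction_of_shortest, 0.5)
})

test_that("clan competition keeps the published three survivors on the case-study hits", {
  kept <- clan_competition(case_study_hits(), case_study_clans(), threshold = 0.5)
  expect_equal(nrow(kept), 3L)
  expect_setequal(kept$rfam_id,
                  c("Sarbecovirus-5UTR", "Corona_FSE", "Sarbecovirus-3UTR"))
  expect_equal(kept$rfam_id,  # query-coordinate order preserved
               c("Sarbecovirus-5UTR", "Corona_FSE", "Sarbecovirus-3UTR"))
})

test_that("disjoint same-clan hits and overlapping different-clan hits both survive", {
  clans <- c(RF00001 = "CLA", RF00002 = "CLA", RF00003 = "CLB")
  disjoint <- bind_hits(hit_row("RF00001", 1, 100, 1e-12),
                        hit_row("RF00002", 200, 300, 1e-6))
  expect_equal(nrow(clan_competition(disjoint, clans, 0.5)), 2L)
  crossclan <- bind_hits(hit_row("RF00001", 1, 100, 1e-12),
                         hit_row("RF00003", 1, 100, 1e-6))
  expect_equal(nrow(clan_competition(crossclan, clans, 0.5)), 2L)
  unclanned <- bind_hits(hit_row("RF00001", 1, 100, 1e-12),
                         hit_row("RF00009", 1, 100, 1e-2))
  expect_equal(nrow(clan_competition(unclanned, clans, 0.5)), 2L)
})

test_that("hits on opposite strands never compete", {
  clans <- c(RF00001 = "CLA", RF00002 = "CLA")
  mixed <- bind_hits(hit_row("RF00001", 1, 100, 1e-12, strand = "plus"),
                     hit_row("RF00002", 1, 100, 1e-6, strand = "minus"))
  expect_equal(nrow(clan_competition(mixed, clans, 0.5)), 2L)
})

test_that("the filter is idempotent and permutation-invariant", {
  set.seed(21)
  for (i in 1:60) {
    inst <- random_hit_instance()
    once <- clan_competition(inst$hits, inst$clans, 0.5)
    expect_identical(clan_competition(once, inst$clans, 0.5), once)
    perm <- inst$hits[sample.int(nrow(inst$hits)), ]
    class(perm) <- c("rfam_hits", "data.frame")
    expect_identical(as.data.frame(clan_competition(perm, inst$clans, 0.5)),
                     as.data.frame(once))
  }
})

test_that("no two retained same-clan hits overlap at or above the threshold", {
  set.seed(22)
  for (i in 1:40) {
    inst <- random_hit_instance()
    thr <- sample(c(0.3, 0.5, 0.8), 1L)
    kept <- clan_competition(inst$hits, inst$clans, thr)
    if (nrow(kept) < 2L) next
    clan_of <- unname(inst$clans[kept$rfam_accession])
    for (a in seq_len(nrow(kept) - 1L)) {
      for (b in (a + 1L):nrow(kept)) {
        if (is.na(clan_of[a]) || is.na(clan_of[b]) || clan_of[a] != clan_of[b]) next
        if (kept$strand[a] != kept$strand[b]) next
        frac <- overlap_fraction(kept[a, ], kept[b, ])$fraction_of_shortest
        expect_lt(frac, thr)
      }
    }
  }
})

test_that("raising the threshold never removes more hits", {
  set.seed(23)
  for (i in 1:40) {
    inst <- random_hit_instance()
    thresholds <- c(0.2, 0.5, 0.9, 1.0)
    keys <- lapply(thresholds, function(t) {
      k <- clan_competition(inst$hits, inst$clans, t)
      paste(k$rfam_accession, k$query_start, k$query_end, k$strand)
    })
    for (j in seq_along(thresholds)[-1L]) {
      expect_true(all(keys[[j - 1L]] %in% keys[[j]]))
    }
  }
})

test_that("disabling the filter exposes the nested case-study hits", {
  all_hits <- case_study_hits()
  kept <- clan_competition(all_hits, case_study_clans(), 0.5)
  key <- function(h) paste(h$rfam_accession, h$query_start, h$query_end)
  expect_true(all(key(kept) %in% key(all_hits)))
  expect_gt(nrow(all_hits), nrow(kept))  # filter-off strictly contains filter-on
})
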