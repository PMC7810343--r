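---
title: "Methods: fragmented Rfam search, clan competition, and offline replay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fragmented Rfam search, clan competition, and offline replay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rfamtools)
```

This vignette documents how `rfamtools` does what it does: the fragmentation
and remapping arithmetic behind unlimited-length sequence search, the exact
semantics of clan-competition filtering, the transport and replay design
that keeps everything deterministic offline, what the synthetic fixtures do
and do not emulate, and the numerical and design choices made where the
behaviour was genuinely open.

## Searching sequences of unlimited length

The Rfam sequence-search service scans a query against the library of family
covariance models, but accepts at most `w` = 10,000 nt per query. The scan
itself always happens server-side; `rfamtools` orchestrates it.

A query of length `L ≤ w` is submitted as a single fragment `[1, L]`. A
longer query is split by `plan_fragments(L, w, v)` into windows starting at
`1, 1 + (w − v), 1 + 2(w − v), …` for a user-chosen overlap `v`
(`fragments_overlap`, in nucleotides, `0 ≤ v < w`). Every fragment except
possibly the last spans exactly `w` nt; the last ends exactly at `L`, so the
final pair of fragments may share more than `v` positions. We deliberately
never emit a short "tail" window followed by nothing: ending the last
fragment at `L` while keeping the arithmetic start positions means every
position of the query is scanned within at least one full-context window.

```{r}
plan_fragments(29903, 10000, 3000)
```

Coordinates are 1-based inclusive everywhere in the package; conversion to
anything else happens only inside slicing code. A hit reported at
fragment-local `(s, e)` maps to the parent as `(s + o, e + o)` with
`o = parent_start − 1` (`map_hit_to_parent()`), leaving strand and scores
untouched.

The overlap exists so that a motif lying across a window boundary is seen in
full by at least one window: any hit shorter than `v + 1` nt is guaranteed
to be fully contained in some fragment. The same guarantee implies hits
inside an overlap are reported twice, so `deduplicate_hits()` collapses
hits that agree on (family accession, parent start, parent end, strand),
keeping the copy with the lower e-value, and sorts by query coordinates —
which makes the operation idempotent and independent of input order.
Near-duplicates with *shifted* boundaries (a motif truncated at a window
edge) are intentionally **not** merged here: merging would require guessing
which boundary is right. With an overlap comfortably larger than the motif
(the bundled case study uses `v` = 3,000 nt for elements ≤ 353 nt), the
untruncated copy exists and the truncated one is either identical (and
collapses) or falls to clan competition as biological redundancy.

A failure on any fragment aborts the whole search with a structured error
rather than returning partial results: a silently missing genome segment
would look exactly like "no non-coding RNA there", and a loud error is the
lesser evil.

## Clan competition

Rfam clans group families that are evolutionarily related or structurally
similar enough that two of their hits over the same region annotate the same
element. The filter (`clan_competition()`) implements:

* **Overlap measure.** For hits `a`, `b` (1-based inclusive),
  `overlap = max(0, min(end_a, end_b) − max(start_a, start_b) + 1)`, and the
  decisive quantity is `overlap / min(len_a, len_b)` — the fraction *of the
  shorter hit*. Containment therefore always scores 1.0. The default
  threshold is 0.5.
* **Rank order.** Ascending e-value, ties broken by descending bit score,
  then by accession (and finally by coordinates, so the order is total).
  E-value is primary because it is the quantity the filter is defined to
  discard on; bit score covers e-value ties.
* **Greedy kept-set semantics.** Walk the hits best-first; keep a hit unless
  it shares a clan *and strand* with an **already-kept** hit at or above the
  threshold overlap. Unclanned families are always kept. For chains A–B–C
  where A overlaps B and B overlaps C but A does not overlap C, this keeps A
  and C: discards are compared against kept hits only, never against other
  discarded hits. That choice is one of two defensible readings; it is fixed
  here, documented, and enforced by a property test against an independently
  written oracle.
* **Strands never compete across each other**: sense and antisense elements
  are distinct annotations.

These semantics give three useful invariants, all under test: the filter is
idempotent, permutation-invariant, and monotone in the threshold (raising
the threshold never removes more hits).

```{r}
kept <- clan_competition(case_study_hits(), case_study_clans(), threshold = 0.5)
kept$rfam_id
```

Clan membership comes from a bundled snapshot table
(`inst/extdata/clans.tsv`, two-column TSV) so filtering is deterministic
offline; the CLI's `refresh-clans` command rewrites a copy of it.

## Transport and replay

Every remote interaction is an `endpoint_request()` passed to `fetch()` on a
connection. The replay backend resolves a request against an on-disk store —
one JSON envelope (canonical request, status, content kind) plus one raw
body file per entry — keyed by a canonicalized form of the request: endpoint
kind, sorted parameters, and for sequence submissions the MD5 digest of the
uppercased fragment. Canonicalization makes the key independent of parameter
order and of the client that recorded it. In replay mode an unrecorded
request raises a replay-miss error; nothing ever falls through to the
network, which is what lets the full test suite assert zero network use.

Numerical choices, all configurable on `rfam_connection()`:

* transient-failure retries: up to 3, with exponential backoff 5 s × 1.5ⁿ
  capped at 60 s (delays are monotone non-decreasing by construction);
* job polling uses the same schedule, with a 10-minute default budget per
  fragment;
* live submissions are spaced at least 1 s apart, as politeness to a public
  service.

The service's job-expiry behaviour is undocumented, so an unknown job is
conservatively treated as expired. Payloads that are opaque at this layer
(SVG, CM, NHX, images) stay opaque: the transport returns bytes verbatim and
the format layer validates only what it needs (an `INFERNAL` header token, an
`<svg>` root element).

## Formats

* **Stockholm.** The parser captures sequence rows, `#=GC` column
  annotations (concatenated across interleaved blocks, so multi-block input
  parses identically to its single-block form), `#=GR` row annotations and
  `#=GF`/`#=GS` file annotations; the writer emits a single block that
  round-trips exactly (property-tested on random alignments, 1–20 rows,
  widths 1–200, gap density 0–0.5). The `pfam` export is pinned as
  single-block Stockholm with the consensus structure rendered in extended
  dot-bracket instead of WUSS.
* **Gaps.** Both `-` and `.` count as gaps for ungapped FASTA export,
  because Rfam Stockholm uses `.` for insert-state columns.
* **WUSS → dot-bracket.** Bracket families `<>`, `()`, `[]`, `{}` and
  pseudoknot letter pairs (`Aa`, `Bb`, …) pass through unchanged — extended
  dot-bracket retains families, it does not flatten to `()` — and every
  unpaired WUSS symbol (`:`, `_`, `-`, `~`, `,`, `.`) becomes `.`. Balance
  is validated per family with a stack; conversion provably preserves the
  pairing map (tested against an independent matcher).
* **NHX trees.** `[...]` comment blocks are preserved opaquely and the
  Newick skeleton is parsed with `ape`. The root counts as internal iff it
  has at least two children; a lone labelled tip is special-cased to 1 tip /
  0 internal nodes (`ape` would report a phantom internal node).
* **TSV exports** escape embedded tabs/newlines so arbitrary description
  fields survive a round trip.

Degenerate inputs are errors, not guesses: empty sequences, residues outside
the IUPAC alphabet (ambiguity codes are accepted and forwarded — the service
tolerates them; the position of the first illegal character is reported),
ragged alignments, unbalanced structures, overlap ≥ window.

## What the synthetic fixtures emulate — and what they do not

`generate_world()` builds a random genome with literal family motifs
(30–60 nt) planted at known non-overlapping positions, plus the replay store
an *exact-match* search service would produce: each fragment reports every
motif fully contained in it, at fragment-local coordinates. This is the
right fixture for the orchestration logic — fragmentation, remapping,
deduplication and filtering are exercised end-to-end, and recovery of the
planted annotations must be exact (tested over 20 seeds).

`build_case_study()` does the same for a 29,903-nt genome carrying seven
coronavirus non-coding RNA elements (two 5'-UTR variants at 2–300, the
frameshifting stem-loop at 13470–13551, and four overlapping 3'-UTR
elements) with the clan groupings those families have: the two 5'-UTR
families in one clan, the two 3'-UTR families plus the 3'-UTR pseudoknot and
s2m in another, the frameshifting element unclanned. The genome background
is random — a labelled synthetic stand-in, not the real viral sequence — and
the e-values/bit scores are synthetic constants chosen once so that the
Sarbecovirus-specific hit ranks best within each clan, which is the ranking
the known survivor set implies. Searching it with a 3,000-nt overlap returns
the seven hits with the filter off and exactly
{Sarbecovirus-5UTR, Corona_FSE, Sarbecovirus-3UTR} with it on; because every
competing overlap in that table is a containment (fraction 1.0), the
survivor set is the same at any threshold up to 1.0.

What none of this emulates: covariance-model scoring itself (hit boundaries
in real searches wobble with the model, scores depend on the Rfam release),
truncated boundary hits, minus-strand hits from the live service, server
latency, or release-dependent hit counts. Passing tests demonstrate the
client-side pipeline is exact; they say nothing about what a given Rfam
release will return for a given genome, which is why live-service numbers
are reproduced on replay fixtures rather than asserted against the network.

## Problem sizes

The property suites run at sizes chosen to give dense coverage while staying
desk-scale: 1,000 random ≤8-hit instances against the independent
clan-filter oracle (plus idempotence, permutation-invariance and
threshold-monotonicity on each); 500 random (length, window, overlap)
triples for fragment-cover reconstruction; 200 random alignments for the
Stockholm round trip; 200 random balanced structures for WUSS conversion;
20 seeded worlds for end-to-end recovery.

## Known limitations

* The live HTTP backend maps endpoints best-effort and is exercised only
  when network is available; the replay backend is the contractual, tested
  path.
* The `pfam` dialect is pinned by this package's definition (single-block,
  dot-bracket consensus), not reverse-engineered from server output.
* Clan snapshots age; `refresh-clans` exists precisely because clan
  membership changes across Rfam releases.
* No local Infernal execution: a hit is whatever the (replayed or live)
  service reports.
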