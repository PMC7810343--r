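# rfamtools

An R client toolkit for the [Rfam](https://rfam.org) database of non-coding
RNA families. Rfam defines each family by a seed alignment, a consensus
secondary structure and a covariance model (a profile stochastic context-free
grammar combining sequence and structure conservation). `rfamtools` gives
genomic workflows programmatic access to all of it: keyword and sequence
search, and retrieval of family summaries, consensus structures, seed
alignments, covariance models, phylogenetic trees, member sequence regions
and PDB mappings — each converted into a standard bioinformatics format
(Stockholm, FASTA, extended dot-bracket, WUSS, NHX, Infernal CM, SVG, TSV).

It is written for RNA bioinformaticians who want to annotate non-coding RNA
across whole genomes or pipelines rather than through the interactive web
interface.

Two features do the heavy lifting:

* **Unlimited-length sequence search.** The search service accepts at most
  10,000 nt per query. A longer query of length *L* is split into windows
  starting at 1, 1 + (*w* − *v*), 1 + 2(*w* − *v*), … (window *w* = 10,000,
  overlap *v* chosen by the user), each fragment is searched separately, and
  every hit at fragment-local position (*s*, *e*) is remapped to the parent as
  (*s* + offset, *e* + offset) with offset = fragment start − 1. Hits found
  twice inside an overlap are collapsed, keeping the copy with the lower
  e-value.
* **Clan competition.** Rfam groups related families into clans; two
  same-clan hits covering the same region are redundant. Hits are ranked by
  e-value (ties: higher bit score, then accession) and walked best-first: a
  hit is discarded iff it shares a clan and strand with an already-kept hit
  and their overlap is at least a threshold fraction (default 0.5) of the
  *shorter* hit. Disabling the filter keeps nested elements visible.

All remote interaction runs through a pluggable transport
(`rfam_connection()`): a live HTTP backend, or a deterministic on-disk
**replay store** that makes every workflow — and the entire test suite —
runnable offline with zero network calls.

## Worked example

The bundled case-study fixture is a synthetic 29,903-nt coronavirus-like
genome whose recorded search responses place seven non-coding RNA elements
at their known genome coordinates:

```r
library(rfamtools)

fx   <- build_case_study()                     # genome + replay store
conn <- rfam_connection("replay", replay_dir = fx$replay_dir)

hits <- rfam_sequence_search(fx$genome, conn,
                             search_options(fragments_overlap = 3000),
                             clans = fx$clans)
hits
#> Rfam hits: 7
#>  rfam_accession           rfam_id query_start query_end strand bit_score  e_value
#>         RF03117         bCoV-5UTR           2       300   plus      90.1  2.4e-26
#>         RF03120 Sarbecovirus-5UTR           2       300   plus     141.8  1.1e-38
#>         RF00507        Corona_FSE       13470     13551   plus      67.4  1.6e-17
#>         RF03122         bCoV-3UTR       29519     29871   plus      85.2  3.0e-24
#>         RF03125 Sarbecovirus-3UTR       29537     29871   plus     120.6  5.0e-33
#>         RF00165        Corona_pk3       29604     29663   plus      38.5  2.1e-09
#>         RF00164               s2m       29728     29770   plus      41.2  6.8e-08
```

The 29,903-nt query was searched as four fragments (1–10000, 7001–17000,
14001–24000, 21001–29903) and the hits remapped to genome coordinates: both
5'-UTR variants at 2–300, the frameshifting element at 13470–13551, and four
overlapping elements in the 3'-UTR. Turning on clan competition removes the
redundant clan-mates (the bCoV UTRs are essentially the same hits as the
Sarbecovirus ones; the pseudoknot and s2m sit inside the larger 3'-UTR):

```r
opts <- search_options(fragments_overlap = 3000, clan_competition_filter = TRUE)
rfam_sequence_search(fx$genome, conn, opts, clans = fx$clans)$rfam_id
#> [1] "Sarbecovirus-5UTR" "Corona_FSE"        "Sarbecovirus-3UTR"
```

Family data come back in standard formats:

```r
fam <- build_family_fixtures()
conn2 <- rfam_connection("replay", replay_dir = fam)

rfam_consensus_structure(conn2, "RF03120", format = "DB")
#> <consensus_structure> DB, 60 positions
#> AUAUUAGGUUUUUACCUACCCAGGAAAAGCCAACCAACCUCGAUCUCUUGUAGAUCUGUU
#> ..<<<<<<<.<<<...>>>.>>>>>>>..((((<<<<....>>>>....)))).......

rfam_seed_tree(conn2, "RF03120")
#> <nhx_tree> 19 tips, 17 internal nodes, with branch lengths; 1 NHX comment block(s)
```

## Command line

Every operation is also a subcommand of the bundled script
(`inst/scripts/rfamtools`):

```sh
rfamtools search-sequence genome.fasta --overlap 3000 --no-clan-filter \
    --offline --replay-dir store/            # 7-row hit TSV
rfamtools structure RF00005 --format DB      # two-line consensus record
rfamtools seed-alignment RF00005 --format fastau
rfamtools cm RF00005 --out RF00005.cm
```

`--offline` forces the replay backend; exit codes distinguish validation
errors (2), missing families (3) and transport failures (4).

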