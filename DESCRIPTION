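Package: rfamtools
Title: Client Toolkit for the Rfam Database of RNA Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Programmatic access to the Rfam database of non-coding RNA
    families: keyword and sequence search (with automatic splitting of
    queries longer than the server's 10,000-nucleotide limit into
    overlapping fragments and remapping of hits to the original
    coordinates), clan-competition filtering of overlapping hits, and
    retrieval of family data (summaries, consensus secondary structures,
    seed alignments, covariance models, phylogenetic trees, member
    sequence regions and PDB mappings) with converters to standard
    bioinformatics formats (Stockholm, FASTA, extended dot-bracket, WUSS,
    NHX, Infernal CM, SVG, TSV). All remote interaction goes through a
    pluggable transport with a deterministic replay store, so workflows
    and tests run fully offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    ape,
    seqinr,
    stats,
    tools,
    utils
Suggests:
    curl,
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
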