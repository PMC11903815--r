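Package: MetaPathDA
Title: EC-Centric Pathway Mapping and Differential Abundance for Metaproteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps peptide- and protein-level identifications from
    metaproteomic experiments onto metabolic pathway graphs via Enzyme
    Commission (EC) numbers. Parses KGML-dialect pathway graphs and EC
    link tables, resolves peptides or UniProtKB accessions to EC numbers
    and taxa through a pluggable (offline, table-backed) resolver, builds
    an interlinked item-EC-node-pathway-taxon index, ranks and filters
    pathways by match counts, computes per-node two-group differential
    abundance (proportion difference for peptides, log2 fold-change of
    abundance sums for proteins) with diverging-scale normalization,
    summarizes per-node taxonomy by lowest common ancestor, and exports
    dense CSV mappings and standalone SVG pathway overlays. Includes a
    seed-deterministic synthetic-data generator with planted enrichment
    effects so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    xml2,
    jsonlite,
    yaml,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
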