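Package: glycoconj
Title: Standardization, Canonical Identification and Exchange of
    Glycopeptide and Glycoprotein Entries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for standardizing glycoconjugate identifications from
    glycoproteomics experiments. Parses and validates glycopeptide and
    glycoprotein entries in the GlyComb tab-separated dialect, computes
    monoisotopic masses of monosaccharide compositions, assigns
    deterministic content-addressed GlyComb-style identifiers so that
    identical entries always receive identical IDs, extracts entries from
    PMI-Byonic-style summary worksheets by modification-mass matching
    against a local FASTA sequence database, classifies entries by
    glycosylation class (N-linked, O-linked, C-mannosylation), exports
    entries as GlycoCoO-style RDF triples, detects cross-dataset overlaps
    via canonical IDs, and generates seeded synthetic ground-truth
    worksheets for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    Biostrings,
    digest,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
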