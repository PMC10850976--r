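# glycoconj

Standardization, canonical identification and exchange of glycopeptide and
glycoprotein entries from glycoproteomics experiments.

## The problem

Glycoproteomics LC-MS/MS experiments identify which residues of which
peptides carry which glycans — but the results are scattered across
repositories in each lab's own spreadsheet format, and there is no
identifier that lets two labs recognize that they observed *the same
glycoconjugate*: the same peptide (or protein) with the same set of
(site, glycan) modifications. Protein-level accessions are too coarse —
one peptide can carry many distinct glycosylation patterns, each
potentially disease-relevant.

`glycoconj` implements the GlyComb-style standardization method around a
simple contract: a glycoconjugate entry is a peptide sequence or UniProt
accession together with its full set of (residue number, glycan) pairs, and
**identical entries always receive identical identifiers**. IDs here are
content-addressed: the entry is serialized into a canonical form

```
kind|key|pos1:glycan1;pos2:glycan2;...
```

(sites sorted by position with unknown `?` sites last, glycan compositions
re-serialized in a fixed symbol order) and the ID is `GC` plus the first
24 bits of the SHA-256 hash of that string, printed as 6 uppercase hex
characters. Equal entries hash equally on any machine with no central
registry; hash collisions between distinct entries are detected and
reported, never silently merged.

Around that core the package provides:

* **TSV entry model** — parse/validate/serialize glycopeptide rows
  (`peptide TAB site TAB glycan [TAB uniprot]`) and glycoprotein rows
  (`uniprot TAB site TAB glycan`), with all-or-nothing per-entry error
  handling and strict sequence validation against a local FASTA database.
* **Glycan compositions** — Byonic-style notation such as
  `HexNAc(4)Hex(7)NeuAc(1)` with monoisotopic residue masses derived from
  an auditable elemental-formula table; GlyTouCan accession tokens
  (`G00912UN`) are accepted interchangeably. Only the substituents
  `Phospho` and `Sulfate` are supported; anything else is a hard error.
* **Byonic worksheet conversion** — extract entries from PMI-Byonic-style
  summary worksheets by comparing each bracketed per-residue modification
  mass against the glycan composition mass (tolerance 1.0 Da, so
  integer-rounded worksheet masses still match), including
  peptide-to-protein coordinate mapping with verbatim sequence
  consistency checks.
* **Glycosylation classes** — per-site (N-linked on Asn, O-linked on
  Ser/Thr, C-mannosylation on Trp) and per-entry
  (N-only / O-only / both / neither) classification with summary tables.
* **RDF export** — GlycoCoO-style triples with a deterministic, sorted
  N-Triples/Turtle serializer and an editable vocabulary map.
* **Overlap detection** — cross-dataset entry intersection via IDs,
  same-peptide/different-pattern pairs, and peptide subsumption pairs.
* **Synthetic fixtures** — a seeded generator of ground-truthed proteins,
  glycopeptides and worksheet rows, so the whole pipeline is testable
  offline.

## Worked example

```r
library(glycoconj)
entries <- readGlycoTSV(c(
  "DILTILANTTLQITCR\t8\tHexNAc(4)Hex(7)NeuAc(1)\tP35918",
  "QQLQEQSAPPSKPDGQLQFR\t11\tHexNAc(1)Hex(1)",
  "QQLQEQSAPPSKPDGQLQFR\t7\tHexNAc(1)Hex(1)"), "glycopeptide")
entries
#> GlycoconjugateSet of kind 'glycopeptide' with 2 entries (3 site rows)
#>   DILTILANTTLQITCR: 8:HexNAc(4)Hex(7)NeuAc(1)
#>   QQLQEQSAPPSKPDGQLQFR: 7:HexNAc(1)Hex(1); 11:HexNAc(1)Hex(1)

glycombIDs(entries)
#>     DILTILANTTLQITCR QQLQEQSAPPSKPDGQLQFR
#>           "GC513FA5"           "GC89F191"

classifyEntries(entries)
#>     DILTILANTTLQITCR QQLQEQSAPPSKPDGQLQFR
#>             "N_ONLY"             "O_ONLY"
```

The three input rows collapse into two entries: rows sharing a peptide
aggregate, so the mucin peptide with serine sites 7 and 11 is *one* entry —
and a submission carrying only site 11 would be a different entry with a
different ID. The 16-mer carries an N-glycan on Asn-8 (an N-T-T sequon);
its composition mass is what the worksheet converter matches against:

```r
compositionMass("HexNAc(4)Hex(7)NeuAc(1)")
#> [1] 2237.783
p <- parseAnnotatedPeptide("R.DILTILAN[+2237.78]TTLQITCR.S")
matchGlycanSite(p$mods, "HexNAc(4)Hex(7)NeuAc(1)")
#> [1] 8
```

A shell front-end with the same operations is installed at
`system.file("exec", "glycoconj", package = "glycoconj")` (subcommands
`validate`, `assign-ids`, `classify`, `convert-byonic`, `export-rdf`,
`overlap`, `make-fixtures`).

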