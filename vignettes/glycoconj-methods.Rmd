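---
title: "Methods: canonical identification of glycoconjugate entries"
author: "glycoconj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: canonical identification of glycoconjugate entries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoconj)
```

## The entry model

The unit this package standardizes is the *glycoconjugate entry*: a
peptide sequence (glycopeptide) or UniProt accession (glycoprotein)
together with the complete set of its (residue number, glycan) pairs. Two
consequences follow and drive every design choice:

* the glycosylation *pattern* is part of identity — the same peptide with
  sites {7, 11} and with {11} are different entries;
* a site's glycan may be ambiguous at the composition level only
  (mass spectrometry usually cannot resolve monosaccharide isomers), so a
  glycan is either a composition multiset like `HexNAc(4)Hex(7)NeuAc(1)`
  or a GlyTouCan accession, and the same residue may carry several
  candidate glycans as separate (site, glycan) pairs.

Unknown residue numbers are first-class (`?` in the TSV dialect): an
entry may record that a glycan was observed without a localized site.

## Canonical form and content-addressed IDs

An entry's canonical form is
`kind|key|p1:g1;p2:g2;...` with sites sorted by
(position ascending, unknown sites last, canonical glycan string), glycan
compositions re-serialized in the fixed symbol order HexNAc, Hex, Fuc,
NeuAc, NeuGc, Pent, HexA, Phospho, Sulfate with no whitespace, and all
sorting done in the C locale. Any fixed symbol order would do; this one
matches how Byonic-style tools conventionally print compositions, and it
is global and documented, which is what representation-independence
requires. The optional fourth-column source accession of glycopeptide
rows is recorded as metadata but *excluded* from the canonical form: the
same peptide-plus-pattern reported against differently named source
proteins is still the same glycoconjugate observation, and including the
accession would split it.

The identifier is `GC` plus the first 24 bits of SHA-256 over the UTF-8
canonical form, as 6 uppercase hex characters. Hashing gives the
observable contract — exact same entry, exact same ID, on any machine,
with no registry — while making no claim to reproduce any repository's
actually issued accessions (those are issuance-order artifacts and are
not recoverable from entry content). The cost of a 24-bit ID space is
birthday collisions: at 10^4 distinct entries about
`choose(10^4, 2) / 2^24` ≈ 3 are expected. `glycombIDs()` therefore
detects every ID shared by distinct canonical forms and reports it (a
warning plus a `collisions` attribute); collisions are surfaced, never
silently merged, and downstream overlap logic treats the reported IDs as
suspect. Tests assert exactly this contract rather than the statistically
unattainable "zero collisions at every scale".

## Parsing and validation choices

* **All-or-nothing entries.** A malformed row invalidates every row of
  the entry it belongs to, with diagnostics for each line. Rationale: a
  partially parsed pattern is not a smaller version of the same entry —
  it is a *different* entry and would silently receive a different ID.
* **Closed alphabet.** Peptides are restricted to the 20 standard
  residues; ambiguity codes (B/J/O/U/X/Z) are rejected because ID
  stability demands that equal strings mean equal molecules.
* **Accession discipline.** Keys must match the standard 6/10-character
  UniProt pattern; isoform suffixes are rejected. Glycoprotein entries
  are validated against a local FASTA database: accession present, every
  known site within the sequence, residue letters recorded.
* **GlyTouCan tokens** are recognized by shape (`G` + 5 digits + 2
  uppercase letters, the shape of all published accessions) — a
  documented dialect assumption, applied consistently when
  auto-dispatching the third TSV column.
* **Composition grammar.** `Symbol(count)` groups, whitespace between
  symbol and count tolerated on input (worksheets print `HexNAc (4)`),
  never emitted; repeated symbols merge by summation; `dHex`→`Fuc` and
  `Sulfo`→`Sulfate` aliases normalize before serialization. The
  vocabulary is fixed to seven monosaccharides plus the substituents
  `Phospho` and `Sulfate`; other substituents (`Methyl`, `Acetyl`, ...)
  are hard errors. The substituent restriction is part of the method; the
  monosaccharide list is this package's explicit assumption, chosen to
  cover standard Byonic output.

## Worksheet conversion by mass matching

PSM rows from a summary worksheet give an annotated peptide
(`R.DILTILAN[+2237.78]TTLQITCR.S`), a glycan composition, and optionally
the peptide's start coordinate and a protein-name field. The glycosylated
residue is the one whose bracketed modification mass lies within
**tolerance = 1.0 Da** (the one tunable that matters; units Da, must be
positive) of the composition's monoisotopic residue-mass sum. The default
is deliberately wide because some worksheets print glycan masses rounded
to integers; the worst integer-rounding error is 0.5 Da, and unrelated
modifications (oxidation +15.99, phospho +79.97, carbamidomethyl +57.02)
sit far more than 1 Da from any supported glycan composition, so no
modification whitelist is needed. When several modifications qualify, the
smallest absolute mass difference wins, ties broken by smallest position,
and the row is flagged ambiguous — the contract favors determinism and
an audit trail over guessing.

Glycoprotein extraction additionally requires `start` and an extractable
accession, maps peptide site *s* to protein site `start + s − 1`, and
rejects any row whose bare peptide does not occur verbatim in the
database sequence at the stated start. Row accounting is total: every
input row either contributes sites or appears in the diagnostics.

Masses come from a shipped, auditable table
(`inst/extdata/monosaccharides.tsv`: symbol, elemental formula,
monoisotopic residue mass) plus an element-mass table; tests recompute
every residue mass from an independently typed element table to below
1e-6 Da.

## Classification

Site classes are a pure function of the residue letter: Asn → N-linked,
Ser/Thr → O-linked, Trp → C-mannosylation, unknown position → undefined,
anything else → other. Sequon checking (N-X-S/T, X ≠ P) is provided as a
separate advisory validator and is *not* a classification criterion, so
that entry bookkeeping depends only on the reported residue. At entry
level the partition N-only / O-only / both / neither is exhaustive and
exclusive; C-mannosylated-only and all-undefined entries fall in
"neither".

## RDF export

Entries serialize as GlycoCoO-style triples: a typed entry node with
identifier and sequence/accession literals; one node per distinct site
with residue-number (and, where resolvable, residue-name) literals; one
saccharide node per (site, glycan). Compositions covered by a
user-supplied offline mapping table serialize as GlyTouCan accessions;
unmapped compositions stay as composition literals with an explicit
unverified flag — never dropped. The predicate IRIs live in an editable
vocabulary map (`inst/extdata/rdf_vocabulary.tsv`): the export adopts
only a small, best-effort subset of the glycoconjugate ontology, and the
map is configuration precisely so it can be revised against an ontology
release without code changes. Serialization is deterministic (statements
sorted) for diffability; triple counts are affine in (#sites, #glycans),
which the tests exploit as a structural invariant.

## Synthetic data

`simulateGlycoproteomics()` defines the conditions every pipeline test
runs under: random proteins hosting non-overlapping peptide slots;
events with site residues drawn as N 0.45, S 0.20, T 0.15, W 0.05, other
0.15 (N sites always in genuine N-X-S/T sequons); N-glycan pool
HexNAc(2)Hex(5..9), mucin-type O-pool HexNAc(1..2)Hex(0..1)NeuAc(0..2),
Hex(1) for C-mannosylation — proportions and pools chosen once as
representative of routine N/O-glycoproteomics output. Worksheet noise is
explicit: mass rounding (exact, two decimals, or integer — the regimes
worksheets actually exhibit), duplicate rows, unglycosylated rows, and
four enumerated corruption operators (shifted start, peptide/protein
mismatch, unknown glycan token, out-of-tolerance mass), each indexed in
the ground truth so every error path has a dedicated fixture. About a
third of event rows carry an unrelated oxidation bracket.

What the generator does *not* emulate: spectra and identification-score
noise, co-eluting isobaric compositions, missed-cleavage peptide overlap
within one protein, site-localization ambiguity across candidate
residues, and real UniProt sequence churn. Passing round-trip tests
therefore demonstrate that the *conversion and identification logic* is
lossless and order-independent under realistic worksheet formatting —
not that site assignments from real, noisy spectra are correct.

Test and acceptance problem sizes — 1000 events per rounding mode for
round-trip recovery, 10,000 random entries for ID semantics, 1000 for
the classification partition, 50-entry fixtures with 7 planted
duplicates for overlap — are the package's chosen operating points:
large enough to exercise birthday-collision behavior and aggregation at
scale, small enough to run routinely.

## Numerical and degenerate-input choices

* Mass comparisons use absolute differences in Da; the additivity of
  composition masses is exact to 1e-9 Da in tests.
* Empty compositions have mass 0; an empty entry set serializes to an
  empty TSV and an empty RDF graph.
* Unknown positions sort after all known positions; two unknown sites
  with different glycans are both kept (`?:glycanA;?:glycanB`).
* All ordering uses radix (C-locale) sorting so canonical forms, TSV
  output and RDF statements are machine- and locale-invariant.
* Seeds: every stochastic routine takes an explicit integer seed; the
  renderer derives its row-noise seed as `seed + 1`.

## Known limitations

* IDs are 24-bit by design (to match the printed ID shape); collision
  handling is detection-and-report, not avoidance. A registry needing
  guaranteed uniqueness should widen the hash.
* Compositions and accessions only compare equal through an explicit
  offline mapping table; no live accession resolution is attempted.
* Site-localization ambiguity (multiple candidate residues for one
  glycan) is excluded rather than modeled; ambiguous matches are logged
  and resolved deterministically.
* Isoform and obsolete-accession reconciliation for glycoprotein overlap
  is out of scope; overlap keys on the exact accession plus site set.
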