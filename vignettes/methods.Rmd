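---
title: "Variant-to-structure mapping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variant-to-structure mapping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(struct3dmap)
library(data.table)
```

## The problem

A coding variant is reported against a transcript and a protein sequence
position; a structure file speaks author numbering — residue numbers
chosen by depositors, with insertion codes, gaps, and frequently an
engineered or homologous sequence rather than the reference protein.
`struct3dmap` bridges the two with an explicit, testable chain of maps:

```
transcript --(ID map)--> protein --(local alignment)--> chain sequence
          --(seq_to_key)--> author residue key --(distances)--> interface context
```

Every link is materialized as data (position maps, annotation rows,
interface records), so any mapped residue can be traced back to the
alignment column and the atoms that produced it.

## Structure model

`parse_structure()` reads PDB and mmCIF through bio3d and reduces each
file to one deterministic coordinate set:

* **multi-model files**: model 1 only — one coordinate set per
  structure, matching common practice for NMR ensembles;
* **altlocs**: per atom site, the highest-occupancy conformer wins, ties
  broken by the alphabetically first altloc identifier;
* **observed residues**: a residue participates in sequences and
  distances if it has at least one heavy atom, so Cα-only models remain
  mappable;
* **hetero residues** with a known parent amino acid (MSE, SEP, TPO, …)
  stay in their polymer chain and map to the parent's one-letter code;
  anything else non-polymeric is a ligand instance, waters are excluded
  everywhere. Unknown residues become `'X'` and can never count as
  alignment identities, so wildcards cannot inflate Pident.

Chain classification is majority-based: >50% standard amino acids →
protein, >50% standard nucleotides → nucleic, all-water → water,
otherwise ligand. Sequences are built from **observed** residues in
author order (ATOM-derived, not SEQRES-derived): unobserved residues
cannot carry a variant anywhere in space, so emitting them would create
rows with no structural meaning.

## Alignment and homology transfer

The aligner is optimal local alignment (Smith–Waterman) under affine
gaps, BLOSUM62 with gap open 11 / extend 1 — the standard protein-search
parameterization — delegated to `Biostrings::pairwiseAlignment()`. A gap
of length *k* costs `11 + k`. Tie-breaking among co-optimal tracebacks
follows that routine's deterministic rule; scores, and therefore
e-values and filtering decisions, are unaffected by which co-optimal
path is reported, and the test suite pins the scores against an
independent cubic-time dynamic program that evaluates whole gap blocks
directly.

Derived statistics:

* **Pident** uses the BLAST-tabular convention — identities divided by
  alignment length *including gap columns* — so an external BLAST
  backend producing tabular output is drop-in comparable.
* **E-value** uses Karlin–Altschul statistics with the published gapped
  BLOSUM62 parameters (λ = 0.267, K = 0.041) and an m·n pairwise search
  space. There is no database-length correction because the tool aligns
  pairs, not a database; numbers from a BLAST backend can therefore
  differ slightly in the conservative direction.
* Filtering defaults: Pident ≥ 50 and e-value ≤ 1e-5, both inclusive at
  the boundary. One alignment is kept per (query, structure, chain) —
  the optimal one.

`build_position_map()` walks the alignment columns: both-sides-non-gap
columns produce one entry from query position to author residue key;
gap columns produce nothing, which is exactly how query insertions end
up absent from the structural annotation.

## Interfaces

A protein-chain residue is an interface residue toward an entity if the
minimum heavy-atom–heavy-atom distance between the residue and that
entity is at most the cutoff. Choices behind that sentence:

* **distance definition**: minimum heavy-atom distance, not Cα–Cα and
  not centroids — the most common contact convention, and the one the
  brute-force oracle in the tests implements independently;
* **cutoff default 5.0 Å**: the standard contact threshold; fully
  user-configurable;
* **entities**: every other protein or nucleic chain, and every
  individual non-water HET residue instance — two copies of the same
  ligand are two distinct interfaces; intra-chain contacts are ignored;
  modified polymer residues (MSE, …) are part of their chain, never
  ligands.

When several structures cover one query protein, interface redundancy is
removed in two steps: records whose source alignment has Pident < 80 are
dropped (the 80.0 boundary survives), then per (query, partner type) only
the structure with the highest Pident contributes, ties going to the
lexicographically smallest structure ID. The local-alignment Pident
already computed for the mapping is the identity used here. Redundancy
removal applies to interface annotation only; plain structural coverage
rows keep all passing templates, which is what makes the coverage
summary meaningful at several Pident thresholds.

## Variant normalization and classification

Four input dialects normalize to one record schema (VEP tabular located
by header names; VEP-like tolerating extra/missing optional columns; MAF
through `Transcript_ID` + `HGVSp_Short`; VCF through a VEP `CSQ`/`ANN`
field, one record per transcript consequence). A VCF without consequence
annotation is rejected with a pointer to run the predictor first —
consequence prediction is out of scope. Protein-position intervals
("86-88") are kept as intervals and expanded to per-position queries at
mapping time, so in-frame indels are not silently dropped. Transcript
versions are stripped for matching, preserved in output.

Classification is definitional and exhaustive: `non-coding` iff the
record has no protein position; `unmapped` iff it has one but no
annotation row covers it (with a reason code distinguishing a missing
ID-map entry from missing coverage); `interface` iff a covering row
carries at least one interface flag; otherwise `structure`. A variant
covered by several structures yields several long-format rows;
`summarize_mapped()` reduces to a best class under the ordering
interface > structure > unmapped > non-coding. Reference-allele
discrepancies (variant `aa_ref` vs the query residue) set a
`ref_mismatch` flag instead of dropping rows — such mismatches are
common and should be visible, not silently fatal.

Model-quality filters: minimum Pident, minimum pLDDT (the per-residue
B-factor of predicted models), and pDockQ. The pDockQ table is an
explicit input (computing pDockQ is out of scope); when supplied, listed
models must score strictly above the threshold (default 0.23, the
accepted-model boundary) and unlisted structures — e.g. experimental
ones — pass through untouched.

The transcript→protein map is likewise an explicit input TSV rather than
a bundled resource: which UniProt/Ensembl release to trust is a dataset
decision, not a tool decision.

## Outputs

Annotation files are versioned-header TSV (greppable, diffable,
byte-stable); the mapped table is RFC-4180 CSV and/or Parquet — the
package's binary columnar format, chosen for typed, compressed
round-trips through the arrow stack; both carry identical rows. The
SetID file is the two-column `set_id variant_id` format of region-based
rare-variant association tools, with three grouping policies
(per-protein, per-interface, per-class) since different tests want
different region definitions. ChimeraX scripts use current `.cxc`
command syntax with a configurable palette (defaults: interface red,
structure blue, grey cartoon base); selectors render author numbering
including insertion codes (`/A:7A`), and a parser is shipped so tests
can round-trip selectors back to residue sets.

Determinism is a contract: fixed ordering of rows and files, and
per-protein independence so `jobs > 1` produces byte-identical output to
a serial run.

## The fixture generator

Fixtures are ideal geometry, not physics: straight Cα traces with 3.8 Å
spacing, adjacent chains offset by a configurable separation, optional
single-atom ligands and waters, author numbering fully scriptable
(gaps, insertion codes), point mutations to dial in designed Pident
values, and per-residue B-factors to emulate pLDDT. Because the
coordinates are closed-form, the contact set at any cutoff is known
exactly; the shipped ground truth is computed by a brute-force all-pairs
scan inside the generator, never by the production interface code. The
canonical demonstration complex uses chain lengths 30 + 20 at 4.5 Å
separation — long enough that every random-sequence self-match clears
the default e-value threshold at any seed, small enough that the whole
pipeline runs in seconds.

What fixtures do **not** emulate: real side-chain packing, SEQRES vs
ATOM discrepancies beyond designed gaps, crystallographic symmetry,
multi-domain homology with conflicting templates, or genuinely noisy
variant files. Green tests demonstrate the mapping logic is exact under
controlled inputs; they do not certify parsing of every PDB archive
idiosyncrasy.

## Numerical and degenerate-input choices

* Empty optimal alignments (score 0) report Pident 0 and undefined
  spans rather than erroring.
* TSV serialization uses 6 significant digits for Pident/e-value/
  B-factor; comparisons in tests allow for that.
* Zero-polymer structures parse to an empty chain list with a warning;
  a corrupt file inside a structure directory is skipped with a warning
  while the run proceeds; an empty proteome or structure directory is
  fatal.
* Protein IDs containing `|` or path separators (UniProt-style) are
  sanitized only in file names; records keep the original ID.

## Problem sizes

The shipped checks use 200 random pairs (length ≤ 15) for the alignment
oracle, 50 generated structures × cutoffs {3, 4, 5, 8} Å for the
interface oracle, and the 5-variant demonstration complex for the
end-to-end runs — sizes chosen so the whole suite completes in well
under a minute per module while still exercising every code path;
the oracles are exhaustive, so correctness evidence does not depend on
scale.

## Known limitations

* No biological-assembly expansion or symmetry mates: interfaces are
  computed on the deposited asymmetric unit.
* No ΔSASA-based interface definition and no interaction energetics.
* The internal aligner is pairwise; proteome-scale sensitivity tuning
  (word sizes, composition-based statistics) belongs to an external
  BLAST backend consuming the same tabular contract.
* No liftover, no consequence prediction, no association testing — the
  tool prepares inputs for those, it does not replace them.
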