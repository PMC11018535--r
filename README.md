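# struct3dmap

Mapping annotated protein positions and genetic variants onto protein
structures, at any scale, for any organism.

Interpreting coding variants benefits enormously from structural context:
whether a mutated residue sits in a protein–protein, protein–ligand or
protein–nucleic interface, and how reliable the underlying structural
model is. Getting a variant onto a structure is, however, notoriously
error-prone: author residue numbering in PDB/mmCIF files rarely matches
database sequence positions (insertion codes, numbering gaps, engineered
mutations), and most proteins are covered only through homologous
structures. `struct3dmap` is a command-line style pipeline, written as an
R package, that automates this transfer end to end:

1. **`make_structural_db()`** — aligns a proteome (FASTA) against the
   protein chains of a directory of structures (`.pdb` / `.cif`,
   experimental or AlphaFold-style predicted models) by optimal local
   alignment (Smith–Waterman, BLOSUM62, affine gaps 11/1, Karlin–Altschul
   e-values), keeps templates with Pident ≥ 50% and e-value ≤ 1e-5
   (configurable), detects inter-chain interfaces as residues with any
   heavy-atom pair within 5 Å (configurable) of another chain, ligand
   instance or nucleic acid, removes interface redundancy across
   structures (drop < 80% Pident; keep the highest-Pident structure per
   interface type), and writes one TSV of structurally annotated
   positions per protein. Per-residue B-factors are carried through —
   for predicted models this is the pLDDT confidence score.
2. **`make_variants_db()`** — normalizes variant files (VEP tabular,
   VEP-like, MAF, or VCF with a VEP `CSQ` field) into per-transcript
   record files.
3. **`map_variants()`** — joins the two databases through a
   transcript→protein ID map and classifies every variant as
   `interface`, `structure`, `unmapped` or `non-coding`; optional
   filters by consequence type, Pident, pLDDT and per-model pDockQ
   (models must score > 0.23 to be included when the filter is on).
   Results are written as CSV and/or Parquet plus a SetID file for
   region-based rare-variant association testing.
4. **`make_visualization()`** — emits ChimeraX `.cxc` scripts coloring
   mapped residues by class.

A fixture module (`fixture_spec()` / `make_structure_fixture()` /
`make_variant_fixture()` / `demo_fixture()`) generates toy structures,
proteomes and variant files with exact designed ground truth, so the full
pipeline is testable without downloading anything.

Key quantities, in the field's usual notation:

- **Pident** = 100 · (identical columns) / (alignment length incl. gaps);
  `X` never counts as an identity.
- **E-value** = m·n·2^(−S′), with bit score S′ = (λS − ln K)/ln 2 using
  the published gapped BLOSUM62 parameters (λ = 0.267, K = 0.041).
- **Interface residue**: minimum heavy-atom distance to another entity
  ≤ cutoff (default 5 Å); waters excluded; every ligand copy is its own
  interface.

## Worked example

Every command is also available from the shell via the dispatcher script
`inst/cli/struct3dmap` (subcommands `makestructuraldb`, `makevariantsdb`,
`mapper`, `makevisualization`, `fixtures`):

```sh
CLI=inst/cli/struct3dmap
Rscript $CLI fixtures --out demo --seed 1
Rscript $CLI makestructuraldb --proteome demo/proteome.fasta \
        --structures demo/structures --out demo/protdb
Rscript $CLI makevariantsdb --input demo/variants.vep.tsv --out demo/vardb
Rscript $CLI mapper --protdb demo/protdb --vardb demo/vardb \
        --idmap demo/id_map.tsv --out demo/out --format both --setid per-interface
Rscript $CLI makevisualization --mapped demo/out/mapped.csv --out demo/viz
```

which prints

```
fixture tree written under demo
covered 2/2 proteins using 1 structures
wrote 1 transcript file(s)
wrote 5 mapped row(s) to demo/out
wrote 1 ChimeraX script(s)
```

The demo fixture is a designed two-chain complex (chain A, 30 residues,
its query extended to 40; chain B, 20 residues, 4.5 Å away) with five
variants on chain A's transcript. The per-protein annotation file starts

```
# struct3dmap structural-annotation schema v1
protein_id  protein_pos  protein_aa  structure_id  chain_id  resnum  icode  structure_aa  is_identity  pident  evalue       bfactor  interface_flags
query_A     1            D           demo_complex  A         1              D             TRUE         100     2.50932e-19  50       B:protein:4.500
```

i.e. query position 1 lands on author residue 1 of chain A at 100%
identity, and that residue touches chain B at 4.5 Å. The mapped table
classifies the five variants as 2× `interface` (designed contact
positions 3 and 4), 1× `structure` (position 25, covered but not in
contact), 1× `unmapped` (position 35, beyond the structure) and 1×
`non-coding` (an intron consequence), and the per-interface SetID file
groups the interface variants into their (protein, partner) set:

```
query_A_B var_01
query_A_B var_02
```

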