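# Shared in-code fixtures: small hand-written structure/variant texts for
# format corner cases, and a cached demo fixture tree for end-to-end tests.

write_lines_tmp <- function(lines, ext) {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# Hand-written PDB exercising: insertion code (7A), a numbering gap
# (10 -> 14), an MSE residue, altloc conformers with unequal occupancy,
# a hydrogen, two copies of the same ligand, and waters.
corner_case_pdb <- function() {
  write_lines_tmp(c(
    "HEADER    CORNER CASES",
    "ATOM      1  CA  ALA A   5       0.000   0.000   0.000  1.00 90.11           C",
    "ATOM      2  CA  GLY A   6       3.800   0.000   0.000  1.00 85.50           C",
    "ATOM      3  CA  TRP A   7       7.600   0.000   0.000  1.00 80.25           C",
    "ATOM      4  CA  SER A   7A     11.400   0.000   0.000  1.00 75.00           C",
    "ATOM      5  CA  LYS A   8      15.200   0.000   0.000  1.00 70.75           C",
    "ATOM      6  CA ATYR A  10      19.000   0.000   0.000  0.40 60.00           C",
    "ATOM      7  CA BTYR A  10      19.100   0.500   0.000  0.60 61.00           C",
    "HETATM    8  CA  MSE A  14      22.800   0.000   0.000  1.00 55.00           C",
    "ATOM      9  H   ALA A   5       0.000   1.000   0.000  1.00  0.00           H",
    "HETATM   10 FE   HEM A 101       0.000   3.000   0.000  1.00 30.00          FE",
    "HETATM   11 FE   HEM A 102       3.800   3.000   0.000  1.00 30.00          FE",
    "HETATM   12  O   HOH A 201       0.000   1.500   0.000  1.00 20.00           O",
    "END"), ".pdb")
}

nucleic_pdb <- function() {
  write_lines_tmp(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00 50.00           C",
    "ATOM      2  CA  GLY A   2       3.800   0.000   0.000  1.00 50.00           C",
    "ATOM      3  CA  LEU A   3       7.600   0.000   0.000  1.00 50.00           C",
    "ATOM      4  P    DA B   1       0.000   4.000   0.000  1.00 50.00           P",
    "ATOM      5  P    DT B   2       3.800   4.000   0.000  1.00 50.00           P",
    "ATOM      6  P    DG B   3       7.600   4.000   0.000  1.00 50.00           P",
    "ATOM      7  P    DC B   4      11.400   4.000   0.000  1.00 50.00           P",
    "END"), ".pdb")
}

vep_fixture_lines <- function() c(
  "## ENSEMBL VARIANT EFFECT PREDICTOR output",
  paste("#Uploaded_variation", "Location", "Allele", "Gene", "Feature",
        "Feature_type", "Consequence", "Protein_position", "Amino_acids",
        sep = "\t"),
  paste("rs001", "1:1258", "N", "GENE1", "ENST0001.3", "Transcript",
        "missense_variant", "86", "H/N", sep = "\t"),
  paste("rs002", "1:1291", "N", "GENE1", "ENST0001.3", "Transcript",
        "synonymous_variant", "97", "E", sep = "\t"),
  paste("rs003", "1:2000", "-", "GENE1", "ENST0002", "Transcript",
        "intron_variant", "-", "-", sep = "\t"))

maf_fixture_lines <- function() c(
  "#version 2.4",
  paste("Hugo_Symbol", "Chromosome", "Start_Position", "Reference_Allele",
        "Tumor_Seq_Allele2", "Variant_Classification", "Transcript_ID",
        "HGVSp_Short", sep = "\t"),
  paste("XRCC2", "7", "152649", "C", "A", "Missense_Mutation",
        "ENST0003.2", "p.H86N", sep = "\t"),
  paste("XRCC2", "7", "152700", "G", "T", "Silent",
        "ENST0003.2", "p.E97E", sep = "\t"))

vcf_fixture_lines <- function() c(
  "##fileformat=VCFv4.2",
  paste0("##INFO=<ID=CSQ,Number=.,Type=String,Description=\"Consequence ",
         "annotations. Format: Allele|Consequence|Gene|Feature|",
         "Protein_position|Amino_acids\">"),
  paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
        sep = "\t"),
  paste("1", "1009", ".", "A", "T", ".", ".",
        "CSQ=T|missense_variant|GENE_A|ENST_A.1|3|P/L,T|intron_variant|GENE_A|ENST_Z||",
        sep = "\t"))

# One demo fixture tree shared by the end-to-end tests (built once per run)
demo_env <- new.env()
get_demo <- function(seed = 42L) {
  key <- paste0("s", seed)
  if (is.null(demo_env[[key]])) {
    dir <- file.path(tempdir(), paste0("struct3dmap_demo_", seed))
    unlink(dir, recursive = TRUE)
    dir.create(dir, recursive = TRUE)
    fx <- demo_fixture(dir, seed = seed)
    fx$protdb <- file.path(dir, "protdb")
    fx$vardb <- file.path(dir, "vardb")
    make_structural_db(fx$proteome, fx$structures, fx$protdb)
    make_variants_db(fx$variants, fx$vardb)
    demo_env[[key]] <- fx
  }
  demo_env[[key]]
}
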