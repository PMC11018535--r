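Package: struct3dmap
Title: Mapping Annotated Protein Positions and Genetic Variants onto Protein Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A command-line style pipeline that maps annotated protein
    positions and genetic variants (VCF, VEP, VEP-like, MAF) onto
    experimental and predicted protein structures (PDB and mmCIF).
    Proteome sequences are aligned to structure-chain sequences by
    optimal local alignment with percent-identity and e-value filtering;
    inter-chain protein, ligand and nucleic-acid interfaces are detected
    from heavy-atom distances; mapped residues carry structural context,
    model quality (B-factor / pLDDT, optional pDockQ filtering) and an
    interface / structure / unmapped / non-coding classification.
    Includes a synthetic-fixture generator so the full pipeline is
    testable without downloading any structure or variant data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    Biostrings,
    bio3d,
    jsonlite,
    vcfR,
    arrow,
    parallel,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
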