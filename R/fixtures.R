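# Synthetic-fixture generator: toy structures, proteomes and variant
# files with known ground truth, so every pipeline stage is testable
# without downloading any real data.
#
# Geometry is ideal by construction: each protein chain is a straight
# C-alpha trace along x (3.8 A spacing), successive chains are offset
# along y by a configurable separation, so every inter-residue distance
# has a closed form and the designed contact set at any cutoff is known
# exactly. The ground truth shipped next to each fixture is computed by a
# brute-force all-pairs scan over the designed coordinates inside this
# generator, never by the production interface code.

#' Describe a synthetic structure fixture
#'
#' @param structure_id file stem for the generated files.
#' @param chains list of per-chain specs; each a list with `id`, `n_res`,
#'   and optionally `query_extra` (extra residues appended to the query
#'   sequence beyond the structure chain, creating uncovered positions),
#'   `resnums` (explicit author numbers, for gaps), `icodes` (explicit
#'   insertion codes, `""` when absent), `bfactors` (per-residue B-factor
#'   / pLDDT, recycled), `start_resnum` (default 1).
#' @param chain_sep separation between adjacent chain axes in Angstrom
#'   (default 4.5).
#' @param ca_spacing C-alpha spacing along the chain (default 3.8).
#' @param cutoff contact cutoff used for the designed ground truth
#'   (default 5).
#' @param mutations list of `list(chain, pos, aa)` point mutations applied
#'   to the *structure* sequence relative to the query, to create
#'   sub-100% Pident (keep them away from the chain termini so the local
#'   alignment still spans the whole chain).
#' @param ligands list of `list(name, chain, resnum, x, y, z)` single-atom
#'   hetero components (element Fe).
#' @param waters list of `list(chain, resnum, x, y, z)` water molecules
#'   (excluded from interfaces by definition).
#' @param seed integer seed controlling the random sequences; the same
#'   seed always yields byte-identical files.
#' @return a `FixtureSpec` list.
#' @export
fixture_spec <- function(structure_id = "fixture", chains,
                         chain_sep = 4.5, ca_spacing = 3.8, cutoff = 5,
                         mutations = list(), ligands = list(),
                         waters = list(), seed = 1L) {
  if (chain_sep <= 0) abort("chain separation must be positive")
  structure(list(structure_id = structure_id, chains = chains,
                 chain_sep = chain_sep, ca_spacing = ca_spacing,
                 cutoff = cutoff, mutations = mutations, ligands = ligands,
                 waters = waters, seed = as.integer(seed)),
            class = "FixtureSpec")
}

random_aa_seq <- function(n) {
  paste(sample(unname(.AA3TO1), n, replace = TRUE), collapse = "")
}

# Build the designed atom table (one CA per residue + ligand/water atoms)
# and the per-chain sequence/numbering bookkeeping.
fixture_layout <- function(spec) {
  set.seed(spec$seed)
  chains <- list()
  atoms <- list()
  for (k in seq_along(spec$chains)) {
    ch <- spec$chains[[k]]
    n <- ch$n_res
    start <- ch$start_resnum %||% 1L
    resnums <- if (!is.null(ch$resnums)) as.integer(ch$resnums)
               else seq.int(start, start + n - 1L)
    icodes <- if (!is.null(ch$icodes)) as.character(ch$icodes)
              else rep("", n)
    stopifnot(length(resnums) == n, length(icodes) == n)
    bf <- rep(ch$bfactors %||% 50, length.out = n)
    qextra <- ch$query_extra %||% 0L
    qseq <- random_aa_seq(n + qextra)
    sseq_chars <- strsplit(substr(qseq, 1L, n), "")[[1]]
    for (m in spec$mutations) {
      if (m$chain != ch$id) next
      if (m$pos < 1L || m$pos > n) abort("mutation position outside chain")
      sseq_chars[m$pos] <- m$aa
    }
    chains[[ch$id]] <- list(
      id = ch$id, n_res = n, resnums = resnums, icodes = icodes,
      bfactors = bf, query_id = ch$query_id %||% paste0("query_", ch$id),
      query_seq = qseq, struct_seq = paste(sseq_chars, collapse = ""))
    atoms[[length(atoms) + 1L]] <- data.table::data.table(
      record = "ATOM", chain = ch$id, resnum = resnums, icode = icodes,
      resname = unname(.AA1TO3[sseq_chars]), atom = "CA", element = "C",
      x = (seq_len(n) - 1L) * spec$ca_spacing,
      y = (k - 1L) * spec$chain_sep, z = 0,
      occ = 1, bfactor = bf)
  }
  for (lg in spec$ligands) {
    atoms[[length(atoms) + 1L]] <- data.table::data.table(
      record = "HETATM", chain = lg$chain, resnum = as.integer(lg$resnum),
      icode = "", resname = lg$name, atom = "FE", element = "FE",
      x = lg$x, y = lg$y, z = lg$z, occ = 1, bfactor = lg$bfactor %||% 50)
  }
  for (w in spec$waters) {
    atoms[[length(atoms) + 1L]] <- data.table::data.table(
      record = "HETATM", chain = w$chain, resnum = as.integer(w$resnum),
      icode = "", resname = "HOH", atom = "O", element = "O",
      x = w$x, y = w$y, z = w$z, occ = 1, bfactor = 0)
  }
  list(chains = chains, atoms = data.table::rbindlist(atoms))
}

# Brute-force all-pairs designed contacts: protein-chain residues vs every
# other entity (other protein chains and ligand instances), by direct
# distance arithmetic over the designed coordinates.
fixture_truth_contacts <- function(spec, layout) {
  at <- layout$atoms
  prot <- at[record == "ATOM"]
  recs <- list()
  ents <- list()
  for (cid in unique(prot$chain))
    ents[[length(ents) + 1L]] <- list(id = cid, type = "protein",
                                      atoms = prot[chain == cid])
  lig <- at[record == "HETATM" & resname != "HOH"]
  if (nrow(lig) > 0L) {
    for (i in seq_len(nrow(lig))) {
      li <- lig[i]
      ents[[length(ents) + 1L]] <- list(
        id = paste0(li$chain, "_", li$resname, "_",
                    reskey_label(li$resnum, li$icode)),
        type = "ligand", atoms = li)
    }
  }
  for (cid in unique(prot$chain)) {
    A <- prot[chain == cid]
    for (e in ents) {
      if (e$type == "protein" && e$id == cid) next
      B <- e$atoms
      for (i in seq_len(nrow(A))) {
        d <- sqrt((A$x[i] - B$x)^2 + (A$y[i] - B$y)^2 + (A$z[i] - B$z)^2)
        if (min(d) <= spec$cutoff) {
          recs[[length(recs) + 1L]] <- data.table::data.table(
            chain_id = cid, resnum = A$resnum[i], icode = A$icode[i],
            partner_entity = e$id, partner_type = e$type,
            min_distance = min(d))
        }
      }
    }
  }
  if (length(recs) == 0L)
    return(data.table::data.table(chain_id = character(), resnum = integer(),
                                  icode = character(),
                                  partner_entity = character(),
                                  partner_type = character(),
                                  min_distance = numeric()))
  data.table::rbindlist(recs)
}

pdb_atom_line <- function(i, rec, at) {
  name <- if (nchar(at$atom) < 4L) sprintf(" %-3s", at$atom) else at$atom
  sprintf("%-6s%5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, i, name, "", at$resname, at$chain, at$resnum,
          ifelse(at$icode == "", " ", at$icode),
          at$x, at$y, at$z, at$occ, at$bfactor, at$element)
}

write_pdb_fixture <- function(atoms, path, structure_id) {
  lines <- sprintf("HEADER    SYNTHETIC FIXTURE%43s", toupper(substr(structure_id, 1, 4)))
  for (i in seq_len(nrow(atoms)))
    lines <- c(lines, pdb_atom_line(i, atoms$record[i], atoms[i]))
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}

write_cif_fixture <- function(atoms, path, structure_id) {
  lines <- c(
    paste0("data_", structure_id),
    "#",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num")
  for (i in seq_len(nrow(atoms))) {
    a <- atoms[i]
    lines <- c(lines, sprintf(
      "%-6s %d %s %s . %s %s 1 %d %s %.3f %.3f %.3f %.2f %.2f %d %s %s %s 1",
      a$record, i, a$element, a$atom, a$resname, a$chain, i,
      ifelse(a$icode == "", "?", a$icode),
      a$x, a$y, a$z, a$occ, a$bfactor, a$resnum, a$resname, a$chain, a$atom))
  }
  lines <- c(lines, "#")
  writeLines(lines, path)
  invisible(path)
}

#' Generate a synthetic structure fixture with ground truth
#'
#' Writes the designed structure in both PDB and mmCIF format (identical
#' content) plus a ground-truth JSON listing chain sequences, query
#' sequences, author residue keys, per-residue B-factors, the designed
#' contact set at the spec's cutoff (computed by brute force over the
#' designed coordinates) and the expected Pident of each query against
#' its mutated chain.
#'
#' @param spec a [fixture_spec()].
#' @param outdir output directory.
#' @return invisibly, a list with `paths` (pdb / cif / truth) and `truth`.
#' @export
make_structure_fixture <- function(spec, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  layout <- fixture_layout(spec)
  contacts <- fixture_truth_contacts(spec, layout)
  chains_truth <- lapply(layout$chains, function(ch) {
    n_mut <- sum(strsplit(ch$struct_seq, "")[[1]] !=
                   strsplit(substr(ch$query_seq, 1, ch$n_res), "")[[1]])
    list(id = ch$id, n_res = ch$n_res, resnums = ch$resnums,
         icodes = ch$icodes, bfactors = ch$bfactors,
         query_id = ch$query_id, query_seq = ch$query_seq,
         struct_seq = ch$struct_seq,
         expected_pident = 100 * (ch$n_res - n_mut) / ch$n_res)
  })
  truth <- list(structure_id = spec$structure_id, cutoff = spec$cutoff,
                seed = spec$seed, chains = chains_truth,
                contacts = contacts)
  paths <- list(
    pdb = file.path(outdir, paste0(spec$structure_id, ".pdb")),
    cif = file.path(outdir, paste0(spec$structure_id, ".cif")),
    truth = file.path(outdir, paste0(spec$structure_id, ".truth.json")))
  write_pdb_fixture(layout$atoms, paths$pdb, spec$structure_id)
  write_cif_fixture(layout$atoms, paths$cif, spec$structure_id)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(list(paths = paths, truth = truth))
}

#' Write the fixture proteome (query sequences) as FASTA
#'
#' @param truth ground truth from [make_structure_fixture()] (or a list of
#'   them, concatenated).
#' @param path output FASTA path.
#' @return invisibly, the path.
#' @export
fixture_proteome <- function(truth, path) {
  if (!is.null(truth$chains)) truth <- list(truth)
  lines <- character(0)
  for (t in truth)
    for (ch in t$chains)
      lines <- c(lines, paste0(">", ch$query_id), ch$query_seq)
  writeLines(lines, path)
  invisible(path)
}

#' Generate a VEP-format variant fixture with designed classes
#'
#' Writes a minimal valid VEP tabular file whose records, when run through
#' the full pipeline against the structure fixture, yield exactly the
#' designed classes. The expected class of each variant is derived from
#' the ground truth: `non-coding` when the consequence carries no protein
#' position, `interface` when the position falls on a designed contact of
#' the query's chain, `structure` when it is covered by the chain but not
#' in contact, `unmapped` when it lies beyond the structure-covered span.
#'
#' @param truth ground truth from [make_structure_fixture()].
#' @param variants list of `list(chain, pos, consequence)`; use `pos = NA`
#'   with a non-coding consequence. Optional `alt` overrides the alternate
#'   amino acid.
#' @param path output path of the VEP file.
#' @param transcript_map named character vector mapping chain id to the
#'   transcript id used in the file (default `ENST_<chain>`).
#' @return invisibly, a list with `path`, `expected` (data.table of
#'   variant id and designed class) and `id_map` (transcript to query
#'   protein).
#' @export
make_variant_fixture <- function(truth, variants, path,
                                 transcript_map = NULL) {
  chains <- truth$chains
  names(chains) <- vapply(chains, `[[`, "", "id")
  contacts <- data.table::as.data.table(truth$contacts)
  rows <- character(0)
  expected <- list()
  header <- paste(c("#Uploaded_variation", "Location", "Allele", "Gene",
                    "Feature", "Feature_type", "Consequence",
                    "Protein_position", "Amino_acids"), collapse = "\t")
  aa_letters <- unname(.AA3TO1)
  for (i in seq_along(variants)) {
    v <- variants[[i]]
    ch <- chains[[v$chain]]
    tx <- if (!is.null(transcript_map)) transcript_map[[v$chain]] else
      paste0("ENST_", v$chain)
    vid <- sprintf("var_%02d", i)
    if (is.na(v$pos)) {
      rows <- c(rows, paste(c(vid, "1:1000", "-", paste0("GENE_", v$chain),
                              tx, "Transcript", v$consequence, "-", "-"),
                            collapse = "\t"))
      expected[[i]] <- data.table::data.table(variant_id = vid,
                                              expected_class = "non-coding")
      next
    }
    qaa <- substr(ch$query_seq, v$pos, v$pos)
    alt <- v$alt %||% aa_letters[match(qaa, aa_letters) %% 20L + 1L]
    rows <- c(rows, paste(c(vid, sprintf("1:%d", 1000 + 3L * v$pos), "N",
                            paste0("GENE_", v$chain), tx, "Transcript",
                            v$consequence, as.character(v$pos),
                            paste0(qaa, "/", alt)), collapse = "\t"))
    covered <- v$pos <= ch$n_res
    on_iface <- covered && nrow(contacts) > 0L &&
      any(contacts$chain_id == ch$id &
            contacts$resnum == ch$resnums[v$pos] &
            contacts$icode == ch$icodes[v$pos])
    expected[[i]] <- data.table::data.table(
      variant_id = vid,
      expected_class = if (on_iface) "interface"
                       else if (covered) "structure" else "unmapped")
  }
  writeLines(c(header, rows), path)
  id_map <- data.table::rbindlist(lapply(names(chains), function(cid)
    data.table::data.table(
      transcript_id = if (!is.null(transcript_map)) transcript_map[[cid]]
                      else paste0("ENST_", cid),
      protein_id = chains[[cid]]$query_id)))
  invisible(list(path = path, expected = data.table::rbindlist(expected),
                 id_map = id_map))
}

#' Build the canonical end-to-end demonstration fixture
#'
#' Two protein chains: chain A (30 residues, query extended to 40 so
#' positions 31-40 are structurally uncovered) and chain B (20 residues)
#' laid side by side 4.5 Angstrom apart, so at the default 5 Angstrom
#' cutoff the designed protein-protein contacts are exactly the first 20
#' positions of A (each facing its B counterpart) and all of B. Five
#' variants on chain A's transcript are designed to classify as 2x
#' interface, 1x structure, 1x unmapped and 1x non-coding.
#'
#' @param dir output directory.
#' @param seed integer seed for the random sequences.
#' @return a list with all paths (`structures`, `proteome`, `variants`,
#'   `id_map` data.table), the structure `truth` and the designed variant
#'   `expected` classes.
#' @export
demo_fixture <- function(dir, seed = 1L) {
  sdir <- file.path(dir, "structures")
  spec <- fixture_spec(
    structure_id = "demo_complex",
    chains = list(list(id = "A", n_res = 30L, query_extra = 10L),
                  list(id = "B", n_res = 20L)),
    chain_sep = 4.5, cutoff = 5, seed = seed)
  fx <- make_structure_fixture(spec, sdir)
  proteome <- file.path(dir, "proteome.fasta")
  fixture_proteome(fx$truth, proteome)
  vf <- make_variant_fixture(
    fx$truth,
    variants = list(
      list(chain = "A", pos = 3L, consequence = "missense_variant"),
      list(chain = "A", pos = 4L, consequence = "missense_variant"),
      list(chain = "A", pos = 25L, consequence = "missense_variant"),
      list(chain = "A", pos = 35L, consequence = "missense_variant"),
      list(chain = "A", pos = NA, consequence = "intron_variant")),
    path = file.path(dir, "variants.vep.tsv"))
  list(structures = sdir, proteome = proteome, variants = vf$path,
       id_map = vf$id_map, truth = fx$truth, expected = vf$expected)
}
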