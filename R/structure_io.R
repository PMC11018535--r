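# Parsing of PDB / mmCIF files into a uniform structure model.
#
# The model keeps author residue numbering (including insertion codes),
# per-atom coordinates and B-factors (pLDDT for predicted models), and
# classifies every chain as protein / nucleic / ligand / water. Sequences
# are extracted from observed residues only, with an exact map from
# 1-based sequence position to the author residue key, which is what makes
# homology transfer of variant positions onto author numbering possible.

# Standard residue dictionaries ------------------------------------------

#' @keywords internal
.AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

.AA1TO3 <- stats::setNames(names(.AA3TO1), unname(.AA3TO1))

# Modified polymer residues with a known parent amino acid. These are
# HETATM records inside polymer chains (e.g. selenomethionine) and must be
# treated as part of their chain, never as ligands.
.AA_PARENT <- c(
  MSE = "M", SEP = "S", TPO = "T", PTR = "Y", CSO = "C", CME = "C",
  HYP = "P", MLY = "K", M3L = "K", PCA = "Q", KCX = "K", CSD = "C",
  OCS = "C", FME = "M", LLP = "K", HIC = "H", ALY = "K", SEC = "C",
  PYL = "K"
)

.NUC1 <- c(
  A = "A", C = "C", G = "G", U = "U", I = "I", N = "N",
  DA = "A", DC = "C", DG = "G", DT = "T", DU = "U", DI = "I", DN = "N"
)

.WATER <- c("HOH", "DOD", "WAT", "H2O")

aa_one_letter <- function(resname) {
  out <- .AA3TO1[resname]
  miss <- is.na(out)
  out[miss] <- .AA_PARENT[resname[miss]]
  out[is.na(out)] <- "X"
  unname(out)
}

is_aa_like <- function(resname) resname %in% c(names(.AA3TO1), names(.AA_PARENT))
is_nuc_like <- function(resname) resname %in% names(.NUC1)
is_water_res <- function(resname) resname %in% .WATER

# Element inference from a PDB atom name when the element column is empty:
# strip digits/primes, take the leading letter(s).
guess_element <- function(elety) {
  x <- gsub("[0-9']", "", toupper(elety))
  two <- substr(x, 1, 2)
  one <- substr(x, 1, 1)
  ifelse(two %in% c("FE", "ZN", "MG", "MN", "CU", "NA", "CL", "BR", "SE", "CA"),
         two, one)
}

# Parsing -----------------------------------------------------------------

#' Parse a PDB or mmCIF file into a structure model
#'
#' Reads a macromolecular structure file (format inferred from the file
#' extension, overridable) and returns a uniform model: one coordinate set
#' (the first model of multi-model files), alternate locations resolved to
#' the highest-occupancy conformer (ties broken by the alphabetically first
#' altloc identifier), hydrogens and waters retained but flagged. Chains
#' are classified with [classify_chain()] and polymer sequences extracted
#' with [extract_sequence()].
#'
#' B-factors are carried through per atom and averaged per residue; for
#' AlphaFold-style predicted models this column holds the per-residue pLDDT
#' confidence score.
#'
#' @param path path to a `.pdb` / `.ent` / `.cif` file.
#' @param format `"auto"` (default, from extension), `"pdb"` or `"cif"`.
#' @return an object of class `StructureModel`: a list with
#'   `structure_id`, `source_format`, `model_number`, `atoms` (data.table of
#'   retained atoms), `residues` (per-residue table with one-letter code and
#'   mean B-factor) and `chains` (chain-level table with the `kind`
#'   classification).
#' @export
parse_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort("structure file not found: %s", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "cif") "cif" else "pdb"
  }
  pdb <- tryCatch(
    suppressWarnings(
      if (format == "cif") bio3d::read.cif(path, multi = FALSE, rm.alt = FALSE)
      else bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE)
    ),
    error = function(e) abort("failed to parse structure file %s: %s",
                              path, conditionMessage(e))
  )
  atoms <- data.table::as.data.table(pdb$atom)
  if (nrow(atoms) == 0L)
    abort("failed to parse structure file %s: no atom records", path)

  a <- data.table::data.table(
    chain   = as.character(atoms$chain),
    resnum  = as.integer(atoms$resno),
    icode   = norm_icode(atoms$insert),
    resname = toupper(as.character(atoms$resid)),
    atom    = as.character(atoms$elety),
    alt     = norm_icode(atoms$alt),
    x = atoms$x, y = atoms$y, z = atoms$z,
    occ     = ifelse(is.na(atoms$o), 1, atoms$o),
    bfactor = ifelse(is.na(atoms$b), 0, atoms$b),
    record  = as.character(atoms$type)
  )
  a[is.na(chain) | chain == "", chain := "_"]
  elem <- as.character(atoms$elesy)
  elem[is.na(elem) | elem == ""] <- guess_element(a$atom[is.na(elem) | elem == ""])
  a[, element := toupper(elem)]
  if (any(!is.finite(a$x) | !is.finite(a$y) | !is.finite(a$z)))
    abort("non-finite coordinates in %s", path)

  # altloc resolution: per atom site, keep highest occupancy, tie -> first id
  a[, ord := .I]
  data.table::setorder(a, chain, resnum, icode, atom, -occ, alt)
  a <- a[!duplicated(a[, .(chain, resnum, icode, atom)])]
  data.table::setorder(a, ord)
  a[, ord := NULL]

  a[, is_water := is_water_res(resname)]
  a[, is_hetero := record == "HETATM"]
  # polymer membership: ATOM records, or HETATM with a known polymer parent
  a[, is_polymer := record == "ATOM" |
      (is_hetero & (resname %in% names(.AA_PARENT)))]
  a[is_water == TRUE, is_polymer := FALSE]
  a[, is_hydrogen := element %in% c("H", "D")]

  residues <- a[, .(
    resname = resname[1L],
    bfactor = mean(bfactor),
    n_atoms = .N,
    n_heavy = sum(!is_hydrogen),
    is_polymer = is_polymer[1L],
    is_water = is_water[1L],
    is_hetero = any(is_hetero),
    file_order = min(.I)
  ), by = .(chain, resnum, icode)]
  residues[, one_letter := ifelse(is_nuc_like(resname) & !is_aa_like(resname),
                                  unname(.NUC1[resname]), aa_one_letter(resname))]
  data.table::setorder(residues, file_order)

  chain_ids <- unique(residues$chain)
  chains <- data.table::rbindlist(lapply(chain_ids, function(cid) {
    data.table::data.table(chain_id = cid,
                           kind = classify_chain(residues[chain == cid]))
  }))

  model <- structure(list(
    structure_id = tools::file_path_sans_ext(basename(path)),
    source_format = format,
    model_number = 1L,
    atoms = a,
    residues = residues,
    chains = chains
  ), class = "StructureModel")

  if (!any(chains$kind == "protein"))
    warn("structure %s has no protein chain", model$structure_id)
  model
}

#' @export
print.StructureModel <- function(x, ...) {
  cat(sprintf("StructureModel '%s' (%s): %d chains, %d residues, %d atoms\n",
              x$structure_id, x$source_format,
              nrow(x$chains), nrow(x$residues), nrow(x$atoms)))
  for (i in seq_len(nrow(x$chains)))
    cat(sprintf("  chain %s: %s\n", x$chains$chain_id[i], x$chains$kind[i]))
  invisible(x)
}

#' Classify a chain as protein, nucleic, ligand or water
#'
#' A chain is `protein` if more than half of its polymer residues are
#' standard (or parent-mapped) amino acids, `nucleic` if more than half are
#' standard nucleotides, `water` if every residue is a water component, and
#' `ligand` otherwise. Each non-polymer HET component instance is treated
#' downstream as its own ligand entity.
#'
#' @param residues a per-residue data.table with columns `resname`,
#'   `is_polymer`, `is_water` (one chain's residues, as found in
#'   `StructureModel$residues`).
#' @return one of `"protein"`, `"nucleic"`, `"ligand"`, `"water"`.
#' @export
classify_chain <- function(residues) {
  if (nrow(residues) == 0L) abort("cannot classify an empty chain")
  if (all(residues$is_water)) return("water")
  poly <- residues[residues$is_polymer & !residues$is_water, ]
  if (nrow(poly) > 0L) {
    if (mean(is_aa_like(poly$resname)) > 0.5) return("protein")
    if (mean(is_nuc_like(poly$resname)) > 0.5) return("nucleic")
  }
  "ligand"
}

#' Extract the observed-residue sequence of a polymer chain
#'
#' Builds the one-letter sequence from residues with at least one observed
#' heavy atom, in author order, together with an exact bijective map from
#' 1-based sequence position to the author residue key (chain, residue
#' number, insertion code). Gaps in author numbering produce no gap
#' characters; nonstandard residues map to their parent's letter or `'X'`.
#'
#' @param model a `StructureModel`.
#' @param chain_id chain identifier (must be a protein or nucleic chain).
#' @return a list with `seq` (character scalar, possibly empty) and
#'   `map` (data.table with `seqpos`, `chain`, `resnum`, `icode`,
#'   `one_letter`, `bfactor`).
#' @export
extract_sequence <- function(model, chain_id) {
  kind <- model$chains$kind[model$chains$chain_id == chain_id]
  if (length(kind) == 0L) abort("no such chain: %s", chain_id)
  if (!kind %in% c("protein", "nucleic"))
    abort("chain %s is %s; sequences are defined for polymer chains only",
          chain_id, kind)
  res <- model$residues[chain == chain_id & is_polymer & !is_water & n_heavy >= 1L]
  data.table::setorder(res, file_order)
  map <- data.table::data.table(
    seqpos = seq_len(nrow(res)),
    chain = res$chain, resnum = res$resnum, icode = res$icode,
    one_letter = res$one_letter, bfactor = res$bfactor
  )
  list(seq = paste(res$one_letter, collapse = ""), map = map)
}
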