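# Inter-chain interface detection by heavy-atom distance, and the
# interface redundancy-removal policy applied when one query protein is
# covered by several structures.

# Interface entities of a structure: every protein or nucleic chain is one
# entity; every non-polymer, non-water HET residue instance is its own
# ligand entity (two copies of the same ligand are two distinct
# interfaces). Waters are never entities.
interface_entities <- function(model) {
  ch <- model$chains
  ents <- list()
  for (i in seq_len(nrow(ch))) {
    kind <- ch$kind[i]
    cid <- ch$chain_id[i]
    if (kind %in% c("protein", "nucleic")) {
      ents[[length(ents) + 1L]] <- data.table::data.table(
        entity_id = cid, entity_type = kind, chain = cid,
        resnum = NA_integer_, icode = NA_character_)
    }
  }
  lig <- model$residues[is_polymer == FALSE & is_water == FALSE]
  if (nrow(lig) > 0L) {
    ents[[length(ents) + 1L]] <- data.table::data.table(
      entity_id = paste0(lig$chain, "_", lig$resname, "_",
                         reskey_label(lig$resnum, lig$icode)),
      entity_type = "ligand", chain = lig$chain,
      resnum = lig$resnum, icode = lig$icode)
  }
  data.table::rbindlist(ents)
}

# Heavy, non-water atoms of one entity
entity_atoms <- function(model, ent) {
  a <- model$atoms[is_hydrogen == FALSE & is_water == FALSE]
  if (ent$entity_type == "ligand")
    a[chain == ent$chain & resnum == ent$resnum & icode == ent$icode &
        is_polymer == FALSE]
  else
    a[chain == ent$chain & is_polymer == TRUE]
}

# Minimum distance from each residue of atom set A to anywhere in atom set
# B, vectorized over the full cross pairing.
min_dist_per_residue <- function(A, B) {
  MA <- as.matrix(A[, .(x, y, z)])
  MB <- as.matrix(B[, .(x, y, z)])
  d2 <- outer(rowSums(MA^2), rowSums(MB^2), "+") - 2 * MA %*% t(MB)
  d2[d2 < 0] <- 0
  dmin <- sqrt(apply(d2, 1L, min))
  out <- data.table::data.table(resnum = A$resnum, icode = A$icode, d = dmin)
  out[, .(min_distance = min(d)), by = .(resnum, icode)]
}

#' Compute inter-chain interface residues of a structure
#'
#' A residue of a protein chain is an interface residue toward an entity
#' (another protein or nucleic chain, or an individual ligand instance) if
#' the minimum Euclidean distance over heavy-atom pairs between the
#' residue and any residue of that entity is at most `cutoff`. Hydrogens
#' and waters are excluded from the distance computation; intra-chain
#' contacts are ignored. One record is produced per (residue, partner
#' entity) pair, and each ligand copy is a distinct interface.
#'
#' @param model a `StructureModel`.
#' @param cutoff contact distance cutoff in Angstrom (default 5.0).
#' @return data.table of interface records: `structure_id`, `chain_id`,
#'   `resnum`, `icode`, `partner_entity`, `partner_type`, `min_distance`,
#'   `interface_id`. Empty (with a warning) when the structure has no
#'   protein chain.
#' @export
compute_interfaces <- function(model, cutoff = 5.0) {
  stopifnot(cutoff > 0)
  empty <- data.table::data.table(
    structure_id = character(), chain_id = character(),
    resnum = integer(), icode = character(),
    partner_entity = character(), partner_type = character(),
    min_distance = numeric(), interface_id = character())
  prot <- model$chains[kind == "protein"]
  if (nrow(prot) == 0L) {
    warn("structure %s has no protein chain; no interfaces computed",
         model$structure_id)
    return(empty)
  }
  ents <- interface_entities(model)
  out <- list(empty)
  for (p in prot$chain_id) {
    A <- model$atoms[chain == p & is_polymer == TRUE &
                       is_hydrogen == FALSE & is_water == FALSE]
    if (nrow(A) == 0L) next
    partners <- ents[!(entity_type %in% c("protein", "nucleic") & chain == p)]
    for (j in seq_len(nrow(partners))) {
      ent <- partners[j]
      B <- entity_atoms(model, ent)
      if (nrow(B) == 0L) next
      # bounding-box prefilter; the distance math below is exact
      if (min(A$x) - cutoff > max(B$x) || min(B$x) - cutoff > max(A$x) ||
          min(A$y) - cutoff > max(B$y) || min(B$y) - cutoff > max(A$y) ||
          min(A$z) - cutoff > max(B$z) || min(B$z) - cutoff > max(A$z)) next
      md <- min_dist_per_residue(A, B)
      hit <- md[min_distance <= cutoff]
      if (nrow(hit) == 0L) next
      out[[length(out) + 1L]] <- data.table::data.table(
        structure_id = model$structure_id, chain_id = p,
        resnum = hit$resnum, icode = hit$icode,
        partner_entity = ent$entity_id, partner_type = ent$entity_type,
        min_distance = hit$min_distance,
        interface_id = paste(model$structure_id, p, ent$entity_id, sep = "__"))
    }
  }
  data.table::rbindlist(out)
}

#' Remove redundant interfaces across structures of one protein
#'
#' Applies the two-step redundancy policy used when multiple structures
#' cover the same query protein: records whose source alignment has
#' `pident < pident_floor` are dropped (strictly below, so 80.0 survives
#' the default floor of 80); then, for each (query protein, partner type)
#' combination, only records from the structure with the highest Pident
#' are kept, ties broken by the lexicographically smallest structure ID.
#' All ligand instances within the winning structure are retained, so the
#' best structure per interface *type* contributes all its interfaces of
#' that type. The operation is idempotent.
#'
#' @param records data.table of interface records joined to their source
#'   alignments: must carry `query_id`, `structure_id`, `partner_type`,
#'   `pident`.
#' @param pident_floor minimum percent identity (default 80).
#' @return the surviving records, input order preserved.
#' @export
deduplicate_interfaces <- function(records, pident_floor = 80) {
  if (nrow(records) == 0L) return(records)
  stopifnot(all(c("query_id", "structure_id", "partner_type", "pident")
                %in% names(records)))
  rec <- records[pident >= pident_floor]
  if (nrow(rec) == 0L) return(rec)
  best <- rec[, .(pident = max(pident)), by = .(query_id, partner_type, structure_id)]
  data.table::setorder(best, query_id, partner_type, -pident, structure_id)
  winner <- best[, .SD[1L], by = .(query_id, partner_type)]
  rec <- data.table::copy(rec)
  rec[, .ord__ := .I]
  out <- rec[winner[, .(query_id, partner_type, structure_id)],
             on = c("query_id", "partner_type", "structure_id"), nomatch = NULL]
  data.table::setorder(out, .ord__)
  out[, .ord__ := NULL]
  out[]
}
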