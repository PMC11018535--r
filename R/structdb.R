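# The makestructuraldb step: align a proteome to a directory of
# structures, compute and deduplicate interfaces, and write one
# tab-separated structural-annotation file per covered protein plus a
# JSON run manifest.

.DB_SCHEMA_HEADER <- "# struct3dmap structural-annotation schema v1"
.DB_COLUMNS <- c("protein_id", "protein_pos", "protein_aa", "structure_id",
                 "chain_id", "resnum", "icode", "structure_aa", "is_identity",
                 "pident", "evalue", "bfactor", "interface_flags")

# Serialize a set of interface flags for one residue into one TSV field:
# comma-joined "partner_entity:partner_type:min_distance" triplets.
format_interface_flags <- function(partner_entity, partner_type, min_distance) {
  if (length(partner_entity) == 0L) return("")
  paste(sprintf("%s:%s:%.3f", partner_entity, partner_type, min_distance),
        collapse = ",")
}

#' Parse the `interface_flags` field of an annotation row
#'
#' @param flags character vector of serialized flag sets (possibly `""`).
#' @return a list of data.tables with `partner_entity`, `partner_type`,
#'   `min_distance` (zero rows for empty sets).
#' @export
parse_interface_flags <- function(flags) {
  lapply(flags, function(f) {
    if (is.na(f) || f == "") {
      return(data.table::data.table(partner_entity = character(),
                                    partner_type = character(),
                                    min_distance = numeric()))
    }
    parts <- strsplit(strsplit(f, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
    data.table::data.table(
      partner_entity = vapply(parts, `[`, "", 1L),
      partner_type = vapply(parts, `[`, "", 2L),
      min_distance = as.numeric(vapply(parts, `[`, "", 3L)))
  })
}

# Read a FASTA proteome into a named character vector of sequences.
read_proteome <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) abort("proteome %s contains no sequences", path)
  ids <- sub("\\s.*$", "", names(aa))
  stats::setNames(toupper(as.character(aa)), ids)
}

# Parse every structure in a directory; corrupt files are skipped with a
# warning, and chain sequences plus interfaces are precomputed once.
load_structures <- function(dir, cutoff) {
  files <- sort(list.files(dir, pattern = "\\.(pdb|ent|cif)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0L) abort("no structure files (.pdb/.ent/.cif) in %s", dir)
  out <- list()
  skipped <- character()
  for (f in files) {
    m <- tryCatch(suppressWarnings(parse_structure(f)), error = function(e) {
      warn("skipping unparseable structure %s: %s", f, conditionMessage(e))
      NULL
    })
    if (is.null(m)) { skipped <- c(skipped, basename(f)); next }
    if (m$structure_id %in% names(out)) next  # same entry in both formats
    chains <- m$chains[kind == "protein"]$chain_id
    seqs <- lapply(stats::setNames(chains, chains),
                   function(cid) extract_sequence(m, cid))
    seqs <- seqs[vapply(seqs, function(s) nchar(s$seq) > 0L, logical(1))]
    out[[m$structure_id]] <- list(model = m, chain_seqs = seqs,
                                  interfaces = compute_interfaces(m, cutoff))
  }
  if (length(out) == 0L) abort("no parseable structure files in %s", dir)
  attr(out, "skipped") <- skipped
  out
}

# Annotation rows for one query protein against all loaded structures.
annotate_protein <- function(pid, qseq, structs, pident_min, evalue_max,
                             interface_pident_floor) {
  maps <- list()
  n_aln <- 0L; n_pass <- 0L
  for (sid in names(structs)) {
    st <- structs[[sid]]
    for (cid in names(st$chain_seqs)) {
      cs <- st$chain_seqs[[cid]]
      aln <- local_align(qseq, cs$seq, query_id = pid,
                         structure_id = sid, chain_id = cid)
      n_aln <- n_aln + 1L
      if (length(filter_alignments(list(aln), pident_min, evalue_max)) == 0L)
        next
      n_pass <- n_pass + 1L
      maps[[length(maps) + 1L]] <- build_position_map(aln, cs)
    }
  }
  if (length(maps) == 0L) {
    return(list(rows = NULL, n_aln = n_aln, n_pass = n_pass))
  }
  pm <- data.table::rbindlist(maps)

  # candidate interface records seen through this protein's position maps,
  # then the redundancy policy across structures
  iface <- data.table::rbindlist(lapply(names(structs), function(sid)
    structs[[sid]]$interfaces))
  cand <- merge(pm, iface,
                by.x = c("structure_id", "chain_id", "resnum", "icode"),
                by.y = c("structure_id", "chain_id", "resnum", "icode"))
  if (nrow(cand) > 0L) {
    cand <- deduplicate_interfaces(cand, interface_pident_floor)
  }

  qaa <- strsplit(qseq, "")[[1]]
  rows <- data.table::data.table(
    protein_id = pid,
    protein_pos = pm$query_pos,
    protein_aa = qaa[pm$query_pos],
    structure_id = pm$structure_id,
    chain_id = pm$chain_id,
    resnum = pm$resnum,
    icode = pm$icode,
    structure_aa = pm$structure_aa,
    is_identity = pm$is_identity,
    pident = pm$pident,
    evalue = pm$evalue,
    bfactor = pm$bfactor
  )
  if (nrow(cand) > 0L) {
    fl <- cand[, .(interface_flags = format_interface_flags(
      partner_entity, partner_type, min_distance)),
      by = .(structure_id, chain_id, resnum, icode, query_pos)]
    rows <- merge(rows, fl,
                  by.x = c("structure_id", "chain_id", "resnum", "icode",
                           "protein_pos"),
                  by.y = c("structure_id", "chain_id", "resnum", "icode",
                           "query_pos"),
                  all.x = TRUE)
  } else {
    rows[, interface_flags := ""]
  }
  rows[is.na(interface_flags), interface_flags := ""]
  data.table::setorder(rows, protein_id, structure_id, chain_id, protein_pos)
  data.table::setcolorder(rows, .DB_COLUMNS)
  list(rows = rows, n_aln = n_aln, n_pass = n_pass)
}

write_annotation_file <- function(rows, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.DB_SCHEMA_HEADER, con)
  writeLines(paste(.DB_COLUMNS, collapse = "\t"), con)
  if (nrow(rows) > 0L) {
    body <- rows[, lapply(.SD, as.character)]
    body[, evalue := sprintf("%.6g", rows$evalue)]
    body[, pident := sprintf("%.6g", rows$pident)]
    body[, bfactor := sprintf("%.6g", rows$bfactor)]
    writeLines(do.call(paste, c(as.list(body), sep = "\t")), con)
  }
  invisible(path)
}

#' Read one structural-annotation file or a whole database directory
#'
#' @param path a per-protein `.tsv` annotation file or a directory
#'   produced by [make_structural_db()].
#' @return data.table of annotation rows.
#' @export
read_structural_db <- function(path) {
  files <- if (dir.exists(path))
    sort(list.files(path, pattern = "\\.tsv$", full.names = TRUE))
  else path
  out <- data.table::rbindlist(lapply(files, function(f) {
    dt <- data.table::fread(f, sep = "\t", skip = 1L, header = TRUE,
                            colClasses = list(character = c("icode",
                                                            "interface_flags")),
                            na.strings = NULL)
    dt
  }))
  if (nrow(out) > 0L) {
    out[is.na(icode), icode := ""]
    out[is.na(interface_flags), interface_flags := ""]
  }
  out
}

#' Build a structurally annotated protein database
#'
#' For every proteome protein, aligns its sequence to every protein chain
#' of every structure, keeps alignments passing the Pident / e-value
#' thresholds, transfers author residue numbering, B-factors (pLDDT for
#' predicted models) and deduplicated interface annotations through the
#' position maps, and writes one tab-separated annotation file per covered
#' protein (file names are sanitized with [sanitize_id()]; the rows keep
#' the original ID). A JSON manifest records counts and parameters.
#'
#' Per-protein work is independent: with `jobs > 1` proteins are processed
#' in parallel and the output is byte-identical to a serial run.
#'
#' @param proteome path to a FASTA file of query protein sequences.
#' @param structures directory of `.pdb` / `.cif` structure files.
#' @param outdir output directory (created if needed).
#' @param pident_min minimum percent identity (default 50).
#' @param evalue_max maximum e-value (default 1e-5).
#' @param cutoff interface distance cutoff in Angstrom (default 5.0).
#' @param interface_pident_floor Pident floor for interface redundancy
#'   removal (default 80).
#' @param jobs number of parallel worker processes (default 1).
#' @return invisibly, the manifest list.
#' @export
make_structural_db <- function(proteome, structures, outdir,
                               pident_min = 50, evalue_max = 1e-5,
                               cutoff = 5.0, interface_pident_floor = 80,
                               jobs = 1L) {
  seqs <- read_proteome(proteome)
  structs <- load_structures(structures, cutoff)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  pids <- names(seqs)
  worker <- function(pid) annotate_protein(pid, seqs[[pid]], structs,
                                           pident_min, evalue_max,
                                           interface_pident_floor)
  res <- if (jobs > 1L)
    parallel::mclapply(pids, worker, mc.cores = jobs, mc.preschedule = TRUE)
  else lapply(pids, worker)
  names(res) <- pids

  covered <- character(); uncovered <- character()
  n_aln <- 0L; n_pass <- 0L
  for (pid in pids) {
    r <- res[[pid]]
    n_aln <- n_aln + r$n_aln; n_pass <- n_pass + r$n_pass
    if (is.null(r$rows)) { uncovered <- c(uncovered, pid); next }
    covered <- c(covered, pid)
    write_annotation_file(r$rows,
                          file.path(outdir, paste0(sanitize_id(pid), ".tsv")))
  }

  manifest <- list(
    schema = "struct3dmap-manifest-v1",
    n_proteins = length(pids),
    n_proteins_covered = length(covered),
    proteins_covered = covered,
    proteins_without_hits = uncovered,
    n_structures_used = length(structs),
    structures_skipped = as.character(attr(structs, "skipped")),
    n_alignments_computed = n_aln,
    n_alignments_passing = n_pass,
    parameters = list(pident_min = pident_min, evalue_max = evalue_max,
                      interface_cutoff = cutoff,
                      interface_pident_floor = interface_pident_floor)
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Structural coverage of a proteome by Pident threshold
#'
#' For each Pident threshold, the fraction of proteome residues covered by
#' at least one annotation row at or above that identity, and the fraction
#' of proteins with at least one such row. Lowering the threshold can only
#' increase both fractions.
#'
#' @param db_dir database directory from [make_structural_db()].
#' @param proteome FASTA file the database was built from.
#' @param thresholds numeric vector of Pident thresholds (default
#'   `c(100, 90, 80, 70, 60, 50)`).
#' @return data.table with `pident_min`, `residue_coverage`,
#'   `protein_coverage`.
#' @export
coverage_summary <- function(db_dir, proteome,
                             thresholds = c(100, 90, 80, 70, 60, 50)) {
  seqs <- read_proteome(proteome)
  total_res <- sum(nchar(seqs))
  db <- read_structural_db(db_dir)
  data.table::rbindlist(lapply(thresholds, function(t) {
    hit <- db[pident >= t]
    cov_res <- if (nrow(hit) == 0L) 0 else
      nrow(unique(hit[, .(protein_id, protein_pos)])) / total_res
    cov_prot <- if (nrow(hit) == 0L) 0 else
      length(unique(hit$protein_id)) / length(seqs)
    data.table::data.table(pident_min = t, residue_coverage = cov_res,
                           protein_coverage = cov_prot)
  }))
}
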