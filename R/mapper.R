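# The mapper step: join per-transcript variant files to per-protein
# structural annotations, classify every variant, and write the
# analysis-ready table plus a SetID file for region-based rare-variant
# association testing.

.CLASS_ORDER <- c("interface", "structure", "unmapped", "non-coding")

.MAP_STRUCT_COLS <- c("structure_id", "chain_id", "resnum", "icode",
                      "structure_aa", "is_identity", "pident", "evalue",
                      "bfactor", "interface_flags")

mapped_empty <- function() {
  dt <- data.table::data.table(
    variant_id = character(), transcript_id = character(),
    gene_id = character(), consequence = character(),
    protein_id = character(), protein_pos = integer(),
    protein_aa = character(), aa_ref = character(), aa_alt = character(),
    structure_id = character(), chain_id = character(), resnum = integer(),
    icode = character(), structure_aa = character(), is_identity = logical(),
    pident = numeric(), evalue = numeric(), bfactor = numeric(),
    interface_flags = character(), class = character(),
    ref_mismatch = logical(), reason = character(),
    source_format = character())
  dt
}

#' Read a transcript-to-protein identifier map
#'
#' A two-column (or more) tab-separated file with a header naming at least
#' `transcript_id` and `protein_id`. Versions are stripped for matching.
#'
#' @param path TSV file.
#' @return data.table with `transcript_key`, `protein_id`.
#' @export
read_id_map <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  missing <- setdiff(c("transcript_id", "protein_id"), names(dt))
  if (length(missing) > 0L)
    abort("ID map %s is missing column(s): %s", path,
          paste(missing, collapse = ", "))
  unique(dt[, .(transcript_key = strip_version(transcript_id),
                protein_id)])
}

# Structural-row filters shared by the mapper options.
filter_annotation_rows <- function(rows, min_pident = NULL, min_plddt = NULL,
                                   pdockq = NULL, min_pdockq = 0.23) {
  if (!is.null(min_pident)) rows <- rows[pident >= min_pident]
  if (!is.null(min_plddt)) rows <- rows[bfactor >= min_plddt]
  if (!is.null(pdockq)) {
    # models listed in the score table must exceed the threshold; rows from
    # structures without a score (e.g. experimental) are untouched
    scored <- rows$structure_id %in% pdockq$structure_id
    sc <- pdockq$pdockq[match(rows$structure_id, pdockq$structure_id)]
    rows <- rows[!scored | sc > min_pdockq]
  }
  rows
}

#' Read a per-model pDockQ score table
#'
#' @param path TSV with header columns `structure_id` and `pdockq`.
#' @return data.table.
#' @export
read_pdockq_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  missing <- setdiff(c("structure_id", "pdockq"), names(dt))
  if (length(missing) > 0L)
    abort("pDockQ table %s is missing column(s): %s", path,
          paste(missing, collapse = ", "))
  dt[, .(structure_id = as.character(structure_id),
         pdockq = as.numeric(pdockq))]
}

#' Map variants onto the structural annotation database
#'
#' For every variant record and every structural-annotation row covering
#' one of its protein positions, emits one long-format row classified as
#' `interface` (the covering row carries at least one interface flag) or
#' `structure` (covered, no flag). A variant with a protein position but
#' no covering row yields one `unmapped` row (with a reason code); a
#' record without a protein position yields one `non-coding` row.
#' Interval positions (in-frame indels) are expanded to one query per
#' covered position.
#'
#' A reference-allele sanity check compares the variant's reference amino
#' acid with the query protein residue at that position and sets a
#' `ref_mismatch` flag instead of dropping discordant rows.
#'
#' @param protdb_dir structural database from [make_structural_db()].
#' @param vardb_dir variants database from [make_variants_db()].
#' @param id_map data.table from [read_id_map()], or a path to the TSV.
#'   An identity map (`transcript_id == protein_id`) is allowed.
#' @param consequences optional character vector restricting the mapped
#'   consequence types (default: no filtering).
#' @param min_pident,min_plddt optional structural-row quality filters.
#' @param pdockq optional data.table from [read_pdockq_table()] (or a
#'   path); when supplied, rows from models scored at or below
#'   `min_pdockq` are excluded.
#' @param min_pdockq pDockQ inclusion threshold (default 0.23; models must
#'   score strictly above it).
#' @return data.table of mapped rows (class `mapped_variants`).
#' @export
map_variants <- function(protdb_dir, vardb_dir, id_map,
                         consequences = NULL, min_pident = NULL,
                         min_plddt = NULL, pdockq = NULL,
                         min_pdockq = 0.23) {
  if (is.character(id_map)) id_map <- read_id_map(id_map)
  id_map <- data.table::as.data.table(id_map)
  if (!"transcript_key" %in% names(id_map))
    id_map[, transcript_key := strip_version(transcript_id)]
  if (is.character(pdockq)) pdockq <- read_pdockq_table(pdockq)
  idx_path <- file.path(vardb_dir, "index.json")
  if (!file.exists(idx_path)) abort("no index.json in %s", vardb_dir)
  index <- jsonlite::read_json(idx_path)

  out <- list(mapped_empty())
  db_cache <- new.env()
  for (tk in sort(names(index))) {
    vr <- read_variant_file(file.path(vardb_dir, index[[tk]]$path))
    pid <- id_map$protein_id[match(tk, id_map$transcript_key)]

    for (i in seq_len(nrow(vr))) {
      v <- vr[i]
      base <- data.table::data.table(
        variant_id = v$variant_id, transcript_id = v$transcript_id,
        gene_id = v$gene_id, consequence = v$consequence,
        protein_id = if (is.na(pid)) NA_character_ else pid,
        aa_ref = v$aa_ref, aa_alt = v$aa_alt,
        source_format = v$source_format)
      if (!is.null(consequences) &&
          !any(strsplit(v$consequence, ",|&")[[1]] %in% consequences)) next
      if (is.na(v$protein_start)) {
        out[[length(out) + 1L]] <- cbind(base, data.table::data.table(
          protein_pos = NA_integer_, protein_aa = NA_character_,
          class = "non-coding", ref_mismatch = NA, reason = ""))
        next
      }
      if (is.na(pid)) {
        out[[length(out) + 1L]] <- cbind(base, data.table::data.table(
          protein_pos = v$protein_start, protein_aa = NA_character_,
          class = "unmapped", ref_mismatch = NA,
          reason = "transcript_not_in_idmap"))
        next
      }
      rows <- load_protein_rows(db_cache, protdb_dir, pid)
      rows <- filter_annotation_rows(rows, min_pident, min_plddt,
                                     pdockq, min_pdockq)
      positions <- seq.int(v$protein_start, v$protein_end)
      hits <- rows[protein_pos %in% positions]
      if (nrow(hits) == 0L) {
        out[[length(out) + 1L]] <- cbind(base, data.table::data.table(
          protein_pos = v$protein_start, protein_aa = NA_character_,
          class = "unmapped", ref_mismatch = NA,
          reason = if (nrow(rows) == 0L) "no_structural_coverage"
                   else "position_not_covered"))
        next
      }
      hit_rows <- cbind(
        base[rep(1L, nrow(hits))],
        hits[, .(protein_pos, protein_aa, structure_id, chain_id, resnum,
                 icode, structure_aa, is_identity, pident, evalue, bfactor,
                 interface_flags)])
      hit_rows[, class := ifelse(interface_flags != "", "interface",
                                 "structure")]
      hit_rows[, ref_mismatch := NA]
      if (!is.na(v$aa_ref) && nchar(v$aa_ref) == 1L && length(positions) == 1L)
        hit_rows[, ref_mismatch := protein_aa != v$aa_ref]
      hit_rows[, reason := ""]
      out[[length(out) + 1L]] <- hit_rows
    }
  }
  mapped <- data.table::rbindlist(out, use.names = TRUE, fill = TRUE)
  data.table::setcolorder(mapped, names(mapped_empty()))
  data.table::setorder(mapped, variant_id, transcript_id, protein_id,
                       protein_pos, structure_id, chain_id, resnum, na.last = TRUE)
  data.table::setattr(mapped, "class",
                      c("mapped_variants", class(mapped)))
  mapped
}

load_protein_rows <- function(cache, protdb_dir, pid) {
  key <- sanitize_id(pid)
  if (!is.null(cache[[key]])) return(cache[[key]])
  f <- file.path(protdb_dir, paste0(key, ".tsv"))
  rows <- if (file.exists(f)) read_structural_db(f) else
    read_structural_db(character(0))
  if (nrow(rows) == 0L)
    rows <- data.table::data.table(
      protein_id = character(), protein_pos = integer(),
      protein_aa = character(), structure_id = character(),
      chain_id = character(), resnum = integer(), icode = character(),
      structure_aa = character(), is_identity = logical(),
      pident = numeric(), evalue = numeric(), bfactor = numeric(),
      interface_flags = character())
  cache[[key]] <- rows
  rows
}

#' Per-variant summary with the best structural class
#'
#' Collapses the long mapped table to one row per (variant, transcript)
#' with the best class under the ordering
#' interface > structure > unmapped > non-coding.
#'
#' @param mapped data.table from [map_variants()].
#' @return data.table with `variant_id`, `transcript_id`, `protein_id`,
#'   `best_class`, `n_structure_hits`.
#' @export
summarize_mapped <- function(mapped) {
  if (nrow(mapped) == 0L)
    return(data.table::data.table(variant_id = character(),
                                  transcript_id = character(),
                                  protein_id = character(),
                                  best_class = character(),
                                  n_structure_hits = integer()))
  mapped[, .(
    protein_id = protein_id[1L],
    best_class = .CLASS_ORDER[min(match(class, .CLASS_ORDER))],
    n_structure_hits = sum(!is.na(structure_id))
  ), by = .(variant_id, transcript_id)]
}

#' Write mapper outputs: mapped table plus SetID file
#'
#' The mapped table is written as RFC-4180 CSV and/or as a binary
#' columnar table (Parquet) with identical rows; the SetID file is the
#' two-column whitespace-separated `set_id variant_id` format consumed by
#' region-based rare-variant association tests.
#'
#' Grouping policies: `"per-protein"` (one set per protein, all its
#' structure-covered variants), `"per-interface"` (one set per
#' (protein, partner entity), its interface variants), `"per-class"`
#' (one set per (protein, class) for the interface and structure classes).
#'
#' @param mapped data.table from [map_variants()].
#' @param outdir output directory.
#' @param format `"csv"`, `"parquet"`, or both.
#' @param setid_grouping one of `"per-interface"`, `"per-protein"`,
#'   `"per-class"`.
#' @param basename file stem (default `"mapped"`).
#' @return invisibly, named list of written paths.
#' @export
write_outputs <- function(mapped, outdir, format = "csv",
                          setid_grouping = c("per-interface", "per-protein",
                                             "per-class"),
                          basename = "mapped") {
  setid_grouping <- match.arg(setid_grouping)
  bad <- setdiff(format, c("csv", "parquet"))
  if (length(bad) > 0L)
    abort("unknown output format: %s", paste(bad, collapse = ", "))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  tbl <- data.table::as.data.table(mapped)
  if ("csv" %in% format) {
    p <- file.path(outdir, paste0(basename, ".csv"))
    data.table::fwrite(tbl, p, quote = "auto", na = "NA")
    paths$csv <- p
  }
  if ("parquet" %in% format) {
    p <- file.path(outdir, paste0(basename, ".parquet"))
    arrow::write_parquet(tbl, p)
    paths$parquet <- p
  }
  paths$setid <- file.path(outdir, paste0(basename, ".setID"))
  writeLines(format_setid(tbl, setid_grouping), paths$setid)
  invisible(paths)
}

format_setid <- function(mapped, grouping) {
  m <- mapped[class %in% c("interface", "structure")]
  if (nrow(m) == 0L) return(character(0))
  sets <- switch(grouping,
    "per-protein" = m[, .(set_id = protein_id, variant_id)],
    "per-class" = m[, .(set_id = paste(protein_id, class, sep = "_"),
                        variant_id)],
    "per-interface" = {
      mi <- m[class == "interface"]
      if (nrow(mi) == 0L) return(character(0))
      expanded <- mi[, {
        fl <- parse_interface_flags(interface_flags)[[1L]]
        .(partner_entity = fl$partner_entity)
      }, by = .(protein_id, variant_id, interface_flags)]
      expanded[, .(set_id = paste(protein_id, partner_entity, sep = "_"),
                   variant_id)]
    })
  sets <- unique(sets[, .(set_id, variant_id)])
  data.table::setorder(sets, set_id, variant_id)
  paste(sets$set_id, sets$variant_id)
}

#' Read back a mapped table written by [write_outputs()]
#'
#' @param path a `.csv` or `.parquet` file.
#' @return data.table of mapped rows.
#' @export
read_mapped <- function(path) {
  ext <- tolower(tools::file_ext(path))
  tbl <- if (ext == "parquet") {
    data.table::as.data.table(arrow::read_parquet(path))
  } else {
    data.table::fread(path, na.strings = "NA",
                      colClasses = list(character = c("icode",
                                                      "interface_flags")))
  }
  if (nrow(tbl) > 0L) {
    tbl[is.na(icode), icode := ""]
    tbl[is.na(interface_flags), interface_flags := ""]
  }
  tbl[]
}
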