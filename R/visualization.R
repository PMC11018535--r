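# The makevisualization step: emit ChimeraX command scripts (.cxc) that
# open each structure and color mapped variant positions by class.

default_palette <- function() {
  list(interface = "red", structure = "blue", base = "gray")
}

# Compact a set of residues of one chain into a ChimeraX residue spec:
# plain-numbered consecutive residues collapse to ranges, insertion-coded
# residues are rendered individually (e.g. "1,3-4,7A").
residue_spec_items <- function(resnum, icode) {
  ord <- order(resnum, icode)
  resnum <- resnum[ord]; icode <- icode[ord]
  plain <- resnum[icode == ""]
  items <- character(0)
  if (length(plain) > 0L) {
    plain <- sort(unique(plain))
    run_id <- cumsum(c(1L, diff(plain) != 1L))
    for (r in split(plain, run_id)) {
      items <- c(items,
                 if (length(r) == 1L) as.character(r)
                 else paste0(r[1L], "-", r[length(r)]))
    }
  }
  ins <- icode != ""
  if (any(ins)) items <- c(items, paste0(resnum[ins], icode[ins]))
  items
}

#' Write ChimeraX visualization scripts for mapped variants
#'
#' One `.cxc` script per structure appearing in the mapped table with at
#' least one `interface` or `structure` class row: the script opens the
#' structure, draws a grey cartoon, then colors structure-class residues
#' and interface-class residues with the configured palette (a residue in
#' both classes is colored as interface). A legend comment header lists
#' the variant IDs per residue. Structures with only unmapped or
#' non-coding rows produce no script.
#'
#' @param mapped data.table from [map_variants()].
#' @param outdir output directory.
#' @param palette named list with colors `interface`, `structure`, `base`.
#' @param structure_paths optional named character vector mapping
#'   `structure_id` to the file path used in the `open` command (defaults
#'   to `<structure_id>.pdb`).
#' @return invisibly, character vector of script paths written.
#' @export
make_visualization <- function(mapped, outdir, palette = default_palette(),
                               structure_paths = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  m <- data.table::as.data.table(mapped)[class %in% c("interface", "structure")]
  written <- character(0)
  for (sid in sort(unique(m$structure_id))) {
    ms <- m[structure_id == sid]
    # residue-level class: interface wins over structure
    res <- ms[, .(class = .CLASS_ORDER[min(match(class, .CLASS_ORDER))],
                  variants = paste(sort(unique(variant_id)), collapse = ",")),
              by = .(chain_id, resnum, icode)]
    lines <- c(
      sprintf("# struct3dmap visualization for structure %s", sid),
      sprintf("# legend: residue -> variant ids"))
    data.table::setorder(res, chain_id, resnum, icode)
    for (i in seq_len(nrow(res)))
      lines <- c(lines, sprintf("# /%s:%s [%s] %s", res$chain_id[i],
                                reskey_label(res$resnum[i], res$icode[i]),
                                res$class[i], res$variants[i]))
    src <- if (!is.null(structure_paths) && sid %in% names(structure_paths))
      structure_paths[[sid]] else paste0(sid, ".pdb")
    lines <- c(lines,
               sprintf("open %s", src),
               "hide atoms",
               "show cartoon",
               sprintf("color %s", palette$base))
    for (cls in c("structure", "interface")) {
      rc <- res[class == cls]
      if (nrow(rc) == 0L) next
      for (ch in sort(unique(rc$chain_id))) {
        items <- residue_spec_items(rc[chain_id == ch]$resnum,
                                    rc[chain_id == ch]$icode)
        sel <- sprintf("/%s:%s", ch, paste(items, collapse = ","))
        lines <- c(lines,
                   sprintf("color %s %s", sel, palette[[cls]]),
                   sprintf("show %s atoms", sel))
      }
    }
    path <- file.path(outdir, paste0(sanitize_id(sid), ".cxc"))
    writeLines(lines, path)
    written <- c(written, path)
  }
  if (length(written) == 0L)
    message("no structures with interface/structure class rows; no scripts written")
  invisible(written)
}

#' Parse residue selectors back out of a ChimeraX script
#'
#' Reads the `color /CHAIN:items COLOR` commands of a script written by
#' [make_visualization()] and expands every selector to its residue set.
#' Used to verify that emitted selectors round-trip exactly to the mapped
#' residue classes.
#'
#' @param path a `.cxc` file.
#' @param palette the palette the script was written with (colors are
#'   mapped back to classes).
#' @return data.table with `chain_id`, `resnum`, `icode`, `class`.
#' @export
parse_cxc_selectors <- function(path, palette = default_palette()) {
  lines <- readLines(path)
  cmd <- grep("^color /", lines, value = TRUE)
  color_to_class <- stats::setNames(
    c("interface", "structure"),
    c(palette$interface, palette$structure))
  out <- list(data.table::data.table(chain_id = character(),
                                     resnum = integer(), icode = character(),
                                     class = character()))
  for (l in cmd) {
    parts <- strsplit(l, " +")[[1]]  # "color" "/A:1,3-4,7A" "red"
    cls <- color_to_class[[parts[3L]]]
    sel <- sub("^/", "", parts[2L])
    ch <- sub(":.*$", "", sel)
    items <- strsplit(sub("^[^:]*:", "", sel), ",", fixed = TRUE)[[1]]
    for (it in items) {
      if (grepl("^[0-9]+-[0-9]+$", it)) {
        r <- as.integer(strsplit(it, "-", fixed = TRUE)[[1]])
        out[[length(out) + 1L]] <- data.table::data.table(
          chain_id = ch, resnum = seq.int(r[1L], r[2L]), icode = "",
          class = cls)
      } else if (grepl("^[0-9]+$", it)) {
        out[[length(out) + 1L]] <- data.table::data.table(
          chain_id = ch, resnum = as.integer(it), icode = "", class = cls)
      } else {
        out[[length(out) + 1L]] <- data.table::data.table(
          chain_id = ch, resnum = as.integer(sub("[A-Za-z]+$", "", it)),
          icode = sub("^[0-9]+", "", it), class = cls)
      }
    }
  }
  # interface wins where a residue appears under both classes
  res <- data.table::rbindlist(out)
  res[, .(class = .CLASS_ORDER[min(match(class, .CLASS_ORDER))]),
      by = .(chain_id, resnum, icode)]
}
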