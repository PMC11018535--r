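#' @import data.table
#' @importFrom stats setNames
#' @importFrom utils head tail
NULL

#' Sanitize an identifier for use in a file name
#'
#' Pipe characters (common in UniProt-style IDs such as `sp|P12345|NAME`)
#' and path separators are replaced with underscores so that every record
#' identifier yields a safe, portable file name. The original identifier is
#' always preserved inside output tables; only file names are sanitized.
#'
#' @param id character vector of identifiers.
#' @return character vector of file-name-safe identifiers.
#' @export
#' @examples
#' sanitize_id("sp|P12345|NAME")
sanitize_id <- function(id) {
  gsub("[|/\\\\:]", "_", id)
}

#' Strip a trailing version suffix from a transcript or protein identifier
#'
#' Ensembl-style identifiers often carry a version (`ENST00000380152.7`).
#' Matching between variant files and ID maps is done on the unversioned
#' accession while the original string is preserved in outputs.
#'
#' @param id character vector.
#' @return character vector without `.N` version suffixes.
#' @export
strip_version <- function(id) {
  sub("\\.[0-9]+$", "", id)
}

# Internal: stop with a formatted message
abort <- function(...) stop(sprintf(...), call. = FALSE)

# Internal: warn with a formatted message
warn <- function(...) warning(sprintf(...), call. = FALSE)

# Internal: normalize an insertion code to "" when absent
norm_icode <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x %in% c("?", ".", " ")] <- ""
  x
}

# Internal: residue key label "resnum[icode]" used in file output and selectors
reskey_label <- function(resnum, icode) {
  paste0(resnum, ifelse(icode == "" | is.na(icode), "", icode))
}
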