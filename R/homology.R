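# Homology transfer: local alignment of proteome sequences to
# structure-chain sequences, identity/e-value filtering, and the
# per-position coordinate map that carries a query protein position onto
# an author-numbered structure residue.

# Karlin-Altschul parameters for gapped protein search, as published for
# the BLOSUM62 matrix. Keys are "open_extend".
.KA_PARAMS <- list(
  BLOSUM62 = list(
    "11_1" = c(lambda = 0.267, K = 0.041),
    "10_1" = c(lambda = 0.243, K = 0.035),
    "12_2" = c(lambda = 0.300, K = 0.072)
  )
)

.AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWYX", "")[[1]]

validate_aa_seq <- function(seq, what = "sequence") {
  if (is.na(seq) || nchar(seq) == 0L) abort("%s is empty", what)
  chars <- unique(strsplit(seq, "")[[1]])
  bad <- setdiff(chars, .AA_ALPHABET)
  if (length(bad) > 0L)
    abort("%s contains symbols outside the amino-acid alphabet: %s",
          what, paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Optimal local alignment of a query protein to a structure-chain sequence
#'
#' Computes the optimal Smith-Waterman local alignment under affine gap
#' penalties (a gap of length k costs `gap_open + k * gap_extend`, the
#' BLAST convention). Percent identity uses the BLAST-tabular convention
#' (100 x identical columns / alignment length including gaps); `'X'`
#' never counts as an identity, even against another `'X'`, so unknown
#' residues cannot inflate Pident. The bit score and e-value follow
#' Karlin-Altschul statistics with the matrix's published lambda/K and an
#' m x n pairwise search space.
#'
#' @param query_seq,subject_seq uppercase amino-acid strings (`X` allowed).
#' @param matrix substitution matrix name (currently `"BLOSUM62"`).
#' @param gap_open,gap_extend affine gap penalties (defaults 11 / 1, the
#'   BLAST protein defaults).
#' @param query_id,structure_id,chain_id identifiers carried into the result.
#' @return an object of class `ChainAlignment`: raw `score`, `bitscore`,
#'   `evalue`, `pident`, `n_identical`, `aln_len`, 1-based inclusive spans
#'   `qstart`/`qend`/`sstart`/`send`, and `colmap`, a data.table with one
#'   row per alignment column (`qpos` / `spos`, `NA` for gaps).
#' @export
local_align <- function(query_seq, subject_seq,
                        matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                        query_id = NA_character_, structure_id = NA_character_,
                        chain_id = NA_character_) {
  validate_aa_seq(query_seq, "query sequence")
  validate_aa_seq(subject_seq, "subject sequence")
  submat <- substitution_matrix(matrix)

  al <- Biostrings::pairwiseAlignment(
    pattern = query_seq, subject = subject_seq, type = "local",
    substitutionMatrix = submat,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  qa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  qstart <- Biostrings::start(Biostrings::pattern(al))
  sstart <- Biostrings::start(Biostrings::subject(al))

  qpos <- ifelse(qa == "-", NA_integer_, qstart - 1L + cumsum(qa != "-"))
  spos <- ifelse(sa == "-", NA_integer_, sstart - 1L + cumsum(sa != "-"))
  colmap <- data.table::data.table(col = seq_along(qa), qpos = qpos, spos = spos,
                                   q_aa = qa, s_aa = sa)
  n_identical <- sum(qa == sa & qa != "-" & qa != "X")
  aln_len <- length(qa)
  raw <- Biostrings::score(al)

  ka <- .KA_PARAMS[[matrix]][[paste(gap_open, gap_extend, sep = "_")]]
  if (is.null(ka))
    abort("no Karlin-Altschul parameters for %s with gap open %s / extend %s",
          matrix, gap_open, gap_extend)
  bitscore <- (ka[["lambda"]] * raw - log(ka[["K"]])) / log(2)
  evalue <- nchar(query_seq) * nchar(subject_seq) * 2^(-bitscore)

  no_hit <- aln_len == 0L || all(is.na(qpos))  # empty optimal alignment
  structure(list(
    query_id = query_id, structure_id = structure_id, chain_id = chain_id,
    score = raw, bitscore = bitscore, evalue = evalue,
    qstart = if (no_hit) NA_integer_ else qstart,
    qend = if (no_hit) NA_integer_ else max(qpos, na.rm = TRUE),
    sstart = if (no_hit) NA_integer_ else sstart,
    send = if (no_hit) NA_integer_ else max(spos, na.rm = TRUE),
    n_identical = n_identical, aln_len = aln_len,
    pident = if (no_hit) 0 else 100 * n_identical / aln_len,
    colmap = colmap
  ), class = "ChainAlignment")
}

#' @export
print.ChainAlignment <- function(x, ...) {
  cat(sprintf(
    "ChainAlignment %s -> %s/%s: score %g, bits %.1f, e %.2g, pident %.1f%% (%d/%d)\n",
    x$query_id, x$structure_id, x$chain_id,
    x$score, x$bitscore, x$evalue, x$pident, x$n_identical, x$aln_len))
  invisible(x)
}

#' Substitution matrix lookup
#'
#' @param name matrix name, e.g. `"BLOSUM62"`.
#' @return a numeric scoring matrix.
#' @export
substitution_matrix <- function(name = "BLOSUM62") {
  e <- new.env()
  ok <- tryCatch({
    utils::data(list = name, package = "Biostrings", envir = e)
    TRUE
  }, warning = function(w) FALSE, error = function(e) FALSE)
  if (!ok) abort("unknown substitution matrix: %s", name)
  get(name, envir = e)
}

#' Filter alignments by percent identity and e-value
#'
#' Keeps alignments with `pident >= pident_min` and `evalue <= evalue_max`;
#' both comparisons are inclusive, so an alignment exactly at 50% identity
#' or at the 1e-5 e-value boundary is retained. Input order is preserved.
#'
#' @param alns list of `ChainAlignment` objects.
#' @param pident_min minimum percent identity (default 50).
#' @param evalue_max maximum e-value (default 1e-5).
#' @return the retained sub-list, in input order.
#' @export
filter_alignments <- function(alns, pident_min = 50, evalue_max = 1e-5) {
  keep <- vapply(alns, function(a)
    a$pident >= pident_min && a$evalue <= evalue_max, logical(1))
  alns[keep]
}

#' Build the query-position to structure-residue coordinate map
#'
#' For every alignment column where both query and subject are non-gap,
#' emits one entry mapping the 1-based query protein position onto the
#' author residue key of the structure chain, together with the aligned
#' structure amino acid, an identity flag and the source alignment's
#' Pident. Gap columns produce no entry, so query positions inserted
#' relative to the structure are simply absent from the map.
#'
#' @param aln a `ChainAlignment`.
#' @param chain_seq result of [extract_sequence()] for the aligned chain
#'   (provides `map` from sequence position to residue key and B-factor).
#' @return data.table with columns `query_id`, `query_pos`, `structure_id`,
#'   `chain_id`, `resnum`, `icode`, `structure_aa`, `is_identity`,
#'   `pident`, `evalue`, `bfactor`.
#' @export
build_position_map <- function(aln, chain_seq) {
  cm <- aln$colmap[!is.na(qpos) & !is.na(spos)]
  if (nrow(cm) > 0L && max(cm$spos) > nrow(chain_seq$map))
    abort(paste0("alignment subject position %d outside chain length %d: ",
                 "aligner/parser mismatch for %s/%s"),
          max(cm$spos), nrow(chain_seq$map), aln$structure_id, aln$chain_id)
  key <- chain_seq$map[cm$spos]
  data.table::data.table(
    query_id = aln$query_id,
    query_pos = cm$qpos,
    structure_id = aln$structure_id,
    chain_id = key$chain,
    resnum = key$resnum,
    icode = key$icode,
    structure_aa = cm$s_aa,
    is_identity = cm$q_aa == cm$s_aa & cm$q_aa != "X",
    pident = aln$pident,
    evalue = aln$evalue,
    bfactor = key$bfactor
  )
}
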