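# The makevariantsdb step: normalize variant / annotated-position files
# (VEP tabular, VEP-like, MAF, VEP-annotated VCF) into a single record
# schema and split them into per-transcript files for fast mapping.

.VR_COLUMNS <- c("variant_id", "transcript_id", "transcript_key", "gene_id",
                 "consequence", "protein_start", "protein_end",
                 "aa_ref", "aa_alt", "source_format", "extras")

vr_empty <- function() {
  data.table::data.table(
    variant_id = character(), transcript_id = character(),
    transcript_key = character(), gene_id = character(),
    consequence = character(), protein_start = integer(),
    protein_end = integer(), aa_ref = character(), aa_alt = character(),
    source_format = character(), extras = character())
}

# "86" -> (86,86); "86-88" -> (86,88); "-" / "" / "86-?" partial -> NA sides
parse_protein_position <- function(x) {
  x <- as.character(x)
  start <- rep(NA_integer_, length(x)); end <- start
  ok <- !is.na(x) & x != "" & x != "-"
  single <- ok & grepl("^[0-9]+$", x)
  start[single] <- as.integer(x[single]); end[single] <- start[single]
  range <- ok & grepl("^[0-9?]+-[0-9?]+$", x) & !single
  if (any(range)) {
    sp <- strsplit(x[range], "-", fixed = TRUE)
    s <- suppressWarnings(as.integer(vapply(sp, `[`, "", 1L)))
    e <- suppressWarnings(as.integer(vapply(sp, `[`, "", 2L)))
    s[is.na(s)] <- e[is.na(s)]
    e[is.na(e)] <- s[is.na(e)]
    start[range] <- s; end[range] <- e
  }
  list(start = start, end = end)
}

# "H/N" -> (H,N); "H" (synonymous) -> (H,H); "-" -> absent
parse_amino_acids <- function(x) {
  x <- as.character(x)
  ref <- rep(NA_character_, length(x)); alt <- ref
  ok <- !is.na(x) & x != "" & x != "-"
  one <- ok & grepl("^[A-Z*]+$", x)
  ref[one] <- x[one]; alt[one] <- x[one]
  two <- ok & grepl("^[A-Z*-]*/[A-Z*-]*$", x)
  if (any(two)) {
    sp <- strsplit(x[two], "/", fixed = TRUE)
    r <- vapply(sp, function(p) if (length(p) >= 1L) p[1L] else "", "")
    a <- vapply(sp, function(p) if (length(p) >= 2L) p[2L] else "", "")
    r[r %in% c("", "-")] <- NA_character_
    a[a %in% c("", "-")] <- NA_character_
    ref[two] <- r; alt[two] <- a
  }
  n_bad <- sum(ok & !one & !two)
  if (n_bad > 0L)
    warn("%d amino-acid change string(s) could not be parsed; records kept with amino-acid fields absent",
         n_bad)
  list(ref = ref, alt = alt)
}

# "p.H86N" (HGVSp short) -> consequence-level fields
parse_hgvsp_short <- function(x) {
  x <- sub("^p\\.", "", as.character(x))
  m <- regmatches(x, regexec("^([A-Z])([0-9]+)([A-Z*])$", x))
  ref <- vapply(m, function(g) if (length(g) == 4L) g[2L] else NA_character_, "")
  pos <- vapply(m, function(g) if (length(g) == 4L) g[3L] else NA_character_, "")
  alt <- vapply(m, function(g) if (length(g) == 4L) g[4L] else NA_character_, "")
  list(ref = ref, pos = suppressWarnings(as.integer(pos)), alt = alt)
}

detect_variant_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "vcf") return("vcf")
  if (ext == "maf") return("maf")
  head <- readLines(path, n = 200L)
  head <- head[head != ""]
  if (any(grepl("^##fileformat=VCF", head))) return("vcf")
  first_data <- head[!grepl("^##", head)][1L]
  cols <- strsplit(first_data, "\t", fixed = TRUE)[[1]]
  if ("Hugo_Symbol" %in% cols || "Tumor_Seq_Allele2" %in% cols) return("maf")
  if (any(grepl("Uploaded_variation", cols))) return("vep")
  abort("could not infer variant file format for %s; pass format explicitly",
        path)
}

read_vep_table <- function(path, source_format) {
  lines <- readLines(path)
  lines <- lines[!grepl("^##", lines)]
  dt <- data.table::fread(text = paste(lines, collapse = "\n"), sep = "\t",
                          header = TRUE, na.strings = NULL,
                          colClasses = "character")
  data.table::setnames(dt, sub("^#", "", names(dt)))
  required <- c("Uploaded_variation", "Feature", "Consequence")
  missing <- setdiff(required, names(dt))
  if (length(missing) > 0L)
    abort("variant file %s is missing required column(s): %s",
          path, paste(missing, collapse = ", "))
  pp <- parse_protein_position(
    if ("Protein_position" %in% names(dt)) dt$Protein_position else
      rep(NA_character_, nrow(dt)))
  aa <- parse_amino_acids(
    if ("Amino_acids" %in% names(dt)) dt$Amino_acids else
      rep(NA_character_, nrow(dt)))
  known <- c("Uploaded_variation", "Feature", "Consequence",
             "Protein_position", "Amino_acids", "Gene")
  extra_cols <- setdiff(names(dt), known)
  extras <- if (length(extra_cols) == 0L) rep("", nrow(dt)) else
    apply(dt[, extra_cols, with = FALSE], 1L, function(r)
      paste(sprintf("%s=%s", extra_cols, r), collapse = ";"))
  data.table::data.table(
    variant_id = dt$Uploaded_variation,
    transcript_id = dt$Feature,
    transcript_key = strip_version(dt$Feature),
    gene_id = if ("Gene" %in% names(dt)) dt$Gene else NA_character_,
    consequence = dt$Consequence,
    protein_start = pp$start, protein_end = pp$end,
    aa_ref = aa$ref, aa_alt = aa$alt,
    source_format = source_format,
    extras = as.character(extras))
}

read_maf_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = NULL,
                          colClasses = "character", skip = "Hugo_Symbol")
  required <- c("Transcript_ID", "Variant_Classification")
  missing <- setdiff(required, names(dt))
  if (length(missing) > 0L)
    abort("MAF file %s is missing required column(s): %s",
          path, paste(missing, collapse = ", "))
  vid <- if (all(c("Chromosome", "Start_Position", "Reference_Allele",
                   "Tumor_Seq_Allele2") %in% names(dt)))
    paste(dt$Chromosome, dt$Start_Position, dt$Reference_Allele,
          dt$Tumor_Seq_Allele2, sep = "_")
  else paste0("maf_row_", seq_len(nrow(dt)))
  hg <- if ("HGVSp_Short" %in% names(dt)) parse_hgvsp_short(dt$HGVSp_Short)
  else list(ref = rep(NA_character_, nrow(dt)),
            pos = rep(NA_integer_, nrow(dt)),
            alt = rep(NA_character_, nrow(dt)))
  ps <- hg$pos; pe <- hg$pos
  if ("Protein_position" %in% names(dt)) {
    pp <- parse_protein_position(dt$Protein_position)
    use <- is.na(ps) & !is.na(pp$start)
    ps[use] <- pp$start[use]; pe[use] <- pp$end[use]
  }
  data.table::data.table(
    variant_id = vid,
    transcript_id = dt$Transcript_ID,
    transcript_key = strip_version(dt$Transcript_ID),
    gene_id = if ("Gene" %in% names(dt)) dt$Gene else
      (if ("Hugo_Symbol" %in% names(dt)) dt$Hugo_Symbol else NA_character_),
    consequence = dt$Variant_Classification,
    protein_start = ps, protein_end = pe,
    aa_ref = hg$ref, aa_alt = hg$alt,
    source_format = "maf",
    extras = "")
}

read_vcf_table <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  meta <- v@meta
  csq_line <- grep("^##INFO=<ID=(CSQ|ANN),", meta, value = TRUE)
  if (length(csq_line) == 0L)
    abort(paste0("VCF %s has no CSQ/ANN consequence annotation; ",
                 "run the Ensembl Variant Effect Predictor on it first"), path)
  tag <- sub("^##INFO=<ID=([A-Za-z]+),.*$", "\\1", csq_line[1L])
  fmt <- sub('.*Format: ?([^">]+)[">].*', "\\1", csq_line[1L])
  fields <- strsplit(fmt, "|", fixed = TRUE)[[1]]
  fixm <- vcfR::getFIX(v)
  if (is.null(dim(fixm))) fixm <- t(fixm)  # single-record VCF
  fix <- as.data.frame(fixm, stringsAsFactors = FALSE)
  info <- vcfR::extract.info(v, element = tag)
  out <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    if (is.na(info[i])) next
    vid <- paste(fix$CHROM[i], fix$POS[i], fix$REF[i], fix$ALT[i], sep = "_")
    for (tc in strsplit(info[i], ",", fixed = TRUE)[[1]]) {
      vals <- strsplit(tc, "|", fixed = TRUE)[[1]]
      length(vals) <- length(fields)
      rec <- stats::setNames(as.list(vals), fields)
      pp <- parse_protein_position(rec$Protein_position %||% NA_character_)
      aa <- parse_amino_acids(rec$Amino_acids %||% NA_character_)
      out[[i]] <- data.table::rbindlist(list(out[[i]], data.table::data.table(
        variant_id = vid,
        transcript_id = rec$Feature %||% NA_character_,
        transcript_key = strip_version(rec$Feature %||% NA_character_),
        gene_id = rec$Gene %||% NA_character_,
        consequence = rec$Consequence %||% NA_character_,
        protein_start = pp$start, protein_end = pp$end,
        aa_ref = aa$ref, aa_alt = aa$alt,
        source_format = "vcf",
        extras = "")))
    }
  }
  res <- data.table::rbindlist(out)
  if (nrow(res) == 0L) vr_empty() else res
}

`%||%` <- function(a, b) {
  if (is.null(a) || length(a) == 0L || (length(a) == 1L && is.na(a))) b else a
}

#' Parse a variant / annotated-position file into normalized records
#'
#' Supported dialects: Ensembl VEP tabular output (columns located by
#' header name), "VEP-like" files with extra or missing optional columns,
#' MAF (Mutation Annotation Format, using `Transcript_ID` and
#' `HGVSp_Short`-style protein changes such as `p.H86N`), and VCF carrying
#' a VEP `CSQ`/`ANN` annotation field (one record per transcript
#' consequence). A VCF without consequence annotation is rejected: running
#' the predictor is outside this tool.
#'
#' Protein position intervals such as `86-88` are kept as intervals;
#' records lacking a protein position (non-coding consequences) are
#' retained with the position absent. Transcript versions are stripped
#' into `transcript_key` for matching and preserved in `transcript_id`.
#'
#' @param path input file.
#' @param format `"auto"` (default), `"vep"`, `"veplike"`, `"maf"` or
#'   `"vcf"`.
#' @return data.table of variant records (one row per transcript
#'   consequence) with columns `variant_id`, `transcript_id`,
#'   `transcript_key`, `gene_id`, `consequence`, `protein_start`,
#'   `protein_end`, `aa_ref`, `aa_alt`, `source_format`, `extras`.
#' @export
parse_variants <- function(path, format = c("auto", "vep", "veplike", "maf",
                                            "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort("variant file not found: %s", path)
  if (format == "auto") format <- detect_variant_format(path)
  out <- switch(format,
    vep = read_vep_table(path, "vep"),
    veplike = read_vep_table(path, "veplike"),
    maf = read_maf_table(path),
    vcf = read_vcf_table(path))
  data.table::setcolorder(out, .VR_COLUMNS)
  out[]
}

#' Split variant records into one file per transcript
#'
#' Every record is written exactly once to its transcript's file (named by
#' the version-stripped, sanitized transcript accession); records with no
#' transcript go to an `__unassigned__` bucket. A JSON index lists
#' transcript, path and record count; within-file order equals input
#' order.
#'
#' @param records data.table from [parse_variants()].
#' @param outdir output directory.
#' @return invisibly, the index list.
#' @export
split_by_transcript <- function(records, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  records <- data.table::copy(records)
  records[, .bucket__ := transcript_key]
  records[is.na(.bucket__) | .bucket__ == "" | .bucket__ == "-",
          .bucket__ := "__unassigned__"]
  index <- list()
  for (b in sort(unique(records$.bucket__))) {
    sub <- records[.bucket__ == b][, .bucket__ := NULL]
    fn <- paste0(sanitize_id(b), ".tsv")
    data.table::fwrite(sub, file.path(outdir, fn), sep = "\t", quote = FALSE,
                       na = "NA")
    index[[b]] <- list(path = fn, n_records = nrow(sub))
  }
  jsonlite::write_json(index, file.path(outdir, "index.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(index)
}

#' Build a per-transcript variants database from one input file
#'
#' Convenience wrapper: [parse_variants()] then [split_by_transcript()].
#'
#' @inheritParams parse_variants
#' @param outdir output directory.
#' @return invisibly, the index list.
#' @export
make_variants_db <- function(path, outdir, format = "auto") {
  records <- parse_variants(path, format)
  split_by_transcript(records, outdir)
}

#' Read back one per-transcript variants file
#'
#' @param path `.tsv` file written by [split_by_transcript()].
#' @return data.table of variant records.
#' @export
read_variant_file <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(
                            character = c("variant_id", "transcript_id",
                                          "transcript_key", "gene_id",
                                          "consequence", "aa_ref", "aa_alt",
                                          "source_format", "extras"),
                            integer = c("protein_start", "protein_end")),
                          na.strings = "NA")
  dt
}
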