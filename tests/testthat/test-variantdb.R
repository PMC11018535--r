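test_that("VEP tabular rows parse field-by-field as designed", {
  f <- write_lines_tmp(vep_fixture_lines(), ".tsv")
  vr <- parse_variants(f)
  expect_identical(nrow(vr), 3L)

  expect_identical(vr$variant_id, c("rs001", "rs002", "rs003"))
  expect_identical(vr$transcript_id[1], "ENST0001.3")
  expect_identical(vr$transcript_key[1], "ENST0001")  # version stripped
  # "H86N"-style change resolved to (ref H, pos 86, alt N)
  expect_identical(vr$protein_start[1], 86L)
  expect_identical(vr$aa_ref[1], "H")
  expect_identical(vr$aa_alt[1], "N")
  # synonymous single-letter annotation
  expect_identical(vr$aa_ref[2], "E")
  expect_identical(vr$aa_alt[2], "E")
  # "-" protein position is retained with position absent
  expect_true(is.na(vr$protein_start[3]))
  expect_identical(vr$consequence[3], "intron_variant")
})

test_that("interval protein positions are stored as intervals", {
  lines <- vep_fixture_lines()
  lines[3] <- sub("\t86\t", "\t86-88\t", lines[3])
  vr <- parse_variants(write_lines_tmp(lines, ".tsv"))
  expect_identical(vr$protein_start[1], 86L)
  expect_identical(vr$protein_end[1], 88L)
})

test_that("VEP-like files with extra columns parse to the same records", {
  base <- vep_fixture_lines()[-1]  # drop the ## comment
  extra <- c(paste0(base[1], "\tSIFT\tFOO"),
             paste0(base[-1], "\tdeleterious\tbar"))
  v1 <- parse_variants(write_lines_tmp(base, ".tsv"), format = "vep")
  v2 <- parse_variants(write_lines_tmp(extra, ".tsv"), format = "veplike")
  shared <- setdiff(names(v1), c("source_format", "extras"))
  expect_identical(v1[, shared, with = FALSE], v2[, shared, with = FALSE])
  expect_match(v2$extras[1], "SIFT=deleterious")
})

test_that("missing required VEP columns are fatal and name the column", {
  lines <- c("#Uploaded_variation\tConsequence", "rs1\tmissense_variant")
  expect_error(parse_variants(write_lines_tmp(lines, ".tsv"), format = "vep"),
               "Feature")
})

test_that("MAF rows parse through HGVSp short notation", {
  vr <- parse_variants(write_lines_tmp(maf_fixture_lines(), ".maf"))
  expect_identical(vr$source_format, c("maf", "maf"))
  expect_identical(vr$variant_id[1], "7_152649_C_A")
  expect_identical(vr$transcript_key[1], "ENST0003")
  expect_identical(vr$protein_start[1], 86L)
  expect_identical(vr$aa_ref[1], "H")
  expect_identical(vr$aa_alt[1], "N")
  expect_identical(vr$consequence[1], "Missense_Mutation")
})

test_that("VCF with CSQ yields one record per transcript consequence", {
  vr <- parse_variants(write_lines_tmp(vcf_fixture_lines(), ".vcf"))
  expect_identical(nrow(vr), 2L)
  expect_identical(vr$variant_id, rep("1_1009_A_T", 2))
  expect_identical(vr$transcript_key, c("ENST_A", "ENST_Z"))
  expect_identical(vr$protein_start[1], 3L)
  expect_identical(vr$aa_ref[1], "P")
  expect_true(is.na(vr$protein_start[2]))
})

test_that("VCF without consequence annotation is rejected", {
  lines <- c("##fileformat=VCFv4.2",
             paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", sep = "\t"),
             paste("1", "1009", ".", "A", "T", ".", ".", "DP=10", sep = "\t"))
  expect_error(parse_variants(write_lines_tmp(lines, ".vcf")),
               "Variant Effect Predictor")
})

test_that("transcript splitting conserves every record exactly once", {
  lines <- c(vep_fixture_lines(),
             paste("rs004", "1:3000", "N", "GENE2", "ENST0004", "Transcript",
                   "missense_variant", "12", "A/V", sep = "\t"),
             # same variant annotated on a second transcript
             paste("rs001", "1:1258", "N", "GENE1", "ENST0004", "Transcript",
                   "missense_variant", "30", "H/N", sep = "\t"))
  vr <- parse_variants(write_lines_tmp(lines, ".tsv"))
  out <- tempfile("vardb")
  idx <- split_by_transcript(vr, out)
  counts <- vapply(idx, `[[`, 0L, "n_records")
  expect_identical(sum(counts), nrow(vr))
  # the doubly-annotated variant appears in both transcript files
  t1 <- read_variant_file(file.path(out, idx[["ENST0001"]]$path))
  t4 <- read_variant_file(file.path(out, idx[["ENST0004"]]$path))
  expect_true("rs001" %in% t1$variant_id && "rs001" %in% t4$variant_id)
  # within-file order equals input order
  expect_identical(t4$variant_id, c("rs004", "rs001"))
})

test_that("splitting an empty record set writes an empty index", {
  vr <- parse_variants(write_lines_tmp(vep_fixture_lines()[1:2], ".tsv"))
  expect_identical(nrow(vr), 0L)
  out <- tempfile("empty")
  idx <- split_by_transcript(vr, out)
  expect_identical(length(idx), 0L)
  expect_identical(list.files(out), "index.json")
})
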