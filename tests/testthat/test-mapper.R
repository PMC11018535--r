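test_that("the mixed 5-variant fixture yields the designed class histogram", {
  fx <- get_demo()
  mapped <- map_variants(fx$protdb, fx$vardb, fx$id_map)
  smry <- summarize_mapped(mapped)

  # conservation: every input variant appears in the output
  expect_identical(sort(unique(mapped$variant_id)), sort(fx$expected$variant_id))
  got <- merge(smry, fx$expected, by = "variant_id")
  expect_identical(got$best_class, got$expected_class)
  hist_got <- table(factor(got$best_class,
                           c("interface", "structure", "unmapped", "non-coding")))
  expect_identical(as.integer(hist_got), c(2L, 1L, 1L, 1L))
  # one class per row, and the definitional relationships hold
  expect_true(all(mapped$class %in% c("interface", "structure", "unmapped",
                                      "non-coding")))
  expect_identical(mapped$class == "non-coding", is.na(mapped$protein_pos))
  covered <- mapped[!is.na(structure_id)]
  expect_identical(covered$class == "interface",
                   covered$interface_flags != "")
})

test_that("mapping equals an independent cross-join on the fixture", {
  fx <- get_demo()
  mapped <- map_variants(fx$protdb, fx$vardb, fx$id_map)
  # naive oracle: full variant x annotation-row join filtered by
  # transcript->protein identity and position containment
  vr <- read_variant_file(file.path(fx$vardb, "ENST_A.tsv"))
  db <- read_structural_db(file.path(fx$protdb, "query_A.tsv"))
  naive <- 0L
  for (i in seq_len(nrow(vr))) {
    if (is.na(vr$protein_start[i])) next
    for (j in seq_len(nrow(db))) {
      if (db$protein_pos[j] >= vr$protein_start[i] &&
          db$protein_pos[j] <= vr$protein_end[i]) naive <- naive + 1L
    }
  }
  expect_identical(nrow(mapped[!is.na(structure_id)]), naive)
})

test_that("class counts are invariant to input file order", {
  fx <- get_demo()
  base <- map_variants(fx$protdb, fx$vardb, fx$id_map)
  # rewrite the variant db from a shuffled input file
  lines <- readLines(fx$variants)
  shuf <- c(lines[1], lines[c(5, 3, 6, 2, 4)])
  dir2 <- tempfile("shuffled")
  make_variants_db(write_lines_tmp(shuf, ".tsv"), dir2)
  again <- map_variants(fx$protdb, dir2, fx$id_map)
  expect_identical(table(base$class), table(again$class))
  expect_identical(summarize_mapped(base)[order(variant_id)]$best_class,
                   summarize_mapped(again)[order(variant_id)]$best_class)
})

test_that("interval variants expand to one row per covered position", {
  fx <- get_demo()
  lines <- readLines(fx$variants)
  lines[2] <- sub("\t3\t", "\t3-6\t", lines[2])
  dir2 <- tempfile("iv")
  make_variants_db(write_lines_tmp(lines, ".tsv"), dir2)
  mapped <- map_variants(fx$protdb, dir2, fx$id_map)
  v1 <- mapped[variant_id == "var_01"]
  expect_identical(sort(v1$protein_pos), 3:6)
})

test_that("transcripts absent from the ID map surface as unmapped with a reason", {
  fx <- get_demo()
  idmap <- fx$id_map[transcript_id != "ENST_A"]
  mapped <- map_variants(fx$protdb, fx$vardb, idmap)
  coding <- mapped[!is.na(protein_pos)]
  expect_true(all(coding$class == "unmapped"))
  expect_true(all(coding$reason == "transcript_not_in_idmap"))
  # non-coding rows keep their class regardless of the map
  expect_identical(mapped[is.na(protein_pos)]$class, "non-coding")
})

test_that("reference-allele mismatches are flagged, not dropped", {
  fx <- get_demo()
  lines <- readLines(fx$variants)
  # overwrite the reference amino acid of the first variant with W
  f <- strsplit(lines[2], "\t")[[1]]
  f[9] <- "W/Q"
  lines[2] <- paste(f, collapse = "\t")
  truth_aa <- substr(fx$truth$chains$A$query_seq, 3, 3)
  dir2 <- tempfile("mm")
  make_variants_db(write_lines_tmp(lines, ".tsv"), dir2)
  mapped <- map_variants(fx$protdb, dir2, fx$id_map)
  v1 <- mapped[variant_id == "var_01"]
  expect_identical(nrow(v1), 1L)  # still mapped
  expect_identical(unique(v1$ref_mismatch), truth_aa != "W")
})

test_that("the pDockQ filter excludes models at 0.20 and keeps 0.30", {
  fx <- get_demo()
  low <- data.table::data.table(structure_id = "demo_complex", pdockq = 0.20)
  high <- data.table::data.table(structure_id = "demo_complex", pdockq = 0.30)

  m_low <- map_variants(fx$protdb, fx$vardb, fx$id_map, pdockq = low)
  m_high <- map_variants(fx$protdb, fx$vardb, fx$id_map, pdockq = high)
  # at 0.20 every structural row is gone: coding variants become unmapped
  expect_identical(nrow(m_low[!is.na(structure_id)]), 0L)
  expect_true(all(m_low[!is.na(protein_pos)]$class == "unmapped"))
  # at 0.30 the mapping is unchanged relative to no filter
  base <- map_variants(fx$protdb, fx$vardb, fx$id_map)
  expect_equal(m_high, base)
  # unscored structures pass through untouched
  other <- data.table::data.table(structure_id = "some_other_model",
                                  pdockq = 0.10)
  expect_equal(map_variants(fx$protdb, fx$vardb, fx$id_map, pdockq = other),
               base)
})

test_that("quality and consequence filters restrict rows as configured", {
  fx <- get_demo()
  base <- map_variants(fx$protdb, fx$vardb, fx$id_map)
  hi <- map_variants(fx$protdb, fx$vardb, fx$id_map, min_pident = 100)
  expect_identical(nrow(hi), nrow(base))  # demo alignments are exact
  none <- map_variants(fx$protdb, fx$vardb, fx$id_map, min_pident = 100.5)
  expect_identical(nrow(none[!is.na(structure_id)]), 0L)
  plddt <- map_variants(fx$protdb, fx$vardb, fx$id_map, min_plddt = 60)
  expect_identical(nrow(plddt[!is.na(structure_id)]), 0L)  # fixture pLDDT 50
  mis <- map_variants(fx$protdb, fx$vardb, fx$id_map,
                      consequences = "missense_variant")
  expect_false("intron_variant" %in% mis$consequence)
})

test_that("CSV and Parquet outputs carry identical row multisets", {
  fx <- get_demo()
  mapped <- map_variants(fx$protdb, fx$vardb, fx$id_map)
  out <- tempfile("out")
  p <- write_outputs(mapped, out, format = c("csv", "parquet"),
                     setid_grouping = "per-interface")
  csv <- read_mapped(p$csv)
  pq <- read_mapped(p$parquet)
  data.table::setorderv(csv, names(csv), na.last = TRUE)
  data.table::setorderv(pq, names(pq), na.last = TRUE)
  expect_equal(as.data.frame(csv), as.data.frame(pq), tolerance = 1e-12)
})

test_that("SetID groupings produce the designed sets", {
  fx <- get_demo()
  mapped <- map_variants(fx$protdb, fx$vardb, fx$id_map)
  out <- tempfile("setid")
  p <- write_outputs(mapped, out, setid_grouping = "per-interface")
  setid <- read.table(p$setid, col.names = c("set_id", "variant_id"))
  # one set per (protein, partner entity) holding its interface variants
  expect_identical(unique(setid$set_id), "query_A_B")
  expect_identical(sort(setid$variant_id), c("var_01", "var_02"))
  p2 <- write_outputs(mapped, out, setid_grouping = "per-class",
                      basename = "byclass")
  s2 <- read.table(p2$setid, col.names = c("set_id", "variant_id"))
  expect_identical(sort(unique(s2$set_id)),
                   c("query_A_interface", "query_A_structure"))
  # (set, variant) pairs are unique
  expect_false(any(duplicated(s2)))
})

test_that("empty mapped tables write header-only CSV and empty SetID", {
  out <- tempfile("emptyout")
  p <- write_outputs(struct3dmap:::mapped_empty(), out,
                     setid_grouping = "per-protein")
  expect_identical(length(readLines(p$setid)), 0L)
  csv <- readLines(p$csv)
  expect_identical(length(csv), 1L)
  expect_match(csv, "variant_id")
  expect_error(write_outputs(struct3dmap:::mapped_empty(), out,
                             format = "xlsx"), "unknown output format")
})
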