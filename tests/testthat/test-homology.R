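test_that("self-alignment of an identical 30-mer is the identity map at Pident 100", {
  set.seed(11)
  q <- random_seq(30)
  al <- local_align(q, q)
  expect_equal(al$pident, 100)
  expect_identical(al$n_identical, 30L)
  expect_identical(al$aln_len, 30L)
  expect_identical(al$colmap$qpos, 1:30)
  expect_identical(al$colmap$spos, 1:30)
  expect_lt(al$evalue, 1e-5)
})

test_that("alignment scores match the exhaustive oracle on random pairs", {
  set.seed(101)
  mat <- substitution_matrix("BLOSUM62")
  for (i in 1:60) {
    q <- random_seq(sample(3:12, 1))
    s <- random_seq(sample(3:12, 1))
    al <- local_align(q, s)
    expect_equal(al$score, sw_oracle_score(q, s, mat),
                 info = sprintf("pair %s / %s", q, s))
  }
})

test_that("identity counting is symmetric and X never counts as identical", {
  set.seed(12)
  for (i in 1:20) {
    q <- random_seq(sample(8:20, 1))
    s <- random_seq(sample(8:20, 1))
    expect_identical(local_align(q, s)$n_identical,
                     local_align(s, q)$n_identical)
  }
  al <- local_align("AAXAAWWWW", "AAXAAWWWW")
  expect_identical(al$n_identical, 8L)  # the X-X column is not an identity
  expect_lt(al$pident, 100)
})

test_that("alphabet violations are rejected naming the offending symbol", {
  expect_error(local_align("ACDB1", "ACD"), "B, 1")
  expect_error(local_align("ACD", "ac"), "a")
  expect_error(local_align("", "ACD"), "empty")
})

test_that("threshold filtering is inclusive at both boundaries", {
  mk <- function(pident, evalue) {
    structure(list(pident = pident, evalue = evalue), class = "ChainAlignment")
  }
  alns <- list(mk(100, 0), mk(50.0, 1e-5), mk(49.9, 1e-10),
               mk(80, 1e-3), mk(50.0, 1.0000001e-5))
  kept <- filter_alignments(alns, pident_min = 50, evalue_max = 1e-5)
  expect_identical(vapply(kept, `[[`, 0, "pident"), c(100, 50))
  # order preserved; raising the cutoff is monotone non-increasing
  for (p in c(0, 30, 50, 70, 90, 100.0001)) {
    n1 <- length(filter_alignments(alns, p, 1e-5))
    n2 <- length(filter_alignments(alns, p + 5, 1e-5))
    expect_lte(n2, n1)
  }
})

test_that("position maps land on author numbering, skipping gap columns", {
  spec <- fixture_spec(
    structure_id = "posmap",
    chains = list(list(id = "A", n_res = 10L,
                       resnums = c(5L, 6L, 7L, 7L, 8L, 10L, 14L, 15L, 16L, 17L),
                       icodes = c("", "", "", "A", "", "", "", "", "", ""))),
    seed = 5L)
  fx <- make_structure_fixture(spec, tempfile("pm"))
  m <- parse_structure(fx$paths$pdb)
  cs <- extract_sequence(m, "A")
  al <- local_align(fx$truth$chains$A$query_seq, cs$seq, query_id = "query_A",
                    structure_id = "posmap", chain_id = "A")
  pm <- build_position_map(al, cs)

  expect_identical(pm$query_pos, 1:10)
  expect_identical(pm$resnum[1], 5L)          # numbering starts at 5
  expect_identical(pm$resnum[4], 7L)          # insertion code residue
  expect_identical(pm$icode[4], "A")
  expect_identical(pm$resnum[5:7], c(8L, 10L, 14L))  # author gaps preserved
  expect_true(all(pm$is_identity))
  # every entry resolves in the parsed structure
  found <- merge(pm, m$residues, by.x = c("chain_id", "resnum", "icode"),
                 by.y = c("chain", "resnum", "icode"))
  expect_identical(nrow(found), nrow(pm))
})

test_that("query insertions produce no structural image", {
  # query has 4 extra residues in the middle relative to the subject
  sub <- "WWWCCWWWHHKKWWW"
  qry <- paste0(substr(sub, 1, 8), "MNPQ", substr(sub, 9, 15))
  al <- local_align(qry, sub)
  gap_cols <- al$colmap[is.na(spos)]
  expect_identical(nrow(gap_cols), 4L)
  cs <- list(map = data.table::data.table(
    seqpos = 1:15, chain = "A", resnum = 1:15, icode = "",
    one_letter = strsplit(sub, "")[[1]], bfactor = 50))
  pm <- build_position_map(al, cs)
  expect_false(any(gap_cols$qpos %in% pm$query_pos))
  expect_identical(nrow(pm), 15L)
})

test_that("subject positions beyond the chain raise a consistency error", {
  al <- local_align("WWCCWW", "WWCCWW")
  short <- list(map = data.table::data.table(
    seqpos = 1:3, chain = "A", resnum = 1:3, icode = "",
    one_letter = c("W", "W", "C"), bfactor = 0))
  expect_error(build_position_map(al, short), "mismatch")
})

test_that("e-values scale with the pairwise search space", {
  set.seed(21)
  q <- random_seq(25)
  a1 <- local_align(q, q)
  a2 <- local_align(paste0(q, random_seq(50)), q)
  expect_gt(a2$evalue, a1$evalue)  # same raw score region, larger m.n
  expect_equal(a1$bitscore,
               (0.267 * a1$score - log(0.041)) / log(2), tolerance = 1e-10)
})
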