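test_that("two parallel peptides 4 A apart contact at cutoff 5 but not 3", {
  spec <- fixture_spec(
    structure_id = "pair",
    chains = list(list(id = "A", n_res = 3L), list(id = "B", n_res = 3L)),
    chain_sep = 4.0, seed = 9L)
  fx <- make_structure_fixture(spec, tempfile("pair"))
  m <- parse_structure(fx$paths$pdb)

  at5 <- compute_interfaces(m, 5)
  expect_identical(nrow(unique(at5[, .(chain_id, resnum)])), 6L)
  expect_true(all(at5$partner_type == "protein"))
  expect_true(all(at5$min_distance <= 5))
  at3 <- compute_interfaces(m, 3)
  expect_identical(nrow(at3), 0L)
})

test_that("single-chain structures yield no interfaces", {
  spec <- fixture_spec(structure_id = "solo",
                       chains = list(list(id = "A", n_res = 6L)), seed = 2L)
  fx <- make_structure_fixture(spec, tempfile("solo"))
  expect_identical(nrow(compute_interfaces(parse_structure(fx$paths$pdb))), 0L)
})

test_that("each ligand copy is a distinct interface; waters never partner", {
  m <- parse_structure(corner_case_pdb())
  rec <- compute_interfaces(m, 5)
  lig <- rec[partner_type == "ligand"]
  expect_identical(sort(unique(lig$partner_entity)),
                   c("A_HEM_101", "A_HEM_102"))
  expect_identical(length(unique(lig$interface_id)), 2L)
  expect_false(any(grepl("HOH", rec$partner_entity)))
  # the water sits 1.5 A from ALA 5 yet produces no record
  expect_false(any(rec$partner_type == "water"))
})

test_that("interface detection equals the brute-force all-pairs scan", {
  set.seed(31)
  for (i in 1:8) {
    n1 <- sample(4:9, 1); n2 <- sample(4:9, 1)
    sep <- runif(1, 3.2, 7.5)
    spec <- fixture_spec(
      structure_id = sprintf("rnd%02d", i),
      chains = list(list(id = "A", n_res = n1), list(id = "B", n_res = n2)),
      chain_sep = sep,
      ligands = list(list(name = "ZN", chain = "C", resnum = 1L,
                          x = runif(1, 0, 10), y = runif(1, 0, 10), z = 0)),
      seed = i)
    fx <- make_structure_fixture(spec, tempfile(spec$structure_id))
    m <- parse_structure(fx$paths$pdb)
    prev <- NULL
    for (cutoff in c(3, 4, 5, 8)) {
      got <- compute_interfaces(m, cutoff)
      want <- brute_force_interfaces(m, cutoff)
      expect_identical(iface_key(got), iface_key(want),
                       info = sprintf("fixture %d cutoff %g", i, cutoff))
      # monotone in cutoff: smaller-cutoff set is a subset
      if (!is.null(prev) && nrow(prev) > 0L) {
        expect_identical(
          nrow(data.table::fintersect(
            got[, .(chain_id, resnum, icode, partner_entity)],
            prev[, .(chain_id, resnum, icode, partner_entity)])),
          nrow(unique(prev[, .(chain_id, resnum, icode, partner_entity)])))
      }
      prev <- got
      # protein-protein symmetry
      ab <- got[chain_id == "A" & partner_entity == "B"]
      ba <- got[chain_id == "B" & partner_entity == "A"]
      expect_identical(nrow(ab) > 0L, nrow(ba) > 0L)
    }
  }
})

test_that("interface dedup drops sub-floor records and keeps the best structure per type", {
  rec <- data.table::data.table(
    query_id = "q1",
    structure_id = c("s2", "s2", "s1", "s1", "s3", "s0"),
    partner_type = c("protein", "protein", "protein", "ligand", "ligand",
                     "protein"),
    partner_entity = c("B", "B", "B", "L_HEM_1", "L_ZN_1", "B"),
    resnum = c(1L, 2L, 1L, 3L, 4L, 1L),
    pident = c(95, 95, 85, 92, 88, 79.9))

  out <- deduplicate_interfaces(rec, pident_floor = 80)
  # 79.9 dropped (strictly below floor); 80.0 would be kept
  expect_false("s0" %in% out$structure_id)
  boundary <- deduplicate_interfaces(
    data.table::data.table(query_id = "q", structure_id = "s",
                           partner_type = "protein", pident = 80.0),
    pident_floor = 80)
  expect_identical(nrow(boundary), 1L)

  # protein interfaces come only from the 95-Pident structure
  expect_identical(unique(out[partner_type == "protein"]$structure_id), "s2")
  # ligand interfaces come from their own best structure: s1 at 92
  expect_identical(unique(out[partner_type == "ligand"]$structure_id), "s1")
  # idempotent
  expect_identical(deduplicate_interfaces(out, 80), out)
})

test_that("dedup ties break to the lexicographically smallest structure", {
  rec <- data.table::data.table(
    query_id = "q1", structure_id = c("sB", "sA"),
    partner_type = "protein", partner_entity = "B",
    resnum = 1L, pident = c(90, 90))
  out <- deduplicate_interfaces(rec, 80)
  expect_identical(unique(out$structure_id), "sA")
})
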