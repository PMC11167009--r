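test_that("parsing yields sanitized graphs and rejects illegal input", {
  m <- parse_molecule("CCO")
  expect_s3_class(m, "mol_graph")
  expect_equal(nrow(m$atoms), 3L)
  expect_equal(nrow(m$bonds), 2L)
  expect_true(all(m$bonds$order == 1L))

  benz <- parse_molecule("c1ccccc1")
  expect_equal(nrow(benz$atoms), 6L)
  expect_equal(nrow(benz$bonds), 6L)
  expect_true(all(benz$atoms$aromatic))

  expect_error(parse_molecule("CO=CC"), class = "ts_valence_error")
  expect_error(parse_molecule("[CH5]"), class = "ts_valence_error")
  expect_error(parse_molecule("F=F"), class = "ts_valence_error")
  expect_error(parse_molecule("C((C"), class = "ts_parse_error")
  expect_error(parse_molecule("xyz"), class = "ts_parse_error")
  expect_error(parse_molecule(""), class = "ts_parse_error")
})

test_that("canonical writing is input-order independent and idempotent", {
  expect_identical(write_canonical(parse_molecule("OCC")),
                   write_canonical(parse_molecule("CCO")))
  expect_identical(write_canonical(parse_molecule("c1ccccc1")),
                   write_canonical(parse_molecule("C1=CC=CC=C1")))
  for (s in fixture_smiles_small()[1:15]) {
    can <- write_canonical(parse_molecule(s))
    expect_identical(write_canonical(parse_molecule(can)), can)
  }
})

test_that("multi-component input keeps the largest covalent part", {
  expect_warning(m <- parse_molecule("CCCCCC.O"), "multi-component")
  expect_identical(write_canonical(m), "CCCCCC")
})

test_that("molecules_equal agrees with a graph-isomorphism oracle", {
  small <- c("CCO", "OCC", "C(O)C", "CCN", "c1ccccc1", "C1=CC=CC=C1",
             "CC(C)O", "COC", "c1ccncc1", "c1ccccn1", "CC(=O)O", "OC(C)=O")
  mols <- lapply(small, parse_molecule)
  for (a in seq_along(small)) {
    for (b in seq_along(small)) {
      expect_identical(
        molecules_equal(mols[[a]], mols[[b]]),
        as.logical(graphs_isomorphic(mols[[a]], mols[[b]])),
        info = paste(small[[a]], "vs", small[[b]])
      )
    }
  }
})

test_that("molecule equality is an equivalence relation on fixtures", {
  ms <- fixture_smiles_small()[1:10]
  for (s in ms) expect_true(molecules_equal(s, s))
  # symmetry/transitivity via canonical representatives
  cans <- vapply(ms, canon1, character(1))
  for (a in 1:5) {
    for (b in 1:5) {
      expect_identical(molecules_equal(ms[[a]], ms[[b]]),
                       molecules_equal(ms[[b]], ms[[a]]))
      expect_identical(molecules_equal(ms[[a]], ms[[b]]),
                       cans[[a]] == cans[[b]])
    }
  }
})

test_that(".smi files round-trip and skip bad lines", {
  tmp <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO ethanol", "not_a_smiles", "c1ccccc1 benzene"), tmp)
  expect_message(tab <- read_smi(tmp), "skipped")
  expect_equal(nrow(tab), 2L)
  expect_identical(tab$name, c("ethanol", "benzene"))
  out <- withr::local_tempfile(fileext = ".smi")
  write_smi(tab, out)
  tab2 <- read_smi(out)
  expect_identical(tab2$smiles, tab$smiles)
})
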