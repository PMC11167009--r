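# RDKit BRICS reference multisets (computed once with the published BRICS
# rules in an independent toolkit and frozen; dummy labels stripped).
brics_reference <- list(
  list(smiles = "CC(=O)Oc1ccccc1C(=O)O",
       frags = c("*C(=O)O", "*C(C)=O", "*O*", "*c1ccccc1*")),
  list(smiles = "CCN(CC)C(=O)Cc1ccccc1",
       frags = c("*C(=O)C*", "*CC", "*CC", "*N(*)*", "*c1ccccc1")),
  list(smiles = "CC(C)Cc1ccc(C(C)C(=O)O)cc1",
       frags = c("*C(C)C(=O)O", "*CC(C)C", "*c1ccc(*)cc1")),
  list(smiles = "COc1ccc2cc(C(C)C(=O)O)ccc2c1",
       frags = c("*C(C)C(=O)O", "*OC", "*c1ccc2cc(*)ccc2c1")),
  list(smiles = CELECOXIB,
       frags = c("*C(F)(F)F", "*c1ccc(C)cc1", "*c1ccc(S(N)(=O)=O)cc1",
                 "*n1nc(*)cc1*")),
  list(smiles = "CN(C)CCOC(c1ccccc1)c1ccccc1",
       frags = c("*C(*)*", "*CC*", "*N(C)C", "*O*", "*c1ccccc1", "*c1ccccc1"))
)

test_that("matched-molecular-pair cuts reproduce the published worked example", {
  cel <- parse_molecule(CELECOXIB)
  cuts <- find_cut_bonds(cel, "mmpa")
  expect_equal(nrow(cuts), 6L)
  expect_identical(cuts$cut_id, 1:6)
  fs <- fragment_molecule(cel, "mmpa", "tsid")
  expect_length(fs$fragments, 7L)
  printed <- celecoxib_case()
  expect_identical(fragset_multiset(fs), printed$fragment_multiset)
})

test_that("BRICS cuts match the independent reference multisets", {
  for (case in brics_reference) {
    fs <- fragment_molecule(parse_molecule(case$smiles), "brics", "tsdy")
    expect_identical(fragset_multiset(fs), smiles_multiset(case$frags),
                     info = case$smiles)
  }
})

test_that("scaffold cuts separate side chains and linkers from rings", {
  tol <- parse_molecule("Cc1ccccc1")
  cuts <- find_cut_bonds(tol, "scaffold")
  expect_equal(nrow(cuts), 1L)
  # ring-linker-ring: both ring attachments of the CH2 linker are cut
  dppm <- parse_molecule("c1ccccc1Cc1ccccc1")
  expect_equal(nrow(find_cut_bonds(dppm, "scaffold")), 2L)
  expect_equal(nrow(find_cut_bonds(parse_molecule("C"), "mmpa")), 0L)
  expect_warning(
    fs <- fragment_molecule(parse_molecule("CCCCO"), "scaffold", "tsdy"),
    "no ring scaffold"
  )
  expect_length(fs$fragments, 1L)
})

test_that("fragment sets satisfy the tree law and atom conservation", {
  for (s in fixture_smiles_small()[1:12]) {
    mol <- parse_molecule(s)
    for (scheme in c("brics", "mmpa", "scaffold")) {
      for (style in c("tsdy", "tsid")) {
        fs <- suppressWarnings(fragment_molecule(mol, scheme, style))
        expect_length(fs$fragments, nrow(fs$cuts) + 1L)
        expect_equal(nrow(fs$adjacency), length(fs$fragments) - 1L)
        heavy <- sum(vapply(fs$fragments, function(f) {
          nrow(f$graph$atoms)  # dummies included
        }, integer(1)))
        expect_equal(heavy - 2L * nrow(fs$cuts), mg_n_heavy(mol))
        # an ID appears on exactly two attachment points across the set
        if (style == "tsid" && nrow(fs$cuts)) {
          ids <- unlist(lapply(fs$fragments, function(f) f$attach$cut_id))
          expect_true(all(table(ids) == 2L))
        }
      }
    }
  }
})

test_that("re-fragmenting the canonical form gives the same multiset", {
  for (s in fixture_smiles_small()[1:8]) {
    a <- fragment_molecule(parse_molecule(s), "mmpa", "tsdy")
    b <- fragment_molecule(parse_molecule(canon1(s)), "mmpa", "tsdy")
    expect_identical(fragset_multiset(a), fragset_multiset(b), info = s)
  }
})

test_that("shared-atom style adds one connector per cut", {
  cel <- parse_molecule(CELECOXIB)
  fs <- fragment_molecule(cel, "mmpa", "tssa")
  conn <- vapply(fs$fragments, function(f) f$role == "connector", logical(1))
  expect_equal(sum(conn), nrow(fs$cuts))
  expect_true(all(vapply(fs$fragments[conn], function(f) {
    nrow(f$graph$atoms) == 2L
  }, logical(1))))
  # every adjacency record references a shared atom on both sides
  expect_true(all(fs$adjacency$kind == "shared"))
})

test_that("junction clusters cover the molecule and form a tree", {
  cel <- parse_molecule(CELECOXIB)
  fs <- fragment_molecule(cel, "junction", "tssa")
  covered <- sort(unique(unlist(lapply(fs$fragments, function(f) f$src_atoms))))
  expect_identical(covered, seq_len(nrow(cel$atoms)))
  expect_equal(nrow(fs$adjacency), length(fs$fragments) - 1L)
  amt <- build_amt(fs)
  expect_s3_class(amt, "ts_amt")
})

test_that("trees root deterministically and enumerate one root per fragment", {
  cel <- parse_molecule(CELECOXIB)
  fs <- fragment_molecule(cel, "mmpa", "tsid")
  amt <- build_amt(fs)
  # pyrazole core carries two branches in the printed decomposition
  n_children <- lengths(amt$children)
  pyrazole <- which(vapply(fs$fragments, function(f) {
    grepl("n", f$smiles) || grepl("N", f$smiles)
  }, logical(1)) & vapply(fs$fragments, function(f) {
    nrow(f$attach) == 3L
  }, logical(1)))
  expect_equal(n_children[[pyrazole]], 2L)
  amts <- enumerate_roots(fs)
  expect_length(amts, 7L)
  expect_identical(vapply(amts, function(a) a$root, integer(1)), 1:7)
  # single fragment -> single-node tree
  one <- build_amt(fragment_molecule(parse_molecule("C"), "mmpa", "tsdy"))
  expect_length(one$nodes, 1L)
  expect_equal(lengths(one$children), 0L)
  # a 3-fragment chain: root has one child, depth two
  chain <- build_amt(fragment_molecule(parse_molecule("CCCCCCCCCC"), "mmpa", "tsdy"))
  expect_gte(length(chain$nodes), 3L)
  expect_equal(length(chain$children[[chain$root]]), 1L)
})
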