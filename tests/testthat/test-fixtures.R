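test_that("fixture generation is deterministic and chemically sound", {
  a <- generate_fixture_molecules(25, seed = 7)
  b <- generate_fixture_molecules(25, seed = 7)
  expect_identical(a, b)
  expect_identical(generate_fixture_molecules(1, seed = 7)$smiles[[1]],
                   a$smiles[[1]])
  ok <- vapply(a$smiles, function(s) {
    !inherits(tryCatch(parse_molecule(s), error = function(e) e), "error")
  }, logical(1))
  expect_true(all(ok))
  c <- generate_fixture_molecules(25, seed = 8)
  expect_false(identical(a$smiles, c$smiles))
})

test_that("most fixtures carry at least one eligible matched-pair bond", {
  fx <- generate_fixture_molecules(60, seed = 5)
  n_cuts <- vapply(fx$smiles, function(s) {
    nrow(find_cut_bonds(parse_molecule(s), "mmpa"))
  }, integer(1))
  expect_gte(mean(n_cuts >= 1L), 0.9)
})

test_that("the embedded worked example is internally consistent", {
  cel <- celecoxib_case()
  expect_length(cel$tsid_fragments, 7L)
  expect_length(cel$fragment_multiset, 7L)
  # the unlabelled code is the labelled code with IDs removed
  expect_identical(gsub("\\[[0-9]+\\*\\]", "*", cel$tsid), cel$tsdy)
  # labelled and unlabelled fragment multisets coincide after stripping
  tsdy_frags <- ts_tokenize(cel$tsdy)
  tsdy_frags <- tsdy_frags$token[tsdy_frags$type == "FRAG"]
  expect_identical(smiles_multiset(tsdy_frags), cel$fragment_multiset)
  # and the package's own encoder reproduces that multiset
  fs <- fragment_molecule(parse_molecule(cel$smiles), "mmpa", "tsid")
  expect_identical(fragset_multiset(fs), cel$fragment_multiset)
})

test_that("random well-formed trees decode to valid molecules", {
  pool <- tsmiles:::harvest_fragment_pool(fixture_smiles_small()[1:10],
                                          "mmpa", "tsdy")
  expect_gte(length(pool), 20L)
  ok <- vapply(1:40, function(k) {
    amt <- tsmiles:::with_local_seed(500L + k, {
      tsmiles:::compose_random_tree(pool, max_frags = 5L)
    })
    res <- ts_decode(ts_serialize(amt_to_fbt(amt)), "tsdy",
                     assembly_selector("random", seed = k))
    res$valid
  }, logical(1))
  expect_true(all(ok))
})
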