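test_that("ID-labelled encode/decode is the identity on all four schemes", {
  for (s in c(CELECOXIB, fixture_smiles_small()[1:8])) {
    mol <- parse_molecule(s)
    for (scheme in c("junction", "brics", "mmpa", "scaffold")) {
      code <- suppressWarnings(encode_molecule(mol, scheme, "tsid"))
      res <- ts_decode(code, "tsid")
      expect_true(res$valid, info = paste(scheme, s))
      expect_true(molecules_equal(res$mol, mol), info = paste(scheme, s))
    }
  }
})

test_that("record-guided assembly reconstructs the source exactly", {
  for (s in c(CELECOXIB, fixture_smiles_small()[1:6])) {
    mol <- parse_molecule(s)
    for (scheme in c("junction", "brics", "mmpa", "scaffold")) {
      for (style in c("tsdy", "tssa")) {
        fs <- suppressWarnings(fragment_molecule(mol, scheme, style))
        res <- assemble(build_amt(fs), assembly_selector("record"))
        expect_true(res$valid, info = paste(scheme, style, s))
        expect_true(molecules_equal(res$mol, mol),
                    info = paste(scheme, style, s))
      }
    }
  }
})

test_that("the published worked-example string decodes to the drug", {
  cel <- celecoxib_case()
  res <- ts_decode(cel$tsid, "tsid")
  expect_true(res$valid)
  expect_true(molecules_equal(res$mol, parse_molecule(cel$smiles)))
  hits <- tsmiles:::ob_smarts_matches(
    tsmiles:::mg_to_molblock(res$mol),
    list("c1cc[nH0]n1", "C(F)(F)F", "S(=O)(=O)N")
  )
  expect_true(all(lengths(hits) > 0))
  # removing the IDs gives the unlabelled code of the same tree
  expect_identical(gsub("\\[[0-9]+\\*\\]", "*", cel$tsid), cel$tsdy)
})

test_that("join_pair enumerates the expected candidates per style", {
  # ID-forced: unique candidate
  cand <- join_pair("[1*]C", "[1*]c1ccccc1", "tsid")
  expect_length(cand, 1L)
  expect_identical(write_canonical(cand[[1]]), canon1("Cc1ccccc1"))
  # unlabelled dummies: one candidate per distinguishable pairing
  cand2 <- join_pair("*C", "*c1ccc(CC)c(*)c1", "tsdy")
  expect_length(cand2, 2L)
  expect_true(all(vapply(cand2, function(g) {
    length(tsmiles:::mg_dummy_atoms(g)) == 1L
  }, logical(1))))
  # shared atom: superpositions onto ring carbons all sanitize
  cand3 <- join_pair("CC", "c1ccccc1", "tssa")
  expect_gte(length(cand3), 1L)
  expect_true(any(vapply(cand3, function(g) {
    identical(write_canonical(g), canon1("Cc1ccccc1"))
  }, logical(1))))
  expect_error(join_pair("*C", "CC", "tsdy"),
               NA)  # no candidates is an empty list, not an error
  expect_length(join_pair("*C", "CC", "tsdy"), 0L)
})

test_that("random reconstruction is seed-reproducible and always valid", {
  smis <- fixture_smiles_small()[1:10]
  a <- reconstruct_corpus(smis, "mmpa", "tsdy",
                          assembly_selector("random", seed = 11L))
  b <- reconstruct_corpus(smis, "mmpa", "tsdy",
                          assembly_selector("random", seed = 11L))
  expect_identical(a, b)
  expect_true(all(a$valid))
  expect_equal(nrow(a), length(smis))
  # ID labels force the identity regardless of the selector
  d <- reconstruct_corpus(smis, "mmpa", "tsid",
                          assembly_selector("random", seed = 11L))
  expect_identical(d$generated, d$source)
})

test_that("the source molecule is among the enumerable assembly outcomes", {
  checked <- 0L
  for (s in fixture_smiles_small()) {
    if (checked >= 3L) break
    mol <- parse_molecule(s)
    for (style in c("tsdy", "tssa")) {
      fs <- fragment_molecule(mol, "mmpa", style)
      if (length(fs$fragments) < 2L || length(fs$fragments) > 4L) next
      outcomes <- enumerate_assemblies(build_amt(fs))
      expect_true(write_canonical(mol) %in% outcomes,
                  info = paste(style, s))
      checked <- checked + 1L
    }
  }
  expect_gte(checked, 2L)
})

test_that("goal-directed selection maximises the scorer", {
  mol <- parse_molecule("CCc1ccc(N)cc1O")
  amt <- build_amt(fragment_molecule(mol, "mmpa", "tsdy"))
  # constant scorer: any valid assembly, deterministic under a seed
  g1 <- goal_directed_select(amt, function(s) 1, n_candidates = 4L, seed = 5L)
  g2 <- goal_directed_select(amt, function(s) 1, n_candidates = 4L, seed = 5L)
  expect_identical(g1$smiles, g2$smiles)
  expect_true(g1$valid)
  # indicator scorer: hit rate grows with the candidate budget
  target <- write_canonical(mol)
  scorer <- function(s) as.numeric(identical(s, target))
  hit <- function(n, seeds) {
    mean(vapply(seeds, function(sd) {
      goal_directed_select(amt, scorer, n_candidates = n, seed = sd)$score
    }, numeric(1)))
  }
  p1 <- hit(1L, 1:40)
  p6 <- hit(6L, 1:40)
  expect_gte(p6, p1)
  # with the per-draw hit rate q, expected top-score rate is 1-(1-q)^n
  q <- mean(vapply(101:260, function(sd) {
    as.numeric(identical(
      assemble(amt, assembly_selector("random", seed = sd))$smiles, target
    ))
  }, numeric(1)))
  expect_gt(q, 0)
  pred <- 1 - (1 - q)^6
  expect_lt(abs(p6 - pred), 4 * sqrt(pred * (1 - pred) / 40) + 0.05)
})

test_that("unresolved attachment points fail strictly and mend under repair", {
  # a lone open dummy cannot be resolved
  expect_error(ts_decode("*CC&&&", "tsdy"), class = "ts_no_candidate_error")
  res <- ts_decode("*CC&&&", "tsdy", repair = TRUE)
  expect_true(res$valid)
  expect_identical(res$smiles, "CC")
  expect_gte(res$repairs, 1L)
})
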