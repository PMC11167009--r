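test_that("the smallest trees serialise to the expected strings", {
  expect_identical(encode_molecule("CCO", "mmpa", "vanilla"), "CCO&&&")
  fbt <- ts_parse("CCO&&&", "vanilla")
  expect_equal(tsmiles:::fbt_n_fragments(fbt), 1L)
  tk <- ts_tokenize("CCO&&&")
  expect_identical(tk$type, c("FRAG", "AMP", "AMP", "AMP"))
})

test_that("serialize/parse and tree conversions are mutually inverse", {
  pool <- tsmiles:::harvest_fragment_pool(fixture_smiles_small()[1:12],
                                          "mmpa", "tsdy")
  for (k in 1:60) {
    amt <- tsmiles:::with_local_seed(1000L + k, {
      tsmiles:::compose_random_tree(pool, max_frags = 6L)
    })
    s <- ts_serialize(amt_to_fbt(amt))
    # string round trip
    expect_identical(ts_serialize(ts_parse(s, "tsdy")), s)
    # tree round trip (same topology, same fragments, same child order)
    amt2 <- fbt_to_amt(amt_to_fbt(amt))
    expect_identical(ts_serialize(amt_to_fbt(amt2)), s)
    # token-count law with sentinel: AMP = FRAG + 2
    tk <- ts_tokenize(s)
    expect_equal(sum(tk$type == "AMP"), sum(tk$type == "FRAG") + 2L)
  }
})

test_that("node counts obey full-binary arithmetic", {
  for (s in fixture_smiles_small()[1:10]) {
    fbt <- amt_to_fbt(build_amt(fragment_molecule(parse_molecule(s),
                                                  "mmpa", "tsid")))
    n <- length(fbt$payload)
    f <- tsmiles:::fbt_n_fragments(fbt)
    expect_equal(n, 2L * f + 1L)
    expect_equal(n %% 2L, 1L)
  }
})

test_that("caret separators are lexically necessary but structurally inert", {
  cel <- celecoxib_case()
  base <- ts_serialize(ts_parse(cel$tsid, "tsid"))
  doubled <- gsub("\\^", "^^", cel$tsid)
  expect_identical(ts_serialize(ts_parse(doubled, "tsid")), base)
})

test_that("malformed streams raise without repair and mend with it", {
  expect_error(ts_parse("&CC&&", "tsdy"), class = "ts_malformed_stream_error")
  expect_error(ts_parse("", "tsdy"), class = "ts_empty_string_error")
  expect_error(ts_parse("CC&CC", "tsdy"), class = "ts_malformed_stream_error")
  expect_error(ts_parse("CC&&&CC&&&", "tsdy"),
               class = "ts_malformed_stream_error")
  # truncated stream is padded under repair
  fixed <- ts_parse("CC&CC", "tsdy", repair = TRUE)
  expect_gte(attr(fixed, "repairs"), 1L)
  expect_identical(ts_serialize(fixed), "CC&CC&&&")
  # unparseable fragment token demoted to an empty node under repair
  expect_error(ts_parse("CC&xx(&&", "tsdy"), class = "ts_fragment_parse_error")
  mended <- ts_parse("CC&xx(&&", "tsdy", repair = TRUE)
  expect_equal(tsmiles:::fbt_n_fragments(mended), 1L)
  # surplus trailing ampersands are fine even without repair
  expect_identical(ts_serialize(ts_parse("CC&&&&&&", "tsdy")), "CC&&&")
})

test_that("the printed worked-example strings tokenize to the documented counts", {
  cel <- celecoxib_case()
  tk_id <- ts_tokenize(cel$tsid)
  expect_equal(sum(tk_id$type == "FRAG"), 7L)
  expect_equal(sum(tk_id$type == "AMP"), 9L)
  tk_sa <- ts_tokenize(cel$tssa)
  expect_equal(sum(tk_sa$type == "FRAG"), 12L)
  expect_equal(sum(tk_sa$type == "AMP"), 14L)
  # whitespace in the typeset codes is ignored
  spaced <- gsub("&", " & ", cel$tsid)
  expect_identical(ts_serialize(ts_parse(spaced, "tsid")),
                   ts_serialize(ts_parse(cel$tsid, "tsid")))
})

test_that("nesting depth counts open parentheses per fragment token", {
  expect_equal(max_nesting_depth("CCCC"), 0L)
  expect_equal(max_nesting_depth("CC(C(C)C)C"), 2L)
  expect_equal(max_nesting_depth("CC(C(C(C)C)C)C"), 3L)
  # every printed ID-labelled fragment stays at depth <= 1
  cel <- celecoxib_case()
  expect_lte(max_nesting_depth(cel$tsid), 1L)
  expect_error(max_nesting_depth("CC)C("), class = "ts_unbalanced_error")
})

test_that("encoding is deterministic and vectorises with per-row errors", {
  cel <- parse_molecule(CELECOXIB)
  expect_identical(encode_molecule(cel, "mmpa", "tsid"),
                   encode_molecule(cel, "mmpa", "tsid"))
  tab <- ts_encode(c("CCO", "not_a_smiles", CELECOXIB), "mmpa", "tsdy")
  expect_equal(nrow(tab), 3L)
  expect_true(is.na(tab$tsmiles[[2]]))
  expect_false(is.na(tab$error[[2]]))
  expect_equal(tab$n_fragments[[3]], 7L)
})
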