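test_that("a report on identical sets is the fixed point of every metric", {
  tr <- fixture_smiles_small()[1:15]
  rep <- distribution_report(tr, tr)
  expect_equal(rep$valid, 1)
  expect_equal(rep$novelty, 0)
  expect_equal(rep$kld_score, 1)
  expect_true(all(tidy(rep)$wasserstein == 0))
  expect_true(is.na(rep$fcd))
  g <- glance(rep)
  expect_identical(names(g)[1:4], c("valid", "unique", "novelty", "kld_score"))
})

test_that("validity, uniqueness and novelty count as documented", {
  generated <- c("CCO", "CCO", "CCN", "CO=CC")  # 1 dup, 1 novel, 1 invalid
  training <- c("CCO", "CCC")
  rep <- distribution_report(generated, training)
  expect_equal(rep$valid, 0.75)
  expect_equal(rep$unique, 2 / 3)
  expect_equal(rep$novelty, 1 / 2)
  # novelty + (fraction of unique found in training) = 1
  expect_equal(rep$novelty + (1 - rep$novelty), 1)
  expect_error(distribution_report(character(0), training),
               class = "ts_empty_input_error")
})

test_that("reports are invariant under input permutation", {
  set.seed(9)
  gen <- sample(fixture_smiles_small()[1:12])
  tr <- fixture_smiles_small()[5:20]
  a <- glance(distribution_report(gen, tr))
  b <- glance(distribution_report(rev(gen), sample(tr)))
  expect_equal(a, b)
})

test_that("the KL score decreases monotonically under a mean shift", {
  set.seed(42)
  x <- stats::rnorm(2000)
  scores <- vapply(c(0, 0.5, 1, 2), function(d) {
    exp(-tsmiles:::kl_divergence(x, x + d))
  }, numeric(1))
  expect_equal(scores[[1]], 1)
  expect_true(all(diff(scores) < 0))
  expect_true(all(scores > 0 & scores <= 1))
})

test_that("Wasserstein-1 has the closed-form and translation properties", {
  expect_equal(tsmiles:::w1_distance(100, 200), 100)
  expect_equal(tsmiles:::w1_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(7)
  x <- stats::rnorm(500)
  expect_equal(tsmiles:::w1_distance(x, x + 3.5), 3.5, tolerance = 1e-8)
  pd <- property_distances(c("CCO", "CCN"), c("CCO", "CCN"))
  expect_true(all(pd$wasserstein == 0))
})

test_that("token frequencies sum to one over the extended alphabet", {
  td <- token_distribution(c("CC&CC&&"))
  expect_equal(sum(td$freq), 1)
  expect_equal(td$freq[td$token == "&"], 3 / 7)
  expect_equal(td$freq[td$token == "C"], 4 / 7)
  td2 <- token_distribution(c("Clc1ccccc1", "BrC(Br)[13CH3]"))
  expect_true(all(c("Cl", "Br", "[13CH3]") %in% td2$token))
  td3 <- token_distribution("C%12CC%12")
  expect_true("%12" %in% td3$token)
})

test_that("nesting profiles aggregate into the documented bands", {
  np <- nesting_profile(c("CCCC"))
  expect_equal(np$bands$prop[np$bands$band == "0-2"], 1)
  np2 <- nesting_profile(c("CC(C(C(C)C)C)C"))
  expect_equal(np2$bands$prop[np2$bands$band == "3-5"], 1)
  np3 <- nesting_profile(c("CCCC", "CC(C(C(C)C)C)C"))
  expect_equal(sum(np3$bands$prop), 1)
  expect_equal(np3$histogram$n[np3$histogram$depth == 0], 1L)
})

test_that("tree-shape counting distinguishes sizes but not labels", {
  amts <- lapply(c("CCCCO", "NCCCC"), function(s) {
    build_amt(fragment_molecule(parse_molecule(s), "mmpa", "tsdy"))
  })
  expect_equal(count_fbt_types(amts), 1L)  # two chains of equal length
  amts2 <- lapply(c("CCCCO", "CCCCCCCO"), function(s) {
    build_amt(fragment_molecule(parse_molecule(s), "mmpa", "tsdy"))
  })
  expect_equal(count_fbt_types(amts2), 2L)
  # synthetic path trees of lengths 1..10 give 10 distinct shapes
  link <- tsmiles:::parse_fragment_token("*CC*", "tsdy")
  path_amt <- function(k) {
    structure(
      list(
        nodes = rep(list(link), k),
        children = c(lapply(seq_len(k - 1L), function(v) v + 1L),
                     list(integer(0))),
        parent = c(NA_integer_, seq_len(k - 1L)),
        parent_edge = rep(NA_integer_, k),
        parent_fwd = rep(TRUE, k),
        edges = tsmiles:::empty_adjacency(), root = 1L,
        scheme = NA_character_, style = "tsdy", source = NULL
      ),
      class = "ts_amt"
    )
  }
  expect_equal(count_fbt_types(lapply(1:10, path_amt)), 10L)
})

test_that("plot builders return ggplot objects", {
  td <- token_distribution(c("CC&CC&&", "c1ccccc1&&&"))
  expect_s3_class(autoplot(td), "ggplot")
  expect_s3_class(autoplot(nesting_profile(c("CCCC", "CC(C)C"))), "ggplot")
  rep <- distribution_report(c("CCO", "CCN"), c("CCO", "CCC"))
  expect_s3_class(autoplot(rep), "ggplot")
})
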