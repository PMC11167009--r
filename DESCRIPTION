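Package: tsmiles
Title: Tree-Based Fragment SMILES Encoding and Assembly of Molecules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Encodes molecules as tree-structured SMILES-type strings by
    fragmenting the molecular graph (junction, BRICS, matched-molecular-pair
    or Murcko-scaffold cuts), arranging the fragments in an acyclic molecular
    tree, embedding that tree in a full binary tree and serialising it in
    breadth-first order with two extra symbols, "&" for an empty node and "^"
    as a fragment separator.  Decodes such strings back to molecules by
    rebuilding the tree and reassembling fragments at shared atoms or dummy
    attachment points, either deterministically, at random, or guided by a
    user scoring function.  Includes a training-free molecular generator
    based on stochastic reassembly, corpus statistics (token distribution,
    parenthesis nesting depth, tree-shape counts) and distribution-learning
    metrics (validity, uniqueness, novelty, Kullback-Leibler descriptor
    score, Wasserstein property distances).  Chemistry (SMILES parsing,
    canonicalisation, SMARTS matching) is delegated to Open Babel through
    the ChemmineOB interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    igraph,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    jsonlite,
    ggplot2,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
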