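# Shared fixtures, generated in code. The small set keeps unit tests fast;
# the acceptance suite builds its own larger corpus.

CELECOXIB <- "Cc1ccc(-c2cc(C(F)(F)F)nn2-c2ccc(S(N)(=O)=O)cc2)cc1"

fixture_smiles_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_fixture_molecules(40, seed = 101)$smiles
    }
    cache
  }
})

canon1 <- function(s) write_canonical(parse_molecule(s))

strip_ids <- function(s) gsub("\\[[0-9]+\\*\\]", "*", s)

# canonical multiset of a fragment set, dummy labels removed
fragset_multiset <- function(fs) {
  sort(vapply(fs$fragments, function(f) {
    tsmiles:::ob_canonical_smiles(strip_ids(f$smiles))
  }, character(1), USE.NAMES = FALSE))
}

smiles_multiset <- function(x) {
  sort(vapply(strip_ids(x), tsmiles:::ob_canonical_smiles, character(1),
              USE.NAMES = FALSE))
}

# colored-graph isomorphism oracle (VF2), independent of canonical SMILES
graphs_isomorphic <- function(a, b) {
  if (nrow(a$atoms) != nrow(b$atoms) || nrow(a$bonds) != nrow(b$bonds)) {
    return(FALSE)
  }
  col <- function(m) {
    key <- paste(m$atoms$element, m$atoms$charge)
    as.integer(factor(key, levels = sort(unique(c(
      paste(a$atoms$element, a$atoms$charge),
      paste(b$atoms$element, b$atoms$charge)
    )))))
  }
  ga <- igraph::graph_from_data_frame(
    data.frame(from = a$bonds$i, to = a$bonds$j),
    directed = FALSE, vertices = data.frame(name = seq_len(nrow(a$atoms)))
  )
  gb <- igraph::graph_from_data_frame(
    data.frame(from = b$bonds$i, to = b$bonds$j),
    directed = FALSE, vertices = data.frame(name = seq_len(nrow(b$atoms)))
  )
  igraph::isomorphic(
    ga, gb, method = "vf2",
    vertex.color1 = col(a), vertex.color2 = col(b),
    edge.color1 = a$bonds$order, edge.color2 = b$bonds$order
  )
}

# exhaustive record-free assembly outcomes of an AMT (depth-first over the
# candidate choices at every join), capped at `limit` passes
enumerate_assemblies <- function(amt, limit = 2000L) {
  results <- character(0)
  stack <- list(integer(0))
  runs <- 0L
  while (length(stack) && runs < limit) {
    prefix <- stack[[1]]
    stack <- stack[-1]
    runs <- runs + 1L
    counts <- integer(0)
    i <- 0L
    pick <- function(cand) {
      i <<- i + 1L
      counts[i] <<- length(cand)
      if (i <= length(prefix)) prefix[[i]] else 1L
    }
    st <- tryCatch(
      tsmiles:::assemble_pass(amt, pick, use_records = FALSE),
      error = function(e) NULL
    )
    if (!is.null(st)) {
      res <- tsmiles:::assembly_from_state(st)
      if (res$valid) results <- c(results, res$smiles)
    }
    # branch at every join beyond the explored prefix
    for (d in seq(length(prefix) + 1L, length.out = max(0L, length(counts) - length(prefix)))) {
      if (counts[[d]] > 1L) {
        for (k in 2:counts[[d]]) {
          stack <- c(stack, list(c(prefix, rep(1L, d - length(prefix) - 1L), k)))
        }
      }
    }
  }
  unique(results)
}
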