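# Download-free inputs: a seeded generator of valid, fragmentable molecules
# (stands in for large public corpora, which are out of scope here) and the
# embedded Celecoxib worked example.

ring_unit <- function(kind) {
  switch(kind,
    benzene = list(
      atoms = tibble::tibble(element = rep("C", 6), charge = 0L, iso = 0L,
                             aromatic = TRUE),
      bonds = tibble::tibble(i = 1:6, j = c(2:6, 1L),
                             order = c(2L, 1L, 2L, 1L, 2L, 1L)),
      sites = 1:6
    ),
    pyridine = list(
      atoms = tibble::tibble(element = c("N", rep("C", 5)), charge = 0L,
                             iso = 0L, aromatic = TRUE),
      bonds = tibble::tibble(i = 1:6, j = c(2:6, 1L),
                             order = c(2L, 1L, 2L, 1L, 2L, 1L)),
      sites = 2:6   # keep substitution off the ring nitrogen
    ),
    cyclohexane = list(
      atoms = tibble::tibble(element = rep("C", 6), charge = 0L, iso = 0L,
                             aromatic = FALSE),
      bonds = tibble::tibble(i = 1:6, j = c(2:6, 1L), order = 1L),
      sites = 1:6
    ),
    cyclopentane = list(
      atoms = tibble::tibble(element = rep("C", 5), charge = 0L, iso = 0L,
                             aromatic = FALSE),
      bonds = tibble::tibble(i = 1:5, j = c(2:5, 1L), order = 1L),
      sites = 1:5
    )
  )
}

chain_unit <- function(len) {
  list(
    atoms = tibble::tibble(element = rep("C", len), charge = 0L, iso = 0L,
                           aromatic = FALSE),
    bonds = if (len > 1L) {
      tibble::tibble(i = seq_len(len - 1L), j = seq_len(len - 1L) + 1L,
                     order = 1L)
    } else mol_graph_empty_bonds(),
    sites = 1L
  )
}

atom_unit <- function(el) {
  list(
    atoms = tibble::tibble(element = el, charge = 0L, iso = 0L,
                           aromatic = FALSE),
    bonds = mol_graph_empty_bonds(),
    sites = 1L
  )
}

grow_one_molecule <- function(target, ring_prob) {
  rings <- c("benzene", "pyridine", "cyclohexane", "cyclopentane")
  ring_w <- c(0.45, 0.2, 0.2, 0.15)
  pick_ring <- function() ring_unit(sample(rings, 1L, prob = ring_w))
  g <- if (stats::runif(1) < ring_prob) {
    u <- pick_ring()
    new_mol_graph(u$atoms, u$bonds)
  } else {
    u <- chain_unit(sample(2:4, 1L))
    new_mol_graph(u$atoms, u$bonds)
  }
  guard <- 0L
  while (mg_n_heavy(g) < target && guard < 50L) {
    guard <- guard + 1L
    free <- mg_free_valence(g)
    # grow only from carbon sites with a free slot (keeps heteroatoms terminal)
    host <- which(free >= 1L & g$atoms$element == "C")
    if (!length(host)) break
    at <- if (length(host) == 1L) host else sample(host, 1L)
    kind <- sample(c("ring", "chain", "methyl", "hetero"), 1L,
                   prob = c(0.25, 0.3, 0.25, 0.2))
    u <- switch(kind,
      ring = pick_ring(),
      chain = chain_unit(sample(2:3, 1L)),
      methyl = chain_unit(1L),
      hetero = atom_unit(sample(c("O", "N", "F", "S"), 1L,
                                prob = c(0.35, 0.3, 0.2, 0.15)))
    )
    site <- if (length(u$sites) == 1L) u$sites else sample(u$sites, 1L)
    off <- nrow(g$atoms)
    g$atoms <- dplyr::bind_rows(g$atoms, u$atoms)
    g$bonds <- dplyr::bind_rows(
      g$bonds,
      tibble::tibble(i = u$bonds$i + off, j = u$bonds$j + off,
                     order = u$bonds$order),
      tibble::tibble(i = at, j = site + off, order = 1L)
    )
  }
  ob_molblock_to_smiles(mg_to_molblock(g))
}

#' Generate a reproducible set of fragmentable molecules
#'
#' Seeded random growth over a small atom alphabet (C, N, O, S, F; benzene,
#' pyridine, cyclohexane and cyclopentane rings; short chains) with valence
#' bookkeeping, so every output parses and sanitizes. Rings carry
#' substituents by construction, which keeps all fragmentation schemes
#' non-trivial on most of the set.
#'
#' @param n number of molecules.
#' @param seed integer seed; the same `(n, seed, ...)` gives an identical
#'   set.
#' @param heavy_range target heavy-atom range (min, max).
#' @param ring_prob probability that a molecule is seeded from a ring.
#' @return a tibble with columns `id` and `smiles` (canonical).
#' @examples
#' generate_fixture_molecules(3, seed = 7)
#' @export
generate_fixture_molecules <- function(n, seed = 1L,
                                       heavy_range = c(8L, 24L),
                                       ring_prob = 0.6) {
  stopifnot(n >= 1L)
  with_local_seed(as.integer(seed), {
    smiles <- vapply(seq_len(n), function(i) {
      target <- sample(seq(heavy_range[[1]], heavy_range[[2]]), 1L)
      s <- grow_one_molecule(target, ring_prob)
      if (is.na(s)) s <- "c1ccccc1C"  # unreachable fallback, kept defensive
      s
    }, character(1))
    tibble::tibble(id = seq_len(n), smiles = smiles)
  })
}

#' The Celecoxib worked example
#'
#' The three published tree-SMILES codes of Celecoxib under the
#' matched-molecular-pair decomposition (whitespace-normalised), the seven
#' ID-labelled fragment tokens, and the molecule's SMILES. The ID-stripped
#' canonical fragment multiset is derived from the embedded code at call
#' time.
#'
#' @return a list with elements `name`, `smiles`, `tsid`, `tsdy`, `tssa`,
#'   `tsid_fragments`, `fragment_multiset` (ID-stripped canonical forms).
#' @export
celecoxib_case <- function() {
  tsid <- paste0(
    "[1*]C&[1*]C1=CC=C([2*])C=C1&[2*]C1=CC([3*])=NN1[5*]&[3*]C([4*])(F)F&",
    "[4*]F^[5*]C1=CC=C([6*])C=C1&&[6*]S(N)(=O)=O&&&"
  )
  tsdy <- gsub("\\[[0-9]+\\*\\]", "*", tsid)
  tssa <- paste0(
    "CC&C1=CC=CC=C1&CC&C1=C[NH]N=C1&CN&C1=CC=CC=C1^CC^CS&C&",
    "N[SH](=O)=O&CF&&&&FCF&&"
  )
  frags <- ts_tokenize(tsid)
  frags <- frags$token[frags$type == "FRAG"]
  multiset <- sort(vapply(gsub("\\[[0-9]+\\*\\]", "*", frags),
                          ob_canonical_smiles, character(1),
                          USE.NAMES = FALSE))
  list(
    name = "celecoxib",
    smiles = "Cc1ccc(-c2cc(C(F)(F)F)nn2-c2ccc(S(N)(=O)=O)cc2)cc1",
    tsid = tsid, tsdy = tsdy, tssa = tssa,
    tsid_fragments = frags,
    fragment_multiset = multiset
  )
}

# Random well-formed trees from a harvested fragment pool: repeatedly attach
# a random dummy-bearing fragment to an open attachment point, closing with
# single-point fragments. Used by the theoretical-validity experiments.
compose_random_tree <- function(pool, max_frags = 6L) {
  n_dummies <- vapply(pool, function(f) sum(f$attach$kind == "dummy"),
                      integer(1))
  starters <- which(n_dummies >= 1L)
  terminals <- which(n_dummies == 1L)
  if (!length(starters) || !length(terminals)) {
    ts_error("ts_fixture_error", "fragment pool has no usable attachments")
  }
  nodes <- list(); children <- list(); parent <- integer(0)
  open <- list()  # list of node indices with unconsumed dummies
  add <- function(frag, par) {
    nodes[[length(nodes) + 1L]] <<- frag
    children[[length(children) + 1L]] <<- integer(0)
    parent <<- c(parent, par)
    length(nodes)
  }
  root_frag <- pool[[sample(starters, 1L)]]
  v <- add(root_frag, NA_integer_)
  open_slots <- sum(root_frag$attach$kind == "dummy")
  open <- rep(v, open_slots)
  while (length(open)) {
    slot <- open[[1]]; open <- open[-1]
    pick_from <- if (length(nodes) >= max_frags) terminals else starters
    frag <- pool[[sample(pick_from, 1L)]]
    w <- add(frag, slot)
    children[[slot]] <- c(children[[slot]], w)
    open <- c(open, rep(w, sum(frag$attach$kind == "dummy") - 1L))
  }
  structure(
    list(
      nodes = nodes, children = children, parent = parent,
      parent_edge = rep(NA_integer_, length(nodes)),
      parent_fwd = rep(TRUE, length(nodes)),
      edges = empty_adjacency(), root = 1L,
      scheme = NA_character_, style = "tsdy", source = NULL
    ),
    class = "ts_amt"
  )
}

# Harvest dummy-bearing fragments from a molecule set.
harvest_fragment_pool <- function(smiles, scheme = "mmpa", style = "tsdy",
                                  config = ts_config()) {
  pool <- list()
  for (s in smiles) {
    fs <- tryCatch(
      fragment_molecule(parse_molecule(s), scheme, style, config),
      error = function(e) NULL
    )
    if (is.null(fs)) next
    pool <- c(pool, fs$fragments)
  }
  pool
}
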