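# Fragmentation: cut-bond discovery per scheme, fragment construction per
# code style, and the acyclic molecular tree (AMT) over the fragments.

ts_schemes <- c("junction", "brics", "mmpa", "scaffold")
ts_styles <- c("tssa", "tsdy", "tsid", "vanilla")

#' Configuration for fragmentation and tree-building policies
#'
#' @param mmpa_max_acyclic largest acyclic fragment (real heavy atoms) left
#'   uncut by the matched-molecular-pair scheme's recursive phase.
#' @param mmpa_smarts SMARTS defining an eligible matched-molecular-pair
#'   bond. The default cuts single acyclic bonds with at least one carbon
#'   end that is not multiply bonded to a heteroatom.
#' @param ring_merge_shared rings sharing at least this many atoms are merged
#'   into one junction cluster.
#' @param child_order `"size"` (descending subtree heavy-atom count, ties by
#'   fragment SMILES) or `"index"`.
#' @param kekule write fragment SMILES in Kekulé spelling (explicit
#'   single/double bonds) instead of the default aromatic lower-case
#'   dialect.
#' @return a `ts_config` list.
#' @export
ts_config <- function(mmpa_max_acyclic = 3L,
                      mmpa_smarts = "[#6;!$([#6]=[!#6]);!$([#6]#[!#6])]-!@[!#1]",
                      ring_merge_shared = 3L,
                      child_order = c("size", "index"),
                      kekule = FALSE) {
  structure(
    list(
      mmpa_max_acyclic = as.integer(mmpa_max_acyclic),
      mmpa_smarts = mmpa_smarts,
      ring_merge_shared = as.integer(ring_merge_shared),
      child_order = match.arg(child_order),
      kekule = isTRUE(kekule)
    ),
    class = "ts_config"
  )
}

mg_bond_index <- function(mol) {
  key <- paste(pmin(mol$bonds$i, mol$bonds$j), pmax(mol$bonds$i, mol$bonds$j))
  stats::setNames(seq_len(nrow(mol$bonds)), key)
}

bond_key <- function(i, j) paste(pmin(i, j), pmax(i, j))

# components of the molecule after deleting the given bond rows
# (plain union-find; called heavily by the recursive cut search)
mg_components_without <- function(mol, bond_rows) {
  n <- nrow(mol$atoms)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  keep <- setdiff(seq_len(nrow(mol$bonds)), bond_rows)
  for (r in keep) {
    a <- find(mol$bonds$i[[r]]); b <- find(mol$bonds$j[[r]])
    if (a != b) parent[[a]] <- b
  }
  vapply(seq_len(n), find, integer(1))
}

#' Find the bonds a fragmentation scheme would cut
#'
#' @param mol a `mol_graph` from [parse_molecule()].
#' @param scheme `"brics"`, `"mmpa"`, `"scaffold"` or `"junction"` (the
#'   junction scheme is cluster-based; it reports no cut bonds here and is
#'   resolved inside [fragment_molecule()]).
#' @param config a [ts_config()].
#' @return a tibble with columns `i`, `j` (atom indices), `order` and
#'   `cut_id` (consecutive, in discovery order). Empty when the molecule is
#'   a single fragment under the scheme.
#' @export
find_cut_bonds <- function(mol, scheme = ts_schemes, config = ts_config()) {
  scheme <- match.arg(scheme, ts_schemes)
  empty <- tibble::tibble(
    i = integer(0), j = integer(0), order = integer(0), cut_id = integer(0)
  )
  if (mg_n_heavy(mol) < 2L) return(empty)
  cuts <- switch(scheme,
    junction = empty[, c("i", "j", "order")],
    brics = brics_cut_bonds(mol),
    mmpa = mmpa_cut_bonds(mol, config),
    scaffold = scaffold_cut_bonds(mol)
  )
  if (!nrow(cuts)) return(empty)
  cuts$cut_id <- seq_len(nrow(cuts))
  cuts
}

brics_cut_bonds <- function(mol) {
  block <- mg_to_molblock(mol)
  pats <- lapply(brics_pairs, brics_pair_smarts)
  hits <- ob_smarts_matches(block, pats)
  bidx <- mg_bond_index(mol)
  seen <- character(0)
  out <- list()
  for (p in seq_along(hits)) {
    for (m in hits[[p]]) {
      if (length(m) != 2L) next
      key <- bond_key(m[[1]], m[[2]])
      if (key %in% seen || !key %in% names(bidx)) next
      seen <- c(seen, key)
      row <- bidx[[key]]
      out[[length(out) + 1L]] <- c(m[[1]], m[[2]], mol$bonds$order[[row]])
    }
  }
  if (!length(out)) {
    return(tibble::tibble(i = integer(0), j = integer(0), order = integer(0)))
  }
  mat <- do.call(rbind, out)
  tibble::tibble(i = mat[, 1], j = mat[, 2], order = mat[, 3])
}

# Eligible matched-molecular-pair bonds: SMARTS-defined, always single and
# acyclic. Cut policy: (1) every eligible bond touching a ring atom; (2) any
# remaining acyclic fragment larger than `mmpa_max_acyclic` real heavy atoms
# is split recursively at its most size-balanced eligible bond.
mmpa_cut_bonds <- function(mol, config) {
  block <- mg_to_molblock(mol)
  hits <- ob_smarts_matches(block, list(config$mmpa_smarts))[[1]]
  if (!length(hits)) {
    return(tibble::tibble(i = integer(0), j = integer(0), order = integer(0)))
  }
  mat <- unique(t(vapply(hits, function(m) {
    c(min(m[[1]], m[[2]]), max(m[[1]], m[[2]]))
  }, integer(2))))
  elig <- tibble::tibble(i = mat[, 1], j = mat[, 2])
  bidx <- mg_bond_index(mol)
  rows <- bidx[bond_key(elig$i, elig$j)]
  elig <- elig[!is.na(rows) & mol$bonds$order[rows] == 1L, , drop = FALSE]
  elig <- elig[order(elig$i, elig$j), , drop = FALSE]
  ring_at <- mg_ring_atoms(mol)
  phase1 <- elig$i %in% ring_at | elig$j %in% ring_at
  cut <- elig[phase1, , drop = FALSE]
  rest <- elig[!phase1, , drop = FALSE]
  # phase 2: recursive balanced splitting of oversized acyclic fragments
  repeat {
    if (!nrow(rest)) break
    memb <- mg_components_without(mol, bidx[bond_key(cut$i, cut$j)])
    real <- !mol$atoms$element %in% c("H", "*")
    comp_size <- table(memb[real])
    cand <- NULL
    for (r in seq_len(nrow(rest))) {
      cm <- memb[[rest$i[[r]]]]
      if (comb_size_of(comp_size, cm) <= config$mmpa_max_acyclic) next
      # split sizes if this bond were cut
      memb2 <- mg_components_without(
        mol, bidx[bond_key(c(cut$i, rest$i[[r]]), c(cut$j, rest$j[[r]]))]
      )
      sa <- sum(memb2[real] == memb2[[rest$i[[r]]]])
      sb <- sum(memb2[real] == memb2[[rest$j[[r]]]])
      bal <- abs(sa - sb)
      if (is.null(cand) || bal < cand$bal) {
        cand <- list(row = r, bal = bal)
      }
    }
    if (is.null(cand)) break
    cut <- rbind(cut, rest[cand$row, , drop = FALSE])
    rest <- rest[-cand$row, , drop = FALSE]
  }
  if (!nrow(cut)) {
    return(tibble::tibble(i = integer(0), j = integer(0), order = integer(0)))
  }
  tibble::tibble(i = cut$i, j = cut$j, order = 1L)
}

comb_size_of <- function(tab, key) {
  v <- tab[as.character(key)]
  if (is.na(v)) 0L else as.integer(v)
}

# Murcko scaffold = ring atoms plus linker atoms between rings (iteratively
# pruning non-ring leaves). Cuts: scaffold/side-chain bonds and ring/linker
# bonds, single and acyclic.
scaffold_cut_bonds <- function(mol) {
  empty <- tibble::tibble(i = integer(0), j = integer(0), order = integer(0))
  ring_at <- mg_ring_atoms(mol)
  if (!length(ring_at)) return(empty)
  n <- nrow(mol$atoms)
  keep <- rep(TRUE, n)
  repeat {
    deg <- integer(n)
    bb <- mol$bonds[keep[mol$bonds$i] & keep[mol$bonds$j], , drop = FALSE]
    tab <- table(c(bb$i, bb$j))
    deg[as.integer(names(tab))] <- as.integer(tab)
    drop <- which(keep & deg <= 1L & !seq_len(n) %in% ring_at)
    if (!length(drop)) break
    keep[drop] <- FALSE
  }
  scaffold <- which(keep)
  rb <- mg_ring_bonds(mol)
  out <- list()
  for (r in seq_len(nrow(mol$bonds))) {
    if (rb[[r]] || mol$bonds$order[[r]] != 1L) next
    i <- mol$bonds$i[[r]]; j <- mol$bonds$j[[r]]
    side_chain <- xor(i %in% scaffold, j %in% scaffold)
    ring_linker <- (i %in% scaffold && j %in% scaffold) &&
      xor(i %in% ring_at, j %in% ring_at)
    if (side_chain || ring_linker) out[[length(out) + 1L]] <- c(i, j)
  }
  if (!length(out)) return(empty)
  mat <- do.call(rbind, out)
  tibble::tibble(i = mat[, 1], j = mat[, 2], order = 1L)
}

# Dummy-style variant of the junction scheme: separate ring systems from
# their substituents by cutting every single acyclic bond incident to a ring
# atom (the reduced graph of rings vs substituents).
junction_bond_cuts <- function(mol) {
  empty <- tibble::tibble(i = integer(0), j = integer(0), order = integer(0))
  ring_at <- mg_ring_atoms(mol)
  if (!length(ring_at)) return(empty)
  rb <- mg_ring_bonds(mol)
  sel <- !rb & mol$bonds$order == 1L &
    (mol$bonds$i %in% ring_at | mol$bonds$j %in% ring_at)
  if (!any(sel)) return(empty)
  tibble::tibble(i = mol$bonds$i[sel], j = mol$bonds$j[sel], order = 1L)
}

# ---- fragments -----------------------------------------------------------

# `smiles = NA` defers serialisation so a whole fragment set can be
# canonicalised in one batched conversion (fill_fragment_smiles).
new_fragment <- function(graph, attach, src_atoms, role = "cluster",
                         smiles = NULL) {
  if (!mg_valence_ok(graph)) {
    ts_error("ts_fragmentation_error", "fragment violates valence rules")
  }
  if (is.null(smiles)) {
    smiles <- ob_molblock_to_smiles(mg_to_molblock(graph))
    if (is.na(smiles)) {
      ts_error("ts_fragmentation_error", "fragment could not be serialised")
    }
  }
  structure(
    list(graph = graph, smiles = smiles, attach = attach,
         src_atoms = src_atoms, role = role),
    class = "ts_fragment"
  )
}

fill_fragment_smiles <- function(frags, kekule = FALSE) {
  todo <- which(vapply(frags, function(f) is.na(f$smiles), logical(1)))
  if (!length(todo)) return(frags)
  blocks <- vapply(frags[todo], function(f) mg_to_molblock(f$graph),
                   character(1))
  smis <- if (kekule) {
    ob_molblocks_to_smiles_kekule(blocks)
  } else {
    ob_molblocks_to_smiles_batch(blocks)
  }
  if (anyNA(smis)) {
    ts_error("ts_fragmentation_error", "fragment could not be serialised")
  }
  for (k in seq_along(todo)) frags[[todo[[k]]]]$smiles <- smis[[k]]
  frags
}

frag_n_heavy <- function(frag) mg_n_heavy(frag$graph)

empty_attach <- function() {
  tibble::tibble(
    atom = integer(0), kind = character(0),
    cut_id = integer(0), order = integer(0)
  )
}

#' Fragment a molecule under a scheme and code style
#'
#' Dummy-atom styles (`"tsdy"`, `"tsid"`) replace each cut bond by a pair of
#' dummy atoms (`*`, labelled with the cut id for TSID); the shared-atom
#' style (`"tssa"`) keeps the fragments intact and adds a two-atom connector
#' piece per cut, sharing one atom with each side. `"vanilla"` returns the
#' whole molecule as a single fragment. The junction scheme builds
#' ring/bond clusters for TSSA and ring-substituent cuts for dummy styles.
#'
#' @param mol a `mol_graph`.
#' @inheritParams find_cut_bonds
#' @param style one of `"tssa"`, `"tsdy"`, `"tsid"`, `"vanilla"`.
#' @return a `ts_fragset`.
#' @export
fragment_molecule <- function(mol, scheme = ts_schemes, style = ts_styles,
                              config = ts_config()) {
  scheme <- match.arg(scheme, ts_schemes)
  style <- match.arg(style, ts_styles)
  if (style == "vanilla") {
    return(single_fragment_set(mol, scheme, style, config))
  }
  if (scheme == "junction" && style == "tssa") {
    return(junction_cluster_set(mol, config))
  }
  cuts <- if (scheme == "junction") {
    cc <- junction_bond_cuts(mol)
    if (nrow(cc)) cc$cut_id <- seq_len(nrow(cc))
    cc
  } else {
    find_cut_bonds(mol, scheme, config)
  }
  if (scheme == "scaffold" && !length(mg_ring_atoms(mol))) {
    warning("molecule has no ring scaffold; kept as a single fragment",
            call. = FALSE)
  }
  if (!nrow(cuts)) return(single_fragment_set(mol, scheme, style, config))
  if (style == "tssa") {
    tssa_fragment_set(mol, cuts, scheme, config)
  } else {
    dummy_fragment_set(mol, cuts, scheme, style, config)
  }
}

empty_adjacency <- function() {
  tibble::tibble(
    a = integer(0), b = integer(0), cut_id = integer(0), kind = character(0),
    order = integer(0), a_atoms = list(), b_atoms = list()
  )
}

single_fragment_set <- function(mol, scheme, style, config = ts_config()) {
  frag <- new_fragment(
    graph = new_mol_graph(mol$atoms, mol$bonds),
    attach = empty_attach(),
    src_atoms = seq_len(nrow(mol$atoms)),
    role = "whole",
    smiles = if (config$kekule) NA_character_ else
      if (!is.na(mol$smiles)) mol$smiles else NULL
  )
  if (config$kekule) frag <- fill_fragment_smiles(list(frag), TRUE)[[1]]
  structure(
    list(
      source = mol, scheme = scheme, style = style,
      fragments = list(frag),
      cuts = tibble::tibble(i = integer(0), j = integer(0),
                            order = integer(0), cut_id = integer(0)),
      adjacency = empty_adjacency()
    ),
    class = "ts_fragset"
  )
}

dummy_fragment_set <- function(mol, cuts, scheme, style, config = ts_config()) {
  bidx <- mg_bond_index(mol)
  cut_rows <- bidx[bond_key(cuts$i, cuts$j)]
  memb <- mg_components_without(mol, cut_rows)
  comp_ids <- sort(unique(memb))
  frag_of_comp <- stats::setNames(seq_along(comp_ids), comp_ids)
  frags <- vector("list", length(comp_ids))
  dummy_local <- list()  # per cut and side, local dummy index
  for (ci in seq_along(comp_ids)) {
    atoms_in <- which(memb == comp_ids[[ci]])
    sub <- mg_induced_subgraph(mol, atoms_in)
    map <- attr(sub, "map")
    attach <- empty_attach()
    g <- sub
    for (k in seq_len(nrow(cuts))) {
      for (side in c("i", "j")) {
        a_src <- cuts[[side]][[k]]
        if (memb[[a_src]] != comp_ids[[ci]]) next
        g$atoms <- dplyr::bind_rows(g$atoms, tibble::tibble(
          element = "*", charge = 0L,
          iso = if (style == "tsid") cuts$cut_id[[k]] else 0L,
          aromatic = FALSE
        ))
        d_local <- nrow(g$atoms)
        g$bonds <- dplyr::bind_rows(g$bonds, tibble::tibble(
          i = map[[a_src]], j = d_local, order = cuts$order[[k]]
        ))
        attach <- dplyr::bind_rows(attach, tibble::tibble(
          atom = d_local, kind = "dummy",
          cut_id = cuts$cut_id[[k]], order = cuts$order[[k]]
        ))
        dummy_local[[paste(k, side)]] <- c(frag = ci, atom = d_local)
      }
    }
    frags[[ci]] <- new_fragment(
      graph = g, attach = attach,
      src_atoms = c(atoms_in, rep(NA_integer_, nrow(attach))),
      smiles = NA_character_
    )
  }
  frags <- fill_fragment_smiles(frags, config$kekule)
  adj <- empty_adjacency()
  for (k in seq_len(nrow(cuts))) {
    di <- dummy_local[[paste(k, "i")]]
    dj <- dummy_local[[paste(k, "j")]]
    adj <- dplyr::bind_rows(adj, tibble::tibble(
      a = di[["frag"]], b = dj[["frag"]], cut_id = cuts$cut_id[[k]],
      kind = "dummy", order = cuts$order[[k]],
      a_atoms = list(di[["atom"]]), b_atoms = list(dj[["atom"]])
    ))
  }
  structure(
    list(source = mol, scheme = scheme, style = style,
         fragments = frags, cuts = cuts, adjacency = adj),
    class = "ts_fragset"
  )
}

tssa_fragment_set <- function(mol, cuts, scheme, config = ts_config()) {
  bidx <- mg_bond_index(mol)
  cut_rows <- bidx[bond_key(cuts$i, cuts$j)]
  memb <- mg_components_without(mol, cut_rows)
  comp_ids <- sort(unique(memb))
  frags <- vector("list", length(comp_ids))
  local_of <- function(frag, src) match(src, frag$src_atoms)
  for (ci in seq_along(comp_ids)) {
    atoms_in <- which(memb == comp_ids[[ci]])
    sub <- mg_induced_subgraph(mol, atoms_in)
    frags[[ci]] <- new_fragment(
      graph = sub, attach = empty_attach(), src_atoms = atoms_in,
      smiles = NA_character_
    )
  }
  adj <- empty_adjacency()
  for (k in seq_len(nrow(cuts))) {
    i <- cuts$i[[k]]; j <- cuts$j[[k]]
    conn <- mg_induced_subgraph(mol, c(i, j))
    conn$bonds <- tibble::tibble(i = 1L, j = 2L, order = cuts$order[[k]])
    conn_frag <- new_fragment(
      graph = conn, attach = empty_attach(),
      src_atoms = c(i, j), role = "connector", smiles = NA_character_
    )
    frags[[length(frags) + 1L]] <- conn_frag
    conn_ix <- length(frags)
    fa <- memb[[i]]; fb <- memb[[j]]
    ia <- match(fa, comp_ids); ib <- match(fb, comp_ids)
    adj <- dplyr::bind_rows(adj, tibble::tibble(
      a = ia, b = conn_ix, cut_id = cuts$cut_id[[k]], kind = "shared",
      order = NA_integer_,
      a_atoms = list(local_of(frags[[ia]], i)), b_atoms = list(1L)
    ))
    adj <- dplyr::bind_rows(adj, tibble::tibble(
      a = conn_ix, b = ib, cut_id = cuts$cut_id[[k]], kind = "shared",
      order = NA_integer_,
      a_atoms = list(2L), b_atoms = list(local_of(frags[[ib]], j))
    ))
    # record the shared atoms on both fragments
    frags[[ia]]$attach <- dplyr::bind_rows(frags[[ia]]$attach, tibble::tibble(
      atom = local_of(frags[[ia]], i), kind = "shared",
      cut_id = cuts$cut_id[[k]], order = NA_integer_
    ))
    frags[[ib]]$attach <- dplyr::bind_rows(frags[[ib]]$attach, tibble::tibble(
      atom = local_of(frags[[ib]], j), kind = "shared",
      cut_id = cuts$cut_id[[k]], order = NA_integer_
    ))
  }
  frags <- fill_fragment_smiles(frags, config$kekule)
  structure(
    list(source = mol, scheme = scheme, style = "tssa",
         fragments = frags, cuts = cuts, adjacency = adj),
    class = "ts_fragset"
  )
}

# Junction-tree clusters for TSSA: merged rings plus non-ring bonds; cluster
# graph edges weighted by shared-atom count, maximum spanning tree as AMT
# adjacency.
junction_cluster_set <- function(mol, config) {
  rings <- mg_rings(mol)
  # merge rings sharing >= ring_merge_shared atoms
  merged <- TRUE
  while (merged && length(rings) > 1L) {
    merged <- FALSE
    for (a in seq_along(rings)) {
      for (b in seq_along(rings)) {
        if (b <= a) next
        if (length(intersect(rings[[a]], rings[[b]])) >= config$ring_merge_shared) {
          rings[[a]] <- sort(union(rings[[a]], rings[[b]]))
          rings <- rings[-b]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
  }
  clusters <- rings
  ring_cluster_of_bond <- function(i, j) {
    for (rc in seq_along(rings)) {
      if (i %in% rings[[rc]] && j %in% rings[[rc]]) return(rc)
    }
    NA_integer_
  }
  for (r in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[[r]]; j <- mol$bonds$j[[r]]
    if (is.na(ring_cluster_of_bond(i, j))) {
      clusters[[length(clusters) + 1L]] <- c(i, j)
    }
  }
  if (!length(clusters)) clusters <- list(1L)
  frags <- lapply(clusters, function(atoms_in) {
    sub <- mg_induced_subgraph(mol, atoms_in)
    new_fragment(graph = sub, attach = empty_attach(), src_atoms = atoms_in,
                 smiles = NA_character_)
  })
  frags <- fill_fragment_smiles(frags, config$kekule)
  if (length(frags) == 1L) {
    fs <- single_fragment_set(mol, "junction", "tssa")
    fs$fragments <- frags
    return(fs)
  }
  # cluster graph
  edges <- list()
  for (a in seq_along(clusters)) {
    for (b in seq_along(clusters)) {
      if (b <= a) next
      sh <- intersect(clusters[[a]], clusters[[b]])
      if (length(sh)) edges[[length(edges) + 1L]] <- list(a = a, b = b, shared = sh)
    }
  }
  if (!length(edges)) {
    ts_error("ts_fragmentation_error", "junction cluster graph is disconnected")
  }
  el <- do.call(rbind, lapply(edges, function(e) c(e$a, e$b)))
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = el[, 1], to = el[, 2],
                   weight = -vapply(edges, function(e) length(e$shared), numeric(1))),
    directed = FALSE,
    vertices = data.frame(name = seq_along(clusters))
  )
  if (igraph::components(g)$no != 1L) {
    ts_error("ts_fragmentation_error", "junction cluster graph is disconnected")
  }
  mst <- igraph::mst(g)
  keep_el <- igraph::as_edgelist(mst, names = TRUE)
  keep_key <- paste(pmin(as.integer(keep_el[, 1]), as.integer(keep_el[, 2])),
                    pmax(as.integer(keep_el[, 1]), as.integer(keep_el[, 2])))
  adj <- empty_adjacency()
  cid <- 0L
  for (e in edges) {
    if (!paste(min(e$a, e$b), max(e$a, e$b)) %in% keep_key) next
    cid <- cid + 1L
    la <- match(e$shared, frags[[e$a]]$src_atoms)
    lb <- match(e$shared, frags[[e$b]]$src_atoms)
    adj <- dplyr::bind_rows(adj, tibble::tibble(
      a = e$a, b = e$b, cut_id = cid, kind = "shared", order = NA_integer_,
      a_atoms = list(la), b_atoms = list(lb)
    ))
    frags[[e$a]]$attach <- dplyr::bind_rows(frags[[e$a]]$attach, tibble::tibble(
      atom = la, kind = "shared", cut_id = cid, order = NA_integer_
    ))
    frags[[e$b]]$attach <- dplyr::bind_rows(frags[[e$b]]$attach, tibble::tibble(
      atom = lb, kind = "shared", cut_id = cid, order = NA_integer_
    ))
  }
  structure(
    list(source = mol, scheme = "junction", style = "tssa",
         fragments = frags,
         cuts = tibble::tibble(i = integer(0), j = integer(0),
                               order = integer(0), cut_id = integer(0)),
         adjacency = adj),
    class = "ts_fragset"
  )
}

#' @export
print.ts_fragset <- function(x, ...) {
  cat(sprintf(
    "<ts_fragset: %s/%s, %d fragment(s), %d cut(s)>\n",
    x$scheme, x$style, length(x$fragments), nrow(x$cuts)
  ))
  for (f in x$fragments) cat(" ", f$smiles, "\n")
  invisible(x)
}

# ---- AMT -----------------------------------------------------------------

#' Build the acyclic molecular tree over a fragment set
#'
#' The fragment adjacency (a spanning tree of the reduced graph) is rooted
#' and the children of every node are put in a deterministic order.
#'
#' @param fragset a `ts_fragset`.
#' @param root optional fragment index to use as root; the default is the
#'   first non-connector fragment containing the first atom of the canonical
#'   SMILES.
#' @param config a [ts_config()] (child ordering policy).
#' @return a `ts_amt`.
#' @export
build_amt <- function(fragset, root = NULL, config = ts_config()) {
  n <- length(fragset$fragments)
  adj <- fragset$adjacency
  if (nrow(adj) != n - 1L) {
    ts_error("ts_cyclic_adjacency_error",
             "fragment adjacency is not a tree (|edges| != |fragments|-1)")
  }
  if (n > 1L) {
    g <- igraph::graph_from_data_frame(
      d = data.frame(from = adj$a, to = adj$b), directed = FALSE,
      vertices = data.frame(name = seq_len(n))
    )
    comp <- igraph::components(g)
    if (comp$no != 1L) {
      ts_error("ts_cyclic_adjacency_error",
               "fragment adjacency is disconnected or cyclic")
    }
  }
  if (is.null(root)) {
    root <- amt_default_root(fragset)
  }
  nbrs <- vector("list", n)
  for (r in seq_len(nrow(adj))) {
    nbrs[[adj$a[[r]]]] <- c(nbrs[[adj$a[[r]]]], list(list(other = adj$b[[r]], edge = r, fwd = TRUE)))
    nbrs[[adj$b[[r]]]] <- c(nbrs[[adj$b[[r]]]], list(list(other = adj$a[[r]], edge = r, fwd = FALSE)))
  }
  parent <- rep(NA_integer_, n)
  parent_edge <- rep(NA_integer_, n)
  parent_fwd <- rep(NA, n)
  children <- vector("list", n)
  subtree_size <- rep(0L, n)
  order_visit <- integer(0)
  stack <- root
  seen <- rep(FALSE, n)
  seen[root] <- TRUE
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    order_visit <- c(order_visit, v)
    for (nb in nbrs[[v]]) {
      if (seen[[nb$other]]) next
      seen[nb$other] <- TRUE
      parent[nb$other] <- v
      parent_edge[nb$other] <- nb$edge
      parent_fwd[nb$other] <- nb$fwd
      children[[v]] <- c(children[[v]], nb$other)
      stack <- c(stack, nb$other)
    }
  }
  if (!all(seen)) {
    ts_error("ts_cyclic_adjacency_error", "fragment adjacency is disconnected")
  }
  for (v in rev(order_visit)) {
    subtree_size[v] <- frag_n_heavy(fragset$fragments[[v]]) +
      sum(subtree_size[children[[v]]])
  }
  if (config$child_order == "size") {
    smiles <- vapply(fragset$fragments, function(f) f$smiles, character(1))
    for (v in seq_len(n)) {
      ch <- children[[v]]
      if (length(ch) > 1L) {
        ord <- order(-subtree_size[ch], smiles[ch], ch, method = "radix")
        children[[v]] <- ch[ord]
      }
    }
  }
  structure(
    list(
      nodes = fragset$fragments, children = children, parent = parent,
      parent_edge = parent_edge, parent_fwd = parent_fwd,
      edges = adj, root = root,
      scheme = fragset$scheme, style = fragset$style,
      source = fragset$source
    ),
    class = "ts_amt"
  )
}

amt_default_root <- function(fragset) {
  roles <- vapply(fragset$fragments, function(f) f$role, character(1))
  holds_first <- vapply(fragset$fragments, function(f) 1L %in% f$src_atoms, logical(1))
  cand <- which(holds_first & roles != "connector")
  if (!length(cand)) cand <- which(holds_first)
  if (!length(cand)) cand <- 1L
  cand[[1]]
}

#' @export
print.ts_amt <- function(x, ...) {
  cat(sprintf(
    "<ts_amt: %s/%s, %d node(s), root = %s>\n",
    x$scheme, x$style, length(x$nodes), x$nodes[[x$root]]$smiles
  ))
  invisible(x)
}

#' Enumerate rooted trees over one fragment set
#'
#' One AMT per fragment chosen as root; all share the same edge set. Used
#' for data augmentation by root enumeration.
#'
#' @inheritParams build_amt
#' @return a list of `ts_amt` objects, one per fragment.
#' @export
enumerate_roots <- function(fragset, config = ts_config()) {
  lapply(seq_along(fragset$fragments), function(r) {
    build_amt(fragset, root = r, config = config)
  })
}
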