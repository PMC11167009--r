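# Internal molecular-graph model. Atoms and bonds live in tibbles; bond
# orders are kekulized (1/2/3) as emitted by Open Babel, and implicit
# hydrogens are never materialised - the valence model fills them in.
# Dummy attachment atoms use element "*" (isotope field carries the cut id).

new_mol_graph <- function(atoms, bonds, smiles = NA_character_) {
  structure(
    list(atoms = atoms, bonds = bonds, smiles = smiles),
    class = "mol_graph"
  )
}

mol_graph_empty_atoms <- function() {
  tibble::tibble(
    element = character(0), charge = integer(0),
    iso = integer(0), aromatic = logical(0)
  )
}

mol_graph_empty_bonds <- function() {
  tibble::tibble(i = integer(0), j = integer(0), order = integer(0))
}

is_mol_graph <- function(x) inherits(x, "mol_graph")

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf(
    "<mol_graph: %d atoms (%d heavy), %d bonds>  %s\n",
    nrow(x$atoms), mg_n_heavy(x), nrow(x$bonds),
    if (is.na(x$smiles)) "" else x$smiles
  ))
  invisible(x)
}

# number of real heavy atoms (dummies and H excluded)
mg_n_heavy <- function(mol) {
  sum(!mol$atoms$element %in% c("H", "*"))
}

mg_dummy_atoms <- function(mol) which(mol$atoms$element == "*")

# ---- V2000 MOL block text ------------------------------------------------

# Charges use M CHG, isotope labels M ISO (that is how dummy-atom cut ids
# ride through Open Babel).
mg_to_molblock <- function(mol, title = "") {
  n <- nrow(mol$atoms)
  b <- nrow(mol$bonds)
  lines <- c(
    title, " tsmiles", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, b),
    sprintf(
      "    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
      mol$atoms$element
    )
  )
  if (b > 0L) {
    lines <- c(lines, sprintf(
      "%3d%3d%3d  0  0  0  0", mol$bonds$i, mol$bonds$j, mol$bonds$order
    ))
  }
  prop_lines <- function(tag, idx, val) {
    out <- character(0)
    while (length(idx) > 0L) {
      k <- min(8L, length(idx))
      out <- c(out, sprintf(
        "M  %s%3d%s", tag, k,
        paste0(sprintf("%4d%4d", idx[seq_len(k)], val[seq_len(k)]), collapse = "")
      ))
      idx <- idx[-seq_len(k)]
      val <- val[-seq_len(k)]
    }
    out
  }
  chg <- which(mol$atoms$charge != 0L)
  if (length(chg)) lines <- c(lines, prop_lines("CHG", chg, mol$atoms$charge[chg]))
  iso <- which(mol$atoms$iso != 0L)
  if (length(iso)) lines <- c(lines, prop_lines("ISO", iso, mol$atoms$iso[iso]))
  paste(c(lines, "M  END", "$$$$", ""), collapse = "\n")
}

# Parse the first V2000 record of an SDF string (as produced by Open Babel).
# Explicit hydrogens are folded away after the valence bookkeeping is done by
# the caller; here they are kept so that hypervalent inputs stay detectable.
mg_from_molblock <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4L) return(NULL)
  counts <- lines[[4]]
  n <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  b <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
  if (is.na(n) || is.na(b) || n < 1L) return(NULL)
  if (length(lines) < 4L + n + b) return(NULL)
  atom_lines <- lines[4L + seq_len(n)]
  element <- trimws(substr(atom_lines, 32L, 34L))
  old_chg_code <- suppressWarnings(as.integer(substr(atom_lines, 37L, 39L)))
  old_chg_code[is.na(old_chg_code)] <- 0L
  charge <- dplyr::case_when(
    old_chg_code == 1L ~ 3L, old_chg_code == 2L ~ 2L, old_chg_code == 3L ~ 1L,
    old_chg_code == 5L ~ -1L, old_chg_code == 6L ~ -2L, old_chg_code == 7L ~ -3L,
    TRUE ~ 0L
  )
  iso <- integer(n)
  # explicit valence marking (field 7 after the symbol; 0 = default, 15 = none)
  val_field <- vapply(atom_lines, function(ln) {
    fs <- strsplit(trimws(substr(ln, 35L, 70L)), "[[:space:]]+")[[1]]
    if (length(fs) >= 6L) suppressWarnings(as.integer(fs[[6]])) else 0L
  }, integer(1), USE.NAMES = FALSE)
  val_field[is.na(val_field) | val_field == 15L] <- 0L
  bond_lines <- if (b > 0L) lines[4L + n + seq_len(b)] else character(0)
  bi <- suppressWarnings(as.integer(substr(bond_lines, 1L, 3L)))
  bj <- suppressWarnings(as.integer(substr(bond_lines, 4L, 6L)))
  bo <- suppressWarnings(as.integer(substr(bond_lines, 7L, 9L)))
  # property block
  for (ln in lines[-seq_len(4L + n + b)]) {
    tag <- substr(ln, 1L, 6L)
    if (tag %in% c("M  CHG", "M  ISO")) {
      k <- as.integer(substr(ln, 7L, 9L))
      for (e in seq_len(k)) {
        off <- 9L + (e - 1L) * 8L
        idx <- as.integer(substr(ln, off + 1L, off + 4L))
        val <- as.integer(substr(ln, off + 5L, off + 8L))
        if (tag == "M  CHG") charge[idx] <- val else iso[idx] <- val
      }
    }
    if (identical(trimws(ln), "M  END")) break
  }
  atoms <- tibble::tibble(
    element = element, charge = charge, iso = iso,
    aromatic = rep(FALSE, n), expl_val = val_field
  )
  bonds <- tibble::tibble(i = bi, j = bj, order = bo)
  new_mol_graph(atoms, bonds)
}

# Drop explicit hydrogen atoms (their valence contribution becomes implicit).
mg_drop_explicit_h <- function(mol) {
  h <- which(mol$atoms$element == "H")
  if (!length(h)) return(mol)
  keep <- setdiff(seq_len(nrow(mol$atoms)), h)
  mg_induced_subgraph(mol, keep)
}

# Induced subgraph on `keep` (source order preserved); attr "map" gives
# old index -> new index (NA when dropped).
mg_induced_subgraph <- function(mol, keep) {
  map <- rep(NA_integer_, nrow(mol$atoms))
  map[keep] <- seq_along(keep)
  bonds <- mol$bonds[mol$bonds$i %in% keep & mol$bonds$j %in% keep, , drop = FALSE]
  bonds$i <- map[bonds$i]
  bonds$j <- map[bonds$j]
  out <- new_mol_graph(mol$atoms[keep, , drop = FALSE], bonds)
  attr(out, "map") <- map
  out
}

# ---- valence model -------------------------------------------------------

# Allowed total bond-order sums for neutral atoms; implicit H fills up to the
# smallest allowed value that is >= the explicit sum.
.valence_table <- list(
  H = 1L, B = 3L, C = 4L, N = 3L, O = 2L, F = 1L,
  Si = 4L, P = c(3L, 5L), S = c(2L, 4L, 6L),
  Cl = 1L, Br = 1L, I = 1L
)

# Maximum allowed bond-order sum for an atom, charge-adjusted; NA = unchecked.
mg_max_valence <- function(element, charge) {
  if (element == "*") return(NA_integer_)
  v <- .valence_table[[element]]
  if (is.null(v)) return(NA_integer_)
  vmax <- max(v)
  if (charge > 0L && element %in% c("N", "O", "S", "P", "C")) vmax <- vmax + charge
  if (charge < 0L) vmax <- vmax + charge  # anions lose binding slots
  vmax
}

# Bond-order sum per atom (explicit neighbours only).
mg_degree_order <- function(mol) {
  n <- nrow(mol$atoms)
  s <- numeric(n)
  if (nrow(mol$bonds)) {
    ii <- c(mol$bonds$i, mol$bonds$j)
    oo <- c(mol$bonds$order, mol$bonds$order)
    agg <- tapply(oo, ii, sum)
    s[as.integer(names(agg))] <- agg
  }
  as.integer(s)
}

# TRUE when every atom respects its valence table entry. An explicit valence
# marking in the MOL block (e.g. from "[CH5]") overrides the bond-order sum
# when larger, so hypervalent bracket atoms are caught.
mg_valence_ok <- function(mol) {
  s <- mg_degree_order(mol)
  ev <- mol$atoms[["expl_val"]]
  if (!is.null(ev)) s <- pmax(s, ifelse(is.na(ev), 0L, ev))
  for (k in seq_len(nrow(mol$atoms))) {
    vmax <- mg_max_valence(mol$atoms$element[[k]], mol$atoms$charge[[k]])
    if (!is.na(vmax) && s[[k]] > vmax) return(FALSE)
  }
  TRUE
}

# Free valence slots per atom (NA-valence elements get Inf).
mg_free_valence <- function(mol) {
  s <- mg_degree_order(mol)
  vapply(seq_len(nrow(mol$atoms)), function(k) {
    vmax <- mg_max_valence(mol$atoms$element[[k]], mol$atoms$charge[[k]])
    if (is.na(vmax)) Inf else vmax - s[[k]]
  }, numeric(1))
}

# ---- ring perception -----------------------------------------------------

mg_igraph <- function(mol) {
  igraph::graph_from_data_frame(
    d = data.frame(from = mol$bonds$i, to = mol$bonds$j),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(mol$atoms)))
  )
}

# Logical vector over bonds: TRUE when the bond lies on a cycle.
mg_ring_bonds <- function(mol) {
  if (!nrow(mol$bonds)) return(logical(0))
  g <- mg_igraph(mol)
  br <- igraph::bridges(g)
  in_ring <- rep(TRUE, nrow(mol$bonds))
  in_ring[as.integer(br)] <- FALSE
  # isolated multi-component guard: an edge is a bridge or cyclic, nothing else
  in_ring
}

mg_ring_atoms <- function(mol) {
  rb <- mg_ring_bonds(mol)
  sort(unique(c(mol$bonds$i[rb], mol$bonds$j[rb])))
}

# Fundamental cycle basis from a BFS spanning forest; each cycle is an
# integer vector of atom indices. Adequate ring set for junction clustering
# of drug-sized molecules.
mg_rings <- function(mol) {
  g <- mg_igraph(mol)
  n <- nrow(mol$atoms)
  if (!nrow(mol$bonds)) return(list())
  comps <- igraph::components(g)
  rings <- list()
  for (cid in seq_len(comps$no)) {
    verts <- which(comps$membership == cid)
    sub <- igraph::induced_subgraph(g, verts)
    vnames <- as.integer(igraph::V(sub)$name)
    bfs <- igraph::bfs(sub, root = 1, father = TRUE)
    father <- as.integer(bfs$father)
    tree_edges <- cbind(seq_along(father), father)
    tree_edges <- tree_edges[!is.na(tree_edges[, 2]), , drop = FALSE]
    el <- igraph::as_edgelist(sub, names = FALSE)
    in_tree <- rep(FALSE, nrow(el))
    if (nrow(tree_edges)) {
      tree_key <- paste(pmin(tree_edges[, 1], tree_edges[, 2]),
                        pmax(tree_edges[, 1], tree_edges[, 2]))
      edge_key <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
      in_tree <- edge_key %in% tree_key
    }
    # path to root for each vertex
    path_up <- function(v) {
      p <- v
      while (!is.na(father[v])) {
        v <- father[v]
        p <- c(p, v)
      }
      p
    }
    for (eix in which(!in_tree)) {
      a <- el[eix, 1]; b <- el[eix, 2]
      pa <- path_up(a); pb <- path_up(b)
      common <- intersect(pa, pb)
      meet <- common[[1]]
      cyc <- c(pa[seq_len(match(meet, pa))], rev(pb[seq_len(match(meet, pb) - 1L)]))
      rings[[length(rings) + 1L]] <- sort(vnames[cyc])
    }
  }
  rings
}
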