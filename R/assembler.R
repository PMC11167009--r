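# Molecular reassembly: root-outward, one neighbourhood at a time. Dummy
# styles fuse matching attachment points into real bonds; the shared-atom
# style superposes one atom (or one bond, for fused ring clusters) of the
# child onto the growing partial molecule. When a join admits several legal
# candidates the selector picks one: that choice is where training-free
# novelty comes from.

#' Create an assembly selector
#'
#' @param mode `"record"` reproduces the recorded decomposition (falls back
#'   to first-available deterministic pairing for strings without records);
#'   `"random"` draws one candidate uniformly at every join; `"scored"`
#'   draws `n_candidates` complete random assemblies and keeps the one with
#'   the highest `scorer` value.
#' @param seed optional integer making random/scored assembly reproducible.
#' @param scorer function mapping a SMILES string to a score in `[0, 1]`.
#' @param n_candidates number of complete assemblies drawn in scored mode.
#' @return an `assembly_selector` list.
#' @export
assembly_selector <- function(mode = c("record", "random", "scored"),
                              seed = NULL, scorer = NULL, n_candidates = 10L) {
  mode <- match.arg(mode)
  if (mode == "scored" && !is.function(scorer)) {
    ts_error("ts_selector_error", "scored mode needs a scorer function")
  }
  structure(
    list(mode = mode, seed = seed, scorer = scorer,
         n_candidates = as.integer(n_candidates)),
    class = "assembly_selector"
  )
}

# Evaluate code under a local RNG stream without touching the caller's seed.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# ---- assembly state ------------------------------------------------------

as_state_init <- function(frag, node) {
  g <- frag$graph
  open <- empty_attach()
  att <- frag$attach[frag$attach$kind == "dummy", , drop = FALSE]
  list(
    P = g,
    node_atoms = stats::setNames(list(seq_len(nrow(g$atoms))), node),
    open = tibble::tibble(
      p_atom = att$atom, cut_id = att$cut_id, order = att$order,
      node = rep(node, nrow(att))
    ),
    src_map = stats::setNames(
      seq_len(nrow(g$atoms))[!is.na(frag$src_atoms)],
      frag$src_atoms[!is.na(frag$src_atoms)]
    )
  )
}

# Remap all state indices through `map` (old P index -> new P index).
# node_atoms vectors are positional (fragment-local index -> P index), so
# consumed atoms become NA but keep their slot.
as_state_remap <- function(st, map) {
  st$node_atoms <- lapply(st$node_atoms, function(v) map[v])
  st$open$p_atom <- map[st$open$p_atom]
  st$open <- st$open[!is.na(st$open$p_atom), , drop = FALSE]
  st$src_map <- {
    m <- map[st$src_map]
    names(m) <- names(st$src_map)
    m[!is.na(m)]
  }
  st
}

# Fuse one open dummy of P with one dummy of the child fragment: both dummies
# vanish and their heavy neighbours get a bond of the recorded order.
as_fuse_dummies <- function(st, open_row, child, node) {
  P <- st$P
  dp <- st$open$p_atom[[open_row]]
  child_att <- attr(child, "join_atom")
  dc <- child_att$atom
  ord <- child_att$order
  np <- c(P$bonds$j[P$bonds$i == dp], P$bonds$i[P$bonds$j == dp])[[1]]
  cg <- child$graph
  nc <- c(cg$bonds$j[cg$bonds$i == dc], cg$bonds$i[cg$bonds$j == dc])[[1]]
  keep_p <- setdiff(seq_len(nrow(P$atoms)), dp)
  subP <- mg_induced_subgraph(P, keep_p)
  mapP <- attr(subP, "map")
  keep_c <- setdiff(seq_len(nrow(cg$atoms)), dc)
  subC <- mg_induced_subgraph(cg, keep_c)
  mapC <- attr(subC, "map")
  off <- nrow(subP$atoms)
  newP <- new_mol_graph(
    atoms = dplyr::bind_rows(subP$atoms, subC$atoms),
    bonds = dplyr::bind_rows(
      subP$bonds,
      tibble::tibble(i = subC$bonds$i + off, j = subC$bonds$j + off,
                     order = subC$bonds$order),
      tibble::tibble(i = mapP[[np]], j = mapC[[nc]] + off, order = ord)
    )
  )
  st$open <- st$open[-open_row, , drop = FALSE]
  st <- as_state_remap(st, mapP)
  st$P <- newP
  # register child atoms (positional; the consumed dummy slot stays NA)
  st$node_atoms[[as.character(node)]] <- mapC + off
  catt <- child$attach[child$attach$kind == "dummy" & child$attach$atom != dc, ,
                       drop = FALSE]
  if (nrow(catt)) {
    st$open <- dplyr::bind_rows(st$open, tibble::tibble(
      p_atom = mapC[catt$atom] + off, cut_id = catt$cut_id,
      order = catt$order, node = node
    ))
  }
  if (any(!is.na(child$src_atoms))) {
    sel <- which(!is.na(child$src_atoms) & !is.na(mapC))
    add <- stats::setNames(mapC[sel] + off, child$src_atoms[sel])
    st$src_map <- c(st$src_map, add)
  }
  st
}

# Superpose child atoms onto P atoms. `pairs` is list(p = P atom indices,
# c = child atom indices); non-merged child atoms are appended.
as_merge_shared <- function(st, pairs, child, node) {
  P <- st$P
  cg <- child$graph
  nC <- nrow(cg$atoms)
  cmap <- rep(NA_integer_, nC)
  cmap[pairs$c] <- pairs$p
  newc <- setdiff(seq_len(nC), pairs$c)
  off <- nrow(P$atoms)
  cmap[newc] <- off + seq_along(newc)
  atoms <- dplyr::bind_rows(P$atoms, cg$atoms[newc, , drop = FALSE])
  bkey <- bond_key(P$bonds$i, P$bonds$j)
  add_bonds <- tibble::tibble(
    i = cmap[cg$bonds$i], j = cmap[cg$bonds$j], order = cg$bonds$order
  )
  dup <- bond_key(add_bonds$i, add_bonds$j) %in% bkey
  add_bonds <- add_bonds[!dup, , drop = FALSE]
  st$P <- new_mol_graph(atoms, bonds = dplyr::bind_rows(P$bonds, add_bonds))
  st$node_atoms[[as.character(node)]] <- cmap
  if (any(!is.na(child$src_atoms))) {
    sel <- which(!is.na(child$src_atoms))
    add <- stats::setNames(cmap[sel], child$src_atoms[sel])
    add <- add[!names(add) %in% names(st$src_map)]
    st$src_map <- c(st$src_map, add)
  }
  st
}

# ---- candidate enumeration ----------------------------------------------

# Dummy-style candidates: rows of st$open crossed with the child's dummies,
# compatible bond order required. Parent-local points are preferred; when the
# parent fragment has none left the search widens to the whole partial
# molecule (needed e.g. for the worked example's published layout, whose
# breadth-first order separates some branches from their true parents).
dummy_join_candidates <- function(st, child, parent_node, style, edge = NULL) {
  catt <- child$attach[child$attach$kind == "dummy", , drop = FALSE]
  if (!nrow(catt) || !nrow(st$open)) return(list())
  out <- list()
  if (style == "tsid" && any(catt$cut_id > 0L)) {
    for (r in seq_len(nrow(catt))) {
      id <- catt$cut_id[[r]]
      if (id <= 0L) next
      hit <- which(st$open$cut_id == id)
      for (h in hit) {
        out[[length(out) + 1L]] <- list(
          open_row = h, c_atom = catt$atom[[r]], order = catt$order[[r]]
        )
      }
    }
    return(out)
  }
  scope <- which(st$open$node == parent_node)
  if (!length(scope)) scope <- seq_len(nrow(st$open))
  for (h in scope) {
    for (r in seq_len(nrow(catt))) {
      if (st$open$order[[h]] != catt$order[[r]]) next
      out[[length(out) + 1L]] <- list(
        open_row = h, c_atom = catt$atom[[r]], order = catt$order[[r]]
      )
    }
  }
  out
}

# Shared-atom candidates: single-atom superpositions plus bond (two-atom)
# superpositions; element, charge and aromatic flag must match and the merged
# atom must keep a legal valence.
shared_join_candidates <- function(st, child, parent_node) {
  P <- st$P
  cg <- child$graph
  pa <- st$node_atoms[[as.character(parent_node)]]
  if (is.null(pa) || !length(pa)) pa <- seq_len(nrow(P$atoms))
  pa <- pa[!is.na(pa)]
  sP <- mg_degree_order(P)
  sC <- mg_degree_order(cg)
  out <- list()
  # element and charge must match and the merged atom must keep a legal
  # valence; aromaticity conflicts are left to the final sanitization.
  ok_atom <- function(p, cc, shared_ord = 0L) {
    if (P$atoms$element[[p]] == "*" || cg$atoms$element[[cc]] == "*") return(FALSE)
    if (P$atoms$element[[p]] != cg$atoms$element[[cc]]) return(FALSE)
    if (P$atoms$charge[[p]] != cg$atoms$charge[[cc]]) return(FALSE)
    vmax <- mg_max_valence(P$atoms$element[[p]], P$atoms$charge[[p]])
    if (is.na(vmax)) return(TRUE)
    sP[[p]] + sC[[cc]] - shared_ord <= vmax
  }
  for (p in pa) {
    for (cc in seq_len(nrow(cg$atoms))) {
      if (ok_atom(p, cc)) {
        out[[length(out) + 1L]] <- list(p = p, c = cc)
      }
    }
  }
  # bond superpositions (fused ring clusters share two atoms)
  pb <- P$bonds[P$bonds$i %in% pa & P$bonds$j %in% pa, , drop = FALSE]
  if (nrow(pb) && nrow(cg$bonds)) {
    for (r in seq_len(nrow(pb))) {
      for (q in seq_len(nrow(cg$bonds))) {
        if (pb$order[[r]] != cg$bonds$order[[q]]) next
        ord <- pb$order[[r]]
        for (orient in 1:2) {
          ci <- if (orient == 1L) cg$bonds$i[[q]] else cg$bonds$j[[q]]
          cj <- if (orient == 1L) cg$bonds$j[[q]] else cg$bonds$i[[q]]
          if (ok_atom(pb$i[[r]], ci, ord) && ok_atom(pb$j[[r]], cj, ord)) {
            out[[length(out) + 1L]] <- list(
              p = c(pb$i[[r]], pb$j[[r]]), c = c(ci, cj)
            )
          }
        }
      }
    }
  }
  out
}

# Record-based pairs for one AMT edge (exact reconstruction of the source).
record_join_pairs <- function(st, amt, v) {
  e <- amt$edges[amt$parent_edge[[v]], , drop = FALSE]
  if (!nrow(e) || is.na(e$kind)) return(NULL)
  fwd <- isTRUE(amt$parent_fwd[[v]])
  parent_local <- if (fwd) e$a_atoms[[1]] else e$b_atoms[[1]]
  child_local <- if (fwd) e$b_atoms[[1]] else e$a_atoms[[1]]
  if (!length(parent_local) || !length(child_local)) return(NULL)
  u <- amt$parent[[v]]
  pmapped <- st$node_atoms[[as.character(u)]][parent_local]
  if (any(is.na(pmapped))) return(NULL)
  list(kind = e$kind, p_atoms = pmapped, c_atoms = child_local,
       order = e$order, cut_id = e$cut_id)
}

# ---- single deterministic/stochastic pass --------------------------------

# One complete assembly pass over the AMT. `pick` chooses among candidates
# (gets the list, returns an index). Returns the state or raises
# ts_no_candidate_error.
assemble_pass <- function(amt, pick, use_records = TRUE) {
  style <- amt$style
  order_bfs <- integer(0)
  queue <- amt$root
  while (length(queue)) {
    v <- queue[[1]]; queue <- c(queue[-1], amt$children[[v]])
    order_bfs <- c(order_bfs, v)
  }
  st <- as_state_init(amt$nodes[[amt$root]], amt$root)
  n_cand <- integer(0)
  for (v in order_bfs[-1]) {
    child <- amt$nodes[[v]]
    u <- amt$parent[[v]]
    rec <- if (use_records) record_join_pairs(st, amt, v) else NULL
    if (style %in% c("tsdy", "tsid")) {
      if (!is.null(rec) && identical(rec$kind, "dummy")) {
        open_row <- which(st$open$p_atom == rec$p_atoms[[1]])
        if (length(open_row) != 1L) {
          ts_error("ts_no_candidate_error", "recorded attachment not open")
        }
        cand <- list(list(open_row = open_row, c_atom = rec$c_atoms[[1]],
                          order = st$open$order[[open_row]]))
        k <- 1L
      } else {
        cand <- dummy_join_candidates(st, child, u, style)
        if (!length(cand)) {
          ts_error("ts_no_candidate_error",
                   paste0("no legal attachment for fragment ", child$smiles))
        }
        k <- pick(cand)
      }
      ch <- cand[[k]]
      ca <- child$attach[child$attach$kind == "dummy" &
                           child$attach$atom == ch$c_atom, , drop = FALSE]
      attr(child, "join_atom") <- list(atom = ch$c_atom, order = ch$order)
      st <- as_fuse_dummies(st, ch$open_row, child, v)
      n_cand <- c(n_cand, length(cand))
    } else {
      if (!is.null(rec) && identical(rec$kind, "shared")) {
        cand <- list(list(p = rec$p_atoms, c = rec$c_atoms))
        k <- 1L
      } else {
        cand <- shared_join_candidates(st, child, u)
        if (!length(cand)) {
          ts_error("ts_no_candidate_error",
                   paste0("no legal superposition for fragment ", child$smiles))
        }
        k <- pick(cand)
      }
      pairs <- cand[[k]]
      # complete the merge with any child atoms whose source atom is already
      # placed (junction clusters can share atoms beyond the tree edge)
      if (use_records && any(!is.na(child$src_atoms))) {
        extra_c <- which(!is.na(child$src_atoms) &
                           as.character(child$src_atoms) %in% names(st$src_map))
        extra_c <- setdiff(extra_c, pairs$c)
        if (length(extra_c)) {
          pairs$p <- c(pairs$p,
                       st$src_map[as.character(child$src_atoms[extra_c])])
          pairs$c <- c(pairs$c, extra_c)
        }
      }
      st <- as_merge_shared(st, pairs, child, v)
      n_cand <- c(n_cand, length(cand))
    }
  }
  st$n_candidates <- n_cand
  st
}

# Drop unresolved dummy atoms (repair) or fail.
as_finalize <- function(st, repair = FALSE) {
  dummies <- mg_dummy_atoms(st$P)
  repairs <- 0L
  if (length(dummies)) {
    if (!repair) {
      ts_error("ts_no_candidate_error",
               paste0(length(dummies), " unresolved attachment point(s)"))
    }
    repairs <- length(dummies)
    keep <- setdiff(seq_len(nrow(st$P$atoms)), dummies)
    st$P <- mg_induced_subgraph(st$P, keep)
    # keep the largest connected component if the repair disconnected it
    memb <- mg_components_without(st$P, integer(0))
    if (length(unique(memb)) > 1L) {
      big <- as.integer(names(which.max(table(memb))))
      st$P <- mg_induced_subgraph(st$P, which(memb == big))
    }
  }
  st$repairs <- repairs
  st
}

new_assembly <- function(mol, smiles, valid, score = NA_real_,
                         n_candidates = integer(0), repairs = 0L,
                         fallback = FALSE) {
  structure(
    list(mol = mol, smiles = smiles, valid = valid, score = score,
         n_candidates = n_candidates, repairs = repairs, fallback = fallback),
    class = "ts_assembly"
  )
}

#' @export
print.ts_assembly <- function(x, ...) {
  cat(sprintf("<ts_assembly: %s%s>\n",
              if (is.na(x$smiles)) "<failed>" else x$smiles,
              if (x$valid) "" else " (invalid)"))
  invisible(x)
}

#' Assemble a molecule from an acyclic molecular tree
#'
#' Root-outward greedy assembly, one neighbourhood at a time. With an
#' ID-labelled tree (TSID) the result is unique; otherwise the selector
#' resolves multi-candidate joins. Random assemblies that fail sanitization
#' are redrawn (bounded), then the recorded decomposition is used as
#' fallback when available, so reconstruction of a molecule's own tree
#' always yields a valid molecule.
#'
#' @param amt a `ts_amt`.
#' @param selector an [assembly_selector()].
#' @param repair drop unresolved attachment points instead of failing.
#' @param max_attempts redraw budget for random assemblies.
#' @return a `ts_assembly` with fields `mol`, `smiles`, `valid`, `score`,
#'   `n_candidates`, `repairs`, `fallback`.
#' @export
assemble <- function(amt, selector = assembly_selector("record"),
                     repair = FALSE, max_attempts = 20L) {
  if (selector$mode == "scored") {
    return(goal_directed_select(amt, selector$scorer, selector$n_candidates,
                                seed = selector$seed, repair = repair))
  }
  with_local_seed(selector$seed, {
    if (selector$mode == "record") {
      st <- assemble_pass(amt, pick = function(cand) 1L, use_records = TRUE)
      st <- as_finalize(st, repair)
      return(assembly_from_state(st))
    }
    # random mode: records are ignored so novelty can arise
    last_err <- NULL
    for (att in seq_len(max_attempts)) {
      st <- tryCatch(
        assemble_pass(amt, pick = function(cand) sample.int(length(cand), 1L),
                      use_records = FALSE),
        ts_error = function(e) e
      )
      if (!inherits(st, "condition")) {
        st <- tryCatch(as_finalize(st, repair), ts_error = function(e) e)
      }
      if (!inherits(st, "condition")) {
        res <- assembly_from_state(st)
        if (res$valid) return(res)
      } else {
        last_err <- st
      }
    }
    # fallback: recorded decomposition (exact source) when available
    st <- tryCatch(
      assemble_pass(amt, pick = function(cand) 1L, use_records = TRUE),
      ts_error = function(e) e
    )
    if (!inherits(st, "condition")) {
      st <- tryCatch(as_finalize(st, repair), ts_error = function(e) e)
    }
    if (inherits(st, "condition")) {
      if (!is.null(last_err)) rlang::cnd_signal(last_err)
      rlang::cnd_signal(st)
    }
    res <- assembly_from_state(st)
    res$fallback <- TRUE
    res
  })
}

assembly_from_state <- function(st) {
  mol <- st$P
  ok <- mg_sanitize_ok(mol)
  smi <- if (ok) ob_molblock_to_smiles(mg_to_molblock(mol)) else NA_character_
  mol$smiles <- smi
  new_assembly(
    mol = if (ok) mol else NULL, smiles = smi, valid = ok,
    n_candidates = st$n_candidates %||% integer(0),
    repairs = st$repairs %||% 0L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Enumerate candidate joins of one fragment onto a partial molecule
#'
#' Low-level surface of the assembly step: all sanitization-passing ways to
#' attach `child` to `partial` under a code style. For ID-labelled dummies
#' the candidate is unique; unlabelled dummies give one candidate per
#' compatible dummy pairing; shared-atom style gives one candidate per legal
#' atom (or bond) superposition.
#'
#' @param partial a `mol_graph`, possibly with open dummy atoms (or a
#'   `ts_fragment`).
#' @param child a `ts_fragment` (e.g. from a tokenized string) or a SMILES
#'   string for one fragment.
#' @param style one of `"tssa"`, `"tsdy"`, `"tsid"`.
#' @return a list of candidate `mol_graph`s (each sanitizable; dummies may
#'   remain open if either side has further attachment points).
#' @export
join_pair <- function(partial, child, style = c("tssa", "tsdy", "tsid")) {
  style <- match.arg(style)
  if (is.character(child)) child <- parse_fragment_token(child, style)
  if (inherits(partial, "ts_fragment")) partial <- partial$graph
  if (is.character(partial)) partial <- parse_fragment_token(partial, style)$graph
  host <- structure(
    list(graph = partial, smiles = NA_character_,
         attach = {
           d <- mg_dummy_atoms(partial)
           ords <- vapply(d, function(k) {
             sel <- partial$bonds$i == k | partial$bonds$j == k
             if (!any(sel)) 1L else partial$bonds$order[sel][[1]]
           }, integer(1))
           tibble::tibble(atom = d, kind = rep("dummy", length(d)),
                          cut_id = partial$atoms$iso[d], order = ords)
         },
         src_atoms = rep(NA_integer_, nrow(partial$atoms)), role = "cluster"),
    class = "ts_fragment"
  )
  st0 <- as_state_init(host, 1L)
  out <- list()
  keys <- character(0)
  add_candidate <- function(g) {
    can <- ob_molblock_to_smiles(mg_to_molblock(g))
    if (is.na(can) || can %in% keys) return()
    keys <<- c(keys, can)
    g$smiles <- can
    out[[length(out) + 1L]] <<- g
  }
  if (style %in% c("tsdy", "tsid")) {
    cand <- dummy_join_candidates(st0, child, 1L, style)
    for (ch in cand) {
      child2 <- child
      attr(child2, "join_atom") <- list(atom = ch$c_atom, order = ch$order)
      st <- as_fuse_dummies(st0, ch$open_row, child2, 2L)
      if (mg_valence_ok(st$P)) add_candidate(st$P)
    }
  } else {
    cand <- shared_join_candidates(st0, child, 1L)
    for (pairs in cand) {
      st <- as_merge_shared(st0, pairs, child, 2L)
      if (mg_valence_ok(st$P)) add_candidate(st$P)
    }
  }
  out
}

#' Decode a tree-SMILES string into a molecule
#'
#' [ts_parse()] + [fbt_to_amt()] + [assemble()].
#'
#' @param s a tree-SMILES string.
#' @param style the code style of the string.
#' @param selector an [assembly_selector()].
#' @param repair tolerate malformed streams and unresolved attachments.
#' @return a `ts_assembly`.
#' @examples
#' ts_decode("CCO&&&", style = "vanilla")
#' @export
ts_decode <- function(s, style = ts_styles,
                      selector = assembly_selector("record"), repair = FALSE) {
  style <- match.arg(style, ts_styles)
  fbt <- ts_parse(s, style, repair = repair)
  amt <- fbt_to_amt(fbt)
  res <- assemble(amt, selector, repair = repair)
  res$repairs <- res$repairs + attr(fbt, "repairs")
  res
}

#' Goal-directed assembly
#'
#' Draws `n_candidates` complete random assemblies of the tree and returns
#' the one with the highest score.
#'
#' @param amt a `ts_amt`.
#' @param scorer function: SMILES string -> numeric score in `[0, 1]`.
#' @param n_candidates number of random assemblies to draw.
#' @param seed optional integer for reproducibility.
#' @param repair passed to [assemble()].
#' @return a `ts_assembly` with the winning score in `$score`.
#' @export
goal_directed_select <- function(amt, scorer, n_candidates = 10L, seed = NULL,
                                 repair = FALSE) {
  stopifnot(is.function(scorer))
  with_local_seed(seed, {
    best <- NULL
    for (k in seq_len(n_candidates)) {
      res <- assemble(amt, assembly_selector("random"), repair = repair)
      if (!res$valid) next
      res$score <- as.numeric(scorer(res$smiles))
      if (is.null(best) || isTRUE(res$score > best$score)) best <- res
    }
    if (is.null(best)) {
      ts_error("ts_no_candidate_error", "no valid assembly could be drawn")
    }
    best
  })
}

#' Training-free generation by corpus reconstruction
#'
#' Every input molecule is fragmented and its own tree is reassembled under
#' the selector; with random selection this is the training-free generator
#' (novel molecules arise from alternative legal attachments). Output has
#' one row per input; failures are reported, never dropped.
#'
#' @param smiles character vector of SMILES (or data frame with a `smiles`
#'   column).
#' @inheritParams fragment_molecule
#' @param selector an [assembly_selector()]; the default draws random
#'   attachments.
#' @param config a [ts_config()].
#' @return a tibble with columns `source` (canonical), `generated`, `valid`,
#'   `fallback`, `error`.
#' @export
reconstruct_corpus <- function(smiles, scheme = ts_schemes, style = ts_styles,
                               selector = assembly_selector("random", seed = 1L),
                               config = ts_config()) {
  if (is.data.frame(smiles)) smiles <- smiles$smiles
  scheme <- match.arg(scheme, ts_schemes)
  style <- match.arg(style, ts_styles)
  seeds <- if (is.null(selector$seed)) rep(list(NULL), length(smiles)) else
    as.list(selector$seed + seq_along(smiles) - 1L)
  rows <- purrr::map2(smiles, seeds, function(s, sd) {
    sel <- selector
    sel$seed <- sd
    res <- tryCatch({
      mol <- parse_molecule(s)
      fs <- fragment_molecule(mol, scheme, style, config)
      amt <- build_amt(fs, config = config)
      out <- assemble(amt, sel)
      tibble::tibble(source = write_canonical(mol), generated = out$smiles,
                     valid = out$valid, fallback = out$fallback,
                     error = NA_character_)
    }, error = function(e) tibble::tibble(
      source = s, generated = NA_character_, valid = FALSE, fallback = FALSE,
      error = conditionMessage(e)
    ))
    res
  })
  dplyr::bind_rows(rows)
}
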