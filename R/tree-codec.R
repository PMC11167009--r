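# AMT <-> FBT conversion and FBT <-> string serialisation. The string
# grammar adds exactly two symbols to SMILES: "&" (empty tree node / branch
# end) and "^" (separator between two adjacent fragment tokens).

# Full binary tree over fragment payloads. `payload[[k]]` is NULL for an
# empty node, otherwise list(frag = ts_fragment, edge = adjacency row or
# NULL, fwd = orientation of that row). Empty nodes are leaves; fragment
# nodes always have both children.
new_fbt <- function(payload, left, right, root, scheme = NA, style = NA) {
  structure(
    list(payload = payload, left = left, right = right, root = root,
         scheme = scheme, style = style),
    class = "ts_fbt"
  )
}

#' Convert an acyclic molecular tree to a full binary tree
#'
#' Child-side convention: the left child of a node holds its next sibling
#' (in the AMT child order), the right child holds its first child; missing
#' positions become empty "&" nodes. The transform is invertible via
#' [fbt_to_amt()].
#'
#' @param amt a `ts_amt` from [build_amt()].
#' @return a `ts_fbt`.
#' @export
amt_to_fbt <- function(amt) {
  payload <- list(); left <- integer(0); right <- integer(0)
  new_node <- function(p) {
    payload[length(payload) + 1L] <<- list(p)
    left <<- c(left, 0L); right <<- c(right, 0L)
    length(payload)
  }
  build_chain <- function(vs) {
    if (!length(vs)) return(new_node(NULL))
    v <- vs[[1]]
    edge <- if (is.na(amt$parent_edge[[v]])) NULL else
      amt$edges[amt$parent_edge[[v]], , drop = FALSE]
    id <- new_node(list(frag = amt$nodes[[v]], edge = edge,
                        fwd = amt$parent_fwd[[v]]))
    l <- build_chain(vs[-1])
    r <- build_chain(amt$children[[v]])
    left[[id]] <<- l; right[[id]] <<- r
    id
  }
  root_id <- build_chain(amt$root)
  new_fbt(payload, left, right, root_id, scheme = amt$scheme, style = amt$style)
}

fbt_is_empty_node <- function(fbt, k) is.null(fbt$payload[[k]])

fbt_n_fragments <- function(fbt) {
  sum(!vapply(seq_along(fbt$payload), fbt_is_empty_node, logical(1), fbt = fbt))
}

fbt_check <- function(fbt) {
  for (k in seq_along(fbt$payload)) {
    if (fbt_is_empty_node(fbt, k)) {
      if (fbt$left[[k]] != 0L || fbt$right[[k]] != 0L) {
        ts_error("ts_malformed_tree_error", "empty node with children")
      }
    } else if (fbt$left[[k]] == 0L || fbt$right[[k]] == 0L) {
      ts_error("ts_malformed_tree_error", "fragment node lacks two children")
    }
  }
  invisible(TRUE)
}

#' Convert a full binary tree back to an acyclic molecular tree
#'
#' Exact inverse of [amt_to_fbt()] under the same child-side convention.
#'
#' @param fbt a `ts_fbt`.
#' @param source optional source molecule to attach to the result.
#' @return a `ts_amt`.
#' @export
fbt_to_amt <- function(fbt, source = NULL) {
  if (fbt_is_empty_node(fbt, fbt$root)) {
    ts_error("ts_malformed_tree_error", "root of the tree carries no fragment")
  }
  fbt_check(fbt)
  nodes <- list(); children <- list(); parent <- integer(0)
  parent_edge_rows <- list(); parent_fwd <- logical(0)
  add_node <- function(frag, par) {
    nodes[[length(nodes) + 1L]] <<- frag
    children[[length(children) + 1L]] <<- integer(0)
    parent <<- c(parent, par)
    parent_edge_rows[length(parent_edge_rows) + 1L] <<- list(NULL)
    parent_fwd <<- c(parent_fwd, NA)
    length(nodes)
  }
  # chain of fragment siblings hanging off a first-child pointer
  sibling_chain <- function(k) {
    out <- integer(0)
    while (k != 0L && !fbt_is_empty_node(fbt, k)) {
      out <- c(out, k)
      k <- fbt$left[[k]]
    }
    out
  }
  walk <- function(k, par) {
    p <- fbt$payload[[k]]
    v <- add_node(p$frag, par)
    if (!is.null(p$edge)) parent_edge_rows[v] <<- list(p$edge)
    parent_fwd[[v]] <<- if (is.null(p$fwd)) NA else p$fwd
    if (!is.na(par)) children[[par]] <<- c(children[[par]], v)
    for (ck in sibling_chain(fbt$right[[k]])) walk(ck, v)
    v
  }
  root <- walk(fbt$root, NA_integer_)
  edges <- empty_adjacency()
  parent_edge <- rep(NA_integer_, length(nodes))
  for (v in seq_along(nodes)) {
    if (is.na(parent[[v]])) next
    row <- parent_edge_rows[[v]]
    if (is.null(row)) {
      row <- tibble::tibble(
        a = parent[[v]], b = v, cut_id = NA_integer_,
        kind = if (identical(fbt$style, "tssa")) "shared" else "dummy",
        order = NA_integer_, a_atoms = list(integer(0)), b_atoms = list(integer(0))
      )
      fwd <- TRUE
    } else {
      fwd <- parent_fwd[[v]]
      if (isTRUE(fwd)) { row$a <- parent[[v]]; row$b <- v }
      else { row$b <- parent[[v]]; row$a <- v }
    }
    edges <- dplyr::bind_rows(edges, row)
    parent_edge[[v]] <- nrow(edges)
  }
  structure(
    list(nodes = nodes, children = children, parent = parent,
         parent_edge = parent_edge,
         parent_fwd = ifelse(is.na(parent_fwd), TRUE, parent_fwd),
         edges = edges, root = root,
         scheme = fbt$scheme, style = fbt$style, source = source),
    class = "ts_amt"
  )
}

#' Serialise a full binary tree to a tree-SMILES string
#'
#' Breadth-first (level-order) traversal: empty nodes emit `&`, fragment
#' nodes emit their SMILES; `^` separates two adjacent fragment tokens and
#' one trailing `&` sentinel is appended.
#'
#' @param fbt a `ts_fbt`.
#' @return a single string.
#' @export
ts_serialize <- function(fbt) {
  fbt_check(fbt)
  queue <- fbt$root
  toks <- character(0)
  while (length(queue)) {
    k <- queue[[1]]; queue <- queue[-1]
    if (fbt_is_empty_node(fbt, k)) {
      toks <- c(toks, "&")
    } else {
      toks <- c(toks, fbt$payload[[k]]$frag$smiles)
      queue <- c(queue, fbt$left[[k]], fbt$right[[k]])
    }
  }
  toks <- c(toks, "&")
  out <- character(0)
  prev_frag <- FALSE
  for (t in toks) {
    is_frag <- !t %in% c("&")
    if (is_frag && prev_frag) out <- c(out, "^")
    out <- c(out, t)
    prev_frag <- is_frag
  }
  paste(out, collapse = "")
}

#' Tokenize a tree-SMILES string
#'
#' Maximal runs of characters other than `&` and `^` become fragment tokens;
#' whitespace is stripped first.
#'
#' @param s a single string.
#' @return a tibble with columns `token` and `type`
#'   (`"FRAG"`, `"AMP"`, `"CARET"`).
#' @export
ts_tokenize <- function(s) {
  if (!is.character(s) || length(s) != 1L || is.na(s)) {
    ts_error("ts_empty_string_error", "input must be a single string")
  }
  s <- gsub("[[:space:]]", "", s)
  if (!nzchar(s)) ts_error("ts_empty_string_error", "empty tree-SMILES string")
  toks <- regmatches(s, gregexpr("[^&^]+|&|\\^", s))[[1]]
  tibble::tibble(
    token = toks,
    type = dplyr::case_when(
      toks == "&" ~ "AMP",
      toks == "^" ~ "CARET",
      TRUE ~ "FRAG"
    )
  )
}

# Wrap a parsed token graph as a ts_fragment; dummy attachment points keep
# their order of appearance in the token.
fragment_from_graph <- function(mol, text) {
  dummies <- mg_dummy_atoms(mol)
  attach <- empty_attach()
  if (length(dummies)) {
    ords <- vapply(dummies, function(d) {
      sel <- mol$bonds$i == d | mol$bonds$j == d
      if (!any(sel)) 1L else mol$bonds$order[sel][[1]]
    }, integer(1))
    attach <- tibble::tibble(
      atom = dummies, kind = "dummy",
      cut_id = mol$atoms$iso[dummies], order = ords
    )
  }
  structure(
    # the fragment keeps its token spelling; canonical form is computed on
    # demand via write_canonical()
    list(graph = mol, smiles = gsub("[[:space:]]", "", text), attach = attach,
         src_atoms = rep(NA_integer_, nrow(mol$atoms)), role = "cluster"),
    class = "ts_fragment"
  )
}

# Parse one fragment token into a ts_fragment.
parse_fragment_token <- function(text, style) {
  mol <- tryCatch(
    parse_molecule(text, canonicalize = FALSE),
    ts_error = function(e) {
      ts_error("ts_fragment_parse_error",
               paste0("fragment token is not valid SMILES: ", text),
               parent = e)
    }
  )
  fragment_from_graph(mol, text)
}

# Parse many fragment tokens with a single conversion call. Returns a list
# named by token; entries are NULL where the token did not parse (callers
# fall back to parse_fragment_token for error classification).
parse_fragment_tokens <- function(texts, style) {
  texts <- unique(texts)
  out <- stats::setNames(vector("list", length(texts)), texts)
  ok <- nzchar(texts) & !grepl(".", texts, fixed = TRUE) &
    vapply(texts, smiles_precheck, logical(1))
  if (!any(ok)) return(out)
  src <- paste0(texts[ok], " ix", which(ok), collapse = "\n")
  sdf <- ob_convert("SMI", "SDF", src)
  if (!nzchar(sdf)) return(out)
  records <- strsplit(sdf, "$$$$\n", fixed = TRUE)[[1]]
  for (rec in records) {
    lines1 <- sub("\n.*$", "", rec)
    ix <- suppressWarnings(as.integer(sub("^\\s*ix", "", lines1)))
    if (is.na(ix) || ix < 1L || ix > length(texts)) next
    mol <- mg_from_molblock(rec)
    if (is.null(mol) || !mg_valence_ok(mol)) next
    mol$atoms$expl_val <- NULL
    mol <- mg_drop_explicit_h(mol)
    out[[texts[[ix]]]] <- fragment_from_graph(mol, texts[[ix]])
  }
  out
}

#' Parse a tree-SMILES string into a full binary tree
#'
#' Queue-based level-order rebuild: the first fragment token is the root and
#' each dequeued fragment consumes the next two tokens as its children.
#' Surplus trailing `&` tokens are accepted. With `repair = TRUE`, truncated
#' streams are padded with `&`, surplus non-trailing tokens are dropped and
#' unparseable fragment tokens are demoted to empty nodes (repairs counted
#' in attribute `"repairs"`); with `repair = FALSE` these conditions raise
#' errors.
#'
#' @param s a single tree-SMILES string.
#' @param style the code style the string was written in.
#' @param repair tolerate malformed streams (for model-generated strings).
#' @return a `ts_fbt` (attribute `"repairs"` counts applied fixes).
#' @export
ts_parse <- function(s, style = ts_styles, repair = FALSE) {
  style <- match.arg(style, ts_styles)
  tk <- ts_tokenize(s)
  tk <- tk[tk$type != "CARET", , drop = FALSE]
  repairs <- 0L
  n <- nrow(tk)
  if (repair) {
    first_frag <- match("FRAG", tk$type)
    if (is.na(first_frag)) {
      ts_error("ts_malformed_stream_error", "no fragment token in stream")
    }
    if (first_frag > 1L) {
      tk <- tk[-seq_len(first_frag - 1L), , drop = FALSE]
      repairs <- repairs + 1L
    }
  } else if (n == 0L || tk$type[[1]] != "FRAG") {
    ts_error("ts_malformed_stream_error", "stream must start with a fragment")
  }
  payload <- list(); left <- integer(0); right <- integer(0)
  new_node <- function(p) {
    payload[length(payload) + 1L] <<- list(p)
    left <<- c(left, 0L); right <<- c(right, 0L)
    length(payload)
  }
  frag_cache <- parse_fragment_tokens(tk$token[tk$type == "FRAG"], style)
  make_payload <- function(text) {
    frag <- frag_cache[[text]]
    if (is.null(frag)) {
      if (!repair) parse_fragment_token(text, style)  # raises with detail
      repairs <<- repairs + 1L
      return(NULL)
    }
    list(frag = frag, edge = NULL, fwd = TRUE)
  }
  pos <- 1L
  next_tok <- function() {
    if (pos > nrow(tk)) {
      if (!repair) {
        ts_error("ts_malformed_stream_error", "token stream too short")
      }
      repairs <<- repairs + 1L
      return(list(type = "AMP", token = "&"))
    }
    t <- list(type = tk$type[[pos]], token = tk$token[[pos]])
    pos <<- pos + 1L
    t
  }
  root_tok <- next_tok()
  root_payload <- make_payload(root_tok$token)
  if (is.null(root_payload)) {
    ts_error("ts_malformed_stream_error", "root fragment is unparseable")
  }
  root <- new_node(root_payload)
  queue <- root
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    for (side in c("left", "right")) {
      t <- next_tok()
      id <- if (t$type == "AMP") new_node(NULL) else {
        p <- make_payload(t$token)
        new_node(p)   # NULL payload (failed parse under repair) = empty node
      }
      if (side == "left") left[[v]] <- id else right[[v]] <- id
      if (!fbt_is_empty_node(list(payload = payload), id)) queue <- c(queue, id)
    }
  }
  if (pos <= nrow(tk)) {
    rest <- tk$type[pos:nrow(tk)]
    if (any(rest == "FRAG")) {
      if (!repair) {
        ts_error("ts_malformed_stream_error", "leftover fragment tokens")
      }
      repairs <- repairs + 1L
    }
  }
  fbt <- new_fbt(payload, left, right, root, scheme = NA, style = style)
  attr(fbt, "repairs") <- repairs
  fbt
}

#' Encode a molecule as a tree-SMILES string
#'
#' Composition of [fragment_molecule()], [build_amt()], [amt_to_fbt()] and
#' [ts_serialize()]; deterministic under fixed policies.
#'
#' @param mol a `mol_graph` or a single SMILES string.
#' @inheritParams fragment_molecule
#' @param root optional fragment index used as tree root.
#' @return a single tree-SMILES string.
#' @examples
#' encode_molecule("CCO", scheme = "mmpa", style = "vanilla")
#' @export
encode_molecule <- function(mol, scheme = ts_schemes, style = ts_styles,
                            config = ts_config(), root = NULL) {
  if (is.character(mol)) mol <- parse_molecule(mol)
  fs <- fragment_molecule(mol, scheme, style, config)
  amt <- build_amt(fs, root = root, config = config)
  ts_serialize(amt_to_fbt(amt))
}

#' Encode a set of molecules
#'
#' Vectorised, tibble-out version of [encode_molecule()]; failures are
#' reported per row instead of raised.
#'
#' @param smiles character vector of SMILES (or a data frame with a
#'   `smiles` column).
#' @inheritParams encode_molecule
#' @return a tibble with columns `smiles`, `tsmiles`, `n_fragments`, `error`.
#' @export
ts_encode <- function(smiles, scheme = ts_schemes, style = ts_styles,
                      config = ts_config()) {
  if (is.data.frame(smiles)) smiles <- smiles$smiles
  scheme <- match.arg(scheme, ts_schemes)
  style <- match.arg(style, ts_styles)
  rows <- purrr::map(smiles, function(s) {
    res <- tryCatch({
      code <- encode_molecule(s, scheme, style, config)
      nf <- nrow(ts_tokenize(code)[ts_tokenize(code)$type == "FRAG", ])
      list(code = code, nf = nf, err = NA_character_)
    }, error = function(e) list(code = NA_character_, nf = NA_integer_,
                                err = conditionMessage(e)))
    tibble::tibble(smiles = s, tsmiles = res$code,
                   n_fragments = res$nf, error = res$err)
  })
  dplyr::bind_rows(rows)
}

#' Maximum parenthesis nesting depth of SMILES or tree-SMILES strings
#'
#' For a plain SMILES string, the maximum open-parenthesis depth; for a
#' tree-SMILES string, the maximum over its fragment tokens.
#'
#' @param text character vector.
#' @return integer vector of depths.
#' @export
max_nesting_depth <- function(text) {
  vapply(text, function(s) {
    s <- gsub("[[:space:]]", "", s)
    toks <- strsplit(s, "[&^]+")[[1]]
    depth_one <- function(t) {
      chars <- strsplit(gsub("[^()]", "", t), "")[[1]]
      d <- 0L; mx <- 0L
      for (ch in chars) {
        d <- d + (if (ch == "(") 1L else -1L)
        if (d < 0L) ts_error("ts_unbalanced_error",
                             paste0("unbalanced parentheses in: ", t))
        mx <- max(mx, d)
      }
      if (d != 0L) ts_error("ts_unbalanced_error",
                            paste0("unbalanced parentheses in: ", t))
      mx
    }
    if (!length(toks)) 0L else max(vapply(toks, depth_one, integer(1)))
  }, integer(1), USE.NAMES = FALSE)
}
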