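# Molecule-level surface: SMILES in, sanitized molecular graph out, canonical
# SMILES as the identity surface for equality / novelty / round-trip checks.

ts_error <- function(class, msg, ...) {
  rlang::abort(msg, class = c(class, "ts_error"), ...)
}

smiles_precheck <- function(text) {
  # Open Babel silently "repairs" some syntax errors; catch the obvious ones.
  chars <- strsplit(gsub("\\[[^]]*\\]", "", text), "")[[1]]
  depth <- 0L
  for (ch in chars) {
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (depth < 0L) return(FALSE)
  }
  if (depth != 0L) return(FALSE)
  n_open <- lengths(regmatches(text, gregexpr("\\[", text)))
  n_close <- lengths(regmatches(text, gregexpr("\\]", text)))
  n_open == n_close
}

#' Parse a SMILES string into a sanitized molecular graph
#'
#' The string is canonicalised with Open Babel and the graph is rebuilt from
#' the canonical form, so isomorphic inputs yield byte-identical graphs
#' (deterministic atom order). Multi-component inputs (salts) keep the
#' largest covalent component with a warning. Stereochemical annotations are
#' not retained: fragment cuts can invalidate stereocentres, so the package
#' works on a single stereo-free canonical surface.
#'
#' @param text a single SMILES string.
#' @param canonicalize rebuild the graph from the canonical SMILES (default);
#'   set to `FALSE` to preserve the atom order of `text` (used for fragment
#'   tokens, where attachment points are matched by order of appearance).
#' @return an object of class `mol_graph`.
#' @examples
#' mol <- parse_molecule("CCO")
#' write_canonical(mol)
#' @export
parse_molecule <- function(text, canonicalize = TRUE) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(trimws(text))) {
    ts_error("ts_parse_error", "empty or non-scalar SMILES input")
  }
  text <- gsub("[[:space:]]", "", text)
  if (!smiles_precheck(text)) {
    ts_error("ts_parse_error", paste0("malformed SMILES (unbalanced brackets): ", text))
  }
  if (canonicalize) {
    can <- ob_canonical_smiles(text)
    if (is.na(can)) {
      ts_error("ts_parse_error", paste0("SMILES could not be parsed: ", text))
    }
    if (grepl(".", can, fixed = TRUE)) {
      parts <- strsplit(can, ".", fixed = TRUE)[[1]]
      mols <- lapply(parts, function(p) parse_molecule(p))
      sizes <- vapply(mols, mg_n_heavy, integer(1))
      warning("multi-component input: keeping largest of ", length(parts),
              " components", call. = FALSE)
      return(mols[[which.max(sizes)]])
    }
    src <- can
  } else {
    if (grepl(".", text, fixed = TRUE)) {
      ts_error("ts_parse_error",
               paste0("disconnected fragment token: ", text))
    }
    src <- text
  }
  block <- ob_smiles_to_molblock(src)
  mol <- if (nzchar(block)) mg_from_molblock(block) else NULL
  if (is.null(mol)) {
    ts_error("ts_parse_error", paste0("SMILES could not be converted: ", text))
  }
  if (!mg_valence_ok(mol)) {
    ts_error("ts_valence_error",
             paste0("SMILES parses but violates valence rules: ", text))
  }
  mol$atoms$expl_val <- NULL
  mol <- mg_drop_explicit_h(mol)
  if (canonicalize) {
    mol <- mg_set_aromatic_flags(mol)
    # the graph was rebuilt from the canonical form, so unless stereo marks
    # were dropped the canonical text can be reused without another call
    mol$smiles <- if (grepl("[@/\\\\]", can)) {
      ob_molblock_to_smiles(mg_to_molblock(mol))
    } else {
      can
    }
    if (is.na(mol$smiles)) {
      ts_error("ts_parse_error", paste0("graph could not be re-serialised: ", text))
    }
  }
  mol
}

# Mark aromatic atoms using Open Babel's perception on this graph.
mg_set_aromatic_flags <- function(mol) {
  if (!nrow(mol$atoms)) return(mol)
  hits <- tryCatch(
    ob_smarts_matches(mg_to_molblock(mol), list("[a]"))[[1]],
    error = function(e) list()
  )
  arom <- rep(FALSE, nrow(mol$atoms))
  arom[unlist(hits)] <- TRUE
  mol$atoms$aromatic <- arom
  mol
}

#' Write the canonical SMILES of a molecular graph
#'
#' Deterministic: two isomorphic graphs produce identical text.
#'
#' @param mol a `mol_graph`.
#' @return a single canonical SMILES string.
#' @export
write_canonical <- function(mol) {
  stopifnot(is_mol_graph(mol))
  if (!is.na(mol$smiles)) return(mol$smiles)
  can <- ob_molblock_to_smiles(mg_to_molblock(mol))
  if (is.na(can)) ts_error("ts_write_error", "molecule could not be serialised")
  can
}

#' Test whether two molecules are identical compounds
#'
#' Equality of canonical SMILES (the same surface used for novelty and
#' round-trip checks).
#'
#' @param a,b `mol_graph` objects or SMILES strings.
#' @return `TRUE` or `FALSE`.
#' @export
molecules_equal <- function(a, b) {
  if (is.character(a)) a <- parse_molecule(a)
  if (is.character(b)) b <- parse_molecule(b)
  identical(write_canonical(a), write_canonical(b))
}

# Sanitization used on assembly outputs: valence-legal and serialisable.
mg_sanitize_ok <- function(mol) {
  if (!is_mol_graph(mol)) return(FALSE)
  if (!nrow(mol$atoms)) return(FALSE)
  if (any(mol$atoms$element == "*")) return(FALSE)   # unresolved attachments
  if (!mg_valence_ok(mol)) return(FALSE)
  can <- ob_molblock_to_smiles(mg_to_molblock(mol))
  !is.na(can)
}

#' Read a .smi file
#'
#' One SMILES per line with an optional whitespace-separated name column.
#' Lines that fail to parse are skipped with a reported count.
#'
#' @param path file path.
#' @return a tibble with columns `smiles` (canonical), `name`, `input`.
#' @export
read_smi <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- regmatches(lines, regexpr("[^[:space:]]+", lines))
  names <- trimws(sub("^[^[:space:]]+", "", lines))
  can <- ob_canonical_smiles_batch(parts)
  bad <- is.na(can)
  if (any(bad)) {
    message(sum(bad), " line(s) failed to parse and were skipped")
  }
  tibble::tibble(
    smiles = can[!bad],
    name = names[!bad],
    input = parts[!bad]
  )
}

#' Write a .smi file
#'
#' @param x a character vector of SMILES or a data frame with a `smiles`
#'   column (and optionally `name`).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_smi <- function(x, path) {
  if (is.data.frame(x)) {
    lines <- if ("name" %in% names(x) && any(nzchar(x$name))) {
      paste(x$smiles, x$name)
    } else {
      x$smiles
    }
  } else {
    lines <- as.character(x)
  }
  writeLines(trimws(lines), path, useBytes = TRUE)
  invisible(path)
}
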