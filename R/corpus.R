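# Corpus files: one tree-SMILES string per line plus a sidecar JSON header
# (scheme, style, policies) so corpora are self-describing.

#' Write a tree-SMILES corpus with a sidecar header
#'
#' @param x character vector of tree-SMILES strings or a data frame with a
#'   `tsmiles` column.
#' @param path output file; the header goes to `<path>.json`.
#' @param scheme,style the settings the corpus was encoded with.
#' @param config the [ts_config()] used.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(x, path, scheme, style, config = ts_config()) {
  if (is.data.frame(x)) x <- x$tsmiles
  x <- x[!is.na(x)]
  writeLines(x, path, useBytes = TRUE)
  header <- list(
    format = "tsmiles-corpus", version = 1L,
    scheme = scheme, style = style, n = length(x),
    config = unclass(config)
  )
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a tree-SMILES corpus
#'
#' @param path corpus file written by [write_corpus()] (the sidecar header
#'   is optional).
#' @return a list with `strings` (character) and `header` (list or NULL).
#' @export
read_corpus <- function(path) {
  strings <- readLines(path, encoding = "UTF-8", warn = FALSE)
  strings <- trimws(strings)
  strings <- strings[nzchar(strings)]
  side <- paste0(path, ".json")
  header <- if (file.exists(side)) jsonlite::read_json(side) else NULL
  list(strings = strings, header = header)
}

#' Decode a corpus of tree-SMILES strings
#'
#' Vectorised [ts_decode()]; failures are reported per row.
#'
#' @param strings character vector of tree-SMILES (or the list returned by
#'   [read_corpus()]).
#' @inheritParams ts_decode
#' @return a tibble with columns `tsmiles`, `smiles`, `valid`, `repairs`,
#'   `error`.
#' @export
decode_corpus <- function(strings, style = ts_styles,
                          selector = assembly_selector("record"),
                          repair = FALSE) {
  if (is.list(strings) && !is.null(strings$strings)) {
    if (missing(style) && !is.null(strings$header$style)) {
      style <- strings$header$style
    }
    strings <- strings$strings
  }
  style <- match.arg(style, ts_styles)
  seeds <- if (is.null(selector$seed)) rep(list(NULL), length(strings)) else
    as.list(selector$seed + seq_along(strings) - 1L)
  rows <- purrr::map2(strings, seeds, function(s, sd) {
    sel <- selector
    sel$seed <- sd
    tryCatch({
      res <- ts_decode(s, style, sel, repair = repair)
      tibble::tibble(tsmiles = s, smiles = res$smiles, valid = res$valid,
                     repairs = res$repairs, error = NA_character_)
    }, error = function(e) tibble::tibble(
      tsmiles = s, smiles = NA_character_, valid = FALSE, repairs = NA_integer_,
      error = conditionMessage(e)
    ))
  })
  dplyr::bind_rows(rows)
}
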