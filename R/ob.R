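# Open Babel bridge. All chemistry perception (SMILES reading/writing,
# canonicalisation, aromaticity, SMARTS) goes through ChemmineOB; this file is
# the only place that talks to it.

ob_ns <- function() getNamespace("ChemmineOB")

# Convert between text chemical formats. Open Babel reports hard failures by
# emitting nothing for the offending record, so callers must check for "".
ob_convert <- function(from, to, text) {
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat(from, to, source = text)),
    error = function(e) ""
  )
  if (length(out) == 0L || is.na(out)) "" else out
}

# One SMILES string -> one canonical SMILES (or NA on failure).
ob_canonical_smiles <- function(smiles) {
  out <- ob_convert("SMI", "CAN", smiles)
  out <- strsplit(out, "\n", fixed = TRUE)[[1]]
  if (length(out) == 0L) return(NA_character_)
  can <- sub("\t.*$", "", out[[1]])
  can <- trimws(can)
  if (!nzchar(can)) NA_character_ else can
}

# Batch: many SMILES -> canonical SMILES, order-safe via index titles.
# Returns a character vector aligned with the input (NA where parsing failed).
ob_canonical_smiles_batch <- function(smiles) {
  n <- length(smiles)
  if (n == 0L) return(character(0))
  src <- paste0(smiles, " ix", seq_len(n), collapse = "\n")
  out <- ob_convert("SMI", "CAN", src)
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  res <- rep(NA_character_, n)
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2L) next
    ix <- suppressWarnings(as.integer(sub("^ix", "", trimws(parts[[2]]))))
    if (!is.na(ix) && ix >= 1L && ix <= n) res[ix] <- trimws(parts[[1]])
  }
  res[!is.na(res) & !nzchar(res)] <- NA_character_
  # a hard parse failure can abort the rest of the stream: retry one by one
  if (anyNA(res)) {
    for (k in which(is.na(res))) res[[k]] <- ob_canonical_smiles(smiles[[k]])
  }
  res
}

# SMILES -> V2000 MOL block text ("" on failure).
ob_smiles_to_molblock <- function(smiles) {
  ob_convert("SMI", "SDF", smiles)
}

# MOL block -> canonical SMILES (NA on failure).
ob_molblock_to_smiles <- function(molblock) {
  out <- ob_convert("SDF", "CAN", molblock)
  out <- strsplit(out, "\n", fixed = TRUE)[[1]]
  if (length(out) == 0L) return(NA_character_)
  can <- sub("\t.*$", "", out[[1]])
  can <- trimws(can)
  if (!nzchar(can)) NA_character_ else can
}

# Batch: many MOL blocks -> canonical SMILES in one conversion call,
# order-safe via index titles (NA where conversion failed).
ob_molblocks_to_smiles_batch <- function(blocks) {
  n <- length(blocks)
  if (n == 0L) return(character(0))
  titled <- vapply(seq_len(n), function(k) {
    sub("^[^\n]*\n", sprintf("ix%d\n", k), blocks[[k]])
  }, character(1))
  out <- ob_convert("SDF", "CAN", paste(titled, collapse = ""))
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  res <- rep(NA_character_, n)
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2L) next
    ix <- suppressWarnings(as.integer(sub("^ix", "", trimws(parts[[2]]))))
    if (!is.na(ix) && ix >= 1L && ix <= n) res[ix] <- trimws(parts[[1]])
  }
  res[!is.na(res) & !nzchar(res)] <- NA_character_
  res
}

# Batch: many MOL blocks -> Kekulé canonical SMILES (no aromatic lower-case
# atoms). Goes through OBConversion directly because convertFormat exposes
# no output options; forEachMol preserves input order.
ob_molblocks_to_smiles_kekule <- function(blocks) {
  n <- length(blocks)
  if (n == 0L) return(character(0))
  ns <- ob_ns()
  out <- ChemmineOB::forEachMol("SDF", paste(blocks, collapse = ""), function(m) {
    conv <- ns$OBConversion()
    on.exit(ns$delete_OBConversion(conv), add = TRUE)
    ns$OBConversion_SetOutFormat(conv, "can")
    ns$OBConversion_AddOption(conv, "k", ns$OBConversion_OUTOPTIONS_get())
    ns$OBConversion_WriteString(conv, m)
  })
  res <- vapply(out, function(s) trimws(sub("\t.*$", "", s)), character(1),
                USE.NAMES = FALSE)
  res[!nzchar(res)] <- NA_character_
  if (length(res) != n) res <- rep(NA_character_, n)
  res
}

# Run SMARTS patterns against the first molecule of an SDF string.
# Returns a list parallel to `patterns`; each element is a list of integer
# vectors of matched atom indices (1-based, in MOL block atom order).
ob_smarts_matches <- function(molblock, patterns) {
  ns <- ob_ns()
  res <- ChemmineOB::forEachMol("SDF", molblock, function(m) {
    lapply(patterns, function(p) {
      sp <- ns$OBSmartsPattern()
      on.exit(ns$delete_OBSmartsPattern(sp), add = TRUE)
      if (!ns$OBSmartsPattern_Init(sp, p)) {
        stop("invalid SMARTS pattern: ", p, call. = FALSE)
      }
      ns$OBSmartsPattern_Match(sp, m)
      ns$OBSmartsPattern_GetUMapList(sp)
    })
  })
  res[[1]]
}

# Open Babel molecular descriptors for a batch of SMILES (one row each, NA
# rows where parsing failed). Used by the metrics module.
ob_properties_batch <- function(smiles) {
  n <- length(smiles)
  empty <- tibble::tibble(
    MW = rep(NA_real_, n), logP = rep(NA_real_, n),
    TPSA = rep(NA_real_, n), MR = rep(NA_real_, n),
    HBD = rep(NA_real_, n), HBA = rep(NA_real_, n)
  )
  if (n == 0L) return(empty)
  src <- paste0(smiles, " ix", seq_len(n), collapse = "\n")
  sdf <- ob_convert("SMI", "SDF", src)
  if (!nzchar(sdf)) return(empty)
  rows <- ChemmineOB::forEachMol("SDF", sdf, function(m) {
    ChemmineOB::prop_OB(list(m))
  })
  for (r in rows) {
    ix <- suppressWarnings(as.integer(sub("^ix", "", trimws(r$title))))
    if (is.na(ix) || ix < 1L || ix > n) next
    empty$MW[ix] <- r$MW
    empty$logP[ix] <- r$logP
    empty$TPSA[ix] <- r$TPSA
    empty$MR[ix] <- r$MR
    empty$HBD[ix] <- r$HBD
    empty$HBA[ix] <- r$HBA1
  }
  empty
}
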