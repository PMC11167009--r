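# Corpus statistics and distribution-learning evaluation: validity /
# uniqueness / novelty, Kullback-Leibler descriptor score, Wasserstein
# property distances, token distribution, nesting-depth profile and
# tree-shape counts.

#' Molecular descriptor set for distribution metrics
#'
#' Continuous descriptors (molecular weight, logP, topological polar surface
#' area, molar refractivity) come from Open Babel; discrete ones (H-bond
#' donors/acceptors, heavy-atom and ring counts) from Open Babel and the
#' molecular graph. `extra` adds user descriptors (function: character
#' vector of SMILES -> numeric vector), treated as continuous.
#'
#' @param continuous,discrete names among `MW`, `logP`, `TPSA`, `MR`,
#'   `HBD`, `HBA`, `N_Atoms`, `N_Rings`.
#' @param extra named list of descriptor functions.
#' @return a `ts_property_set`.
#' @export
ts_property_set <- function(continuous = c("MW", "logP", "TPSA", "MR"),
                            discrete = c("HBD", "HBA", "N_Atoms", "N_Rings"),
                            extra = list()) {
  structure(
    list(continuous = continuous, discrete = discrete, extra = extra),
    class = "ts_property_set"
  )
}

# Descriptor table for a vector of (already validated) SMILES.
ts_properties <- function(smiles, props = ts_property_set()) {
  base_names <- c(props$continuous, props$discrete)
  out <- tibble::tibble(.rows = length(smiles))
  need_ob <- intersect(base_names, c("MW", "logP", "TPSA", "MR", "HBD", "HBA"))
  if (length(need_ob)) {
    ob <- ob_properties_batch(smiles)
    for (nm in need_ob) out[[nm]] <- ob[[nm]]
  }
  if (any(c("N_Atoms", "N_Rings") %in% base_names)) {
    counts <- t(vapply(smiles, function(s) {
      mol <- tryCatch(parse_molecule(s), error = function(e) NULL)
      if (is.null(mol)) return(c(NA_real_, NA_real_))
      c(mg_n_heavy(mol), nrow(mol$bonds) - nrow(mol$atoms) + 1L)
    }, numeric(2), USE.NAMES = FALSE))
    if ("N_Atoms" %in% base_names) out$N_Atoms <- counts[, 1]
    if ("N_Rings" %in% base_names) out$N_Rings <- counts[, 2]
  }
  for (nm in names(props$extra)) out[[nm]] <- props$extra[[nm]](smiles)
  out
}

# Empirical 1-Wasserstein distance between two 1-d samples.
w1_distance <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (!length(x) || !length(y)) return(NA_real_)
  pts <- sort(unique(c(x, y)))
  if (length(pts) < 2L) return(0)
  fx <- stats::ecdf(x)(pts)
  gy <- stats::ecdf(y)(pts)
  sum(abs(fx - gy)[-length(pts)] * diff(pts))
}

# KL(training || generated) with shared histogram bins (Freedman-Diaconis on
# the training side) and Laplace smoothing.
kl_divergence <- function(train, gen, discrete = FALSE, eps = 1e-10) {
  train <- train[is.finite(train)]; gen <- gen[is.finite(gen)]
  if (!length(train) || !length(gen)) return(NA_real_)
  if (discrete) {
    support <- sort(unique(c(train, gen)))
    p <- table(factor(train, levels = support)) + eps
    q <- table(factor(gen, levels = support)) + eps
  } else {
    rng <- range(c(train, gen))
    if (diff(rng) == 0) return(0)
    nb <- max(1L, grDevices::nclass.FD(train))
    breaks <- seq(rng[[1]], rng[[2]], length.out = nb + 1L)
    p <- graphics::hist(train, breaks = breaks, plot = FALSE)$counts + eps
    q <- graphics::hist(gen, breaks = breaks, plot = FALSE)$counts + eps
  }
  p <- p / sum(p); q <- q / sum(q)
  sum(p * log(p / q))
}

validate_smiles_set <- function(smiles) {
  uniq <- unique(smiles)
  can_map <- stats::setNames(rep(NA_character_, length(uniq)), uniq)
  for (s in uniq) {
    can_map[[s]] <- tryCatch(write_canonical(parse_molecule(s)),
                             error = function(e) NA_character_,
                             warning = function(w) NA_character_)
  }
  unname(can_map[smiles])
}

#' Distribution-learning report for a generated set
#'
#' Validity (parseable, valence-legal fraction), uniqueness (distinct
#' canonical forms among the valid), novelty (fraction of valid unique
#' molecules absent from the training set), the averaged
#' `exp(-KL(training || generated))` descriptor score, and per-descriptor
#' Wasserstein distances. A neural-embedding distance (FCD) is not computed
#' here; the report carries an optional slot so an external value can be
#' attached.
#'
#' @param generated,training character vectors of SMILES (or data frames
#'   with a `smiles` column).
#' @param properties a [ts_property_set()].
#' @param fcd optional externally computed FCD value to carry along.
#' @return a `ts_report`; see [tidy.ts_report()] and [glance.ts_report()].
#' @export
distribution_report <- function(generated, training,
                                properties = ts_property_set(), fcd = NA_real_) {
  if (is.data.frame(generated)) generated <- generated$smiles
  if (is.data.frame(training)) training <- training$smiles
  if (!length(generated) || !length(training)) {
    ts_error("ts_empty_input_error", "generated and training must be non-empty")
  }
  gen_can <- validate_smiles_set(generated)
  train_can <- validate_smiles_set(training)
  train_set <- unique(train_can[!is.na(train_can)])
  valid_can <- gen_can[!is.na(gen_can)]
  uniq_can <- unique(valid_can)
  valid <- length(valid_can) / length(generated)
  uniq <- if (length(valid_can)) length(uniq_can) / length(valid_can) else 0
  novelty <- if (length(uniq_can)) mean(!uniq_can %in% train_set) else 0
  tp <- ts_properties(train_set, properties)
  gp <- ts_properties(uniq_can, properties)
  desc <- tibble::tibble(
    property = names(tp),
    discrete = names(tp) %in% properties$discrete,
    kl = vapply(names(tp), function(nm) {
      kl_divergence(tp[[nm]], gp[[nm]], discrete = nm %in% properties$discrete)
    }, numeric(1)),
    wasserstein = vapply(names(tp), function(nm) {
      w1_distance(gp[[nm]], tp[[nm]])
    }, numeric(1))
  )
  kld_score <- mean(exp(-desc$kl), na.rm = TRUE)
  structure(
    list(
      valid = valid, unique = uniq, novelty = novelty,
      kld_score = kld_score, fcd = fcd, descriptors = desc,
      n_input = length(generated), n_valid = length(valid_can),
      n_unique = length(uniq_can), n_training = length(train_set)
    ),
    class = "ts_report"
  )
}

#' @export
print.ts_report <- function(x, ...) {
  cat(sprintf(
    paste0("<ts_report: n = %d>\n  valid    %.3f\n  unique   %.3f\n",
           "  novelty  %.3f\n  KLD      %.3f\n  FCD      %s\n"),
    x$n_input, x$valid, x$unique, x$novelty, x$kld_score,
    if (is.na(x$fcd)) "(not computed)" else sprintf("%.3f", x$fcd)
  ))
  invisible(x)
}

#' Tidy a distribution report (per-descriptor rows)
#'
#' @param x a `ts_report`.
#' @param ... unused.
#' @return a tibble with one row per descriptor: `property`, `discrete`,
#'   `kl`, `exp_neg_kl`, `wasserstein`.
#' @method tidy ts_report
#' @export
tidy.ts_report <- function(x, ...) {
  dplyr::mutate(x$descriptors, exp_neg_kl = exp(-.data$kl),
                .after = "kl")
}

#' One-row summary of a distribution report
#'
#' @param x a `ts_report`.
#' @param ... unused.
#' @return a one-row tibble: `valid`, `unique`, `novelty`, `kld_score`,
#'   `fcd`, `n_input`, `n_valid`, `n_unique`.
#' @method glance ts_report
#' @export
glance.ts_report <- function(x, ...) {
  tibble::tibble(
    valid = x$valid, unique = x$unique, novelty = x$novelty,
    kld_score = x$kld_score, fcd = x$fcd,
    n_input = x$n_input, n_valid = x$n_valid, n_unique = x$n_unique
  )
}

#' Per-property Wasserstein distances between two molecule sets
#'
#' @inheritParams distribution_report
#' @return a tibble with columns `property` and `wasserstein`; zero for
#'   every property iff the empirical distributions coincide.
#' @export
property_distances <- function(generated, training,
                               properties = ts_property_set()) {
  if (is.data.frame(generated)) generated <- generated$smiles
  if (is.data.frame(training)) training <- training$smiles
  if (!length(generated) || !length(training)) {
    ts_error("ts_empty_input_error", "generated and training must be non-empty")
  }
  gp <- ts_properties(generated, properties)
  tp <- ts_properties(training, properties)
  tibble::tibble(
    property = names(tp),
    wasserstein = vapply(names(tp), function(nm) {
      w1_distance(gp[[nm]], tp[[nm]])
    }, numeric(1))
  )
}

# Language-model token alphabet: bracket atoms, two-letter halogens,
# two-digit ring bonds, the tree symbols & and ^, then single characters.
smiles_token_regex <- "\\[[^]]*\\]|Cl|Br|&|\\^|%[0-9]{2}|."

tokenize_lm <- function(s) {
  regmatches(s, gregexpr(smiles_token_regex, s, perl = TRUE))[[1]]
}

#' Token frequency distribution of a corpus
#'
#' Tokens follow the usual SMILES language-model alphabet (bracket atoms,
#' `Cl`/`Br`, ring-bond digits, bond and branch symbols) extended with the
#' tree symbols `&` and `^`.
#'
#' @param corpus character vector of SMILES / tree-SMILES strings.
#' @return a tibble with columns `token`, `n`, `freq` (descending `freq`;
#'   frequencies sum to 1).
#' @export
token_distribution <- function(corpus) {
  toks <- unlist(lapply(corpus, tokenize_lm))
  if (!length(toks)) {
    return(tibble::tibble(token = character(0), n = integer(0),
                          freq = numeric(0)))
  }
  tab <- sort(table(toks), decreasing = TRUE)
  out <- tibble::tibble(
    token = names(tab), n = as.integer(tab), freq = as.numeric(tab) / sum(tab)
  )
  class(out) <- c("ts_token_distribution", class(out))
  out
}

#' Nesting-depth profile of a corpus
#'
#' Maximum parenthesis nesting depth per string (for tree-SMILES, the
#' maximum over fragment tokens), aggregated into the depth bands 0-2, 3-5
#' and 6+.
#'
#' @param corpus character vector of strings.
#' @return a `ts_nesting` list with `histogram` (tibble: depth, n, prop) and
#'   `bands` (tibble: band, n, prop).
#' @export
nesting_profile <- function(corpus) {
  depths <- max_nesting_depth(corpus)
  hist <- tibble::tibble(depth = sort(unique(depths)))
  hist$n <- vapply(hist$depth, function(d) sum(depths == d), integer(1))
  hist$prop <- hist$n / length(depths)
  band <- cut(depths, breaks = c(-1, 2, 5, Inf), labels = c("0-2", "3-5", "6+"))
  bt <- table(band)
  bands <- tibble::tibble(
    band = names(bt), n = as.integer(bt), prop = as.numeric(bt) / length(depths)
  )
  structure(list(histogram = hist, bands = bands, n = length(depths)),
            class = "ts_nesting")
}

#' @export
print.ts_nesting <- function(x, ...) {
  cat(sprintf("<ts_nesting: %d string(s)>\n", x$n))
  print(x$bands)
  invisible(x)
}

# Level-order shape key of a full binary tree (fragment = 1, empty = 0).
fbt_shape_key <- function(fbt) {
  queue <- fbt$root
  bits <- character(0)
  while (length(queue)) {
    k <- queue[[1]]; queue <- queue[-1]
    if (fbt_is_empty_node(fbt, k)) {
      bits <- c(bits, "0")
    } else {
      bits <- c(bits, "1")
      queue <- c(queue, fbt$left[[k]], fbt$right[[k]])
    }
  }
  paste(bits, collapse = "")
}

#' Count distinct full-binary-tree shapes
#'
#' Unlabelled tree shapes after converting each AMT to its full binary
#' tree; the shape key is the level-order fragment/empty bitstring.
#'
#' @param x a list of `ts_amt` or `ts_fbt` objects.
#' @return number of distinct shapes (integer).
#' @export
count_fbt_types <- function(x) {
  keys <- vapply(x, function(t) {
    if (inherits(t, "ts_amt")) t <- amt_to_fbt(t)
    fbt_shape_key(t)
  }, character(1))
  length(unique(keys))
}
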