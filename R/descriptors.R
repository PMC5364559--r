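# Descriptor encoders: fixed-length numeric feature vectors from protein
# sequences. Feature order is frozen (alphabetical residues, nested
# alphabetical di-peptides, attribute-then-block CTD, index-major ACF) so
# trained models are portable.

seq_strings <- function(x) {
  if (inherits(x, "protein_set") || is.data.frame(x)) {
    stats::setNames(x$sequence, x$id)
  } else if (is.character(x)) {
    stats::setNames(x, names(x) %||% paste0("seq", seq_along(x)))
  } else stop("expected a protein_set or character vector of sequences")
}

seq_index <- function(s) {
  idx <- match(strsplit(s, "", fixed = TRUE)[[1L]], AA_ALPHABET)
  if (anyNA(idx)) stop("sequence contains non-standard residues")
  idx
}

#' Assemble a feature matrix
#'
#' @param rows numeric matrix (sequences x features).
#' @param scheme one of `"AAC"`, `"DPC"`, `"PAAC"`, `"CTD"`, `"ACF"`.
#' @param params canonical list of the scheme parameters entering the
#'   fingerprint.
#' @return A `feature_matrix`: the matrix with attributes `scheme`, `params`
#'   and `fingerprint` (hash of scheme + params + feature names).
#' @export
feature_matrix <- function(rows, scheme, params = list()) {
  stopifnot(is.matrix(rows), !is.null(colnames(rows)))
  structure(rows, scheme = scheme, params = params,
            fingerprint = rlang::hash(list(scheme = scheme, params = params,
                                           features = colnames(rows))),
            class = c("feature_matrix", class(rows)))
}

fm_fingerprint <- function(fm) attr(fm, "fingerprint")

# Row subset preserving feature_matrix attributes.
fm_rows <- function(fm, i) {
  feature_matrix(unclass(fm)[i, , drop = FALSE], attr(fm, "scheme"),
                 attr(fm, "params"))
}

#' Amino acid composition (AAC)
#'
#' 20 residue frequencies per sequence; components sum to 1.
#'
#' @param x a `protein_set` or character vector of valid sequences.
#' @return A [feature_matrix()] with 20 columns named by residue.
#' @export
encode_aac <- function(x) {
  seqs <- seq_strings(x)
  rows <- t(vapply(seqs, function(s) {
    idx <- seq_index(s)
    if (length(idx) < 1L) stop("AAC requires sequence length >= 1")
    tabulate(idx, 20L) / length(idx)
  }, numeric(20L)))
  colnames(rows) <- AA_ALPHABET
  feature_matrix(rows, "AAC")
}

dpc_feature_names <- function() {
  as.vector(t(outer(AA_ALPHABET, AA_ALPHABET, paste0)))
}

#' Di-peptide composition (DPC)
#'
#' Frequencies of the 400 ordered residue pairs over the L-1 overlapping
#' adjacent positions; components sum to 1. Requires L >= 2.
#'
#' @inheritParams encode_aac
#' @return A [feature_matrix()] with 400 columns in nested alphabetical
#'   order (AA, AC, ..., YY).
#' @export
encode_dpc <- function(x) {
  seqs <- seq_strings(x)
  rows <- t(vapply(seqs, function(s) {
    idx <- seq_index(s)
    L <- length(idx)
    if (L < 2L) stop("DPC requires sequence length >= 2")
    pair <- (idx[-L] - 1L) * 20L + idx[-1L]
    tabulate(pair, 400L) / (L - 1L)
  }, numeric(400L)))
  colnames(rows) <- dpc_feature_names()
  feature_matrix(rows, "DPC")
}

# Theta(a, b): mean over the standardized properties of the squared
# difference of the property values of residues a and b (index form).
theta_pairwise <- function(params) {
  p <- params$properties
  m <- matrix(0, 20L, 20L)
  for (k in seq_len(nrow(p))) m <- m + outer(p[k, ], p[k, ], "-")^2
  m / nrow(p)
}

#' PAAC sequence-order correlation factor of tier j
#'
#' theta_j = mean over positions i of Theta(R_i, R_{i+j}) with Theta the mean
#' squared standardized-property difference. Requires L >= j + 1.
#'
#' @param sequence a single valid sequence string.
#' @param params a [paac_params()] object.
#' @param j correlation tier, 1 <= j <= lambda.
#' @return A non-negative scalar.
#' @export
paac_theta <- function(sequence, params, j) {
  idx <- seq_index(toupper(sequence))
  L <- length(idx)
  j <- as.integer(j)
  stopifnot(inherits(params, "paac_params"), j >= 1L)
  if (L < j + 1L) stop("sequence too short for tier ", j,
                       " (need length >= ", j + 1L, ")")
  Th <- theta_pairwise(params)
  mean(Th[cbind(idx[seq_len(L - j)], idx[seq_len(L - j) + j])])
}

#' Pseudo amino acid composition (PAAC)
#'
#' The 20 residue frequencies augmented with lambda sequence-order
#' correlation factors, all sharing the denominator
#' 1 + w * sum_j theta_j (Chou's construction with normalized
#' frequencies), so the vector sums to 1. Requires L >= lambda + 1.
#'
#' @inheritParams encode_aac
#' @param params a [paac_params()] object.
#' @return A [feature_matrix()] with 20 + lambda columns.
#' @export
encode_paac <- function(x, params = paac_params()) {
  stopifnot(inherits(params, "paac_params"))
  seqs <- seq_strings(x)
  lam <- params$lambda
  Th <- theta_pairwise(params)
  rows <- t(vapply(seqs, function(s) {
    idx <- seq_index(s)
    L <- length(idx)
    if (L < lam + 1L) stop("PAAC with lambda = ", lam,
                           " requires sequence length >= ", lam + 1L)
    f <- tabulate(idx, 20L) / L
    theta <- vapply(seq_len(lam), function(j) {
      mean(Th[cbind(idx[seq_len(L - j)], idx[seq_len(L - j) + j])])
    }, numeric(1))
    D <- 1 + params$weight * sum(theta)
    c(f, params$weight * theta) / D
  }, numeric(20L + lam)))
  colnames(rows) <- c(AA_ALPHABET, paste0("theta", seq_len(lam)))
  feature_matrix(rows, "PAAC",
                 params = list(lambda = lam, weight = params$weight,
                               properties = unname(params$properties)))
}

ctd_feature_names <- function(groupings) {
  unlist(lapply(groupings, function(g) {
    a <- g$attribute
    c(paste0(a, ".C.g", 1:3),
      paste0(a, ".T.", c("g1g2", "g1g3", "g2g3")),
      as.vector(t(outer(paste0(a, ".D.g", 1:3),
                        c("first", "p25", "p50", "p75", "last"),
                        paste, sep = "."))))
  }), use.names = FALSE)
}

ctd_one <- function(idx, grouping) {
  L <- length(idx)
  g <- grouping$group_of[idx]
  comp <- tabulate(g, 3L) / L
  pair <- pmin(g[-L], g[-1L]) * 10L + pmax(g[-L], g[-1L])
  trans <- c(sum(pair == 12L), sum(pair == 13L), sum(pair == 23L)) / (L - 1L)
  distr <- numeric(15L)
  for (grp in 1:3) {
    pos <- which(g == grp)
    n_g <- length(pos)
    if (n_g > 0L) {
      ks <- pmax(1L, ceiling(c(0, 0.25, 0.50, 0.75, 1) * n_g))
      ks[1L] <- 1L
      distr[(grp - 1L) * 5L + 1:5] <- pos[ks] / L * 100
    }
  }
  c(comp, trans, distr)
}

#' Composition-transition-distribution (CTD) descriptors
#'
#' Per attribute grouping (three residue groups): 3 composition fractions,
#' 3 adjacent-pair transition frequencies (unordered group pairs, divided by
#' L-1), and 15 distribution values (chain position, as percent of L, of the
#' first, 25th-, 50th-, 75th-percentile and last occurrence of each group;
#' all-zero for a group absent from the sequence). 21 features per
#' attribute. Requires L >= 2.
#'
#' @inheritParams encode_aac
#' @param groupings list of [ctd_grouping()] objects (default: the seven
#'   [ctd_groupings()] attributes, 147 features).
#' @return A [feature_matrix()] with `21 * length(groupings)` columns.
#' @export
encode_ctd <- function(x, groupings = ctd_groupings()) {
  stopifnot(length(groupings) >= 1L,
            all(vapply(groupings, inherits, logical(1), "ctd_grouping")))
  seqs <- seq_strings(x)
  nf <- 21L * length(groupings)
  rows <- t(vapply(seqs, function(s) {
    idx <- seq_index(s)
    if (length(idx) < 2L) stop("CTD requires sequence length >= 2")
    unlist(lapply(groupings, function(grp) ctd_one(idx, grp)),
           use.names = FALSE)
  }, numeric(nf)))
  colnames(rows) <- ctd_feature_names(groupings)
  feature_matrix(rows, "CTD",
                 params = list(attributes = vapply(groupings, `[[`,
                                                  character(1), "attribute"),
                               groups = lapply(groupings, `[[`, "groups")))
}

#' Autocorrelation function (ACF) descriptors
#'
#' For each amino acid index m (standardized to zero mean, unit population
#' sd over the 20 residues) and each lag d in 1..n:
#' `mean_i P~_m(R_i) * P~_m(R_(i+d))` over the L-d positions. Output is
#' index-major then lag, M*n features. Requires L >= n + 1.
#'
#' @inheritParams encode_aac
#' @param table an [aaindex_table()].
#' @param n autocorrelation order (maximum lag), default 1.
#' @return A [feature_matrix()] with `M * n` columns named `<id>.lag<d>`.
#' @export
encode_acf <- function(x, table, n = 1L) {
  stopifnot(inherits(table, "aaindex_table"))
  n <- as.integer(n)
  stopifnot(n >= 1L)
  M <- length(table$ids)
  if (M == 0L) stop("empty index table")
  P <- standardize_properties(table$values)
  seqs <- seq_strings(x)
  rows <- t(vapply(seqs, function(s) {
    idx <- seq_index(s)
    L <- length(idx)
    if (L < n + 1L) stop("ACF of order ", n,
                         " requires sequence length >= ", n + 1L)
    V <- P[, idx, drop = FALSE]  # M x L standardized profile
    vals <- vapply(seq_len(n), function(d) {
      rowSums(V[, seq_len(L - d), drop = FALSE] *
                V[, seq_len(L - d) + d, drop = FALSE]) / (L - d)
    }, numeric(M))
    as.vector(t(vals))  # index-major, then lag
  }, numeric(M * n)))
  colnames(rows) <- as.vector(t(outer(table$ids, paste0(".lag", seq_len(n)),
                                      paste0)))
  feature_matrix(rows, "ACF",
                 params = list(order = n, source = table$source,
                               n_indices = M))
}

#' Encode sequences under a named scheme
#'
#' Dispatcher over the five encoders; the route taken by the command-line
#' interface and the evaluation protocols.
#'
#' @inheritParams encode_aac
#' @param scheme `"AAC"`, `"DPC"`, `"PAAC"`, `"CTD"` or `"ACF"`.
#' @param paac [paac_params()] for PAAC.
#' @param groupings CTD attribute groupings.
#' @param table [aaindex_table()] for ACF (default: the synthetic snapshot).
#' @param order ACF autocorrelation order.
#' @return A [feature_matrix()].
#' @export
encode_features <- function(x, scheme = c("AAC", "DPC", "PAAC", "CTD", "ACF"),
                            paac = paac_params(), groupings = ctd_groupings(),
                            table = NULL, order = 1L) {
  scheme <- match.arg(scheme)
  switch(scheme,
         AAC = encode_aac(x),
         DPC = encode_dpc(x),
         PAAC = encode_paac(x, paac),
         CTD = encode_ctd(x, groupings),
         ACF = encode_acf(x, table %||% synthetic_aaindex_snapshot(), order))
}

#' Per-group mean residue composition
#'
#' Arithmetic mean of the AAC vectors of the records in each group; the
#' per-class composition summary behind leucine-enrichment style analyses.
#'
#' @param dataset a `protein_set` or `labeled_dataset`.
#' @param by grouping vector (one value per record); defaults to the labels
#'   when `dataset` carries them.
#' @return A numeric matrix, one row per group, 20 residue columns; each
#'   row sums to 1.
#' @export
composition_summary <- function(dataset, by = NULL) {
  if (nrow(dataset) == 0L) stop("empty dataset")
  if (is.null(by)) {
    if (!"label" %in% names(dataset)) stop("'by' required for unlabeled data")
    by <- dataset$label
  }
  stopifnot(length(by) == nrow(dataset))
  aac <- unclass(encode_aac(dataset))
  groups <- split(seq_len(nrow(dataset)), by)
  if (any(lengths(groups) == 0L)) stop("empty group")
  out <- t(vapply(groups, function(i) colMeans(aac[i, , drop = FALSE]),
                  numeric(20L)))
  colnames(out) <- AA_ALPHABET
  out
}
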