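# AAindex1 flat-file support: the per-residue physicochemical index tables
# backing the autocorrelation (ACF) descriptors.

#' Construct an amino acid index table
#'
#' Entries with any missing residue value are excluded (the usable-index
#' convention: descriptors must never see NA), and the exclusion count kept.
#'
#' @param ids character vector of unique index identifiers.
#' @param values numeric matrix, one row per id, 20 columns in
#'   [AA_ALPHABET] order; may contain NA (those rows are dropped).
#' @param source free-text provenance tag stored in model fingerprints.
#' @return An `aaindex_table`: list with `ids`, `values` (M x 20, complete
#'   rows only), `n_excluded`, `source`.
#' @export
aaindex_table <- function(ids, values, source = "unspecified") {
  stopifnot(is.character(ids), is.matrix(values),
            nrow(values) == length(ids), ncol(values) == 20L)
  if (anyDuplicated(ids)) stop("duplicate index identifiers")
  complete <- stats::complete.cases(values)
  if (!any(complete)) stop("no complete index entries")
  tab <- structure(list(ids = ids[complete],
                        values = `dimnames<-`(values[complete, , drop = FALSE],
                                              list(ids[complete], AA_ALPHABET)),
                        n_excluded = sum(!complete),
                        source = source),
                   class = "aaindex_table")
  tab
}

#' @export
print.aaindex_table <- function(x, ...) {
  cat(sprintf("aaindex_table: %d complete entries (%d excluded), source: %s\n",
              length(x$ids), x$n_excluded, x$source))
  invisible(x)
}

#' Read an AAindex1-format flat file
#'
#' Parses the `H` (identifier) and `I` (index data) records of each `//`
#' delimited block; the two value lines follow the AAindex residue order
#' `A R N D C Q E G H I / L K M F P S T W Y V` and are re-ordered to
#' [AA_ALPHABET]. Entries containing `NA` values are excluded with a message.
#'
#' @param path path to an AAindex1 flat file.
#' @return An [aaindex_table()].
#' @export
load_aaindex <- function(path) {
  if (!file.exists(path)) stop("AAindex file not found: ", path)
  lines <- readLines(path)
  ends <- which(trimws(lines) == "//")
  if (length(ends) == 0L) stop("not an AAindex flat file (no '//' terminators)")
  starts <- c(1L, head(ends, -1L) + 1L)
  ids <- character(0)
  rows <- list()
  for (b in seq_along(ends)) {
    blk <- lines[starts[b]:ends[b]]
    blk <- blk[nzchar(trimws(blk))]
    if (length(blk) <= 1L) next
    h <- grep("^H ", blk, value = TRUE)
    ipos <- grep("^I ", blk)
    if (length(h) != 1L || length(ipos) != 1L) {
      stop("malformed AAindex block ", b, ": need exactly one H and one I record")
    }
    if (ipos + 2L > length(blk)) stop("malformed AAindex block ", b,
                                      ": missing value lines")
    id <- trimws(sub("^H ", "", h))
    vals <- unlist(lapply(blk[ipos + 1:2], function(l) {
      strsplit(trimws(l), "[[:space:]]+")[[1L]]
    }))
    if (length(vals) != 20L) stop("malformed AAindex block '", id,
                                  "': expected 20 values, got ", length(vals))
    num <- suppressWarnings(as.numeric(ifelse(vals == "NA", NA, vals)))
    if (any(is.na(num) & vals != "NA")) stop("malformed AAindex block '", id,
                                             "': non-numeric value")
    names(num) <- AAINDEX_ORDER
    ids <- c(ids, id)
    rows[[length(rows) + 1L]] <- num[AA_ALPHABET]
  }
  values <- do.call(rbind, rows)
  tab <- aaindex_table(ids, values, source = basename(path))
  if (tab$n_excluded > 0) {
    message(tab$n_excluded,
            " AAindex entr(y/ies) with missing values excluded")
  }
  tab
}

#' Write an index table (or raw matrix) in AAindex1 flat format
#'
#' @param ids index identifiers.
#' @param values numeric matrix (rows per id, 20 columns in [AA_ALPHABET]
#'   order); NA allowed.
#' @param path output path.
#' @param digits decimal places printed.
#' @return `path`, invisibly.
#' @export
write_aaindex <- function(ids, values, path, digits = 3L) {
  stopifnot(length(ids) == nrow(values), ncol(values) == 20L)
  colnames(values) <- AA_ALPHABET
  con <- file(path, open = "wt")
  on.exit(close(con))
  fmt <- paste0("%", digits + 5L, ".", digits, "f")
  for (i in seq_along(ids)) {
    v <- values[i, AAINDEX_ORDER]
    cells <- ifelse(is.na(v), sprintf(paste0("%", digits + 5L, "s"), "NA"),
                    sprintf(fmt, v))
    writeLines(c(paste0("H ", ids[i]),
                 "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
                 paste(cells[1:10], collapse = " "),
                 paste(cells[11:20], collapse = " "),
                 "//"), con)
  }
  invisible(path)
}

#' Synthetic stand-in for the full amino acid index collection
#'
#' The real AAindex database (531 usable indices after dropping entries with
#' missing values) cannot be redistributed here, so this generates a
#' deterministic synthetic snapshot with the same structure: `n_complete`
#' complete entries plus `n_incomplete` entries carrying NA values, which the
#' [aaindex_table()] constructor excludes. Values are standard-normal draws
#' from a fixed internal seed, so the snapshot (and any model fingerprint
#' built on it) is stable across sessions. It is suitable for exercising the
#' ACF machinery and its dimension contract, not for physicochemical
#' interpretation.
#'
#' @param n_complete number of complete entries retained (default 531, the
#'   usable-index count of the real collection).
#' @param n_incomplete number of NA-carrying entries excluded at load.
#' @return An [aaindex_table()] with `length(ids) == n_complete`.
#' @export
synthetic_aaindex_snapshot <- function(n_complete = 531L, n_incomplete = 13L) {
  n <- n_complete + n_incomplete
  withr::with_seed(190643L, {
    values <- matrix(round(rnorm(n * 20L), 3L), nrow = n, ncol = 20L)
    na_rows <- if (n_incomplete > 0) sample(n, n_incomplete) else integer(0)
    for (r in na_rows) values[r, sample(20L, sample(1:3, 1L))] <- NA
  })
  ids <- sprintf("SYNTH%05d", seq_len(n))
  aaindex_table(ids, values,
                source = sprintf("synthetic-snapshot-%d+%d", n_complete,
                                 n_incomplete))
}
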