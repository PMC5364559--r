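#' Validate a protein sequence against the 20-letter standard alphabet
#'
#' Case-insensitive: the sequence is uppercased before checking. Gap
#' characters ('-') and ambiguity codes (B, J, O, U, X, Z) are invalid.
#'
#' @param sequence a single character string.
#' @return A list with elements `valid` (logical), and when invalid,
#'   `position` (1-based index of the first offending character, `NA` for an
#'   empty sequence) and `residue` (the offending character).
#' @examples
#' validate_residues("ACDEfg")   # valid
#' validate_residues("ACBDE")    # invalid: 'B' at position 3
#' @export
validate_residues <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (is.na(sequence) || nchar(sequence) == 0L) {
    return(list(valid = FALSE, position = NA_integer_, residue = NA_character_,
                reason = "empty sequence"))
  }
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  bad <- which(!(chars %in% AA_ALPHABET))
  if (length(bad) == 0L) return(list(valid = TRUE))
  list(valid = FALSE, position = bad[1L], residue = chars[bad[1L]],
       reason = sprintf("non-standard residue '%s' at position %d",
                        chars[bad[1L]], bad[1L]))
}

#' Construct a set of validated protein records
#'
#' The basic sequence container: a data frame with columns `id` and
#' `sequence`, every sequence uppercased and restricted to the 20 standard
#' residues.
#'
#' @param id character vector of unique, non-empty identifiers.
#' @param sequence character vector of residue strings (one per id).
#' @return A `protein_set` (data frame with columns `id`, `sequence`).
#' @export
protein_set <- function(id, sequence) {
  stopifnot(is.character(id), is.character(sequence),
            length(id) == length(sequence))
  if (any(!nzchar(id))) stop("empty sequence identifier")
  if (anyDuplicated(id)) {
    stop("duplicate sequence identifiers: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  sequence <- toupper(sequence)
  for (i in seq_along(sequence)) {
    v <- validate_residues(sequence[i])
    if (!v$valid) stop(sprintf("record '%s': %s", id[i], v$reason))
  }
  structure(data.frame(id = id, sequence = sequence,
                       stringsAsFactors = FALSE),
            class = c("protein_set", "data.frame"))
}

#' Attach class labels to a protein set
#'
#' @param x a `protein_set` (or id/sequence data frame).
#' @param label integer vector of +1 (positive / resistant class) and -1
#'   (negative / non-resistant class), one per record.
#' @return A `labeled_dataset`.
#' @export
labeled_dataset <- function(x, label) {
  stopifnot(nrow(x) == length(label))
  label <- as.integer(label)
  if (!all(label %in% c(-1L, 1L))) stop("labels must be +1 or -1")
  out <- data.frame(id = x$id, sequence = x$sequence, label = label,
                    stringsAsFactors = FALSE)
  structure(out, class = c("labeled_dataset", "protein_set", "data.frame"))
}

#' Read protein sequences from a FASTA file
#'
#' Parsing is delegated to [Biostrings::readAAStringSet()]; records are then
#' uppercased and validated against the standard 20-letter alphabet. The
#' record identifier is the first whitespace-delimited token of the header.
#'
#' @param path path to a FASTA file (multi-line records allowed).
#' @param policy `"strict"`: any record with a non-standard residue or a
#'   duplicated identifier aborts the read. `"skip-invalid"`: such records
#'   are dropped (invalid residues) or suffix-disambiguated (duplicate ids),
#'   with a message reporting the counts.
#' @return A [protein_set()] in file order, with attribute `n_skipped`
#'   giving the number of dropped records.
#' @export
read_fasta <- function(path, policy = c("strict", "skip-invalid")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) stop("FASTA file contains no records: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  sq <- toupper(as.character(seqs))
  if (any(!nzchar(ids))) stop("FASTA record with empty identifier")

  if (anyDuplicated(ids)) {
    if (policy == "strict") {
      stop("duplicate FASTA identifiers: ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    }
    dup <- ids[duplicated(ids)]
    ids <- make.unique(ids, sep = "_dup")
    message(length(dup), " duplicate identifier(s) disambiguated with suffix")
  }

  verdicts <- lapply(sq, validate_residues)
  ok <- vapply(verdicts, `[[`, logical(1), "valid")
  if (!all(ok)) {
    if (policy == "strict") {
      i <- which(!ok)[1L]
      stop(sprintf("record '%s': %s", ids[i], verdicts[[i]]$reason))
    }
    message(sum(!ok), " record(s) with non-standard residues skipped")
  }
  out <- protein_set(ids[ok], sq[ok])
  attr(out, "n_skipped") <- sum(!ok)
  out
}

#' Write protein records as FASTA
#'
#' @param x a `protein_set` (or data frame with `id` and `sequence`).
#' @param path output path.
#' @param width line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    writeLines(paste0(">", x$id[i]), con)
    s <- x$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Write a prediction table
#'
#' Tab-separated, with header `sequence_id  predicted_label  probability`;
#' probabilities printed with 4 decimals. Rows flagged as unscorable may
#' carry `NA` label/probability.
#'
#' @param rows data frame with columns `id`, `label` (+1/-1 or NA) and
#'   `probability` (in \[0, 1\] or NA).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(rows, path) {
  stopifnot(all(c("id", "label", "probability") %in% names(rows)))
  p <- rows$probability
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("probabilities outside [0, 1]")
  lines <- c("sequence_id\tpredicted_label\tprobability",
             if (nrow(rows) > 0) {
               sprintf("%s\t%s\t%s", rows$id,
                       ifelse(is.na(rows$label), "NA",
                              sprintf("%+d", as.integer(rows$label))),
                       ifelse(is.na(p), "NA", sprintf("%.4f", p)))
             })
  writeLines(lines, path)
  invisible(path)
}
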