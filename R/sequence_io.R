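#' Peptide record sets
#'
#' A `peptide_set` is a data frame with columns `id` (character),
#' `sequence` (character, uppercase 20-letter amino-acid alphabet after
#' validation) and `label` (integer 0/1 or `NA` when unlabeled). It is the
#' container passed between the I/O, encoder, embedding and synthetic-data
#' functions.
#'
#' @param id character vector of identifiers.
#' @param sequence character vector of amino-acid sequences.
#' @param label optional integer vector of binary class labels
#'   (1 = ACP/positive, 0 = negative); `NA` when unknown.
#' @return A `peptide_set` data frame.
#' @examples
#' peptide_set(c("p1", "p2"), c("KLAKLAK", "GIGAVLK"), label = c(1L, 0L))
#' @export
peptide_set <- function(id, sequence, label = NA_integer_) {
  stopifnot(length(id) == length(sequence))
  sequence <- toupper(as.character(sequence))
  label <- as.integer(label)
  if (length(label) == 1L) label <- rep(label, length(id))
  stopifnot(length(label) == length(id))
  bad <- !is.na(label) & !(label %in% c(0L, 1L))
  if (any(bad)) stop("labels must be 0, 1 or NA")
  structure(
    data.frame(id = as.character(id), sequence = sequence, label = label,
               stringsAsFactors = FALSE),
    class = c("peptide_set", "data.frame")
  )
}

empty_peptide_set <- function() {
  peptide_set(character(0), character(0), integer(0))
}

# split an "id|label=x" header token into id and label
parse_label_suffix <- function(token) {
  m <- regmatches(token, regexec("^(.*)\\|label=([01])$", token))[[1]]
  if (length(m) == 3L) list(id = m[2], label = as.integer(m[3]))
  else list(id = token, label = NA_integer_)
}

#' Read peptide sequences from a FASTA file
#'
#' Parses a FASTA file into a [peptide_set]. The header token before the
#' first whitespace becomes the record id. Two label channels are
#' supported: a `|label=0` / `|label=1` suffix on the header token, and a
#' two-column delimited file (id, label) passed via `labels`. The file is
#' structurally validated first, so malformed input (sequence text before
#' the first header, a header with an empty sequence) raises an error
#' naming the offending line.
#'
#' @param path path to a FASTA file.
#' @param labels optional path to a two-column delimited file (id, label,
#'   no header) or a data frame with columns `id` and `label`.
#' @return A [peptide_set]; empty file yields an empty set.
#' @seealso [write_fasta()], [validate_alphabet()], [filter_by_length()]
#' @export
read_fasta <- function(path, labels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L) return(empty_peptide_set())

  # structural pre-scan: line-numbered errors Biostrings does not report
  first <- nonempty[1]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop("malformed FASTA: sequence text before first header at line ", first)
  }
  headers <- which(startsWith(trimws(lines), ">"))
  for (h in headers) {
    nxt <- lines[seq_len(length(lines)) > h]
    upto <- which(startsWith(trimws(nxt), ">"))
    body <- if (length(upto)) nxt[seq_len(upto[1] - 1L)] else nxt
    if (!any(nzchar(trimws(body)))) {
      stop("malformed FASTA: record with empty sequence at line ", h)
    }
  }

  seqs <- Biostrings::readAAStringSet(path)
  tokens <- sub("\\s.*$", "", names(seqs))
  parsed <- lapply(tokens, parse_label_suffix)
  rec <- peptide_set(
    id = vapply(parsed, `[[`, character(1), "id"),
    sequence = as.character(seqs),
    label = vapply(parsed, `[[`, integer(1), "label")
  )

  if (!is.null(labels)) {
    tab <- if (is.data.frame(labels)) labels
           else utils::read.table(labels, header = FALSE,
                                  col.names = c("id", "label"),
                                  stringsAsFactors = FALSE)
    idx <- match(rec$id, tab$id)
    hit <- !is.na(idx)
    rec$label[hit] <- as.integer(tab$label[idx[hit]])
  }
  rec
}

#' Write a peptide set to FASTA
#'
#' Labels (when present) are written with the `|label=` header-suffix
#' convention so that [read_fasta()] round-trips them.
#'
#' @param records a [peptide_set].
#' @param path output file path.
#' @param label_suffix write `|label=` suffixes for labeled records
#'   (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, label_suffix = TRUE) {
  headers <- records$id
  if (label_suffix) {
    lab <- !is.na(records$label)
    headers[lab] <- paste0(headers[lab], "|label=", records$label[lab])
  }
  x <- Biostrings::AAStringSet(records$sequence)
  names(x) <- headers
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Validate sequences against the canonical amino-acid alphabet
#'
#' Checks every sequence against the 20 canonical letters
#' (`ACDEFGHIKLMNPQRSTVWY`). Ambiguity codes (X, B, Z), non-standard
#' residues (U, O), stops (`*`) and gaps all count as non-canonical.
#' Sequences are uppercased before checking.
#'
#' @param records a [peptide_set].
#' @param policy `"reject"` (default) raises an error naming the first
#'   offending record and character; `"drop"` removes offending records
#'   and reports the dropped count via the `"n_dropped"` attribute and a
#'   message.
#' @return The validated [peptide_set] (with attribute `n_dropped` under
#'   the drop policy).
#' @export
validate_alphabet <- function(records, policy = c("reject", "drop")) {
  policy <- match.arg(policy)
  seqs <- toupper(records$sequence)
  ok_letters <- AA_ALPHABET20
  offending <- vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    bad <- ch[!(ch %in% ok_letters)]
    if (length(bad)) bad[1] else NA_character_
  }, character(1), USE.NAMES = FALSE)
  bad <- !is.na(offending)
  if (policy == "reject") {
    if (any(bad)) {
      i <- which(bad)[1]
      stop("non-canonical residue '", offending[i], "' in record '",
           records$id[i], "'")
    }
    records$sequence <- seqs
    return(records)
  }
  out <- records[!bad, , drop = FALSE]
  out$sequence <- seqs[!bad]
  n_dropped <- sum(bad)
  if (n_dropped > 0) {
    message("validate_alphabet: dropped ", n_dropped,
            " record(s) with non-canonical residues")
  }
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("peptide_set", "data.frame")
  out
}

#' Filter peptides by sequence length
#'
#' Retains records whose length lies in the inclusive interval
#' `[min_len, max_len]`. Defaults to the 5-50 residue window
#' characteristic of functional anticancer peptides.
#'
#' @param records a [peptide_set].
#' @param min_len minimum length, inclusive (default 5).
#' @param max_len maximum length, inclusive (default 50).
#' @return The filtered [peptide_set], input order preserved.
#' @export
filter_by_length <- function(records, min_len = 5L, max_len = 50L) {
  stopifnot(min_len >= 1L, max_len >= min_len)
  len <- nchar(records$sequence)
  out <- records[len >= min_len & len <= max_len, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peptide_set", "data.frame")
  out
}
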