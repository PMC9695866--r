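#' Read DNA sequences from a FASTA file
#'
#' Residues are uppercased and `U` is normalized to `T` on ingest. The id of a
#' record is the first whitespace-delimited token of its header; the remainder
#' is kept as the description. Duplicate ids are made unique by suffixing
#' `_2`, `_3`, ... in file order.
#'
#' @param path Path to a FASTA file.
#' @param allow_gaps Allow `-` characters (alignment input). Default `FALSE`:
#'   plain templates must be ungapped.
#' @return A named character vector of residue strings, one per record, with
#'   the full header lines in the `"descriptions"` attribute.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path, allow_gaps = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty FASTA file: ", path)
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1]) stop("not FASTA: first non-blank line is not a header (", path, ")")
  rec <- cumsum(is_hdr)
  headers <- sub("^>", "", lines[is_hdr])
  seqs <- vapply(split(lines[!is_hdr], rec[!is_hdr]),
                 paste, "", collapse = "")
  ## records with no sequence lines are missing from the split result
  out <- character(length(headers))
  out[as.integer(names(seqs))] <- seqs
  ids <- vapply(strsplit(headers, "[ \t]+"), `[`, "", 1L)
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_")
  empty <- !nzchar(out)
  if (any(empty)) stop("record '", ids[which(empty)[1]], "' has no residues")
  out <- vapply(seq_along(out), function(i) {
    tryCatch(normalize_residues(out[i], context = paste0("record '", ids[i], "'"),
                                allow_gaps = allow_gaps),
             error = function(e) stop(conditionMessage(e), call. = FALSE))
  }, "")
  names(out) <- ids
  attr(out, "descriptions") <- headers
  out
}

#' Write DNA sequences to a FASTA file
#'
#' Sequences are wrapped at 70 columns (cosmetic only). Headers are taken from
#' the `"descriptions"` attribute when present, otherwise from the names.
#'
#' @param seqs Named character vector of residue strings.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), length(seqs) >= 1L, !is.null(names(seqs)))
  desc <- attr(seqs, "descriptions")
  if (is.null(desc)) desc <- names(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", desc[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = 70L)
    writeLines(substring(s, starts, pmin(starts + 69L, nchar(s))), con)
  }
  invisible(path)
}

## Validate a set of equal-length, gapped-or-not rows as an alignment.
as_alignment <- function(rows) {
  stopifnot(is.character(rows), !is.null(names(rows)))
  if (length(rows) < 2L) stop("an alignment needs at least 2 rows")
  len <- unique(nchar(rows))
  if (length(len) != 1L)
    stop("alignment rows differ in length: ", paste(len, collapse = ", "))
  rows[] <- vapply(seq_along(rows), function(i)
    normalize_residues(rows[[i]], context = paste0("row '", names(rows)[i], "'"),
                       allow_gaps = TRUE), "")
  rows
}
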