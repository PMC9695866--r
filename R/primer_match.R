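#' Polymerase extension rule for primer binding sites
#'
#' The combinatorial stand-in for PCR amplification chemistry: a primer is
#' predicted to prime extension from a binding site when (a) the 3'-terminal
#' `clamp_length` positions are mismatch-free and (b) the total mismatch count
#' does not exceed `max_total_mismatches`. The defaults (clamp of 2, at most 4
#' total) encode the empirical behaviour of the cixiid screening assay: a
#' single mismatch at the next-to-last 3' base abolishes amplification, while
#' up to one mismatch away from the 3' end does not.
#'
#' @param max_total_mismatches Maximum tolerated mismatches overall (>= 0).
#' @param clamp_length Number of 3'-terminal positions that must pair
#'   perfectly (>= 1).
#' @return An object of class `"extension_rule"`.
#' @export
extension_rule <- function(max_total_mismatches = 4L, clamp_length = 2L) {
  stopifnot(max_total_mismatches >= 0, clamp_length >= 1)
  structure(list(max_total_mismatches = as.integer(max_total_mismatches),
                 clamp_length = as.integer(clamp_length)),
            class = "extension_rule")
}

#' @export
print.extension_rule <- function(x, ...) {
  cat(sprintf("<extension_rule> 3' clamp %d nt mismatch-free, <= %d total mismatches\n",
              x$clamp_length, x$max_total_mismatches))
  invisible(x)
}

template_id_of <- function(template, template_id) {
  if (!is.null(template_id)) return(template_id)
  nm <- names(template)
  if (!is.null(nm) && nzchar(nm[1])) nm[1] else "template"
}

## Per-window mismatch counts for a primer laid along the plus strand
## (primer_bits already oriented left-to-right on the plus strand).
window_mismatch_counts <- function(template_bits, primer_bits, pessimistic) {
  L <- length(template_bits); k <- length(primer_bits)
  n <- L - k + 1L
  mm <- integer(n)
  for (j in seq_len(k)) {
    tseg <- template_bits[j:(j + n - 1L)]
    bad <- if (pessimistic)
      bitwAnd(tseg, bitwAnd(15L, bitwNot(primer_bits[j]))) != 0L
    else
      bitwAnd(tseg, primer_bits[j]) == 0L
    mm <- mm + bad
  }
  mm
}

## Build a match_profile for one window. start is 0-based on the plus strand.
make_profile <- function(primer, template_seq, template_id, strand, start,
                         pessimistic) {
  k <- primer$length
  window <- substr(template_seq, start + 1L, start + k)
  tb <- seq_bits(window)
  oriented <- if (strand == "plus") primer$sequence else
    reverse_complement(primer$sequence)
  pb <- seq_bits(oriented)
  bad <- if (pessimistic)
    bitwAnd(tb, bitwAnd(15L, bitwNot(pb))) != 0L
  else
    bitwAnd(tb, pb) == 0L
  j <- which(bad)                                    # window positions, 1-based
  offsets <- if (strand == "plus") k - j else j - 1L # from the primer 3' end
  structure(
    list(primer = primer$name, template = template_id, strand = strand,
         start = start, end = start + k,
         mismatch_offsets = sort(as.integer(offsets)),
         total_mismatches = length(j),
         window_sequence = window, primer_length = k),
    class = "match_profile"
  )
}

#' @export
print.match_profile <- function(x, ...) {
  cat(sprintf("<match_profile> %s on %s [%d,%d) %s strand: %d mismatch(es)%s\n",
              x$primer, x$template, x$start, x$end, x$strand,
              x$total_mismatches,
              if (x$total_mismatches)
                paste0(" at 3'-offset ", paste(x$mismatch_offsets, collapse = ";"))
              else ""))
  invisible(x)
}

#' Find the best binding site of a primer on a template
#'
#' Slides the primer along the requested strand of an ungapped template and
#' returns the window with the fewest mismatches (IUPAC codes count as a match
#' whenever their base sets intersect). Ties are broken by the smallest
#' plus-strand start. For `strand = "minus"` the primer is compared against
#' the reverse complement and the interval is reported in plus-strand
#' coordinates; mismatch positions are always reported as 0-based offsets from
#' the primer's 3' terminus (0 = terminal base), because extension blocking is
#' a 3'-end phenomenon.
#'
#' @param primer A [primer()] object.
#' @param template A single residue string (optionally named with its id).
#' @param strand `"plus"`, `"minus"`, or `"both"` (best over both; plus wins
#'   ties). Defaults to the strand implied by the primer's role.
#' @param pessimistic If `TRUE`, a degenerate template code (e.g. `N`) counts
#'   as a mismatch unless its base set is contained in the primer's. Default
#'   `FALSE` (optimistic: intersection suffices).
#' @param template_id Optional id overriding `names(template)`.
#' @return A `"match_profile"`: list with elements `primer`, `template`,
#'   `strand`, `start`/`end` (0-based half-open, plus strand),
#'   `mismatch_offsets` (from the 3' end), `total_mismatches`,
#'   `window_sequence`.
#' @export
find_best_binding_site <- function(primer, template, strand = NULL,
                                   pessimistic = FALSE, template_id = NULL) {
  stopifnot(inherits(primer, "primer"))
  tid <- template_id_of(template, template_id)
  tseq <- normalize_residues(as.character(template)[1],
                             context = paste0("template '", tid, "'"),
                             allow_gaps = FALSE)
  if (is.null(strand))
    strand <- if (primer$role == "forward") "plus" else "minus"
  strand <- match.arg(strand, c("plus", "minus", "both"))
  if (nchar(tseq) < primer$length)
    stop("template '", tid, "' (", nchar(tseq), " nt) is shorter than primer ",
         primer$name, " (", primer$length, " nt)")
  tb <- seq_bits(tseq)
  strands <- if (strand == "both") c("plus", "minus") else strand
  best <- NULL
  for (str in strands) {
    oriented <- if (str == "plus") primer$sequence else
      reverse_complement(primer$sequence)
    mm <- window_mismatch_counts(tb, seq_bits(oriented), pessimistic)
    i <- which.min(mm)                       # earliest window among ties
    cand <- c(mm[i], i - 1L)
    if (is.null(best) || cand[1] < best$mm ||
        (cand[1] == best$mm && cand[2] < best$start))
      best <- list(mm = cand[1], start = cand[2], strand = str)
  }
  make_profile(primer, tseq, tid, best$strand, best$start, pessimistic)
}

#' Enumerate all binding sites of a primer up to a mismatch budget
#'
#' Every window on both strands (or one) with at most `max_mismatches`
#' mismatches, sorted by plus-strand start (plus before minus at equal start).
#' Overlapping sites are all reported.
#'
#' @inheritParams find_best_binding_site
#' @param max_mismatches Mismatch budget per site.
#' @param strands Strands to scan (default both).
#' @return A list of `"match_profile"` objects (possibly empty).
#' @export
all_binding_sites <- function(primer, template, max_mismatches,
                              strands = c("plus", "minus"),
                              pessimistic = FALSE, template_id = NULL) {
  stopifnot(inherits(primer, "primer"))
  tid <- template_id_of(template, template_id)
  tseq <- normalize_residues(as.character(template)[1],
                             context = paste0("template '", tid, "'"),
                             allow_gaps = FALSE)
  if (nchar(tseq) < primer$length)
    stop("template '", tid, "' is shorter than primer ", primer$name)
  tb <- seq_bits(tseq)
  hits <- list()
  for (str in strands) {
    oriented <- if (str == "plus") primer$sequence else
      reverse_complement(primer$sequence)
    mm <- window_mismatch_counts(tb, seq_bits(oriented), pessimistic)
    for (i in which(mm <= max_mismatches))
      hits[[length(hits) + 1L]] <-
        make_profile(primer, tseq, tid, str, i - 1L, pessimistic)
  }
  ord <- order(vapply(hits, `[[`, 0, "start"),
               vapply(hits, function(h) h$strand == "minus", NA))
  hits[ord]
}

#' Predict whether a binding site supports polymerase extension
#'
#' @param profile A `"match_profile"` from [find_best_binding_site()] or
#'   [all_binding_sites()].
#' @param rule An [extension_rule()].
#' @return `TRUE` iff no mismatch falls within the 3' clamp and the total
#'   mismatch count is within the rule's budget.
#' @export
predicts_extension <- function(profile, rule = extension_rule()) {
  stopifnot(inherits(profile, "match_profile"), inherits(rule, "extension_rule"))
  !any(profile$mismatch_offsets < rule$clamp_length) &&
    profile$total_mismatches <= rule$max_total_mismatches
}

#' Tabulate best binding sites of primers across templates
#'
#' The machine-readable analogue of a primer-alignment figure: one row per
#' primer x template with the best site's coordinates, mismatch total, the
#' list of 3'-offsets and the extension verdict.
#'
#' @param primers List of [primer()] objects.
#' @param templates Named character vector of ungapped templates.
#' @param rule An [extension_rule()] used for the `predicted_extension` column.
#' @param pessimistic Passed to [find_best_binding_site()].
#' @return A data.frame with columns `primer`, `template`, `strand`, `start`,
#'   `end`, `total_mismatches`, `offsets_3p` (semicolon-joined),
#'   `predicted_extension`.
#' @export
mismatch_table <- function(primers, templates, rule = extension_rule(),
                           pessimistic = FALSE) {
  stopifnot(length(primers) >= 1L, length(templates) >= 1L,
            !is.null(names(templates)))
  rows <- list()
  for (p in primers) for (i in seq_along(templates)) {
    pr <- find_best_binding_site(p, templates[[i]], strand = NULL,
                                 pessimistic = pessimistic,
                                 template_id = names(templates)[i])
    rows[[length(rows) + 1L]] <- data.frame(
      primer = pr$primer, template = pr$template, strand = pr$strand,
      start = pr$start, end = pr$end,
      total_mismatches = pr$total_mismatches,
      offsets_3p = paste(pr$mismatch_offsets, collapse = ";"),
      predicted_extension = predicts_extension(pr, rule),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Write a mismatch table as tab-separated text
#'
#' @param tab Output of [mismatch_table()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_mismatch_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
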