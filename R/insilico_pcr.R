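#' Predict PCR amplicons for a primer pair on a template
#'
#' Enumerates candidate forward sites (plus strand) and reverse sites (minus
#' strand) with at most the rule's mismatch budget, combines every pair in
#' productive orientation — the forward footprint entirely upstream of the
#' reverse footprint — with a product no longer than `max_product`, and flags
#' each combination as `predicted` when both sites pass the extension rule.
#' Product length is outer edge to outer edge, inclusive of both primer
#' footprints (the convention under which the species-specific cixiid pair
#' yields its published 341 bp product).
#'
#' @param fw,rv [primer()] objects (forward and reverse).
#' @param template A single residue string, optionally named with its id.
#' @param rule An [extension_rule()].
#' @param max_product Maximum product length in bp (default 3000).
#' @param pessimistic Passed to the site search.
#' @param template_id Optional id overriding `names(template)`.
#' @return A data.frame of class `"amplicon_predictions"`, sorted by
#'   `product_length`, with columns `template`, `pair`, `fw_start`, `fw_end`,
#'   `rv_start`, `rv_end` (0-based half-open, plus strand), `product_length`,
#'   `fw_mismatches`, `rv_mismatches`, `predicted`; the underlying
#'   match profiles are kept in attributes `fw_profiles` / `rv_profiles`.
#' @export
simulate_pcr <- function(fw, rv, template, rule = extension_rule(),
                         max_product = 3000L, pessimistic = FALSE,
                         template_id = NULL) {
  stopifnot(inherits(fw, "primer"), inherits(rv, "primer"))
  if (max_product < fw$length + rv$length)
    stop("max_product is shorter than the combined primer footprints")
  tid <- template_id_of(template, template_id)
  fw_sites <- all_binding_sites(fw, template, rule$max_total_mismatches,
                                strands = "plus", pessimistic = pessimistic,
                                template_id = tid)
  rv_sites <- all_binding_sites(rv, template, rule$max_total_mismatches,
                                strands = "minus", pessimistic = pessimistic,
                                template_id = tid)
  pair_name <- paste0(fw$name, "/", rv$name)
  rows <- list(); fps <- list(); rps <- list()
  for (f in fw_sites) for (r in rv_sites) {
    len <- r$end - f$start
    if (f$start >= r$start || f$end > r$start) next  # nested/inverted/overlap
    if (len < fw$length + rv$length || len > max_product) next
    rows[[length(rows) + 1L]] <- data.frame(
      template = tid, pair = pair_name,
      fw_start = f$start, fw_end = f$end,
      rv_start = r$start, rv_end = r$end,
      product_length = len,
      fw_mismatches = f$total_mismatches,
      rv_mismatches = r$total_mismatches,
      predicted = predicts_extension(f, rule) && predicts_extension(r, rule),
      stringsAsFactors = FALSE)
    fps[[length(fps) + 1L]] <- f
    rps[[length(rps) + 1L]] <- r
  }
  if (length(rows) == 0L) {
    out <- data.frame(template = character(), pair = character(),
                      fw_start = integer(), fw_end = integer(),
                      rv_start = integer(), rv_end = integer(),
                      product_length = integer(), fw_mismatches = integer(),
                      rv_mismatches = integer(), predicted = logical(),
                      stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, rows)
    ord <- order(out$product_length, out$fw_start)
    out <- out[ord, , drop = FALSE]
    rownames(out) <- NULL
    fps <- fps[ord]; rps <- rps[ord]
  }
  attr(out, "fw_profiles") <- fps
  attr(out, "rv_profiles") <- rps
  class(out) <- c("amplicon_predictions", "data.frame")
  out
}

#' Cross primer pairs against templates into a specificity matrix
#'
#' The computational analogue of running a PCR panel on a species collection:
#' each cell records whether any productive amplicon is predicted for that
#' primer pair on that template, and the predicted product length(s) if so.
#'
#' @param pairs Named list of `list(fw =, rv =)` primer pairs, e.g.
#'   [cixiid_primer_pairs()].
#' @param templates Named character vector of templates; ids must be unique.
#' @param rule An [extension_rule()].
#' @param max_product,pessimistic Passed to [simulate_pcr()].
#' @return An object of class `"specificity_matrix"`: list with `status`
#'   (character matrix, `"amplified"`/`"not_amplified"`, templates x pairs)
#'   and `product_length` (character matrix of semicolon-joined predicted
#'   lengths, `""` where none).
#' @export
specificity_matrix <- function(pairs, templates, rule = extension_rule(),
                               max_product = 3000L, pessimistic = FALSE) {
  stopifnot(length(pairs) >= 1L, length(templates) >= 1L)
  if (is.null(names(templates)) || anyDuplicated(names(templates)))
    stop("templates must carry unique ids")
  if (is.null(names(pairs)))
    names(pairs) <- vapply(pairs, function(p) paste0(p$fw$name, "/", p$rv$name), "")
  status <- matrix("not_amplified", length(templates), length(pairs),
                   dimnames = list(names(templates), names(pairs)))
  lens <- matrix("", length(templates), length(pairs),
                 dimnames = dimnames(status))
  for (j in seq_along(pairs)) for (i in seq_along(templates)) {
    amp <- simulate_pcr(pairs[[j]]$fw, pairs[[j]]$rv, templates[[i]],
                        rule = rule, max_product = max_product,
                        pessimistic = pessimistic,
                        template_id = names(templates)[i])
    hit <- amp$predicted
    if (any(hit)) {
      status[i, j] <- "amplified"
      lens[i, j] <- paste(amp$product_length[hit], collapse = ";")
    }
  }
  structure(list(status = status, product_length = lens,
                 rule = rule),
            class = "specificity_matrix")
}

#' @export
print.specificity_matrix <- function(x, ...) {
  shown <- x$status
  shown[shown == "amplified"] <- paste0("+(", x$product_length[x$status == "amplified"], ")")
  shown[shown == "not_amplified"] <- "-"
  cat("<specificity_matrix> templates x primer pairs ('+(len)' = predicted amplicon)\n")
  print(shown, quote = FALSE)
  invisible(x)
}

#' Write a specificity matrix as CSV
#'
#' Cells contain `amplified(<lengths>)` or `not_amplified`.
#'
#' @param x A `"specificity_matrix"`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_specificity_csv <- function(x, path) {
  stopifnot(inherits(x, "specificity_matrix"))
  cells <- x$status
  amp <- cells == "amplified"
  cells[amp] <- paste0("amplified(", x$product_length[amp], ")")
  df <- data.frame(template = rownames(cells), cells, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract predicted amplicon sequences
#'
#' @param predictions An `"amplicon_predictions"` object from [simulate_pcr()].
#' @param template The template string the predictions came from.
#' @param predicted_only Keep only amplicons passing the extension rule
#'   (default `TRUE`).
#' @return A named character vector of amplicon sequences with ids
#'   `template|pair|length`, suitable for [write_fasta()].
#' @export
amplicon_sequences <- function(predictions, template, predicted_only = TRUE) {
  stopifnot(inherits(predictions, "amplicon_predictions"))
  keep <- if (predicted_only) predictions$predicted else
    rep(TRUE, nrow(predictions))
  predictions <- predictions[keep, , drop = FALSE]
  if (nrow(predictions) == 0L) return(stats::setNames(character(), character()))
  tseq <- as.character(template)[1]
  seqs <- substring(tseq, predictions$fw_start + 1L, predictions$rv_end)
  stats::setNames(seqs, paste(predictions$template, predictions$pair,
                              predictions$product_length, sep = "|"))
}
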