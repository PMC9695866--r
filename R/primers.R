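#' Define a PCR primer
#'
#' A primer is a named, oriented oligonucleotide written 5' to 3' in IUPAC
#' code (degenerate positions allowed, gaps not). Reverse primers are stored
#' as written; matching functions place them on the minus strand.
#'
#' @param name Primer label.
#' @param sequence 5'->3' IUPAC string, length >= 10, no gaps.
#' @param role `"forward"` or `"reverse"`.
#' @param partner Optional name of the primer this one is paired with.
#' @return An object of class `"primer"`.
#' @examples
#' primer("Plep-fw1", "TTATTGCAGTACCAACAGGT", "forward")
#' @export
primer <- function(name, sequence, role = c("forward", "reverse"),
                   partner = NULL) {
  role <- match.arg(role)
  sequence <- normalize_residues(sequence, context = paste0("primer '", name, "'"),
                                 allow_gaps = FALSE)
  if (nchar(sequence) < 10L)
    stop("primer '", name, "' is shorter than 10 nt")
  structure(
    list(name = name, sequence = sequence, role = role,
         length = nchar(sequence), degeneracy = degeneracy(sequence),
         partner = partner),
    class = "primer"
  )
}

#' @export
print.primer <- function(x, ...) {
  cat(sprintf("<primer> %s (%s, %d nt, degeneracy %g)\n  5'-%s-3'\n",
              x$name, x$role, x$length, x$degeneracy, x$sequence))
  invisible(x)
}

#' The published COI primer set for cixiid planthopper screening
#'
#' The six primers used in the Pentastiridius leporinus detection assay: the
#' species-specific pair Plep-fw1/Plep-rv1 (341 bp product on the target COI),
#' the universal cixiid pair Ron/Calvin (~1000 bp) and the universal
#' hemipteran pair UEA3/UEA8 (~1000 bp). Calvin, and UEA3/UEA8 binding
#' contexts, carry degenerate positions.
#'
#' @return A named list of [primer()] objects:
#'   `Ron`, `Calvin`, `Plep-fw1`, `Plep-rv1`, `UEA3`, `UEA8`.
#' @export
cixiid_primers <- function() {
  p <- list(
    primer("Ron",      "GGATCACCTGATATAGCATTCCC",         "forward", "Calvin"),
    primer("Calvin",   "GGRAARAAWGTTAARTTWACTCC",         "reverse", "Ron"),
    primer("Plep-fw1", "TTATTGCAGTACCAACAGGT",            "forward", "Plep-rv1"),
    primer("Plep-rv1", "TGTGAAATTTACTCCTGTAAATATAGTAAAG", "reverse", "Plep-fw1"),
    primer("UEA3",     "TATAGCATTCCCACGAATAAATAA",        "forward", "UEA8"),
    primer("UEA8",     "AAAAATGTTGAGGGAAAAATGTTA",        "reverse", "UEA3")
  )
  stats::setNames(p, vapply(p, `[[`, "", "name"))
}

#' The standard primer pairs of the screening assay
#'
#' @return A named list of `list(fw =, rv =)` pairs built from
#'   [cixiid_primers()]: `specific` (Plep-fw1/Plep-rv1), `Ron/Calvin`,
#'   `UEA3/UEA8`.
#' @export
cixiid_primer_pairs <- function() {
  p <- cixiid_primers()
  list(
    "specific"   = list(fw = p[["Plep-fw1"]], rv = p[["Plep-rv1"]]),
    "Ron/Calvin" = list(fw = p[["Ron"]],      rv = p[["Calvin"]]),
    "UEA3/UEA8"  = list(fw = p[["UEA3"]],     rv = p[["UEA8"]])
  )
}
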