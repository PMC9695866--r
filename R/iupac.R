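#' @keywords internal
"_PACKAGE"

## IUPAC nucleotide codes as 4-bit base sets: A=1, C=2, G=4, T=8.
## Bitwise AND > 0 <=> the two base sets intersect.
IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L,  # A/G
  Y = 10L, # C/T
  S = 6L,  # C/G
  W = 9L,  # A/T
  K = 12L, # G/T
  M = 3L,  # A/C
  B = 14L, # C/G/T
  D = 13L, # A/G/T
  H = 11L, # A/C/T
  V = 7L,  # A/C/G
  N = 15L
)

IUPAC_LETTERS <- names(IUPAC_BITS)

## Set-wise complement: A<->T, C<->G, R<->Y, K<->M, B<->V, D<->H; S, W, N fixed.
IUPAC_COMPLEMENT_FROM <- "ACGTRYSWKMBDHVN"
IUPAC_COMPLEMENT_TO   <- "TGCAYRSWMKVHDBN"

#' Test whether two IUPAC nucleotide codes are compatible
#'
#' Two codes are compatible when the base sets they denote intersect, e.g.
#' `R` (A/G) is compatible with `A` but not with `C`; `N` is compatible with
#' every base. This is the match criterion used throughout primer matching:
#' a primer position is a mismatch only when its code shares no base with the
#' template code.
#'
#' @param a,b Single IUPAC nucleotide characters (case-insensitive). Gaps are
#'   rejected: compatibility is only defined for bases.
#' @return `TRUE` if the base sets intersect, else `FALSE`.
#' @examples
#' bases_compatible("R", "A") # TRUE
#' bases_compatible("A", "C") # FALSE
#' bases_compatible("N", "Y") # TRUE
#' @export
bases_compatible <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (identical(a, "-") || identical(b, "-"))
    stop("bases_compatible() is undefined for gap characters")
  ba <- IUPAC_BITS[a]; bb <- IUPAC_BITS[b]
  if (is.na(ba)) stop("not an IUPAC nucleotide code: '", a, "'")
  if (is.na(bb)) stop("not an IUPAC nucleotide code: '", b, "'")
  bitwAnd(ba, bb) > 0L
}

#' Reverse complement of an IUPAC string
#'
#' Complements degenerate codes set-wise (R<->Y, W<->W, N<->N, ...) and
#' reverses the sequence, so the result reads 5' to 3' on the opposite strand.
#' An involution: `reverse_complement(reverse_complement(x)) == x`.
#'
#' @param s A gap-free IUPAC DNA string (case-insensitive; `U` is accepted and
#'   treated as `T`).
#' @return The reverse complement, uppercase.
#' @examples
#' reverse_complement("GGATCACCTGATATAGCATTCCC")
#' @export
reverse_complement <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  if (nchar(s) == 0L) return("")
  s <- normalize_residues(s, context = "reverse_complement", allow_gaps = FALSE)
  comp <- chartr(IUPAC_COMPLEMENT_FROM, IUPAC_COMPLEMENT_TO, s)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

## Uppercase, U->T, and validate residues. Errors name the first bad position.
normalize_residues <- function(s, context = "sequence", allow_gaps = FALSE) {
  s <- chartr("u", "t", s)
  s <- toupper(s)
  s <- chartr("U", "T", s)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  if (!allow_gaps && any(chars == "-"))
    stop(context, ": gap character at position ", which(chars == "-")[1],
         " (gaps are only allowed in alignments)")
  ok <- chars %in% IUPAC_LETTERS
  if (allow_gaps) ok <- ok | chars == "-"
  if (!all(ok)) {
    pos <- which(!ok)[1]
    stop(context, ": illegal character '", chars[pos], "' at position ", pos)
  }
  s
}

## Integer bit vector for a residue string (gaps become 0L when allowed).
seq_bits <- function(s, allow_gaps = FALSE) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  bits <- IUPAC_BITS[chars]
  bits[chars == "-"] <- if (allow_gaps) 0L else NA_integer_
  unname(bits)
}

#' Degeneracy of an IUPAC oligonucleotide
#'
#' The number of concrete A/C/G/T sequences a degenerate oligo denotes: the
#' product of per-position base-set sizes (1 for A/C/G/T, 2 for R/Y/S/W/K/M,
#' 3 for B/D/H/V, 4 for N).
#'
#' @param s An IUPAC DNA string without gaps.
#' @return An integer (or double if very large).
#' @examples
#' degeneracy("GGRAARAAWGTTAARTTWACTCC") # Calvin: 2^5 = 32
#' @export
degeneracy <- function(s) {
  s <- normalize_residues(s, context = "degeneracy", allow_gaps = FALSE)
  bits <- seq_bits(s)
  sizes <- vapply(bits, function(b) sum(bitwAnd(b, c(1L, 2L, 4L, 8L)) > 0L), 1L)
  prod(sizes)
}
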