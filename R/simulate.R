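TS_MAP  <- c(A = "G", G = "A", C = "T", T = "C")
TV1_MAP <- c(A = "C", G = "C", C = "A", T = "A")
TV2_MAP <- c(A = "T", G = "T", C = "G", T = "G")

#' Parameters of a synthetic COI-like sequence family
#'
#' Defaults state the world the analysis assumes: small within-species
#' divergence (0.006 substitutions/site, i.e. 0.6 per 100 sites) and an
#' order-of-magnitude larger between-species divergence (0.051, i.e. 5.1 per
#' 100 sites), on fragments of the species-specific amplicon scale (341 nt;
#' set `length = 1000` for the universal-primer scale).
#'
#' @param n_species Number of species.
#' @param n_per_species Sequences (specimens) per species.
#' @param length Sequence length in nt (>= 100).
#' @param intra Expected intraspecific divergence, substitutions/site.
#' @param inter Expected interspecific divergence, substitutions/site; must
#'   exceed `intra` and stay below 0.75.
#' @param model `"JC"` (default) or `"K2P"`.
#' @param kappa Transition/transversion rate ratio for `"K2P"`.
#' @param base_freqs Root base composition (A, C, G, T).
#' @param shape Species-tree shape: `"symmetric"` (star radiation: every
#'   interspecific pair at divergence `inter`) or `"caterpillar"` (chained
#'   species splits, for NJ stress tests).
#' @param seed Integer seed.
#' @return A list of class `"family_params"`.
#' @export
family_params <- function(n_species = 3L, n_per_species = 4L, length = 341L,
                          intra = 0.006, inter = 0.051,
                          model = c("JC", "K2P"), kappa = 2,
                          base_freqs = c(0.25, 0.25, 0.25, 0.25),
                          shape = c("symmetric", "caterpillar"),
                          seed = 1L) {
  model <- match.arg(model); shape <- match.arg(shape)
  if (!(intra >= 0 && intra < inter && inter < 0.75))
    stop("need 0 <= intra < inter < 0.75")
  if (length < 100L) stop("length must be >= 100")
  stopifnot(n_species >= 1L, n_per_species >= 1L,
            abs(sum(base_freqs) - 1) < 1e-8)
  structure(list(n_species = as.integer(n_species),
                 n_per_species = as.integer(n_per_species),
                 length = as.integer(length), intra = intra, inter = inter,
                 model = model, kappa = if (model == "JC") 1 else kappa,
                 base_freqs = base_freqs, shape = shape,
                 seed = as.integer(seed)),
            class = "family_params")
}

## Evolve a character vector of A/C/G/T for an expected d substitutions/site
## under K2P (kappa = 1 gives JC). Closed-form site categories, vectorized.
evolve_chars <- function(x, d, kappa = 1) {
  if (d == 0) return(x)
  e1 <- exp(-4 * d / (kappa + 2))
  e2 <- exp(-2 * d * (kappa + 1) / (kappa + 2))
  p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2
  p_tv <- 0.25 - 0.25 * e1            # each of the two transversion targets
  ev <- sample.int(4L, length(x), replace = TRUE,
                   prob = c(1 - p_ts - 2 * p_tv, p_ts, p_tv, p_tv))
  out <- x
  out[ev == 2L] <- TS_MAP[x[ev == 2L]]
  out[ev == 3L] <- TV1_MAP[x[ev == 3L]]
  out[ev == 4L] <- TV2_MAP[x[ev == 4L]]
  out
}

random_root <- function(length, base_freqs) {
  sample(c("A", "C", "G", "T"), length, replace = TRUE, prob = base_freqs)
}

#' Simulate a COI-like sequence family with known structure
#'
#' A random root sequence is evolved along the species tree (branch lengths
#' scaled so heterospecific pairs diverge by `inter` in expectation), then
#' each species radiates its specimens (conspecific pairs diverge by `intra`).
#' Deterministic for a given seed; the generating tree is returned for
#' recovery tests.
#'
#' @param params A [family_params()] object.
#' @return A list with `sequences` (named character vector, ids
#'   `sp<i>_<j>`), `tree` (the generating [ape::phylo] with those tips) and
#'   `params`.
#' @export
simulate_family <- function(params) {
  stopifnot(inherits(params, "family_params"))
  set.seed(params$seed)
  root <- random_root(params$length, params$base_freqs)
  s <- params$n_species; k <- params$kappa
  ## species branches are net of the tip branches, so a heterospecific pair
  ## diverges by `inter` in expectation and a conspecific pair by `intra`
  half_int <- (params$inter - params$intra) / 2
  half_intra <- params$intra / 2
  ancestors <- vector("list", s)
  sp_branch <- numeric(s)
  if (params$shape == "symmetric" || s == 1L) {
    for (i in seq_len(s)) ancestors[[i]] <- evolve_chars(root, half_int, k)
    sp_branch[] <- half_int
  } else {
    ## caterpillar: chained splits, species i hangs off node i-1
    node <- root
    for (i in seq_len(s)) {
      ancestors[[i]] <- evolve_chars(node, half_int, k)
      sp_branch[i] <- half_int
      node <- evolve_chars(node, half_int, k)
    }
  }
  seqs <- character(0)
  for (i in seq_len(s)) for (j in seq_len(params$n_per_species)) {
    tip <- evolve_chars(ancestors[[i]], half_intra, k)
    seqs[paste0("sp", i, "_", j)] <- paste(tip, collapse = "")
  }
  tree <- ape::read.tree(text = family_tree_newick(s, params$n_per_species,
                                                   sp_branch, half_intra,
                                                   params$shape, half_int))
  list(sequences = seqs, tree = tree, params = params)
}

family_tree_newick <- function(s, npp, sp_branch, tip_len, shape, half_int) {
  clade <- function(i) {
    if (npp == 1L) return(paste0("sp", i, "_1:", tip_len + sp_branch[i]))
    tips <- paste0("sp", i, "_", seq_len(npp), ":", tip_len)
    paste0("(", paste(tips, collapse = ","), "):", sp_branch[i])
  }
  if (shape == "symmetric" || s <= 2L)
    return(paste0("(", paste(vapply(seq_len(s), clade, ""), collapse = ","), ");"))
  nwk <- clade(s)                     # caterpillar: nest from the last species
  for (i in rev(seq_len(s - 1L))) {
    br <- if (i == 1L) "" else paste0(":", half_int)
    nwk <- paste0("(", clade(i), ",", nwk, ")", br)
  }
  paste0(nwk, ";")
}

bits_to_bases <- function(bits) c("A", "C", "G", "T")[
  which(bitwAnd(bits, c(1L, 2L, 4L, 8L)) > 0L)]

## One concrete realization of an IUPAC string; planted mismatch positions
## (1-based along the string) get a base incompatible with the code there.
realize_site <- function(iupac, mismatch_at = integer()) {
  bits <- seq_bits(iupac)
  vapply(seq_along(bits), function(j) {
    opts <- bits_to_bases(bits[j])
    if (j %in% mismatch_at) {
      bad <- setdiff(c("A", "C", "G", "T"), opts)
      if (length(bad) == 0L)
        stop("cannot plant a mismatch against code 'N' at position ", j)
      if (length(bad) == 1L) bad else sample(bad, 1L)
    } else if (length(opts) == 1L) opts else sample(opts, 1L)
  }, "")
}

#' Implant forward/reverse primer binding sites into a template
#'
#' Builds a test template whose best binding sites for the given primers are
#' exactly at the planted coordinates with exactly the planted 3'-offset
#' mismatches; mismatched bases are chosen incompatible with the primer code
#' at that position. The construction is verified by re-running the binding
#' site search; a failure (e.g. a fortuitous better site in the background)
#' is an error, so a returned object always satisfies its own contract.
#'
#' @param base A template residue string (A/C/G/T background).
#' @param fw,rv [primer()] objects.
#' @param product_length Intended outer-edge product length (>= combined
#'   footprints; must fit in the template).
#' @param fw_mismatch_offsets,rv_mismatch_offsets Planted mismatch positions
#'   as 0-based offsets from each primer's 3' end.
#' @param seed Integer seed (degenerate-code realization and mismatch base
#'   choice).
#' @param fw_start Optional 0-based start of the forward footprint; default
#'   centers the product.
#' @return A list of class `"planted_template"`: `sequence` (named), `fw_start`,
#'   `fw_end`, `rv_start`, `rv_end`, `product_length`, `fw_mismatch_offsets`,
#'   `rv_mismatch_offsets`.
#' @export
implant_primer_sites <- function(base, fw, rv, product_length,
                                 fw_mismatch_offsets = integer(),
                                 rv_mismatch_offsets = integer(),
                                 seed = 1L, fw_start = NULL) {
  stopifnot(inherits(fw, "primer"), inherits(rv, "primer"))
  base <- normalize_residues(as.character(base)[1], "base template", FALSE)
  L <- nchar(base)
  if (product_length < fw$length + rv$length)
    stop("product_length smaller than the combined primer footprints")
  if (product_length > L) stop("product_length does not fit in the template")
  if (any(fw_mismatch_offsets >= fw$length) ||
      any(rv_mismatch_offsets >= rv$length))
    stop("mismatch offsets must be smaller than the primer length")
  if (is.null(fw_start)) fw_start <- (L - product_length) %/% 2L
  fw_start <- as.integer(fw_start)
  rv_end <- as.integer(fw_start + product_length)
  if (rv_end > L) stop("planted sites fall off the template")
  set.seed(seed)
  chars <- strsplit(base, "", fixed = TRUE)[[1]]
  ## forward footprint: primer position j has 3'-offset k - j
  k <- fw$length
  fw_site <- realize_site(fw$sequence, mismatch_at = k - fw_mismatch_offsets)
  chars[(fw_start + 1L):(fw_start + k)] <- fw_site
  ## reverse footprint on the plus strand: position j has 3'-offset j - 1
  kr <- rv$length
  rv_site <- realize_site(reverse_complement(rv$sequence),
                          mismatch_at = rv_mismatch_offsets + 1L)
  chars[(rv_end - kr + 1L):rv_end] <- rv_site
  template <- stats::setNames(paste(chars, collapse = ""), "planted_template")
  fw_hit <- find_best_binding_site(fw, template, strand = "plus")
  rv_hit <- find_best_binding_site(rv, template, strand = "minus")
  ok <- fw_hit$start == fw_start &&
    identical(fw_hit$mismatch_offsets, sort(as.integer(fw_mismatch_offsets))) &&
    rv_hit$end == rv_end &&
    identical(rv_hit$mismatch_offsets, sort(as.integer(rv_mismatch_offsets)))
  if (!ok)
    stop("implant construction not recovered by the binding-site search; ",
         "try another seed or a longer/cleaner base template")
  structure(list(sequence = template,
                 fw_start = fw_start, fw_end = fw_start + k,
                 rv_start = rv_end - kr, rv_end = rv_end,
                 product_length = as.integer(product_length),
                 fw_mismatch_offsets = sort(as.integer(fw_mismatch_offsets)),
                 rv_mismatch_offsets = sort(as.integer(rv_mismatch_offsets))),
            class = "planted_template")
}

#' Write a simulated family with its truth sidecar
#'
#' FASTA plus a JSON sidecar recording the generating tree (Newick), the
#' parameters and the seed, so a run can be reproduced and scored.
#'
#' @param fam Output of [simulate_family()].
#' @param fasta_path,json_path Output paths.
#' @return `fasta_path`, invisibly.
#' @export
write_family <- function(fam, fasta_path, json_path) {
  write_fasta(fam$sequences, fasta_path)
  jsonlite::write_json(
    list(tree = ape::write.tree(fam$tree),
         params = unclass(fam$params)),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(fasta_path)
}
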