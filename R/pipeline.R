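#' Configuration for an end-to-end screening run
#'
#' One flat configuration object feeding [run_specificity()] and
#' [run_phylogeny()]. File paths are checked up front so a run fails before
#' any computation. The bundled [cixiid_primer_pairs()] are the default
#' primer set; the pair named `specific` is the one whose non-target
#' amplification constitutes a specificity violation.
#'
#' @param targets,nontargets Paths to FASTA files of target / non-target
#'   templates (either may be `NULL` where unused; `run_specificity()` needs
#'   at least targets).
#' @param alignment Path to a pre-aligned FASTA for the phylogeny.
#' @param pairs Named list of primer pairs (default [cixiid_primer_pairs()]).
#' @param rule An [extension_rule()].
#' @param max_product Maximum product length for [simulate_pcr()].
#' @param replicates Bootstrap replicates (default 1000).
#' @param outgroups Character vector of outgroup tip labels, or `NULL`.
#' @param scale100 Also report distances multiplied by 100 (default `TRUE`).
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed recorded in the manifest and used for all
#'   randomness.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(targets = NULL, nontargets = NULL, alignment = NULL,
                       pairs = cixiid_primer_pairs(),
                       rule = extension_rule(), max_product = 3000L,
                       replicates = 1000L, outgroups = NULL,
                       scale100 = TRUE, out_dir = tempfile("cixscreen_run_"),
                       seed = 1L) {
  for (p in c(targets, nontargets, alignment))
    if (!is.null(p) && !file.exists(p)) stop("input file does not exist: ", p)
  structure(list(targets = targets, nontargets = nontargets,
                 alignment = alignment, pairs = pairs, rule = rule,
                 max_product = as.integer(max_product),
                 replicates = as.integer(replicates), outgroups = outgroups,
                 scale100 = isTRUE(scale100), out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

write_manifest <- function(config, path, extra = list()) {
  inputs <- Filter(Negate(is.null),
                   config[c("targets", "nontargets", "alignment")])
  manifest <- c(list(
    seed = config$seed,
    rule = unclass(config$rule),
    max_product = config$max_product,
    replicates = config$replicates,
    outgroups = config$outgroups,
    pairs = lapply(config$pairs, function(p)
      list(fw = p$fw$sequence, rv = p$rv$sequence)),
    inputs = lapply(inputs, function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))),
    r_version = R.version.string,
    package_version = as.character(utils::packageVersion("cixscreen"))
  ), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Run the in silico primer-specificity analysis
#'
#' Reads target and non-target templates, writes the per-primer mismatch
#' table (TSV), the specificity matrix (CSV), the predicted amplicon
#' sequences (FASTA) and a reproducibility manifest (JSON). The returned
#' `status` is 0 for a clean run and 2 when the `specific` pair is predicted
#' to amplify any non-target — the CI-style screening contract.
#'
#' @param config A [run_config()] with at least `targets` set.
#' @return Invisibly, a list with `status`, `matrix` (the
#'   [specificity_matrix()]), `mismatches` (the [mismatch_table()]) and
#'   `files` (paths written).
#' @export
run_specificity <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$targets)) stop("config$targets is required")
  targets <- read_fasta(config$targets)
  nontargets <- if (!is.null(config$nontargets))
    read_fasta(config$nontargets) else stats::setNames(character(), character())
  templates <- c(targets, nontargets)
  if (anyDuplicated(names(templates)))
    stop("duplicate template ids across targets and non-targets")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  primers <- unlist(lapply(config$pairs, function(p) list(p$fw, p$rv)),
                    recursive = FALSE)
  primers <- primers[!duplicated(vapply(primers, `[[`, "", "name"))]
  mm <- mismatch_table(primers, templates, rule = config$rule)
  sm <- specificity_matrix(config$pairs, templates, rule = config$rule,
                           max_product = config$max_product)
  files <- c(
    mismatches = file.path(config$out_dir, "mismatch_table.tsv"),
    matrix = file.path(config$out_dir, "specificity_matrix.csv"),
    amplicons = file.path(config$out_dir, "amplicons.fasta"),
    manifest = file.path(config$out_dir, "manifest_specificity.json"))
  write_mismatch_table(mm, files[["mismatches"]])
  write_specificity_csv(sm, files[["matrix"]])
  amps <- character()
  for (j in seq_along(config$pairs)) for (i in seq_along(templates)) {
    pred <- simulate_pcr(config$pairs[[j]]$fw, config$pairs[[j]]$rv,
                         templates[[i]], rule = config$rule,
                         max_product = config$max_product,
                         template_id = names(templates)[i])
    amps <- c(amps, amplicon_sequences(pred, templates[[i]]))
  }
  if (length(amps)) write_fasta(amps, files[["amplicons"]]) else
    files <- files[names(files) != "amplicons"]
  specific_pair <- if ("specific" %in% names(config$pairs)) "specific" else
    names(config$pairs)[1]
  violated <- length(nontargets) > 0L &&
    any(sm$status[names(nontargets), specific_pair] == "amplified")
  status <- if (violated) 2L else 0L
  write_manifest(config, files[["manifest"]],
                 extra = list(analysis = "specificity", status = status))
  invisible(list(status = status, matrix = sm, mismatches = mm, files = files))
}

## Species assignment for the barcoding-gap summary: the token before the
## first underscore (sp1_2 -> sp1, Genus_sp1_syn -> Genus); labels without an
## underscore are their own species.
species_of <- function(labels) sub("_.*$", "", labels)

#' Run the barcoding phylogeny analysis
#'
#' Reads a pre-aligned FASTA, computes MCL pairwise-deletion distances
#' (written raw and, optionally, x100), builds the neighbor-joining tree with
#' bootstrap supports, roots it on the configured outgroup, and writes a
#' barcoding-gap summary (maximum intraspecific vs minimum interspecific
#' distance, species inferred from tip-label prefixes). With only two rows a
#' distance is reported but no tree, with a warning.
#'
#' @param config A [run_config()] with `alignment` set.
#' @return Invisibly, a list with `distances`, `tree` (or `NULL`), `gap`
#'   (list with `max_intra`, `min_inter`) and `files`.
#' @export
run_phylogeny <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$alignment)) stop("config$alignment is required")
  aln <- read_fasta(config$alignment, allow_gaps = TRUE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  dd <- mcl_distance_matrix(aln)
  files <- c(dist_raw = file.path(config$out_dir, "distances_per_site.csv"),
             manifest = file.path(config$out_dir, "manifest_phylogeny.json"))
  write_distance_csv(dd, files[["dist_raw"]])
  if (config$scale100) {
    files[["dist_x100"]] <- file.path(config$out_dir, "distances_per_100_sites.csv")
    write_distance_csv(dd, files[["dist_x100"]], scale100 = TRUE)
  }
  tree <- NULL
  if (length(aln) < 3L) {
    warning("fewer than 3 sequences: reporting distances only, no tree")
  } else {
    tree <- bootstrap_supports(aln, replicates = config$replicates,
                               seed = config$seed)
    if (!is.null(config$outgroups))
      tree <- root_with_outgroup(tree, config$outgroups)
    files[["tree"]] <- file.path(config$out_dir, "nj_bootstrap.nwk")
    write_newick(tree, files[["tree"]])
  }
  sp <- species_of(dd$taxa)
  d <- dd$distances
  same <- outer(sp, sp, `==`) & upper.tri(d)
  diff <- outer(sp, sp, `!=`) & upper.tri(d)
  gap <- list(max_intra = if (any(same)) max(d[same]) else NA_real_,
              min_inter = if (any(diff)) min(d[diff]) else NA_real_)
  files[["gap"]] <- file.path(config$out_dir, "barcoding_gap.txt")
  writeLines(c(
    sprintf("maximum intraspecific distance: %s",
            format(gap$max_intra, digits = 6)),
    sprintf("minimum interspecific distance: %s",
            format(gap$min_inter, digits = 6)),
    sprintf("barcoding gap (min inter - max intra): %s",
            format(gap$min_inter - gap$max_intra, digits = 6))),
    files[["gap"]])
  write_manifest(config, files[["manifest"]],
                 extra = list(analysis = "phylogeny",
                              replicates_used =
                                if (!is.null(tree)) attr(tree, "replicates_used")
                                else NULL))
  invisible(list(distances = dd, tree = tree, gap = gap, files = files))
}

#' Simulate a family and write it with its truth sidecar
#'
#' Convenience wrapper for the command line: runs [simulate_family()] and
#' [write_family()] into an output directory.
#'
#' @param params A [family_params()] object.
#' @param out_dir Output directory.
#' @return Invisibly, the [simulate_family()] result with a `files` element.
#' @export
run_simulate <- function(params, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fam <- simulate_family(params)
  files <- c(fasta = file.path(out_dir, "family.fasta"),
             truth = file.path(out_dir, "family_truth.json"))
  write_family(fam, files[["fasta"]], files[["truth"]])
  fam$files <- files
  invisible(fam)
}
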