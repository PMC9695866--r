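#' Neighbor-joining tree from a distance matrix
#'
#' The standard Saitou-Nei agglomeration: repeatedly join the pair minimizing
#' the Q criterion, split the joining branch by the rate-corrected formula,
#' and reduce the matrix. Negative branch lengths are clamped to zero with
#' the deficit moved to the sibling branch created at the same join, so path
#' lengths between the joined clusters are preserved. The result is unrooted
#' (basal trifurcation) and exact on additive matrices.
#'
#' @param D An `"evodist"` object, a `dist`, or a symmetric matrix with
#'   dimnames.
#' @return An [ape::phylo] tree.
#' @export
neighbor_joining <- function(D) {
  m <- if (inherits(D, "evodist")) D$distances else as.matrix(D)
  if (is.null(rownames(m))) stop("distance matrix must carry taxon names")
  n <- nrow(m)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  reps <- as.list(rownames(m))
  fmt <- function(x) sprintf("%.12g", x)
  while (n > 3L) {
    R <- rowSums(m)
    Q <- (n - 2) * m - outer(R, R, `+`)
    diag(Q) <- Inf
    ij <- arrayInd(which.min(Q), dim(Q))
    i <- min(ij); j <- max(ij)
    li <- m[i, j] / 2 + (R[i] - R[j]) / (2 * (n - 2))
    lj <- m[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    newrep <- paste0("(", reps[[i]], ":", fmt(li), ",",
                     reps[[j]], ":", fmt(lj), ")")
    rest <- setdiff(seq_len(n), c(i, j))
    dnew <- (m[i, rest] + m[j, rest] - m[i, j]) / 2
    m <- rbind(cbind(m[rest, rest, drop = FALSE], dnew),
               c(dnew, 0))
    reps <- c(reps[rest], newrep)
    rownames(m) <- colnames(m) <- as.character(seq_along(reps))
    n <- n - 1L
  }
  l1 <- (m[1, 2] + m[1, 3] - m[2, 3]) / 2
  l2 <- m[1, 2] - l1
  l3 <- m[1, 3] - l1
  for (v in c("l1", "l2", "l3")) assign(v, max(0, get(v)))
  nwk <- paste0("(", reps[[1]], ":", fmt(l1), ",",
                reps[[2]], ":", fmt(l2), ",",
                reps[[3]], ":", fmt(l3), ");")
  ape::read.tree(text = nwk)
}

#' Root a tree on its outgroup
#'
#' Places the root on the edge separating a monophyletic outgroup from the
#' ingroup. Errors when the outgroup labels do not form a bipartition of the
#' unrooted tree, naming the smallest clade that does contain them.
#'
#' @param tree An [ape::phylo] tree (unrooted or rooted).
#' @param outgroup_labels Character vector of tip labels.
#' @return A rooted [ape::phylo] tree.
#' @export
root_with_outgroup <- function(tree, outgroup_labels) {
  stopifnot(inherits(tree, "phylo"))
  missing_tips <- setdiff(outgroup_labels, tree$tip.label)
  if (length(missing_tips))
    stop("outgroup label(s) not in tree: ", paste(missing_tips, collapse = ", "))
  if (length(outgroup_labels) >= length(tree$tip.label))
    stop("outgroup cannot contain every tip")
  tryCatch(
    ape::root(tree, outgroup = outgroup_labels, resolve.root = TRUE),
    error = function(e) {
      ## name the offending bipartition: the smallest clade spanning the set
      ingroup_tip <- setdiff(tree$tip.label, outgroup_labels)[1]
      rooted <- ape::root(tree, outgroup = ingroup_tip, resolve.root = TRUE)
      mrca <- ape::getMRCA(rooted, outgroup_labels)
      span <- ape::extract.clade(rooted, mrca)$tip.label
      stop("outgroup {", paste(outgroup_labels, collapse = ", "),
           "} is not monophyletic: its smallest containing clade is {",
           paste(span, collapse = ", "), "}", call. = FALSE)
    })
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Builds the full-data MCL + NJ tree, then resamples alignment columns with
#' replacement `replicates` times, rebuilding distances and the NJ tree for
#' each replicate (reusing the full-alignment rate parameters), and annotates
#' each internal edge of the full-data tree with the percentage of replicate
#' trees containing its bipartition. Replicates in which some pair retains no
#' columns are dropped with a warning and excluded from the denominator.
#'
#' @param alignment Named character vector of aligned rows (>= 3).
#' @param replicates Number of bootstrap replicates (default 1000).
#' @param seed Integer seed; the same seed byte-reproduces the supports.
#' @param method Distance method, `"mcl"` (default), `"p"` or `"jc"`.
#' @return The full-data [ape::phylo] tree with `node.label` set to integer
#'   support percentages (root label empty) and attributes
#'   `"supports"` (numeric, per internal node) and `"replicates_used"`.
#' @export
bootstrap_supports <- function(alignment, replicates = 1000L, seed = 1L,
                               method = c("mcl", "p", "jc")) {
  method <- match.arg(method)
  rows <- as_alignment(alignment)
  if (length(rows) < 3L) stop("need at least 3 taxa for a tree")
  rates <- if (method == "mcl") estimate_mcl_rates(rows) else NULL
  dist_fun <- function(a) {
    if (method == "mcl") mcl_distance_matrix(a, rates = rates)
    else distance_matrix(a, method = method)
  }
  full_tree <- neighbor_joining(dist_fun(rows))
  m <- do.call(rbind, strsplit(unname(rows), "", fixed = TRUE))
  L <- ncol(m)
  set.seed(seed)
  boots <- vector("list", replicates)
  dropped <- 0L
  for (r in seq_len(replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    repl <- stats::setNames(apply(m[, cols, drop = FALSE], 1L, paste,
                                  collapse = ""), names(rows))
    boots[[r]] <- tryCatch(suppressWarnings(neighbor_joining(dist_fun(repl))),
                           error = function(e) NULL)
    if (is.null(boots[[r]])) dropped <- dropped + 1L
  }
  if (dropped > 0L)
    warning(dropped, " bootstrap replicate(s) dropped (degenerate pair)")
  boots <- Filter(Negate(is.null), boots)
  used <- length(boots)
  if (used == 0L) stop("every bootstrap replicate failed")
  counts <- ape::prop.clades(full_tree, boots, rooted = FALSE)
  pct <- 100 * counts / used
  lab <- as.character(round(pct))
  lab[is.na(pct)] <- ""
  full_tree$node.label <- lab
  attr(full_tree, "supports") <- pct
  attr(full_tree, "replicates_used") <- used
  full_tree
}

#' Write a tree as Newick
#'
#' Branch lengths in substitutions per site; internal-node support labels are
#' carried through when present.
#'
#' @param tree An [ape::phylo] tree.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
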