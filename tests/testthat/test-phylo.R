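test_that("pairwise deletion drops gaps and ambiguity codes", {
  expect_equal(pairwise_deletion_mask("ACGT", "ACGT"), 1:4)
  expect_equal(pairwise_deletion_mask("ACN-", "ACGT"), 1:2)
  expect_error(pairwise_deletion_mask("ACGT", "ACG"), "length")
  set.seed(83)
  a <- strsplit(random_dna(100), "")[[1]]
  b <- strsplit(random_dna(100), "")[[1]]
  planted <- sort(sample(100, 12))
  a[planted[1:6]] <- "N"
  b[planted[7:12]] <- "-"
  expect_equal(pairwise_deletion_mask(paste(a, collapse = ""),
                                      paste(b, collapse = "")),
               setdiff(1:100, planted))
})

test_that("p_distance matches a direct column count", {
  expect_equal(p_distance("ACGT", "ACGT"), 0)
  expect_equal(p_distance("ACGT", "ACGA"), 0.25)
  expect_error(p_distance("NNNN", "ACGT"), "no retained")
  set.seed(89)
  for (i in 1:10) {
    a <- strsplit(random_dna(80), "")[[1]]
    b <- strsplit(random_dna(80), "")[[1]]
    a[sample(80, 5)] <- "N"
    keep <- a %in% c("A", "C", "G", "T")
    expect_equal(p_distance(paste(a, collapse = ""), paste(b, collapse = "")),
                 sum(a[keep] != b[keep]) / sum(keep))
  }
})

test_that("identical rows give an all-zero MCL matrix", {
  aln <- stats::setNames(rep(paste(rep("ACGT", 30), collapse = ""), 3),
                         c("a", "b", "c"))
  d <- mcl_distance_matrix(aln)
  expect_true(all(d$distances == 0))
  expect_equal(diag(d$distances), c(a = 0, b = 0, c = 0))
})

test_that("MCL matrices are symmetric, non-negative and dominate p-distance", {
  set.seed(97)
  fam <- simulate_family(family_params(seed = 97, length = 500,
                                       intra = 0.01, inter = 0.08,
                                       model = "K2P", kappa = 3))
  d <- mcl_distance_matrix(fam$sequences)
  expect_equal(d$distances, t(d$distances))
  expect_true(all(d$distances >= 0))
  expect_true(all(diag(d$distances) == 0))
  for (i in 1:11) for (j in (i + 1):12) {
    expect_gte(d$distances[i, j] + 1e-12,
               p_distance(fam$sequences[[i]], fam$sequences[[j]]))
  }
})

test_that("Jukes-Cantor correction flags saturated pairs", {
  aln <- c(a = paste(rep("A", 60), collapse = ""),
           b = paste(rep("C", 60), collapse = ""),
           c = paste(rep("A", 60), collapse = ""))
  expect_warning(d <- distance_matrix(aln, method = "jc"), "saturated")
  expect_true(d$saturated["a", "b"])
  expect_false(d$saturated["a", "c"])
})

test_that("three-taxon NJ reproduces the closed-form branch lengths", {
  m <- matrix(c(0, 0.3, 0.5,
                0.3, 0, 0.6,
                0.5, 0.6, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(m)
  len <- stats::setNames(tr$edge.length[match(1:3, tr$edge[, 2])],
                         tr$tip.label)
  expect_equal(len[["a"]], (0.3 + 0.5 - 0.6) / 2)
  expect_equal(len[["b"]], (0.3 + 0.6 - 0.5) / 2)
  expect_equal(len[["c"]], (0.5 + 0.6 - 0.3) / 2)
})

test_that("NJ is exact on additive matrices and matches ape's topology", {
  set.seed(101)
  for (i in 1:10) {
    tr <- ape::unroot(ape::rtree(6, br = function(n) stats::runif(n, 0.05, 0.5)))
    D <- ape::cophenetic.phylo(tr)
    nj <- neighbor_joining(D)
    D2 <- ape::cophenetic.phylo(nj)[rownames(D), colnames(D)]
    expect_lt(max(abs(D - D2)), 1e-9)
    expect_equal(ape::dist.topo(nj, ape::nj(D)), 0, ignore_attr = TRUE)
  }
  expect_error(neighbor_joining(matrix(0, 2, 2,
                                       dimnames = list(c("a", "b"),
                                                       c("a", "b")))),
               "at least 3")
})

test_that("negative NJ branches are clamped with path lengths preserved", {
  # a non-additive matrix known to produce a negative branch estimate
  m <- matrix(c(0, 0.1, 0.4, 0.45,
                0.1, 0, 0.42, 0.47,
                0.4, 0.42, 0, 0.05,
                0.45, 0.47, 0.05, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  m["a", "b"] <- 0.001  # push one split towards a negative estimate
  m["b", "a"] <- 0.001
  tr <- neighbor_joining(m)
  expect_true(all(tr$edge.length >= 0))
})

test_that("bootstrap supports are seeded, bounded and reproducible", {
  fam <- simulate_family(family_params(seed = 7, length = 400, n_species = 3,
                                       n_per_species = 3))
  t1 <- bootstrap_supports(fam$sequences, replicates = 30, seed = 11)
  t2 <- bootstrap_supports(fam$sequences, replicates = 30, seed = 11)
  expect_identical(t1$node.label, t2$node.label)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  sup <- attr(t1, "supports")
  expect_true(all(sup[!is.na(sup)] >= 0 & sup[!is.na(sup)] <= 100))
  expect_equal(attr(t1, "replicates_used"), 30)
  t3 <- bootstrap_supports(fam$sequences, replicates = 30, seed = 12)
  expect_false(identical(attr(t3, "supports"), attr(t1, "supports")))
})

test_that("bootstrap replicates default to 1000", {
  expect_equal(formals(bootstrap_supports)$replicates, 1000L)
})

test_that("outgroup rooting places the root and round-trips bipartitions", {
  m <- matrix(0.2, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  m["d", ] <- m[, "d"] <- 0.8; diag(m) <- 0
  tr <- neighbor_joining(m)
  rooted <- root_with_outgroup(tr, "d")
  expect_true(ape::is.rooted(rooted))
  expect_true(ape::is.monophyletic(rooted, c("a", "b", "c")))
  # unrooting recovers the original bipartition set
  expect_equal(ape::dist.topo(ape::unroot(rooted), tr), 0, ignore_attr = TRUE)
  expect_error(root_with_outgroup(tr, "z"), "not in tree")
})

test_that("a non-monophyletic outgroup errors with the offending clade", {
  bs <- synthetic_barcode_set()
  tr <- neighbor_joining(mcl_distance_matrix(bs))
  expect_error(
    root_with_outgroup(tr, c("Pleporinus_study_syn", "Catonia_outgroup_syn")),
    "not monophyletic")
  rooted <- root_with_outgroup(tr, attr(bs, "outgroups"))
  expect_true(ape::is.monophyletic(rooted,
                                   setdiff(names(bs), attr(bs, "outgroups"))))
})

test_that("barcode taxa separate into their three genus clades", {
  bs <- synthetic_barcode_set()
  tr <- neighbor_joining(mcl_distance_matrix(bs))
  rooted <- root_with_outgroup(tr, attr(bs, "outgroups"))
  expect_true(ape::is.monophyletic(rooted, grep("^Reptalus", names(bs),
                                                value = TRUE)))
  expect_true(ape::is.monophyletic(rooted, grep("^Hyalesthes", names(bs),
                                                value = TRUE)))
  expect_true(ape::is.monophyletic(rooted, grep("^P", names(bs),
                                                value = TRUE)))
})
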