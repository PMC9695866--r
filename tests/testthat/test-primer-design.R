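test_that("consensus follows strict majority with N on ties and gaps", {
  expect_equal(consensus(c(a = "ACGT")), "ACGT")
  expect_equal(consensus(c(a = "ACGT", b = "ACGA")), "ACGN")
  expect_equal(consensus(c(a = "AC-T", b = "AC-T", c = "ACGT")), "ACNT")
  expect_equal(consensus(c(a = "ACGT", b = "ACGT", c = "TCGA")), "ACGT")
  expect_error(consensus(character()), "empty")
})

test_that("consensus of a low-divergence family recovers the root", {
  set.seed(61)
  root <- random_dna(300)
  rc <- strsplit(root, "")[[1]]
  rows <- stats::setNames(vapply(1:10, function(i) {
    x <- rc
    mut <- which(stats::runif(300) < 0.01)
    x[mut] <- sample(c("A", "C", "G", "T"), length(mut), TRUE)
    paste(x, collapse = "")
  }, ""), paste0("r", 1:10))
  cons <- consensus(rows)
  agree <- mean(strsplit(cons, "")[[1]] == rc)
  expect_gte(agree, 0.95)
})

# one diagnostic column at the 3' edge of a unique window: candidates are
# exactly the pairs whose clamp covers that column (checked by brute force)
test_that("toy diagnostic-column search matches exhaustive enumeration", {
  set.seed(67)
  root <- random_dna(120)
  targets <- c(t1 = root, t2 = root)
  ntc <- strsplit(root, "")[[1]]
  diag_col <- 60                                  # 1-based; 0-based 59
  ntc[diag_col] <- setdiff(c("A", "C", "G", "T"), ntc[diag_col])[1]
  nontargets <- c(n1 = paste(ntc, collapse = ""))
  cons <- design_constraints(primer_length = c(18L, 20L),
                             product_length = c(40L, 120L))
  cand <- enumerate_discriminative_primers(targets, nontargets, cons,
                                           max_candidates = 10000L)
  expect_gt(nrow(cand), 0)

  # brute-force oracle: per-window stats computed once, then all pairs
  win_stats <- new.env()
  get_stats <- function(s0, len, role) {
    key <- paste(s0, len, role)
    if (!is.null(win_stats[[key]])) return(win_stats[[key]])
    ws <- substr(root, s0 + 1, s0 + len)
    pseq <- if (role == "fw") ws else oracle_revcomp(ws)
    tot <- min(oracle_best_site(pseq, nontargets[[1]], "plus")$total,
               oracle_best_site(pseq, nontargets[[1]], "minus")$total)
    # with a single diagnostic column, a clamp mismatch means the window's
    # two 3'-terminal columns cover it
    clamp <- if (role == "fw")
      as.integer(tot > 0 && (diag_col - 1) %in% c(s0 + len - 2, s0 + len - 1))
    else
      as.integer(tot > 0 && (diag_col - 1) %in% c(s0, s0 + 1))
    win_stats[[key]] <- c(tot = tot, clamp = clamp)
    win_stats[[key]]
  }
  oracle <- list()
  for (lf in 18:20) for (sf in 0:(120 - lf)) for (lr in 18:20)
    for (sr in 0:(120 - lr)) {
      if (sf + lf > sr) next
      prod_len <- sr + lr - sf
      if (prod_len < 40 || prod_len > 120) next
      f <- get_stats(sf, lf, "fw"); r <- get_stats(sr, lr, "rv")
      if (f[["tot"]] + r[["tot"]] >= 1 && f[["clamp"]] + r[["clamp"]] >= 1)
        oracle[[paste(sf, lf, sr, lr)]] <- TRUE
    }
  got_keys <- paste(cand$fw_start, cand$fw_len, cand$rv_start, cand$rv_len)
  expect_setequal(got_keys, names(oracle))
  # every candidate's clamp covers the diagnostic column
  covers <- (cand$fw_start + cand$fw_len - 1 - (diag_col - 1)) %in% 0:1 |
    ((diag_col - 1) - cand$rv_start) %in% 0:1
  expect_true(all(covers))
})

test_that("an indistinguishable non-target leaves no candidates", {
  set.seed(71)
  root <- random_dna(120)
  targets <- c(t1 = root, t2 = root)
  cand <- enumerate_discriminative_primers(
    targets, c(n1 = root),
    design_constraints(primer_length = c(18L, 20L),
                       product_length = c(40L, 120L)))
  expect_equal(nrow(cand), 0)
})

test_that("candidates re-validate and tighter constraints give subsets", {
  set.seed(73)
  root <- random_dna(150)
  targets <- c(t1 = root, t2 = root)
  ntc <- strsplit(root, "")[[1]]
  for (p in c(40, 41, 100, 101)) ntc[p] <- setdiff(c("A", "C", "G", "T"),
                                                   ntc[p])[1]
  nontargets <- c(n1 = paste(ntc, collapse = ""))
  loose <- design_constraints(primer_length = c(18L, 20L),
                              product_length = c(40L, 150L))
  tight <- design_constraints(primer_length = c(18L, 20L),
                              product_length = c(40L, 150L),
                              min_nontarget_mismatches = 2L,
                              min_clamp_mismatches = 2L)
  c_loose <- enumerate_discriminative_primers(targets, nontargets, loose,
                                              max_candidates = 100000L)
  c_tight <- enumerate_discriminative_primers(targets, nontargets, tight,
                                              max_candidates = 100000L)
  key <- function(d) paste(d$fw_start, d$fw_len, d$rv_start, d$rv_len)
  expect_true(all(key(c_tight) %in% key(c_loose)))
  expect_lte(nrow(c_tight), nrow(c_loose))

  # re-validate a sample of candidates against the matcher
  take <- head(seq_len(nrow(c_loose)), 10)
  for (i in take) {
    fwp <- primer("fw", c_loose$fw_seq[i], "forward")
    rvp <- primer("rv", c_loose$rv_seq[i], "reverse")
    for (row in targets) {
      expect_equal(find_best_binding_site(fwp, row, strand = "plus",
                                          template_id = "t")$total_mismatches, 0)
      expect_equal(find_best_binding_site(rvp, row, strand = "minus",
                                          template_id = "t")$total_mismatches, 0)
    }
    ft <- find_best_binding_site(fwp, nontargets[[1]], strand = "both",
                                 template_id = "n")$total_mismatches
    rt <- find_best_binding_site(rvp, nontargets[[1]], strand = "both",
                                 template_id = "n")$total_mismatches
    expect_equal(ft + rt, c_loose$min_total_mm[i])
  }
})

test_that("a planted diagnostic pair ranks at the top score", {
  set.seed(79)
  root <- random_dna(200)
  targets <- c(t1 = root, t2 = root)
  ntc <- strsplit(root, "")[[1]]
  # diagnostic sites at the 3' ends of an intended fw [30,50) / rv [150,170)
  ntc[c(49, 50)] <- vapply(c(49, 50), function(p)
    setdiff(c("A", "C", "G", "T"), ntc[p])[1], "")
  ntc[c(151, 152)] <- vapply(c(151, 152), function(p)
    setdiff(c("A", "C", "G", "T"), ntc[p])[1], "")
  nontargets <- c(n1 = paste(ntc, collapse = ""))
  cand <- enumerate_discriminative_primers(
    targets, nontargets,
    design_constraints(primer_length = c(20L, 20L),
                       product_length = c(100L, 200L),
                       min_clamp_mismatches = 2L))
  expect_gt(nrow(cand), 0)
  planted <- cand$fw_start == 30 & cand$fw_len == 20 &
    cand$rv_start == 150 & cand$rv_len == 20
  expect_true(any(planted))
  expect_equal(cand$min_clamp_mm[planted], max(cand$min_clamp_mm))
  expect_equal(cand$min_clamp_mm[1], cand$min_clamp_mm[planted])
})
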