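fw1 <- cixiid_primers()[["Plep-fw1"]]

test_that("an exactly implanted primer is found with zero mismatches", {
  set.seed(3)
  tpl <- paste0(random_dna(10), fw1$sequence, random_dna(70))
  hit <- find_best_binding_site(fw1, tpl, strand = "plus", template_id = "t")
  expect_equal(hit$start, 10)
  expect_equal(hit$end, 30)
  expect_equal(hit$total_mismatches, 0)
  expect_equal(hit$mismatch_offsets, integer(0))
  expect_equal(hit$window_sequence, fw1$sequence)
})

test_that("best-site search agrees with the brute-force window oracle", {
  set.seed(17)
  for (i in 1:50) {
    k <- sample(10:25, 1)
    pseq <- if (i %% 3 == 0) random_iupac(k) else random_dna(k)
    p <- primer("p", pseq, "forward")
    tpl <- random_dna(200)
    for (str in c("plus", "minus")) {
      hit <- find_best_binding_site(p, tpl, strand = str, template_id = "t")
      orc <- oracle_best_site(pseq, tpl, str)
      expect_equal(hit$total_mismatches, orc$total)
      expect_equal(hit$start, orc$start)
    }
  }
})

test_that("mismatch offsets are counted from the 3' terminus on both strands", {
  # template holds the primer with one altered base at a known position
  p <- primer("p", "ACGTACGTACGTACGTACGT", "forward")  # 20 nt
  chars <- strsplit(p$sequence, "")[[1]]
  chars[19] <- "C"  # primer position 19 -> 3'-offset 1
  tpl <- paste0("GGGGG", paste(chars, collapse = ""), "GGGGG")
  hit <- find_best_binding_site(p, tpl, strand = "plus", template_id = "t")
  expect_equal(hit$mismatch_offsets, 1L)
  # same site seen as a minus-strand primer: implant revcomp, offset maps to
  # the plus-strand left edge
  rc <- reverse_complement(p$sequence)
  chars <- strsplit(rc, "")[[1]]
  chars[2] <- setdiff(c("A", "C", "G", "T"),
                      c(chars[2], strsplit(rc, "")[[1]][2]))[1]
  tpl2 <- paste0("GGGGG", paste(chars, collapse = ""), "GGGGG")
  hit2 <- find_best_binding_site(p, tpl2, strand = "minus", template_id = "t")
  expect_equal(hit2$mismatch_offsets, 1L)
})

test_that("strand consistency: minus-strand match equals revcomp on plus", {
  set.seed(29)
  for (i in 1:10) {
    p <- primer("p", random_dna(18), "forward")
    prc <- primer("prc", reverse_complement(p$sequence), "forward")
    tpl <- random_dna(150)
    a <- find_best_binding_site(p, tpl, strand = "minus", template_id = "t")
    b <- find_best_binding_site(prc, tpl, strand = "plus", template_id = "t")
    expect_equal(a$total_mismatches, b$total_mismatches)
    expect_equal(a$start, b$start)
  }
})

test_that("all_binding_sites enumerates, counts and stays monotone", {
  set.seed(31)
  p <- primer("p", random_dna(15), "forward")
  tpl <- paste0(random_dna(30), p$sequence, random_dna(40), p$sequence,
                random_dna(30))
  hits <- all_binding_sites(p, tpl, max_mismatches = 0, strands = "plus",
                            template_id = "t")
  expect_length(hits, 2)
  expect_equal(vapply(hits, `[[`, 0, "start"), c(30, 85))
  # a budget of the primer length admits every window on both strands
  L <- nchar(tpl); k <- p$length
  expect_length(all_binding_sites(p, tpl, max_mismatches = k,
                                  template_id = "t"),
                2 * (L - k + 1))
  # relaxing the budget never removes sites
  n_prev <- 0
  for (mm in c(0, 2, 5, 8, k)) {
    n <- length(all_binding_sites(p, tpl, max_mismatches = mm,
                                  template_id = "t"))
    expect_gte(n, n_prev)
    n_prev <- n
  }
  # counts agree with the oracle
  for (i in 1:10) {
    tpl <- random_dna(120)
    mm_budget <- sample(0:6, 1)
    got <- all_binding_sites(p, tpl, mm_budget, strands = "plus",
                             template_id = "t")
    orc <- which(oracle_window_counts(p$sequence, tpl, "plus") <= mm_budget) - 1L
    expect_equal(vapply(got, `[[`, 0, "start"), as.numeric(orc))
  }
})

test_that("extension rule blocks clamp mismatches and high totals", {
  rule <- extension_rule()
  mk <- function(offsets) structure(
    list(primer = "p", template = "t", strand = "plus", start = 0, end = 20,
         mismatch_offsets = as.integer(offsets),
         total_mismatches = length(offsets),
         window_sequence = "", primer_length = 20L),
    class = "match_profile")
  expect_true(predicts_extension(mk(integer()), rule))
  expect_false(predicts_extension(mk(1L), rule))       # next-to-last 3' base
  expect_false(predicts_extension(mk(0L), rule))       # terminal base
  expect_true(predicts_extension(mk(19L), rule))       # 5'-most position
  expect_true(predicts_extension(mk(c(5L, 9L, 13L, 17L)), rule))   # 4 total
  expect_false(predicts_extension(mk(c(5L, 9L, 13L, 15L, 17L)), rule)) # 5 total
  strict <- extension_rule(max_total_mismatches = 0, clamp_length = 1)
  expect_false(predicts_extension(mk(19L), strict))
})

test_that("degenerate template codes: optimistic vs pessimistic matching", {
  p <- primer("p", "ACGTACGTACGTACGT", "forward")
  tpl <- paste0("TTTTT", sub("^A", "N", p$sequence), "TTTTT")
  opt <- find_best_binding_site(p, tpl, strand = "plus", template_id = "t")
  pes <- find_best_binding_site(p, tpl, strand = "plus", template_id = "t",
                                pessimistic = TRUE)
  expect_equal(opt$total_mismatches, 0)
  expect_equal(pes$total_mismatches, 1)
})

test_that("templates shorter than the primer are rejected", {
  expect_error(find_best_binding_site(fw1, "ACGTACGT", template_id = "t"),
               "shorter than primer")
  expect_error(all_binding_sites(fw1, "ACGTACGT", 0, template_id = "t"),
               "shorter")
})

test_that("mismatch_table reports one row per primer and template", {
  panel <- synthetic_cixiid_panel()
  tab <- mismatch_table(cixiid_primers(), panel$templates)
  expect_equal(nrow(tab), 6 * 3)
  u8 <- tab[tab$primer == "UEA8" & tab$template == "P_leporinus_syn", ]
  expect_equal(u8$total_mismatches, 3)
  expect_match(u8$offsets_3p, "^1;")
  expect_false(u8$predicted_extension)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_mismatch_table(tab, f)
  expect_equal(nrow(utils::read.delim(f)), nrow(tab))
})
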