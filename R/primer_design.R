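#' Constraints for discriminative primer-pair search
#'
#' Defaults span the published species-specific pair (a 20 nt forward and a
#' 31 nt reverse primer with a 341 bp product): candidate primers of 18-32 nt,
#' products of 150-1200 bp, at least one mismatch — including at least one in
#' the 3' clamp — against every non-target, and non-degenerate candidates
#' only.
#'
#' @param primer_length Length range `c(min, max)` in nt.
#' @param product_length Product range `c(min, max)` in bp.
#' @param min_nontarget_mismatches Minimum total mismatches a primer pair
#'   (both primers' best-site counts combined) must show against every
#'   non-target.
#' @param min_clamp_mismatches Minimum mismatches within the 3' clamp region,
#'   combined over the pair, against every non-target. A single diagnostic
#'   column covered by one primer's clamp satisfies the default.
#' @param clamp_length Length of the 3' clamp region used for the clamp counts
#'   (and for [extension_rule()] consistency).
#' @param max_degeneracy Maximum degeneracy of a candidate (1 = A/C/G/T only).
#' @param gc_range Optional GC-content bounds `c(min, max)` in `[0,1]`;
#'   `NULL` (default) disables the filter.
#' @return An object of class `"design_constraints"`.
#' @export
design_constraints <- function(primer_length = c(18L, 32L),
                               product_length = c(150L, 1200L),
                               min_nontarget_mismatches = 1L,
                               min_clamp_mismatches = 1L,
                               clamp_length = 2L,
                               max_degeneracy = 1L,
                               gc_range = NULL) {
  stopifnot(length(primer_length) == 2L, primer_length[1] <= primer_length[2],
            length(product_length) == 2L, product_length[1] <= product_length[2],
            product_length[2] >= 2 * primer_length[1],
            min_nontarget_mismatches >= 0, min_clamp_mismatches >= 0,
            clamp_length >= 1, max_degeneracy >= 1)
  structure(list(primer_length = as.integer(primer_length),
                 product_length = as.integer(product_length),
                 min_nontarget_mismatches = as.integer(min_nontarget_mismatches),
                 min_clamp_mismatches = as.integer(min_clamp_mismatches),
                 clamp_length = as.integer(clamp_length),
                 max_degeneracy = as.integer(max_degeneracy),
                 gc_range = gc_range),
            class = "design_constraints")
}

#' Majority consensus of a target alignment
#'
#' Per column, the strict-majority base; ties and gap-majority columns become
#' `N`. Degenerate row codes are counted as their own symbol (they never reach
#' majority against concrete bases unless they dominate the column).
#'
#' @param target_alignment Named character vector of equal-length rows
#'   (gaps allowed).
#' @return A single consensus string.
#' @export
consensus <- function(target_alignment) {
  if (length(target_alignment) == 0L) stop("empty alignment")
  if (length(target_alignment) == 1L)
    return(normalize_residues(target_alignment[[1]], "consensus row",
                              allow_gaps = TRUE))
  rows <- as_alignment(target_alignment)
  m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  apply(m, 2L, function(col) {
    tab <- sort(table(col), decreasing = TRUE)
    top <- names(tab)[1]
    if (sum(tab == tab[1]) > 1L || top == "-") "N" else top
  }) |> paste(collapse = "")
}

gc_content <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  mean(chars %in% c("G", "C", "S"))
}

## Mismatch summary of a candidate primer against one non-target:
## best site over both strands, totals and clamp-region counts.
nontarget_summary <- function(p, nontarget, clamp_length, id) {
  pr <- find_best_binding_site(p, nontarget, strand = "both", template_id = id)
  c(total = pr$total_mismatches,
    clamp = sum(pr$mismatch_offsets < clamp_length))
}

#' Search an alignment for species-discriminating primer pairs
#'
#' Implements the design criterion behind the published species-specific
#' pair: candidate primers are windows of the target consensus that match
#' every target row perfectly, while the pair combined shows at least the
#' required number of mismatches — and of 3'-clamp mismatches — against the
#' best binding site (either strand) on every non-target sequence. Reverse
#' candidates are the reverse complements of consensus windows. Pairs are
#' ranked by the worst
#' case over non-targets of the combined clamp mismatches of the two primers
#' (descending), then combined totals (descending), then by coordinates for
#' determinism.
#'
#' @param target_alignment Named character vector of aligned target rows.
#' @param nontargets Named character vector of non-target sequences (need not
#'   be aligned to the targets).
#' @param constraints A [design_constraints()].
#' @param max_candidates Cap on returned pairs (default 100).
#' @return A data.frame of class `"primer_pair_candidates"` with one row per
#'   pair: `fw_seq`, `rv_seq`, `fw_start`, `fw_len`, `rv_start`, `rv_len`
#'   (0-based consensus coordinates of the footprints), `product_length`,
#'   `min_clamp_mm`, `min_total_mm` (worst case over non-targets, both
#'   primers combined), and per-non-target columns
#'   `<id>.fw_total`, `<id>.fw_clamp`, `<id>.rv_total`, `<id>.rv_clamp`.
#'   Empty (zero rows) when no pair satisfies the constraints.
#' @export
enumerate_discriminative_primers <- function(target_alignment, nontargets,
                                             constraints = design_constraints(),
                                             max_candidates = 100L) {
  cons <- consensus(target_alignment)
  rows <- if (length(target_alignment) > 1L) as_alignment(target_alignment)
          else stats::setNames(
            normalize_residues(target_alignment[[1]], "target row", TRUE),
            names(target_alignment) %||% "target")
  if (length(nontargets) && is.null(names(nontargets)))
    stop("nontargets must be named")
  cl <- constraints$clamp_length
  L <- nchar(cons)
  row_mat <- do.call(rbind, strsplit(unname(rows), "", fixed = TRUE))
  cons_chars <- strsplit(cons, "", fixed = TRUE)[[1]]

  ## windows of the consensus that match every target row exactly
  window_ok <- function(start, len) {
    idx <- start:(start + len - 1L)
    w <- cons_chars[idx]
    if (any(w == "-" | w == "N")) return(NA_character_)
    ws <- paste(w, collapse = "")
    if (degeneracy(ws) > constraints$max_degeneracy) return(NA_character_)
    sub <- row_mat[, idx, drop = FALSE]
    for (r in seq_len(nrow(sub))) {
      rr <- sub[r, ]
      if (any(rr == "-")) return(NA_character_)
      for (j in seq_along(idx))
        if (!bases_compatible(w[j], rr[j])) return(NA_character_)
    }
    ws
  }

  lens <- constraints$primer_length[1]:constraints$primer_length[2]
  cand <- list()  # keyed by "start:len" -> window string
  for (len in lens) {
    if (len > L) next
    for (start in 1:(L - len + 1L)) {
      ws <- window_ok(start, len)
      if (!is.na(ws)) {
        if (!is.null(constraints$gc_range)) {
          gc <- gc_content(ws)
          if (gc < constraints$gc_range[1] || gc > constraints$gc_range[2]) next
        }
        cand[[paste0(start - 1L, ":", len)]] <- ws
      }
    }
  }
  if (length(cand) == 0L) return(empty_candidates())

  ## evaluate each unique window once per role against every non-target
  keys <- names(cand)
  eval_role <- function(seqs, role) {
    lapply(seq_along(seqs), function(i) {
      p <- primer(paste0(role, "_", keys[i]), seqs[[i]],
                  if (role == "fw") "forward" else "reverse")
      if (length(nontargets) == 0L)
        return(matrix(integer(), nrow = 0, ncol = 2))
      t(vapply(seq_along(nontargets), function(k)
        nontarget_summary(p, nontargets[[k]], cl, names(nontargets)[k]),
        c(total = 0, clamp = 0)))
    })
  }
  fw_stats <- eval_role(unname(cand), "fw")
  rv_stats <- eval_role(lapply(unname(cand), reverse_complement), "rv")

  K <- length(nontargets)
  stat_mat <- function(stats, what) {
    if (K == 0L) return(matrix(0L, length(stats), 0L))
    m <- vapply(stats, function(s) s[, what], numeric(K))
    if (K == 1L) cbind(m) else t(m)      # always windows x non-targets
  }
  Ft <- stat_mat(fw_stats, "total"); Fc <- stat_mat(fw_stats, "clamp")
  Rt <- stat_mat(rv_stats, "total"); Rc <- stat_mat(rv_stats, "clamp")

  starts <- as.integer(sub(":.*", "", keys))
  wlens  <- as.integer(sub(".*:", "", keys))
  ends <- starts + wlens
  out <- list()
  ## the clamp/total requirements apply to the pair: the two primers'
  ## mismatch counts against a non-target are summed (a single diagnostic
  ## site covered by one primer's clamp suffices)
  for (i in seq_along(keys)) {
    prod_len <- ends - starts[i]
    keep <- starts >= ends[i] &
      prod_len >= constraints$product_length[1] &
      prod_len <= constraints$product_length[2]
    if (K > 0L && any(keep)) {
      cs <- Rc[keep, , drop = FALSE] + rep(Fc[i, ], each = sum(keep))
      ts <- Rt[keep, , drop = FALSE] + rep(Ft[i, ], each = sum(keep))
      ok <- rowSums(cs >= constraints$min_clamp_mismatches) == K &
            rowSums(ts >= constraints$min_nontarget_mismatches) == K
      clamp_worst <- apply(cs, 1L, min); total_worst <- apply(ts, 1L, min)
      keep[keep] <- ok
      clamp_worst <- clamp_worst[ok]; total_worst <- total_worst[ok]
    } else {
      clamp_worst <- total_worst <- rep(NA_integer_, sum(keep))
    }
    if (!any(keep)) next
    js <- which(keep)
    rec <- data.frame(
      fw_seq = unlist(cand[i])[rep(1L, length(js))],
      rv_seq = vapply(cand[js], reverse_complement, ""),
      fw_start = starts[i], fw_len = wlens[i],
      rv_start = starts[js], rv_len = wlens[js],
      product_length = ends[js] - starts[i],
      min_clamp_mm = clamp_worst, min_total_mm = total_worst,
      stringsAsFactors = FALSE)
    if (K > 0L) for (k in seq_len(K)) {
      id <- names(nontargets)[k]
      rec[[paste0(id, ".fw_total")]] <- Ft[i, k]
      rec[[paste0(id, ".fw_clamp")]] <- Fc[i, k]
      rec[[paste0(id, ".rv_total")]] <- Rt[js, k]
      rec[[paste0(id, ".rv_clamp")]] <- Rc[js, k]
    }
    out[[length(out) + 1L]] <- rec
  }
  if (length(out) == 0L) return(empty_candidates())
  df <- do.call(rbind, out)
  ord <- order(-xtfrm(df$min_clamp_mm), -xtfrm(df$min_total_mm),
               df$fw_start, df$rv_start, df$fw_len, df$rv_len)
  df <- df[ord, , drop = FALSE][seq_len(min(nrow(df), max_candidates)), ,
                                drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("primer_pair_candidates", "data.frame")
  df
}

empty_candidates <- function() {
  df <- data.frame(fw_seq = character(), rv_seq = character(),
                   fw_start = integer(), fw_len = integer(),
                   rv_start = integer(), rv_len = integer(),
                   product_length = integer(),
                   min_clamp_mm = integer(), min_total_mm = integer(),
                   stringsAsFactors = FALSE)
  class(df) <- c("primer_pair_candidates", "data.frame")
  df
}

#' Write primer-pair candidates as CSV
#'
#' @param candidates Output of [enumerate_discriminative_primers()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_candidates_csv <- function(candidates, path) {
  utils::write.csv(as.data.frame(candidates), path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
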