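## Columns where a character is an unambiguous base.
unambiguous <- function(chars) chars %in% c("A", "C", "G", "T")

#' Columns retained for a sequence pair under pairwise deletion
#'
#' @param a,b Aligned rows (equal-length strings; gaps and ambiguity codes
#'   allowed).
#' @return 1-based indices of columns where both rows carry an unambiguous
#'   A/C/G/T.
#' @export
pairwise_deletion_mask <- function(a, b) {
  if (nchar(a) != nchar(b))
    stop("rows differ in length (", nchar(a), " vs ", nchar(b), ")")
  ca <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  cb <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  which(unambiguous(ca) & unambiguous(cb))
}

#' Proportion of differing sites between two aligned rows
#'
#' Computed over the pairwise-deletion mask only.
#'
#' @param a,b Aligned rows.
#' @return The p-distance (proportion in `[0, 1]`).
#' @export
p_distance <- function(a, b) {
  idx <- pairwise_deletion_mask(a, b)
  if (length(idx) == 0L) stop("no retained columns for this pair")
  ca <- strsplit(toupper(a), "", fixed = TRUE)[[1]][idx]
  cb <- strsplit(toupper(b), "", fixed = TRUE)[[1]][idx]
  mean(ca != cb)
}

## Substitution-category counts for one pair over its retained columns:
## purine transitions (A<->G), pyrimidine transitions (C<->T), transversions.
pair_counts <- function(ca, cb) {
  keep <- unambiguous(ca) & unambiguous(cb)
  ca <- ca[keep]; cb <- cb[keep]
  diff <- ca != cb
  ts_R <- sum((ca == "A" & cb == "G") | (ca == "G" & cb == "A"))
  ts_Y <- sum((ca == "C" & cb == "T") | (ca == "T" & cb == "C"))
  c(n = length(ca), ts_R = ts_R, ts_Y = ts_Y,
    tv = sum(diff) - ts_R - ts_Y)
}

## Expected substitution-category proportions under the Tamura-Nei model at
## branch scale theta_b (transversion-rate x divergence time), with purine /
## pyrimidine transition-to-transversion rate ratios k1, k2 and base
## frequencies g = c(A, C, G, T).
tn_expected_props <- function(theta_b, k1, k2, g) {
  g <- unname(g)
  gA <- g[1]; gC <- g[2]; gG <- g[3]; gT <- g[4]
  gR <- gA + gG; gY <- gC + gT
  e3 <- exp(-2 * theta_b)
  Q <- 2 * gR * gY * (1 - e3)
  w1 <- exp(-2 * theta_b * (gR * k1 + gY))
  w2 <- exp(-2 * theta_b * (gY * k2 + gR))
  P1 <- (2 * gA * gG / gR) * (1 - Q / (2 * gR) - w1)
  P2 <- (2 * gT * gC / gY) * (1 - Q / (2 * gY) - w2)
  c(P1 = P1, P2 = P2, Q = Q)
}

## Composite (multinomial) log-likelihood of one pair's counts.
tn_pair_loglik <- function(theta_b, counts, k1, k2, g) {
  pr <- tn_expected_props(theta_b, k1, k2, g)
  p <- pmax(c(pr, id = 1 - sum(pr)), 1e-12)
  unname(sum(counts[c("ts_R", "ts_Y", "tv")] * log(p[c("P1", "P2", "Q")])) +
    (counts[["n"]] - sum(counts[c("ts_R", "ts_Y", "tv")])) * log(p[["id"]]))
}

TN_THETA_MAX <- 5

tn_fit_theta <- function(counts, k1, k2, g) {
  if (sum(counts[c("ts_R", "ts_Y", "tv")]) == 0L)
    return(list(theta = 0, saturated = FALSE))
  opt <- stats::optimize(function(th) tn_pair_loglik(th, counts, k1, k2, g),
                         interval = c(1e-9, TN_THETA_MAX), maximum = TRUE,
                         tol = 1e-10)
  list(theta = opt$maximum, saturated = opt$maximum > 0.98 * TN_THETA_MAX)
}

## Total expected substitutions per site at branch scale theta_b.
tn_distance_from_theta <- function(theta_b, k1, k2, g) {
  g <- unname(g)
  gA <- g[1]; gC <- g[2]; gG <- g[3]; gT <- g[4]
  4 * (gA * gG * k1 + gT * gC * k2 + (gA + gG) * (gC + gT)) * theta_b
}

#' Estimate shared substitution-rate parameters by composite likelihood
#'
#' Base frequencies are pooled over every unambiguous residue of the
#' alignment; the purine and pyrimidine transition/transversion rate ratios
#' of the Tamura-Nei model are then estimated once for the whole alignment by
#' maximizing the sum of pairwise composite log-likelihoods (each pair
#' profiled over its own branch-scale parameter). These shared rates are the
#' "composite likelihood" part of the MCL distance; [mcl_distance_matrix()]
#' applies them per pair.
#'
#' @param alignment Named character vector of aligned rows.
#' @return A list with `freqs` (named A/C/G/T), `k1`, `k2`.
#' @export
estimate_mcl_rates <- function(alignment) {
  rows <- as_alignment(alignment)
  m <- do.call(rbind, strsplit(toupper(unname(rows)), "", fixed = TRUE))
  obs <- table(factor(m[unambiguous(m)], levels = c("A", "C", "G", "T")))
  if (any(obs == 0)) obs <- obs + 1          # guard degenerate compositions
  g <- as.numeric(obs) / sum(obs)
  names(g) <- c("A", "C", "G", "T")
  n <- nrow(m)
  counts <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ct <- pair_counts(m[i, ], m[j, ])
    if (ct["n"] > 0L && sum(ct[c("ts_R", "ts_Y", "tv")]) > 0L)
      counts[[length(counts) + 1L]] <- ct
  }
  if (length(counts) == 0L)
    return(list(freqs = g, k1 = 1, k2 = 1))
  profile_ll <- function(logk) {
    k1 <- exp(logk[1]); k2 <- exp(logk[2])
    -sum(vapply(counts, function(ct) {
      fit <- tn_fit_theta(ct, k1, k2, g)
      tn_pair_loglik(fit$theta, ct, k1, k2, g)
    }, 0))
  }
  opt <- stats::optim(log(c(2, 2)), profile_ll, method = "L-BFGS-B",
                      lower = log(0.05), upper = log(100))
  list(freqs = g, k1 = exp(opt$par[1]), k2 = exp(opt$par[2]))
}

#' Maximum-composite-likelihood evolutionary distance matrix
#'
#' Tamura-Nei-form distances in substitutions per site: substitution-model
#' rate parameters are estimated once from the whole alignment by composite
#' likelihood ([estimate_mcl_rates()]), then each pair's distance is the
#' composite-ML branch-scale estimate under those shared rates, computed over
#' the pair's own pairwise-deletion column mask. Saturated pairs (distance
#' estimate driven to the optimizer bound) are flagged and set to the largest
#' finite distance in the matrix so that neighbor joining stays runnable; the
#' `saturated` flag matrix reports them loudly.
#'
#' @param alignment Named character vector of aligned rows (>= 2).
#' @param rates Optional precomputed [estimate_mcl_rates()] result (reused
#'   across bootstrap replicates).
#' @return An object of class `"evodist"`: list with `taxa`, `distances`
#'   (symmetric matrix, zero diagonal), `sites_used`, `saturated`, `method`,
#'   `deletion`, `params`.
#' @export
mcl_distance_matrix <- function(alignment, rates = NULL) {
  rows <- as_alignment(alignment)
  taxa <- names(rows)
  m <- do.call(rbind, strsplit(toupper(unname(rows)), "", fixed = TRUE))
  if (is.null(rates)) rates <- estimate_mcl_rates(rows)
  g <- rates$freqs; k1 <- rates$k1; k2 <- rates$k2
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  sites <- matrix(nchar(rows[1]), n, n, dimnames = list(taxa, taxa))
  sat <- matrix(FALSE, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ct <- pair_counts(m[i, ], m[j, ])
    sites[i, j] <- sites[j, i] <- ct[["n"]]
    if (ct[["n"]] == 0L)
      stop("no retained columns for pair ", taxa[i], " / ", taxa[j])
    fit <- tn_fit_theta(ct, k1, k2, g)
    d[i, j] <- d[j, i] <- tn_distance_from_theta(fit$theta, k1, k2, g)
    sat[i, j] <- sat[j, i] <- fit$saturated
  }
  if (any(sat)) {
    finite_max <- max(d[!sat])
    if (!is.finite(finite_max) || all(sat[upper.tri(sat)]))
      stop("all pairs saturated; distances undefined")
    d[sat] <- finite_max
    warning(sum(sat) / 2, " saturated pair(s) set to the maximum finite distance ",
            signif(finite_max, 4))
  }
  structure(list(taxa = taxa, distances = d, sites_used = sites,
                 saturated = sat, method = "mcl", deletion = "pairwise",
                 params = rates),
            class = "evodist")
}

#' Pairwise-deletion distance matrix by a named method
#'
#' Convenience wrapper around [p_distance()], its Jukes-Cantor correction,
#' and [mcl_distance_matrix()].
#'
#' @param alignment Named character vector of aligned rows.
#' @param method `"mcl"` (default), `"p"`, or `"jc"`.
#' @return An `"evodist"` object.
#' @export
distance_matrix <- function(alignment, method = c("mcl", "p", "jc")) {
  method <- match.arg(method)
  if (method == "mcl") return(mcl_distance_matrix(alignment))
  rows <- as_alignment(alignment)
  taxa <- names(rows)
  n <- length(rows)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  sites <- matrix(nchar(rows[1]), n, n, dimnames = list(taxa, taxa))
  sat <- matrix(FALSE, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    idx <- pairwise_deletion_mask(rows[[i]], rows[[j]])
    sites[i, j] <- sites[j, i] <- length(idx)
    p <- p_distance(rows[[i]], rows[[j]])
    if (method == "jc") {
      arg <- 1 - 4 * p / 3
      if (arg <= 0) { sat[i, j] <- sat[j, i] <- TRUE; p <- NA_real_ }
      else p <- -3 / 4 * log(arg)
    }
    d[i, j] <- d[j, i] <- p
  }
  if (any(sat)) {
    finite_max <- max(d[!sat], na.rm = TRUE)
    d[sat] <- finite_max
    warning(sum(sat) / 2, " saturated pair(s) set to ", signif(finite_max, 4))
  }
  structure(list(taxa = taxa, distances = d, sites_used = sites,
                 saturated = sat, method = method, deletion = "pairwise",
                 params = NULL),
            class = "evodist")
}

#' @export
print.evodist <- function(x, ...) {
  cat(sprintf("<evodist> %d taxa, method %s, %s deletion\n",
              length(x$taxa), x$method, x$deletion))
  print(round(x$distances, 4))
  if (any(x$saturated)) cat("note:", sum(x$saturated) / 2, "saturated pair(s)\n")
  invisible(x)
}

#' @export
as.matrix.evodist <- function(x, ...) x$distances

#' Write a distance matrix as CSV
#'
#' @param x An `"evodist"` object.
#' @param path Output file.
#' @param scale100 Multiply by 100 (substitutions per 100 sites, the scale on
#'   which short-fragment barcoding distances are conventionally printed).
#' @param lower Write the lower triangle only (MEGA-style); default full.
#' @return `path`, invisibly.
#' @export
write_distance_csv <- function(x, path, scale100 = FALSE, lower = FALSE) {
  stopifnot(inherits(x, "evodist"))
  d <- x$distances * if (scale100) 100 else 1
  if (lower) d[upper.tri(d, diag = TRUE)] <- NA
  df <- data.frame(taxon = rownames(d), round(d, 6), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
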