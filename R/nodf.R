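# NODF nestedness metric (sites, species, total), maximal matrix packing,
# and the proportional-row / proportional-column (PP) randomization null
# with Z-score and Monte Carlo probability.

#' Maximally pack a community matrix
#'
#' Reorders sites and species by decreasing marginal totals (stable ties:
#' original order preserved), the display convention of a maximally packed
#' matrix. NODF itself depends only on marginal totals and pairwise
#' overlaps, so packing never changes its value.
#'
#' @param m Community matrix.
#' @return The same cells with rows and columns reordered.
#' @export
max_pack <- function(m) {
  m <- as_community_matrix(m)
  m[order(rowSums(m), decreasing = TRUE), order(colSums(m), decreasing = TRUE),
    drop = FALSE]
}

# Mean paired overlap (percent) across all unordered line pairs of one axis.
# For a pair (u, v) with fill(u) > fill(v) the paired overlap is
# 100 * shared / fill(v); pairs with equal fills contribute 0 (the
# "decreasing filling" condition).
nodf_axis <- function(m) {
  f <- rowSums(m)
  ov <- tcrossprod(m)
  n <- nrow(m)
  po <- matrix(0, n, n)
  gt <- outer(f, f, ">")              # gt[u, v]: fill(u) > fill(v)
  fv <- matrix(f, n, n, byrow = TRUE) # fill of the poorer line v
  po[gt] <- 100 * ov[gt] / fv[gt]
  # each unordered unequal-fill pair appears exactly once in po (where gt)
  sum(po) / (n * (n - 1) / 2)
}

#' NODF nestedness metric
#'
#' Nestedness metric based on Overlap and Decreasing Filling, on a 0-100
#' scale. For every ordered pair of lines of one axis in which the first
#' line is strictly fuller, the paired overlap is the percentage of the
#' poorer line's presences shared with the fuller line; pairs with equal
#' fills score 0. The axis score is the mean over all unordered pairs of
#' that axis; the total is the mean over all site pairs and species pairs
#' together. The metric is invariant to row/column permutation.
#'
#' @param m Community matrix (sites in rows), at least 2 x 2, with no empty
#'   sites or species.
#' @return Class `nodf`: `nodf_total`, `nodf_sites` (site-pair score; the
#'   island axis), `nodf_species` (species-pair score), and pair counts.
#' @export
nodf <- function(m) {
  m <- as_community_matrix(m)
  if (nrow(m) < 2L || ncol(m) < 2L) stopf("NODF needs at least 2 x 2")
  if (any(rowSums(m) == 0L) || any(colSums(m) == 0L)) {
    stopf("empty site or species present; drop empty lines first")
  }
  np_sites <- nrow(m) * (nrow(m) - 1) / 2
  np_species <- ncol(m) * (ncol(m) - 1) / 2
  s_sites <- nodf_axis(m) * np_sites
  s_species <- nodf_axis(t(m)) * np_species
  structure(
    list(nodf_total = (s_sites + s_species) / (np_sites + np_species),
         nodf_sites = s_sites / np_sites,
         nodf_species = s_species / np_species,
         n_site_pairs = np_sites, n_species_pairs = np_species),
    class = "nodf"
  )
}

#' One proportional-proportional (PP) null sample
#'
#' Each cell (i, j) is an independent Bernoulli draw with probability equal
#' to the average of row i's and column j's observed fill fractions, so the
#' expected fill of the sample equals the observed fill. Uses the current
#' RNG stream (seed it via [nodf_null_test()] or `set.seed`).
#'
#' @param m Community matrix.
#' @return A 0/1 matrix with the same dimensions and labels.
#' @export
pp_null_sample <- function(m) {
  m <- as_community_matrix(m)
  p <- (outer(rowSums(m) / ncol(m), colSums(m) / nrow(m), "+")) / 2
  out <- (matrix(stats::runif(length(m)), nrow(m)) < p) + 0L
  dimnames(out) <- dimnames(m)
  out
}

#' NODF significance under the PP null model
#'
#' Compares observed NODF against a null distribution of random matrices
#' from [pp_null_sample()]. Null samples that contain empty lines have
#' those lines removed before scoring (mirroring the empirical exclusion of
#' empty inventories); set `drop_degenerate_lines = FALSE` to discard such
#' samples instead.
#'
#' @param m Community matrix (no empty sites/species).
#' @param n_sim Number of null matrices (default 1000; >= 100 recommended).
#' @param seed Optional integer seed for reproducibility.
#' @param axis Which NODF score to test: `"sites"` (default; the island
#'   axis), `"species"`, or `"total"`.
#' @param drop_degenerate_lines See above.
#' @return Class `nodf_null`: `n_obs`, `n_exp_mean`, `n_exp_sd`, `z`
#'   (`(n_obs - mean)/sd`, `NA` with a warning when the null SD is 0), `p`
#'   (one-tailed Monte Carlo probability with +1 correction, in the
#'   direction of the observed deviation), `direction` (`"nested"` /
#'   `"anti-nested"`), `n_sim`, `n_used`, `axis`, `seed`, and the vector of
#'   null values.
#' @export
nodf_null_test <- function(m, n_sim = 1000, seed = NULL,
                           axis = c("sites", "species", "total"),
                           drop_degenerate_lines = TRUE) {
  axis <- match.arg(axis)
  m <- as_community_matrix(m)
  if (n_sim < 1L) stopf("n_sim must be at least 1")
  pick <- function(x) x[[paste0("nodf_", axis)]]
  n_obs <- pick(nodf(m))
  null_values <- with_seed(seed, {
    vapply(seq_len(n_sim), function(i) {
      s <- pp_null_sample(m)
      s <- s[rowSums(s) > 0L, colSums(s) > 0L, drop = FALSE]
      if (nrow(s) < 2L || ncol(s) < 2L) return(NA_real_)
      if (!drop_degenerate_lines &&
          (nrow(s) < nrow(m) || ncol(s) < ncol(m))) return(NA_real_)
      pick(nodf(s))
    }, numeric(1))
  })
  used <- null_values[!is.na(null_values)]
  if (length(used) == 0L) stopf("no usable null samples")
  mu <- mean(used)
  sdv <- stats::sd(used)
  z <- if (length(used) > 1L && sdv > 0) (n_obs - mu) / sdv else {
    warning("null SD is zero: Z undefined")
    NA_real_
  }
  extreme <- if (n_obs >= mu) sum(used >= n_obs) else sum(used <= n_obs)
  structure(
    list(n_obs = n_obs, n_exp_mean = mu, n_exp_sd = sdv, z = z,
         p = (extreme + 1) / (length(used) + 1),
         direction = if (n_obs >= mu) "nested" else "anti-nested",
         n_sim = n_sim, n_used = length(used), axis = axis, seed = seed,
         null_values = used),
    class = "nodf_null"
  )
}

#' @export
print.nodf <- function(x, ...) {
  cat(sprintf("NODF: total = %.2f  sites = %.2f  species = %.2f\n",
              x$nodf_total, x$nodf_sites, x$nodf_species))
  invisible(x)
}

#' @export
print.nodf_null <- function(x, ...) {
  cat(sprintf("NODF (%s) vs PP null, %d of %d randomizations used\n",
              x$axis, x$n_used, x$n_sim))
  cat(sprintf("  N_obs = %.2f  N_exp = %.2f (SD %.2f)  Z = %.2f  p = %.4g (%s)\n",
              x$n_obs, x$n_exp_mean, x$n_exp_sd, x$z, x$p, x$direction))
  invisible(x)
}
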