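# Pairwise and multiple-site partitioning of incidence-based dissimilarity
# into spatial turnover and nestedness-resultant components (Baselga's
# Sorensen family), with Jaccard and Carvalho alternatives, the
# beta_SNE/beta_SOR ratio, and resampling standardization across systems
# with different numbers of sites.

#' Shared and exclusive species counts for a pair of sites
#'
#' @param x,y Incidence vectors (0/1) over the same ordered species list.
#'   If both are named, names must match.
#' @return A list of class `pair_counts` with `a` (shared), `b` (exclusive
#'   to `x`) and `c` (exclusive to `y`).
#' @examples
#' pair_counts(c(1, 1, 1, 0), c(0, 1, 1, 1))  # a = 2, b = 1, c = 1
#' @export
pair_counts <- function(x, y) {
  if (length(x) != length(y)) stopf("incidence vectors differ in length")
  if (!is.null(names(x)) && !is.null(names(y)) && !identical(names(x), names(y))) {
    stopf("species lists of the two sites do not match")
  }
  if (!all(x %in% 0:1) || !all(y %in% 0:1)) stopf("incidence vectors must be 0/1")
  structure(
    list(a = sum(x == 1 & y == 1), b = sum(x == 1 & y == 0), c = sum(x == 0 & y == 1)),
    class = "pair_counts"
  )
}

check_counts <- function(p) {
  if (inherits(p, "pair_counts")) p <- unclass(p)
  if (!all(c("a", "b", "c") %in% names(p))) stopf("need counts a, b and c")
  p <- lapply(p[c("a", "b", "c")], as.numeric)
  if (any(unlist(p) < 0)) stopf("counts must be non-negative")
  if (p$a + p$b + p$c == 0) stopf("both sites empty: dissimilarity undefined")
  p
}

#' Partition pairwise Sorensen dissimilarity
#'
#' Decomposes Sorensen dissimilarity between two sites into an additive
#' turnover component (Simpson dissimilarity, insensitive to richness
#' differences) and a nestedness-resultant component:
#' \deqn{\beta_{sor} = \frac{b+c}{2a+b+c},\quad
#'       \beta_{sim} = \frac{\min(b,c)}{a+\min(b,c)},\quad
#'       \beta_{sne} = \beta_{sor}-\beta_{sim}}
#' where `a` is the number of shared species and `b`, `c` the numbers
#' exclusive to each site. \eqn{\beta_{sne}} also equals the product of the
#' richness-difference fraction \eqn{|b-c|/(2a+b+c)} and the Simpson
#' similarity \eqn{a/(a+\min(b,c))}.
#'
#' @param p A `pair_counts` object or list with elements `a`, `b`, `c`.
#' @return List of class `pairwise_beta` with `beta_sor`, `beta_sim`,
#'   `beta_sne`, all in \[0, 1\] and exactly additive.
#' @export
sorensen_partition <- function(p) {
  p <- check_counts(p)
  a <- p$a; b <- p$b; cc <- p$c
  beta_sor <- (b + cc) / (2 * a + b + cc)
  beta_sim <- if (a + min(b, cc) == 0) 1 else min(b, cc) / (a + min(b, cc))
  structure(
    list(beta_sor = beta_sor, beta_sim = beta_sim, beta_sne = beta_sor - beta_sim),
    class = "pairwise_beta"
  )
}

#' Alternative pairwise partition families
#'
#' Jaccard family: \eqn{\beta_{jac}=(b+c)/(a+b+c)},
#' \eqn{\beta_{jtu}=2\min(b,c)/(a+2\min(b,c))},
#' \eqn{\beta_{jne}=\beta_{jac}-\beta_{jtu}}.
#' Carvalho family: \eqn{\beta_{cc}=(b+c)/(a+b+c)},
#' \eqn{\beta_{repl}=2\min(b,c)/(a+b+c)},
#' \eqn{\beta_{rich}=|b-c|/(a+b+c)}. Both are additive.
#'
#' @param p A `pair_counts` object or list with `a`, `b`, `c`.
#' @param family `"jaccard"` or `"carvalho"`.
#' @return Named list of the three components (total, replacement,
#'   richness-difference / nestedness-resultant).
#' @export
alternative_partitions <- function(p, family = c("jaccard", "carvalho")) {
  family <- match.arg(family)
  p <- check_counts(p)
  a <- p$a; b <- p$b; cc <- p$c
  tot <- (b + cc) / (a + b + cc)
  if (family == "jaccard") {
    jtu <- if (a + 2 * min(b, cc) == 0) 1 else 2 * min(b, cc) / (a + 2 * min(b, cc))
    list(beta_jac = tot, beta_jtu = jtu, beta_jne = tot - jtu)
  } else {
    list(beta_cc = tot,
         beta_repl = 2 * min(b, cc) / (a + b + cc),
         beta_rich = abs(b - cc) / (a + b + cc))
  }
}

# Pairwise a/b/c over all site pairs via matrix algebra.
pairwise_abc <- function(m) {
  shared <- tcrossprod(m)       # a_ij
  r <- rowSums(m)
  b <- r - shared               # b_ij: exclusive to row site i against j
  list(a = shared, b = b, c = t(b))
}

#' Pairwise dissimilarity matrices
#'
#' Computes the three aligned square matrices of a pairwise partition
#' family over all site pairs.
#'
#' @param m Community matrix (no empty sites; use [drop_empty_sites()]).
#' @param family `"sorensen"` (default), `"jaccard"` or `"carvalho"`.
#' @return A named list of three symmetric distance matrices, e.g.
#'   `beta_sor`, `beta_sim`, `beta_sne` for the Sorensen family. Components
#'   are element-wise additive.
#' @export
pairwise_matrices <- function(m, family = c("sorensen", "jaccard", "carvalho")) {
  family <- match.arg(family)
  m <- as_community_matrix(m)
  if (nrow(m) < 2L) stopf("need at least 2 sites")
  if (any(rowSums(m) == 0L)) {
    stopf("empty site(s) present; apply drop_empty_sites() first")
  }
  cnt <- pairwise_abc(m)
  a <- cnt$a; b <- cnt$b; cc <- cnt$c
  mn <- pmin(b, cc); mx <- pmax(b, cc)
  out <- switch(family,
    sorensen = {
      sor <- (b + cc) / (2 * a + b + cc)
      sim <- mn / (a + mn)
      list(beta_sor = sor, beta_sim = sim, beta_sne = sor - sim)
    },
    jaccard = {
      jac <- (b + cc) / (a + b + cc)
      jtu <- 2 * mn / (a + 2 * mn)
      list(beta_jac = jac, beta_jtu = jtu, beta_jne = jac - jtu)
    },
    carvalho = {
      tot <- (b + cc) / (a + b + cc)
      list(beta_cc = tot, beta_repl = 2 * mn / (a + b + cc),
           beta_rich = (mx - mn) / (a + b + cc))
    }
  )
  lapply(out, function(d) { diag(d) <- 0; dimnames(d) <- dimnames(a); d })
}

#' Multiple-site dissimilarity partition
#'
#' Multiple-site Sorensen dissimilarity over n >= 2 sites and its additive
#' decomposition into turnover and nestedness-resultant components:
#' \deqn{\beta_{SOR} = \frac{\Sigma\min + \Sigma\max}
#'                          {2(\Sigma_i S_i - S_T) + \Sigma\min + \Sigma\max}}
#' \deqn{\beta_{SIM} = \frac{\Sigma\min}{(\Sigma_i S_i - S_T) + \Sigma\min}}
#' \deqn{\beta_{SNE} = \beta_{SOR} - \beta_{SIM}}
#' with \eqn{\Sigma\min = \sum_{i<j}\min(b_{ij}, b_{ji})} and
#' \eqn{\Sigma\max = \sum_{i<j}\max(b_{ij}, b_{ji})}, where \eqn{b_{ij}} is
#' the richness exclusive to site i relative to site j, \eqn{S_i} the
#' richness of site i and \eqn{S_T} the pooled (gamma) richness. With
#' exactly two sites this reduces to [sorensen_partition()].
#'
#' @param m Community matrix with at least two non-empty sites.
#' @return An object of class `multisite_beta`: `beta_SOR`, `beta_SIM`,
#'   `beta_SNE`, `beta_ratio` (`beta_SNE / beta_SOR`), `n_sites` and the
#'   underlying `counts` (`sum_min`, `sum_max`, `shared`).
#' @export
multisite_partition <- function(m) {
  m <- as_community_matrix(m)
  if (nrow(m) < 2L) stopf("need at least 2 sites")
  if (any(rowSums(m) == 0L)) {
    stopf("empty site(s) present; apply drop_empty_sites() first")
  }
  cnt <- pairwise_abc(m)
  up <- upper.tri(cnt$b)
  sum_min <- sum(pmin(cnt$b, cnt$c)[up])
  sum_max <- sum(pmax(cnt$b, cnt$c)[up])
  shared <- sum(rowSums(m)) - sum(colSums(m) > 0L)
  beta_SOR <- (sum_min + sum_max) / (2 * shared + sum_min + sum_max)
  beta_SIM <- sum_min / (shared + sum_min)
  beta_SNE <- beta_SOR - beta_SIM
  structure(
    list(beta_SOR = beta_SOR, beta_SIM = beta_SIM, beta_SNE = beta_SNE,
         beta_ratio = if (beta_SOR > 0) beta_SNE / beta_SOR else NA_real_,
         n_sites = nrow(m),
         counts = list(sum_min = sum_min, sum_max = sum_max, shared = shared)),
    class = "multisite_beta"
  )
}

#' Ratio of the nestedness-resultant component to overall dissimilarity
#'
#' `beta_ratio < 0.5` indicates beta diversity dominated by species
#' turnover; `beta_ratio > 0.5` indicates dominance of nested richness
#' differences.
#'
#' @param msb A `multisite_beta` object (or any list with `beta_SOR` and
#'   `beta_SNE`).
#' @return The ratio, with a `"dominance"` attribute
#'   (`"turnover-dominated"`, `"nestedness-dominated"` or `"balanced"`).
#' @export
beta_ratio <- function(msb) {
  if (!all(c("beta_SOR", "beta_SNE") %in% names(msb))) {
    stopf("need beta_SOR and beta_SNE components")
  }
  if (msb$beta_SOR <= 0) stopf("beta_SOR is zero: beta_ratio undefined")
  r <- msb$beta_SNE / msb$beta_SOR
  attr(r, "dominance") <- if (r < 0.5) "turnover-dominated"
                          else if (r > 0.5) "nestedness-dominated"
                          else "balanced"
  r
}

#' Resampled multiple-site dissimilarity
#'
#' Multiple-site values grow with the number of sites, so systems with
#' different numbers of inventories are compared by repeatedly drawing
#' random subsets of equal size (without replacement within a sample) and
#' averaging the partition components over samples.
#'
#' @param m Community matrix without empty sites.
#' @param subset_size Number of sites per sample (>= 2, <= number of sites).
#' @param n_samples Number of random samples (default 100).
#' @param seed Optional integer seed; the same seed yields identical output.
#' @return Class `resampled_beta`: `mean` and `sd` (named vectors over
#'   `beta_SOR`, `beta_SIM`, `beta_SNE`, `beta_ratio`), the per-sample
#'   table `samples`, and the call settings. Component means remain
#'   additive (`mean beta_SOR = mean beta_SIM + mean beta_SNE`).
#' @export
resampled_multisite <- function(m, subset_size, n_samples = 100, seed = NULL) {
  m <- as_community_matrix(m)
  if (subset_size < 2L) stopf("subset_size must be at least 2")
  if (subset_size > nrow(m)) stopf("subset_size exceeds the number of sites")
  if (n_samples < 1L) stopf("n_samples must be at least 1")
  samples <- with_seed(seed, {
    t(vapply(seq_len(n_samples), function(i) {
      idx <- sample.int(nrow(m), subset_size)
      msb <- multisite_partition(m[idx, , drop = FALSE])
      c(beta_SOR = msb$beta_SOR, beta_SIM = msb$beta_SIM,
        beta_SNE = msb$beta_SNE, beta_ratio = msb$beta_ratio)
    }, numeric(4)))
  })
  structure(
    list(mean = colMeans(samples),
         sd = apply(samples, 2, stats::sd),
         samples = as.data.frame(samples),
         subset_size = subset_size, n_samples = n_samples, seed = seed),
    class = "resampled_beta"
  )
}

#' @export
print.multisite_beta <- function(x, ...) {
  cat(sprintf("Multiple-site dissimilarity over %d sites\n", x$n_sites))
  cat(sprintf("  beta_SOR = %.4f  beta_SIM = %.4f  beta_SNE = %.4f\n",
              x$beta_SOR, x$beta_SIM, x$beta_SNE))
  if (is.finite(x$beta_ratio)) {
    cat(sprintf("  beta_ratio = %.4f (%s)\n", x$beta_ratio,
                attr(beta_ratio(x), "dominance")))
  }
  invisible(x)
}

#' @export
print.resampled_beta <- function(x, ...) {
  cat(sprintf("Resampled multiple-site dissimilarity (%d samples of %d sites)\n",
              x$n_samples, x$subset_size))
  for (k in names(x$mean)) {
    cat(sprintf("  %-10s mean = %.4f  sd = %.4f\n", k, x$mean[[k]], x$sd[[k]]))
  }
  invisible(x)
}
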