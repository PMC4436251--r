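# Attribute-difference and geographic distance matrices, Mantel and
# partial Mantel permutation tests, and multiple regression on distance
# matrices (MRM). All statistics operate on the unfolded upper triangle;
# the permutation unit is the site label (simultaneous row/column shuffle),
# the only exchangeable unit for a distance matrix.

#' Attribute-difference distance matrix
#'
#' One-dimensional Euclidean distance between per-site attribute values,
#' optionally log10-transformed first (the usual scale for island area).
#'
#' @param values Numeric vector, one value per site.
#' @param labels Site labels (defaults to `names(values)`).
#' @param transform `"none"` or `"log10"`.
#' @return Symmetric distance matrix with entry `(i, j) = |t(x_i) - t(x_j)|`.
#' @export
attribute_distance <- function(values, labels = names(values),
                               transform = c("none", "log10")) {
  transform <- match.arg(transform)
  if (is.null(labels)) labels <- paste0("site", seq_along(values))
  if (length(labels) != length(values)) stopf("labels/value length mismatch")
  if (anyNA(values)) stopf("missing attribute values")
  if (transform == "log10") {
    if (any(values <= 0)) stopf("log10 transform needs positive values")
    values <- log10(values)
  }
  d <- abs(outer(values, values, "-"))
  dimnames(d) <- list(labels, labels)
  as_distance_matrix(d)
}

#' Great-circle distance matrix between sites
#'
#' Haversine distances in kilometres between site centroids.
#'
#' @param lat,lon Decimal-degree coordinates, one per site.
#' @param labels Site labels.
#' @return Symmetric distance matrix in km.
#' @export
geo_distance <- function(lat, lon, labels = names(lat)) {
  if (length(lat) != length(lon)) stopf("lat/lon length mismatch")
  if (any(abs(lat) > 90) || any(abs(lon) > 180) || anyNA(lat) || anyNA(lon)) {
    stopf("invalid coordinates")
  }
  if (is.null(labels)) labels <- paste0("site", seq_along(lat))
  d <- geosphere::distm(cbind(lon, lat), fun = geosphere::distHaversine) / 1000
  dimnames(d) <- list(labels, labels)
  as_distance_matrix(d)
}

cor_triangles <- function(vx, vy) {
  if (stats::sd(vx) == 0 || stats::sd(vy) == 0) {
    stopf("constant distance triangle: correlation undefined")
  }
  stats::cor(vx, vy)
}

#' Mantel permutation test
#'
#' Pearson correlation between the unfolded upper triangles of two distance
#' matrices, with significance from simultaneous row/column permutation of
#' the second matrix. The p-value is two-sided with +1 correction
#' (`(#{|r_perm| >= |r_obs|} + 1) / (n_perm + 1)`).
#'
#' @param dx,dy Aligned distance matrices (same site label set).
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional integer seed.
#' @return Class `mantel_result`: `r`, `p`, `n_perm`, `partial = FALSE`.
#' @export
mantel_test <- function(dx, dy, n_perm = 999, seed = NULL) {
  dx <- as_distance_matrix(dx)
  dy <- align_distance(dx, as_distance_matrix(dy), "two matrices")
  if (n_perm < 1L) stopf("n_perm must be at least 1")
  vx <- upper_vec(dx)
  r_obs <- cor_triangles(vx, upper_vec(dy))
  r_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      p <- sample.int(nrow(dy))
      cor_triangles(vx, upper_vec(dy[p, p]))
    }, numeric(1))
  })
  structure(
    list(r = r_obs, p = (sum(abs(r_perm) >= abs(r_obs)) + 1) / (n_perm + 1),
         n_perm = n_perm, partial = FALSE, covariate = NULL, seed = seed),
    class = "mantel_result"
  )
}

partial_r <- function(rxy, rxz, ryz) {
  den <- (1 - rxz^2) * (1 - ryz^2)
  if (den <= 0) stopf("covariate perfectly correlated: partial r undefined")
  (rxy - rxz * ryz) / sqrt(den)
}

#' Partial Mantel permutation test
#'
#' Correlation between `dx` and `dy` after partialling out a covariate
#' distance matrix `dz` (typically geographic distance):
#' \deqn{r_{xy.z} = \frac{r_{xy} - r_{xz} r_{yz}}
#'                      {\sqrt{(1-r_{xz}^2)(1-r_{yz}^2)}}}
#' The null permutes `dx`'s site labels and recomputes the partial
#' correlation; the p-value is two-sided with +1 correction.
#'
#' @param dx,dy,dz Aligned distance matrices.
#' @param n_perm Number of permutations (default 9999).
#' @param seed Optional integer seed.
#' @param covariate_label Label recorded in the result.
#' @return Class `mantel_result` with `partial = TRUE`.
#' @export
partial_mantel_test <- function(dx, dy, dz, n_perm = 9999, seed = NULL,
                                covariate_label = "covariate") {
  dx <- as_distance_matrix(dx)
  dy <- align_distance(dx, as_distance_matrix(dy), "response matrices")
  dz <- align_distance(dx, as_distance_matrix(dz), "covariate matrix")
  vy <- upper_vec(dy); vz <- upper_vec(dz)
  ryz <- cor_triangles(vy, vz)
  r_of <- function(d) {
    vx <- upper_vec(d)
    partial_r(cor_triangles(vx, vy), cor_triangles(vx, vz), ryz)
  }
  r_obs <- r_of(dx)
  r_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      p <- sample.int(nrow(dx))
      r_of(dx[p, p])
    }, numeric(1))
  })
  structure(
    list(r = r_obs, p = (sum(abs(r_perm) >= abs(r_obs)) + 1) / (n_perm + 1),
         n_perm = n_perm, partial = TRUE, covariate = covariate_label,
         seed = seed),
    class = "mantel_result"
  )
}

#' Multiple regression on distance matrices (MRM)
#'
#' Ordinary least squares of the unfolded response triangle on the unfolded
#' predictor triangles. Per-coefficient significance comes from permuting
#' the response matrix's site labels and refitting; p-values are two-sided
#' on coefficient magnitude with +1 correction (R-squared is tested
#' one-sided). Because the Sorensen partition is additive, MRM coefficients
#' for `beta_sor` equal the sums of those for `beta_sim` and `beta_sne`
#' when fitted on a shared predictor set.
#'
#' @param response Distance matrix (the dissimilarity being explained).
#' @param predictors Named list of aligned predictor distance matrices.
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional integer seed.
#' @return Class `mrm_result`: `coefficients` (intercept first), `p_coef`,
#'   `r_squared`, `p_r_squared`, `n_perm`.
#' @export
mrm <- function(response, predictors, n_perm = 999, seed = NULL) {
  response <- as_distance_matrix(response)
  if (!is.list(predictors) || length(predictors) == 0L) {
    stopf("predictors must be a non-empty list of distance matrices")
  }
  if (is.null(names(predictors))) {
    names(predictors) <- paste0("X", seq_along(predictors))
  }
  predictors <- lapply(predictors, function(d) {
    align_distance(response, as_distance_matrix(d), "predictor matrices")
  })
  X <- cbind(intercept = 1,
             do.call(cbind, lapply(predictors, upper_vec)))
  if (qr(X)$rank < ncol(X)) stopf("collinear predictor matrices")
  fit_coef <- function(y) qr.coef(qr(X), y)
  rsq <- function(y, beta) {
    res <- y - X %*% beta
    1 - sum(res^2) / sum((y - mean(y))^2)
  }
  y_obs <- upper_vec(response)
  beta_obs <- fit_coef(y_obs)
  r2_obs <- rsq(y_obs, beta_obs)
  perm <- with_seed(seed, {
    t(vapply(seq_len(n_perm), function(i) {
      p <- sample.int(nrow(response))
      y <- upper_vec(response[p, p])
      b <- fit_coef(y)
      c(b, r2 = rsq(y, b))
    }, numeric(ncol(X) + 1)))
  })
  k <- ncol(X)
  p_coef <- vapply(seq_len(k), function(j) {
    (sum(abs(perm[, j]) >= abs(beta_obs[j])) + 1) / (n_perm + 1)
  }, numeric(1))
  names(p_coef) <- colnames(X)
  structure(
    list(coefficients = stats::setNames(as.numeric(beta_obs), colnames(X)),
         p_coef = p_coef, r_squared = r2_obs,
         p_r_squared = (sum(perm[, k + 1] >= r2_obs) + 1) / (n_perm + 1),
         n_perm = n_perm, seed = seed),
    class = "mrm_result"
  )
}

#' @export
print.mantel_result <- function(x, ...) {
  lab <- if (x$partial) sprintf("Partial Mantel (covariate: %s)", x$covariate)
         else "Mantel"
  cat(sprintf("%s: r = %.4f, p = %.4g (%d permutations)\n",
              lab, x$r, x$p, x$n_perm))
  invisible(x)
}

#' @export
print.mrm_result <- function(x, ...) {
  cat(sprintf("MRM (%d permutations), R^2 = %.4f (p = %.4g)\n",
              x$n_perm, x$r_squared, x$p_r_squared))
  tab <- data.frame(estimate = x$coefficients, p = x$p_coef)
  print(round(tab, 4))
  invisible(x)
}
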