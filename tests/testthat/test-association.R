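test_that("attribute distances are one-dimensional Euclidean, optionally logged", {
  expect_true(all(attribute_distance(c(a = 3, b = 3, c = 3)) == 0))
  d <- attribute_distance(c(a = 10, b = 1000), transform = "log10")
  expect_equal(d["a", "b"], 2)
  attrs <- tisl_islands()
  da <- attribute_distance(attrs$area_ha, attrs$island, transform = "log10")
  expect_equal(da["1", "37"], abs(log10(1289.23) - log10(0.57)))
  expect_error(attribute_distance(c(1, -2), transform = "log10"), "positive")
})

test_that("geographic distances follow the haversine geometry", {
  d <- geo_distance(c(a = 10, b = 11), c(a = 30, b = 30))
  expect_equal(d["a", "b"], 111.2, tolerance = 0.01)
  expect_equal(geo_distance(c(5, 5), c(7, 7))[1, 2], 0)
  attrs <- tisl_islands()
  dg <- geo_distance(attrs$lat, attrs$lon, attrs$island)
  expect_true(all(diag(dg) == 0))
  expect_equal(dg, t(dg))
  expect_error(geo_distance(95, 10), "invalid coordinates")
})

test_that("Mantel r is exact for affine relations and label-invariant", {
  dx <- random_distance(8, seed = 1)
  expect_equal(mantel_test(dx, dx, n_perm = 9, seed = 1)$r, 1)
  expect_equal(mantel_test(dx, 3 * dx + 0 * dx, n_perm = 9, seed = 1)$r, 1)
  dy <- random_distance(8, seed = 2)
  r0 <- mantel_test(dx, dy, n_perm = 99, seed = 5)$r
  perm <- sample(8)
  r1 <- mantel_test(dx[perm, perm], dy[perm, perm], n_perm = 99, seed = 5)$r
  expect_equal(r1, r0)
  expect_error(mantel_test(dx, 0 * dx), "constant")
})

test_that("Mantel permutation p matches the exhaustive 4!-relabeling oracle", {
  dx <- random_distance(4, seed = 11)
  dy <- random_distance(4, seed = 12)
  r_obs <- cor(dx[upper.tri(dx)], dy[upper.tri(dy)])
  perms <- as.matrix(expand.grid(rep(list(1:4), 4)))
  perms <- perms[apply(perms, 1, function(p) all(sort(p) == 1:4)), ]
  r_all <- apply(perms, 1, function(p) {
    dp <- dy[p, p]
    cor(dx[upper.tri(dx)], dp[upper.tri(dp)])
  })
  p_exact <- mean(abs(r_all) >= abs(r_obs) - 1e-12)
  res <- mantel_test(dx, dy, n_perm = 4999, seed = 7)
  expect_equal(res$r, r_obs)
  expect_lt(abs(res$p - p_exact), 0.03)
})

test_that("Mantel r agrees with vegan and p-values are seed-deterministic", {
  skip_if_not_installed("vegan")
  dx <- random_distance(10, seed = 3)
  dy <- random_distance(10, seed = 4)
  expect_equal(mantel_test(dx, dy, n_perm = 9, seed = 1)$r,
               vegan::mantel(dx, dy, permutations = 9)$statistic,
               tolerance = 1e-12, ignore_attr = TRUE)
  a <- mantel_test(dx, dy, n_perm = 199, seed = 8)
  b <- mantel_test(dx, dy, n_perm = 199, seed = 8)
  expect_identical(a$p, b$p)
})

test_that("partial Mantel reduces to the closed form and flags degenerate covariates", {
  dx <- random_distance(9, seed = 21)
  dy <- random_distance(9, seed = 22)
  dz <- random_distance(9, seed = 23)
  ut <- upper.tri(dx)
  rxy <- cor(dx[ut], dy[ut]); rxz <- cor(dx[ut], dz[ut]); ryz <- cor(dy[ut], dz[ut])
  hand <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  res <- partial_mantel_test(dx, dy, dz, n_perm = 99, seed = 1)
  expect_equal(res$r, hand)
  expect_true(res$partial)
  # covariate identical to the response: ryz = 1, undefined
  expect_error(partial_mantel_test(dx, dy, dy, n_perm = 9), "undefined")
})

test_that("MRM recovers exact linear structure and matches the normal equations", {
  dx <- random_distance(7, seed = 31)
  resp <- 2 * dx
  resp <- resp + 1
  diag(resp) <- 0
  # exact affine relation on the triangle: slope 2, intercept 1, R^2 = 1
  fit <- mrm(resp, list(x = dx), n_perm = 49, seed = 2)
  expect_equal(unname(fit$coefficients), c(1, 2), tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  # two predictors on 4 sites: solve the normal equations directly
  d1 <- random_distance(4, seed = 32)
  d2 <- random_distance(4, seed = 33)
  y <- random_distance(4, seed = 34)
  X <- cbind(1, d1[upper.tri(d1)], d2[upper.tri(d2)])
  beta_hand <- solve(t(X) %*% X, t(X) %*% y[upper.tri(y)])
  fit2 <- mrm(y, list(a = d1, b = d2), n_perm = 49, seed = 3)
  expect_equal(unname(fit2$coefficients), as.numeric(beta_hand), tolerance = 1e-10)
  expect_error(mrm(y, list(a = d1, b = 2 * d1)), "collinear")
})

test_that("MRM slope sign matches Mantel r with a single predictor", {
  dx <- random_distance(9, seed = 41)
  dy <- random_distance(9, seed = 42)
  fit <- mrm(dy, list(x = dx), n_perm = 49, seed = 1)
  r <- mantel_test(dy, dx, n_perm = 9, seed = 1)$r
  expect_equal(sign(fit$coefficients[["x"]]), sign(r))
})

test_that("MRM coefficients are additive across the Sorensen partition", {
  m <- random_community(10, 25, seed = 51)
  betas <- pairwise_matrices(m)
  attrs <- data.frame(v = runif(10, 1, 100))
  dv <- attribute_distance(attrs$v, rownames(m), transform = "log10")
  dw <- random_distance(10, seed = 52, labels = rownames(m))
  preds <- list(v = dv, w = dw)
  c_sor <- mrm(betas$beta_sor, preds, n_perm = 9, seed = 1)$coefficients
  c_sim <- mrm(betas$beta_sim, preds, n_perm = 9, seed = 1)$coefficients
  c_sne <- mrm(betas$beta_sne, preds, n_perm = 9, seed = 1)$coefficients
  expect_lt(max(abs(c_sor - (c_sim + c_sne))), 1e-10)
})
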