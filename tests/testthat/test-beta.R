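test_that("pair_counts does set arithmetic over aligned species lists", {
  x <- c(sp1 = 1, sp2 = 1, sp3 = 1, sp4 = 0)
  y <- c(sp1 = 0, sp2 = 1, sp3 = 1, sp4 = 1)
  p <- pair_counts(x, y)
  expect_equal(unclass(p), list(a = 2L, b = 1L, c = 1L))
  ident <- pair_counts(x, x)
  expect_equal(c(ident$b, ident$c), c(0L, 0L))
  expect_equal(pair_counts(c(1, 1, 0, 0), c(0, 0, 1, 1))$a, 0L)
  names(y) <- rev(names(y))
  expect_error(pair_counts(x, y), "species lists")
})

test_that("Sorensen partition matches hand-derived values and the product form", {
  nested <- sorensen_partition(list(a = 3, b = 2, c = 0))
  expect_equal(nested$beta_sim, 0)
  expect_equal(nested$beta_sor, 0.25)
  expect_equal(nested$beta_sne, 0.25)
  balanced <- sorensen_partition(list(a = 2, b = 1, c = 1))
  expect_equal(balanced$beta_sne, 0)
  expect_equal(balanced$beta_sor, 1 / 3)
  mixed <- sorensen_partition(list(a = 1, b = 2, c = 1))
  expect_equal(mixed$beta_sor, 0.6)
  expect_equal(mixed$beta_sim, 0.5)
  expect_equal(mixed$beta_sne, 0.1)
  # closed product form: |b-c|/(2a+b+c) * a/(a+min(b,c))
  expect_equal(mixed$beta_sne, (1 / 5) * (1 / 2))
  expect_error(sorensen_partition(list(a = 0, b = 0, c = 0)), "empty")
})

test_that("additivity and the product form hold for random counts", {
  set.seed(99)
  for (i in 1:200) {
    a <- sample(0:20, 1); b <- sample(0:20, 1); cc <- sample(0:20, 1)
    if (a + b + cc == 0) next
    s <- sorensen_partition(list(a = a, b = b, c = cc))
    expect_lt(abs(s$beta_sor - s$beta_sim - s$beta_sne), 1e-12)
    prod_form <- abs(b - cc) / (2 * a + b + cc) *
      (if (a + min(b, cc) > 0) a / (a + min(b, cc)) else 0)
    expect_lt(abs(s$beta_sne - prod_form), 1e-12)
    j <- alternative_partitions(list(a = a, b = b, c = cc), "jaccard")
    expect_lt(abs(j$beta_jac - j$beta_jtu - j$beta_jne), 1e-12)
    cv <- alternative_partitions(list(a = a, b = b, c = cc), "carvalho")
    expect_lt(abs(cv$beta_cc - cv$beta_repl - cv$beta_rich), 1e-12)
  }
})

test_that("alternative families match their stated formulas", {
  j <- alternative_partitions(list(a = 2, b = 1, c = 1), "jaccard")
  expect_equal(j$beta_jac, 0.5)
  expect_equal(j$beta_jtu, 0.5)
  expect_equal(j$beta_jne, 0)
  n <- alternative_partitions(list(a = 3, b = 2, c = 0), "jaccard")
  expect_equal(n$beta_jtu, 0)
  cn <- alternative_partitions(list(a = 3, b = 2, c = 0), "carvalho")
  expect_equal(cn$beta_repl, 0)
  expect_equal(cn$beta_rich, 0.4)
})

test_that("pairwise matrices agree with per-pair partitions and vegan", {
  m <- toy_abc()
  pm <- pairwise_matrices(m)
  expect_equal(pm$beta_sor["A", "C"], 1)
  expect_equal(pm$beta_sim["A", "C"], 1)
  expect_equal(pm$beta_sne["A", "C"], 0)
  expect_equal(pm$beta_sor, pm$beta_sim + pm$beta_sne)
  ident <- rbind(a = c(1, 1, 0), b = c(1, 1, 0))
  pid <- pairwise_matrices(ident)
  expect_true(all(unlist(pid) == 0))
  # element-wise agreement with the scalar path on a random matrix
  r <- random_community(6, 12, seed = 21)
  pr <- pairwise_matrices(r)
  for (i in 1:5) for (j in (i + 1):6) {
    s <- sorensen_partition(pair_counts(r[i, ], r[j, ]))
    expect_equal(pr$beta_sor[i, j], s$beta_sor)
    expect_equal(pr$beta_sim[i, j], s$beta_sim)
  }
  skip_if_not_installed("vegan")
  expect_equal(as.matrix(vegan::betadiver(r, "w")), pr$beta_sor,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(as.matrix(vegan::betadiver(r, "sim")), pr$beta_sim,
               tolerance = 1e-12, ignore_attr = TRUE)
  empty <- rbind(a = c(1, 0), b = c(0, 0))
  expect_error(pairwise_matrices(empty), "drop_empty_sites")
})

test_that("multisite partition matches hand values, the n = 2 reduction and vegan", {
  # A={1,2}, B={2,3}, C={3,4}: shared = 6 - 4 = 2, sum_min = sum_max = 4
  msb <- multisite_partition(toy_abc())
  expect_equal(msb$counts$shared, 2)
  expect_equal(msb$counts$sum_min, 4)
  expect_equal(msb$counts$sum_max, 4)
  expect_equal(msb$beta_SOR, 8 / 12)
  expect_equal(msb$beta_SIM, 4 / 6)
  expect_equal(msb$beta_SNE, 0)
  # two sites: multiple-site form reduces to the pairwise partition
  m2 <- random_community(2, 15, seed = 4)
  two <- multisite_partition(m2)
  pair <- sorensen_partition(pair_counts(m2[1, ], m2[2, ]))
  expect_equal(two$beta_SOR, pair$beta_sor)
  expect_equal(two$beta_SIM, pair$beta_sim)
  expect_equal(two$beta_SNE, pair$beta_sne)
  # perfectly nested gradient: zero turnover, ratio 1
  nested <- generate_nested(c(5, 3, 1), 5)
  nb <- multisite_partition(nested)
  expect_equal(nb$beta_SIM, 0)
  expect_equal(beta_ratio(nb), 1, ignore_attr = TRUE)
  expect_equal(attr(beta_ratio(nb), "dominance"), "nestedness-dominated")
  skip_if_not_installed("vegan")
  for (seed in 1:3) {
    r <- random_community(8, 20, seed = seed)
    ours <- multisite_partition(r)
    ref <- vegan::nestedbetasor(r)
    expect_equal(ours$beta_SIM, unname(ref["turnover"]), tolerance = 1e-12)
    expect_equal(ours$beta_SNE, unname(ref["nestedness"]), tolerance = 1e-12)
    expect_equal(ours$beta_SOR, unname(ref["sorensen"]), tolerance = 1e-12)
  }
})

test_that("beta indices are invariant to site and species permutation", {
  m <- random_community(7, 15, seed = 10)
  set.seed(2)
  p <- m[sample(nrow(m)), sample(ncol(m))]
  expect_equal(multisite_partition(p)[1:3], multisite_partition(m)[1:3])
  a <- pairwise_matrices(m)$beta_sor
  b <- pairwise_matrices(p)$beta_sor
  expect_equal(b[rownames(a), colnames(a)], a)
})

test_that("beta_ratio is undefined at beta_SOR = 0 rather than 0", {
  same <- rbind(a = c(1, 1, 0), b = c(1, 1, 0))
  expect_error(beta_ratio(multisite_partition(same)), "undefined")
})

test_that("resampling is deterministic, degenerate at full size, and convergent", {
  m <- random_community(12, 30, seed = 6)
  full <- multisite_partition(m)
  r_all <- resampled_multisite(m, subset_size = 12, n_samples = 10, seed = 1)
  expect_equal(unname(r_all$mean["beta_SOR"]), full$beta_SOR)
  expect_true(all(r_all$sd == 0))
  r1 <- resampled_multisite(m, 6, 50, seed = 9)
  r2 <- resampled_multisite(m, 6, 50, seed = 9)
  expect_identical(r1$samples, r2$samples)
  expect_lt(abs(r1$mean["beta_SOR"] - r1$mean["beta_SIM"] - r1$mean["beta_SNE"]),
            1e-12)
  # means approach the full-matrix value as the subset grows
  dev <- vapply(c(4, 8, 11), function(k) {
    abs(resampled_multisite(m, k, 100, seed = 2)$mean["beta_SOR"] - full$beta_SOR)
  }, numeric(1))
  expect_true(all(diff(dev) < 0))
  expect_error(resampled_multisite(m, 1, 10), "at least 2")
  expect_error(resampled_multisite(m, 13, 10), "exceeds")
})
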