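# Fixtures are built in code: random binary communities without empty
# lines, small hand-checkable matrices, and random labelled distance
# matrices.

random_community <- function(n_sites, n_species, fill = 0.4, seed = 1) {
  set.seed(seed)
  repeat {
    m <- matrix(rbinom(n_sites * n_species, 1, fill), n_sites, n_species)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) break
  }
  dimnames(m) <- list(paste0("s", seq_len(n_sites)),
                      paste0("sp", seq_len(n_species)))
  m
}

# A = {1,2}, B = {2,3}, C = {3,4}: the hand-worked 3-site example
toy_abc <- function() {
  m <- rbind(A = c(1, 1, 0, 0), B = c(0, 1, 1, 0), C = c(0, 0, 1, 1))
  colnames(m) <- paste0("sp", 1:4)
  m
}

# strict nested gradient: lower-triangular, all marginal totals distinct
strict_gradient <- function(n = 4) {
  m <- matrix(0, n, n)
  m[lower.tri(m, diag = TRUE)] <- 1
  dimnames(m) <- list(paste0("s", 1:n), paste0("sp", 1:n))
  m
}

random_distance <- function(n, seed = 1, labels = paste0("s", seq_len(n))) {
  set.seed(seed)
  d <- as.matrix(dist(matrix(rnorm(n * 2), n)))
  dimnames(d) <- list(labels, labels)
  d
}

# expected locations of the published species-by-island incidence CSVs
# (supplementary files of the source publication; not bundled)
published_matrix_paths <- function() {
  file.path(system.file("extdata", package = "betanest"),
            c("s1_birds_incidence.csv", "s2_lizards_incidence.csv"))
}
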