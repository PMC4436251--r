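# Data model and file I/O for incidence matrices, island attributes and
# distance matrices. The canonical internal orientation is sites in rows,
# species in columns, whatever the orientation of the file read.

#' Coerce and validate a presence/absence community matrix
#'
#' A community matrix is a binary (0/1) numeric matrix with unique site
#' labels as row names and unique species labels as column names. Sites are
#' always rows internally.
#'
#' @param x A matrix or data frame of incidences.
#' @param truncate_abundance If `TRUE`, positive abundances are truncated to
#'   presence (any value > 0 becomes 1). The default `FALSE` is strict:
#'   any cell outside `{0, 1}` is an error.
#' @return An integer 0/1 matrix with `dimnames`, sites in rows.
#' @examples
#' m <- as_community_matrix(rbind(r1 = c(s1 = 1, s2 = 1, s3 = 0),
#'                                r2 = c(s1 = 0, s2 = 1, s3 = 1)))
#' @export
as_community_matrix <- function(x, truncate_abundance = FALSE) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) stopf("community data must be a matrix or data frame")
  if (!is.numeric(x)) stopf("community matrix cells must be numeric 0/1")
  if (nrow(x) == 0L || ncol(x) == 0L) stopf("community matrix has zero extent")
  if (anyNA(x)) stopf("community matrix contains missing values")
  if (truncate_abundance) x[x > 0] <- 1
  bad <- which(!(x == 0 | x == 1), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    rn <- rownames(x)[bad[1L, 1L]] %||% bad[1L, 1L]
    cn <- colnames(x)[bad[1L, 2L]] %||% bad[1L, 2L]
    stopf("non-binary cell value %s at site '%s', species '%s'",
          format(x[bad[1L, , drop = FALSE]]), rn, cn)
  }
  if (is.null(rownames(x))) rownames(x) <- paste0("site", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("sp", seq_len(ncol(x)))
  if (anyDuplicated(rownames(x))) stopf("duplicate site labels")
  if (anyDuplicated(colnames(x))) stopf("duplicate species labels")
  storage.mode(x) <- "integer"
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a community CSV
#'
#' Reads a labelled presence/absence table. The first column holds line
#' labels and the header holds the other axis. Whichever orientation the
#' file uses, the returned matrix always has sites in rows.
#'
#' @param path Path to a CSV file.
#' @param orientation `"sites-in-rows"` (default) if file rows are sites, or
#'   `"species-in-rows"` if file rows are species (the matrix is transposed
#'   on read).
#' @param truncate_abundance Passed to [as_community_matrix()].
#' @return A validated sites x species 0/1 matrix.
#' @export
read_community_csv <- function(path,
                               orientation = c("sites-in-rows", "species-in-rows"),
                               truncate_abundance = FALSE) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  if (orientation == "species-in-rows") m <- t(m)
  as_community_matrix(m, truncate_abundance = truncate_abundance)
}

#' Write a community matrix to CSV
#'
#' Inverse of [read_community_csv()] with `orientation = "sites-in-rows"`;
#' reading the written file reproduces the incidence table exactly.
#'
#' @param m Community matrix.
#' @param path Output path.
#' @export
write_community_csv <- function(m, path) {
  m <- as_community_matrix(m)
  utils::write.csv(as.data.frame(m), path, quote = FALSE)
  invisible(path)
}

#' Remove sites with no species
#'
#' Empty inventories carry no compositional information and are excluded
#' from dissimilarity and nestedness analysis (as done for islands on which
#' no lizard was recorded).
#'
#' @param m Community matrix.
#' @return A list with `matrix` (all retained sites have richness >= 1) and
#'   `removed` (character vector of dropped site labels, possibly empty).
#' @export
drop_empty_sites <- function(m) {
  m <- as_community_matrix(m)
  empty <- rowSums(m) == 0L
  if (all(empty)) stopf("all sites are empty")
  list(matrix = m[!empty, , drop = FALSE], removed = rownames(m)[empty])
}

#' Per-site species richness
#'
#' @param m Community matrix.
#' @return Named integer vector of presences per site.
#' @export
site_richness <- function(m) {
  m <- as_community_matrix(m)
  rowSums(m)
}

#' Matrix fill
#'
#' Percentage of cells of the incidence matrix that are presences.
#'
#' @param m Community matrix.
#' @return A percentage in \[0, 100\].
#' @export
matrix_fill <- function(m) {
  m <- as_community_matrix(m)
  100 * sum(m) / length(m)
}

#' Coefficient of variation of species richness
#'
#' Sample standard deviation over mean of per-site richness; a dimensionless
#' measure of how unequal inventories are, which conditions how much
#' richness differences can contribute to dissimilarity.
#'
#' @param richness Per-site richness counts (e.g. from [site_richness()]).
#' @param exclude_empty If `TRUE`, zero-richness sites are excluded first.
#' @return sd/mean.
#' @export
richness_cv <- function(richness, exclude_empty = FALSE) {
  if (exclude_empty) richness <- richness[richness > 0]
  if (length(richness) < 2L) stopf("need at least 2 sites for a CV")
  mu <- mean(richness)
  if (mu == 0) stopf("mean richness is zero; CV undefined")
  stats::sd(richness) / mu
}

#' Read an island attribute table
#'
#' Expects columns `island`, `lat`, `lon` (decimal degrees), `area_ha`,
#' `isolation` (fraction of a buffer around the island that is water, in
#' (0, 1\]), `habitat_richness`, and optionally `richness_<taxon>` columns.
#'
#' @param path CSV path.
#' @return A validated data frame, one row per island.
#' @export
read_attributes_csv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE)
  validate_attributes(df)
}

validate_attributes <- function(df) {
  required <- c("island", "lat", "lon", "area_ha", "isolation", "habitat_richness")
  missing <- setdiff(required, names(df))
  if (length(missing)) stopf("missing attribute column(s): %s",
                             paste(missing, collapse = ", "))
  if (anyDuplicated(df$island)) stopf("duplicate island codes")
  if (any(!is.finite(df$area_ha)) || any(df$area_ha <= 0)) {
    stopf("island areas must be positive")
  }
  if (any(df$isolation <= 0 | df$isolation > 1)) {
    stopf("isolation must lie in (0, 1]")
  }
  hr <- df$habitat_richness
  if (any(!is.na(hr) & hr < 1)) stopf("habitat_richness must be >= 1")
  if (any(abs(df$lat) > 90) || any(abs(df$lon) > 180)) {
    stopf("coordinates out of range")
  }
  df
}

#' Read / write a labelled square distance matrix
#'
#' CSV layout: first column and header carry the same ordered site labels.
#' On read the matrix is checked for symmetry, zero diagonal and
#' non-negative entries.
#'
#' @param d Square symmetric matrix with matching `dimnames`.
#' @param path CSV path.
#' @return `read_distance_csv` returns the validated matrix;
#'   `write_distance_csv` returns `path` invisibly.
#' @export
write_distance_csv <- function(d, path) {
  d <- as_distance_matrix(d)
  utils::write.csv(as.data.frame(d), path, quote = FALSE)
  invisible(path)
}

#' @rdname write_distance_csv
#' @export
read_distance_csv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as_distance_matrix(as.matrix(df))
}

#' Validate a distance matrix
#'
#' @param d Square numeric matrix.
#' @param tol Numeric tolerance for symmetry and the zero diagonal.
#' @return The matrix, with column names copied from row names if absent.
#' @export
as_distance_matrix <- function(d, tol = 1e-8) {
  if (!is.matrix(d) || !is.numeric(d)) stopf("distance matrix must be numeric")
  if (nrow(d) != ncol(d)) stopf("distance matrix must be square")
  if (is.null(rownames(d))) rownames(d) <- paste0("site", seq_len(nrow(d)))
  if (is.null(colnames(d))) colnames(d) <- rownames(d)
  if (!identical(rownames(d), colnames(d))) stopf("row/column labels differ")
  if (anyNA(d)) stopf("distance matrix contains missing values")
  if (max(abs(d - t(d))) > tol) stopf("distance matrix is not symmetric")
  if (max(abs(diag(d))) > tol) stopf("distance matrix diagonal is not zero")
  if (any(d < -tol)) stopf("distance matrix has negative entries")
  d
}

# Reorder dy's sites to match dx's label order; error if the label sets differ.
align_distance <- function(dx, dy, what = "matrices") {
  if (!setequal(rownames(dx), rownames(dy))) {
    stopf("site labels of the %s do not match", what)
  }
  dy[rownames(dx), rownames(dx), drop = FALSE]
}
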