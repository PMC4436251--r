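# End-to-end orchestration: from a community matrix and an island
# attribute table to the full set of study statistics (multiple-site
# partition, NODF null test, richness models, distance-matrix
# associations), with fixed seeds and machine- plus human-readable output.

#' Run the full beta-diversity analysis for one taxon
#'
#' Reads (or accepts) a community matrix and an island attribute table,
#' drops empty sites, and computes: matrix descriptors (fill, richness CV),
#' the multiple-site Sorensen partition and `beta_ratio` (optionally also
#' resampled to a fixed number of inventories), the NODF-for-sites PP-null
#' test, attribute correlations, the species-area regression and backward
#' stepwise AIC selection, and MRM plus simple and space-partialled Mantel
#' statistics relating each partition component to differences in island
#' area (log10), isolation and habitat richness. Every stochastic stage is
#' seeded deterministically from `config$seed`.
#'
#' @param config A named list (or path to a YAML file with the same
#'   fields): `community` (matrix or CSV path), `orientation` (for CSV
#'   input), `attributes` (data frame or CSV path), `taxon` (label; also
#'   selects a `richness_<taxon>` attribute column when present),
#'   `resample` (`NULL` or list with `subset_size`, `n_samples`), `nodf`
#'   (list with `n_sim`, `axis`), `n_perm` (Mantel/MRM permutations),
#'   `seed`, and optional `out_dir`.
#' @return Invisibly, the report bundle: a nested list of all results. If
#'   `out_dir` is set, writes `results_<taxon>.json` (full precision),
#'   `report_<taxon>.txt` (rounded to 2 decimals) and the three pairwise
#'   dissimilarity matrices as CSVs.
#' @export
reproduce_analysis <- function(config) {
  cfg <- load_config(config)
  seed <- cfg$seed %||% 1L
  taxon <- cfg$taxon %||% "taxon"

  m <- if (is.character(cfg$community)) {
    read_community_csv(cfg$community,
                       orientation = cfg$orientation %||% "sites-in-rows")
  } else as_community_matrix(cfg$community)
  attrs <- if (is.character(cfg$attributes)) read_attributes_csv(cfg$attributes)
           else validate_attributes(cfg$attributes)
  if (!setequal(rownames(m), as.character(attrs$island))) {
    stopf("community sites and attribute island codes do not match")
  }
  attrs <- attrs[match(rownames(m), as.character(attrs$island)), , drop = FALSE]

  dropped <- drop_empty_sites(m)
  mk <- dropped$matrix
  ak <- attrs[match(rownames(mk), as.character(attrs$island)), , drop = FALSE]
  richness <- site_richness(mk)

  descriptors <- list(
    n_sites = nrow(mk), n_species = ncol(mk), removed_sites = dropped$removed,
    fill_percent = matrix_fill(mk),
    richness_cv = richness_cv(richness)
  )

  msb <- multisite_partition(mk)
  resampled <- NULL
  if (!is.null(cfg$resample)) {
    resampled <- resampled_multisite(mk, subset_size = cfg$resample$subset_size,
                                     n_samples = cfg$resample$n_samples %||% 100,
                                     seed = seed + 1L)
  }

  nodf_cfg <- cfg$nodf %||% list()
  # NODF is defined over non-empty lines only; unrecorded species are dropped
  mn <- mk[, colSums(mk) > 0L, drop = FALSE]
  nodf_res <- nodf_null_test(mn, n_sim = nodf_cfg$n_sim %||% 1000,
                             axis = nodf_cfg$axis %||% "sites",
                             seed = seed + 2L)

  correlations <- attribute_correlations(ak)
  sar <- species_area_regression(richness, ak)
  stepwise <- backward_stepwise_aic(richness, ak)

  n_perm <- cfg$n_perm %||% 999
  betas <- pairwise_matrices(mk)
  labels <- rownames(mk)
  preds <- list(
    area = attribute_distance(ak$area_ha, labels, transform = "log10"),
    isolation = attribute_distance(ak$isolation, labels),
    habitat_richness = attribute_distance(ak$habitat_richness, labels)
  )
  dgeo <- geo_distance(ak$lat, ak$lon, labels)

  associations <- lapply(seq_along(betas), function(bi) {
    resp <- betas[[bi]]
    fit <- mrm(resp, preds, n_perm = n_perm, seed = seed + 10L + bi)
    per_pred <- lapply(seq_along(preds), function(pi) {
      list(
        mantel = mantel_test(resp, preds[[pi]], n_perm = n_perm,
                             seed = seed + 100L + 10L * bi + pi),
        partial_mantel = partial_mantel_test(
          resp, preds[[pi]], dgeo, n_perm = n_perm,
          seed = seed + 200L + 10L * bi + pi, covariate_label = "geographic")
      )
    })
    names(per_pred) <- names(preds)
    list(mrm = fit, predictors = per_pred)
  })
  names(associations) <- names(betas)

  bundle <- list(
    taxon = taxon, seed = seed,
    settings = list(n_perm = n_perm, nodf_n_sim = nodf_cfg$n_sim %||% 1000,
                    resample = cfg$resample,
                    package_version = as.character(utils::packageVersion("betanest"))),
    descriptors = descriptors,
    multisite = msb[c("beta_SOR", "beta_SIM", "beta_SNE", "beta_ratio", "n_sites")],
    dominance = attr(beta_ratio(msb), "dominance"),
    resampled = if (!is.null(resampled)) {
      list(mean = as.list(resampled$mean), sd = as.list(resampled$sd),
           subset_size = resampled$subset_size, n_samples = resampled$n_samples)
    },
    nodf = nodf_res[c("n_obs", "n_exp_mean", "n_exp_sd", "z", "p",
                      "direction", "n_sim", "axis")],
    attribute_correlations = correlations,
    species_area = list(terms = sar$terms, r_squared = sar$r_squared,
                        aic = sar$aic),
    stepwise = list(terms = stepwise$terms, r_squared = stepwise$r_squared,
                    aic = stepwise$aic, retained = stepwise$predictors),
    associations = associations
  )

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      strip_models(bundle),
      file.path(cfg$out_dir, sprintf("results_%s.json", taxon)),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    writeLines(format_report(bundle),
               file.path(cfg$out_dir, sprintf("report_%s.txt", taxon)))
    for (nm in names(betas)) {
      write_distance_csv(betas[[nm]],
                         file.path(cfg$out_dir, sprintf("%s_%s.csv", nm, taxon)))
    }
  }
  invisible(bundle)
}

load_config <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stopf("reading YAML configs requires the 'yaml' package")
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stopf("config must be a list or YAML path")
  if (is.null(config$community)) stopf("config$community is required")
  if (is.null(config$attributes)) stopf("config$attributes is required")
  config
}

# drop lm objects and other non-serializable internals before JSON output
strip_models <- function(x) {
  if (inherits(x, "lm")) return(NULL)
  if (is.list(x)) {
    x <- lapply(x, strip_models)
    x[!vapply(x, is.null, logical(1))]
  } else x
}

format_report <- function(b) {
  f2 <- function(x) formatC(x, format = "f", digits = 2)
  lines <- c(
    sprintf("Beta-diversity analysis report: %s (seed %d)", b$taxon, b$seed),
    sprintf("Sites: %d retained (%d removed as empty), species: %d",
            b$descriptors$n_sites, length(b$descriptors$removed_sites),
            b$descriptors$n_species),
    sprintf("Matrix fill: %s%%   richness CV: %s",
            f2(b$descriptors$fill_percent), f2(b$descriptors$richness_cv)),
    "",
    sprintf("Multiple-site partition (n = %d): beta_SOR = %s, beta_SIM = %s, beta_SNE = %s",
            b$multisite$n_sites, f2(b$multisite$beta_SOR),
            f2(b$multisite$beta_SIM), f2(b$multisite$beta_SNE)),
    sprintf("beta_ratio = %s (%s)", f2(b$multisite$beta_ratio), b$dominance)
  )
  if (!is.null(b$resampled)) {
    lines <- c(lines, sprintf(
      "Resampled (%d samples of %d sites): beta_SOR = %s, beta_SIM = %s, beta_SNE = %s, beta_ratio = %s",
      b$resampled$n_samples, b$resampled$subset_size,
      f2(b$resampled$mean$beta_SOR), f2(b$resampled$mean$beta_SIM),
      f2(b$resampled$mean$beta_SNE), f2(b$resampled$mean$beta_ratio)))
  }
  lines <- c(lines, "",
    sprintf("NODF (%s): N_obs = %s, N_exp = %s (SD %s), Z = %s, p = %.3g [%s, %d randomizations]",
            b$nodf$axis, f2(b$nodf$n_obs), f2(b$nodf$n_exp_mean),
            f2(b$nodf$n_exp_sd), f2(b$nodf$z), b$nodf$p, b$nodf$direction,
            b$nodf$n_sim),
    "",
    sprintf("Species-area regression: slope = %s, intercept = %s, R^2 = %s",
            f2(b$species_area$terms$estimate[2]),
            f2(b$species_area$terms$estimate[1]), f2(b$species_area$r_squared)),
    sprintf("Stepwise (AIC) retained: %s (R^2 = %s)",
            paste(b$stepwise$retained, collapse = ", "),
            f2(b$stepwise$r_squared)),
    "", "Associations (MRM slope / partial Mantel r, covariate = geographic):")
  for (nm in names(b$associations)) {
    a <- b$associations[[nm]]
    for (pv in names(a$predictors)) {
      pm <- a$predictors[[pv]]$partial_mantel
      lines <- c(lines, sprintf(
        "  %s ~ d_%s: a = %s, b = %s, r = %s (p = %.3g)",
        nm, pv, f2(a$mrm$coefficients[[pv]]),
        f2(a$mrm$coefficients[["intercept"]]), f2(pm$r), pm$p))
    }
  }
  lines
}
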