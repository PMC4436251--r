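# Island-attribute statistics: Pearson correlations among log-transformed
# variables, species-area regression on the log10-log10 scale, and backward
# stepwise model selection by AIC.

#' Pairwise Pearson correlations among island variables
#'
#' @param attrs Island attribute data frame (see [read_attributes_csv()]).
#' @param vars Columns to correlate (default area, isolation, habitat
#'   richness).
#' @param transform `"log10"` (default; all variables must be positive) or
#'   `"none"`.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
attribute_correlations <- function(attrs,
                                   vars = c("area_ha", "isolation", "habitat_richness"),
                                   transform = c("log10", "none")) {
  transform <- match.arg(transform)
  missing <- setdiff(vars, names(attrs))
  if (length(missing)) stopf("unknown attribute column(s): %s",
                             paste(missing, collapse = ", "))
  x <- as.matrix(attrs[, vars, drop = FALSE])
  if (transform == "log10") {
    if (any(x <= 0)) stopf("log10 transform needs positive values")
    x <- log10(x)
  }
  if (any(apply(x, 2, stats::sd) == 0)) {
    stopf("constant variable: correlation undefined")
  }
  stats::cor(x)
}

regression_result <- function(fit, response, predictors, zero_offset) {
  s <- summary(fit)
  co <- s$coefficients
  structure(
    list(terms = data.frame(term = rownames(co), estimate = co[, 1],
                            std_error = co[, 2], p = co[, 4],
                            row.names = NULL),
         r_squared = s$r.squared, aic = stats::AIC(fit),
         response = response, predictors = predictors,
         zero_offset = zero_offset, model = fit),
    class = "island_regression"
  )
}

prepare_log_frame <- function(richness, attrs, predictors, zero_offset) {
  if (nrow(attrs) != length(richness)) stopf("richness/attribute length mismatch")
  if (any(richness + zero_offset <= 0)) {
    stopf(paste("non-positive richness + offset; raise zero_offset or drop",
                "empty sites first"))
  }
  missing <- setdiff(predictors, names(attrs))
  if (length(missing)) stopf("unknown attribute column(s): %s",
                             paste(missing, collapse = ", "))
  d <- data.frame(.S = log10(richness + zero_offset))
  for (v in predictors) {
    if (any(attrs[[v]] <= 0)) stopf("predictor '%s' must be positive for log10", v)
    d[[v]] <- log10(attrs[[v]])
  }
  d
}

#' Species-area regression on the log10-log10 scale
#'
#' Fits `log10(richness + zero_offset) ~ log10(predictors)` by OLS, the
#' linearized power-law species-area relationship. Sites with zero richness
#' must either be dropped beforehand (the convention followed for empty
#' inventories) or accommodated with a positive `zero_offset`.
#'
#' @param richness Per-island richness counts (at least 3 islands).
#' @param attrs Island attribute data frame aligned with `richness`.
#' @param predictors Attribute columns used as predictors (default area).
#' @param zero_offset Added to richness before the log (default 0).
#' @return Class `island_regression`: a `terms` table (estimate, SE, p),
#'   `r_squared`, `aic`, and the underlying `lm` fit.
#' @export
species_area_regression <- function(richness, attrs, predictors = "area_ha",
                                    zero_offset = 0) {
  if (length(richness) < 3L) stopf("need at least 3 islands")
  d <- prepare_log_frame(richness, attrs, predictors, zero_offset)
  fit <- stats::lm(stats::reformulate(predictors, ".S"), data = d)
  if (any(is.na(stats::coef(fit)))) stopf("degenerate design matrix")
  regression_result(fit, "log10(richness)", predictors, zero_offset)
}

#' Backward stepwise selection by AIC
#'
#' Starts from the full log10-log10 model over the candidate attributes and
#' repeatedly drops the term whose removal lowers AIC most, stopping when
#' no removal lowers AIC (`stats::step`, backward, k = 2). The selected
#' model never has higher AIC than the full model.
#'
#' @inheritParams species_area_regression
#' @param candidates Candidate attribute columns (default area, isolation,
#'   habitat richness).
#' @return Class `island_regression` for the selected model, with a
#'   `candidates` element recording the starting set.
#' @export
backward_stepwise_aic <- function(richness, attrs,
                                  candidates = c("area_ha", "isolation",
                                                 "habitat_richness"),
                                  zero_offset = 0) {
  d <- prepare_log_frame(richness, attrs, candidates, zero_offset)
  full <- stats::lm(stats::reformulate(candidates, ".S"), data = d)
  if (any(is.na(stats::coef(full)))) stopf("full model not estimable")
  best <- stats::step(full, direction = "backward", trace = 0)
  out <- regression_result(best, "log10(richness)",
                           attr(stats::terms(best), "term.labels"), zero_offset)
  out$candidates <- candidates
  out
}

#' @export
print.island_regression <- function(x, ...) {
  cat(sprintf("Regression of %s on log10-transformed %s%s\n", x$response,
              paste(x$predictors, collapse = " + "),
              if (x$zero_offset > 0) sprintf(" (offset %g)", x$zero_offset) else ""))
  print(transform(x$terms, estimate = round(estimate, 4),
                  std_error = round(std_error, 4), p = signif(p, 3)))
  cat(sprintf("R^2 = %.4f, AIC = %.2f\n", x$r_squared, x$aic))
  invisible(x)
}
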