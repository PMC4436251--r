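# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded functions do not
#' perturb the global random stream.
#'
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  env <- globalenv()
  had_seed <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = env, inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = env), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(list = ".Random.seed", envir = env)
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# Upper-triangle unfolding used by all distance-matrix statistics; a fixed
# orientation keeps permutation tests and MRM designs aligned.
upper_vec <- function(d) {
  d[upper.tri(d)]
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
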