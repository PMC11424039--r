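#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif rbinom coef lm AIC logLik pchisq qt predict
#'   sd var median quantile anova as.formula complete.cases pt setNames
#' @importFrom utils write.csv read.csv head modifyList
NULL

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library code never clobbers user streams.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("micoconn_invalid_argument", "error")))
}

check_unit <- function(v, name, tol = 1e-4) {
  n <- sqrt(sum(v^2))
  if (abs(n - 1) > tol) {
    stop_invalid(name, " must be a unit vector (norm = ", format(n), ")")
  }
  invisible(v)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
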