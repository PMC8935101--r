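#' @importFrom rlang abort warn %||%
#' @importFrom stats dbinom dpois dnorm rnorm runif rpois rbinom rgamma
#'   plogis qlogis quantile sd var prcomp glm glm.fit coef binomial poisson
#'   setNames acf
#' @importFrom utils head tail
NULL

# Single entry point for argument failures so messages are uniform.
stop_invalid <- function(msg, class = "hurdlemap_invalid_argument") {
  abort(msg, class = class)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_invalid(sprintf("`%s` must be a single positive finite number.", name))
  }
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    stop_invalid(sprintf("`%s` must be a single non-negative finite number.", name))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != as.integer(x) || x < min) {
    stop_invalid(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

# All randomness flows from one user seed.  Sub-streams are derived by a
# fixed affine map so independent stages never share a stream; the result
# stays inside the 32-bit integer range R requires of set.seed().
derive_seed <- function(seed, offset) {
  # double-precision arithmetic: products of 32-bit seeds overflow integers
  as.integer((abs(as.numeric(seed)) * 1009 + as.numeric(offset) * 9973) %%
    2147483647)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards (so generators are pure in (inputs, seed)).
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

log1p_exp <- function(x) {
  # log(1 + exp(x)) without overflow for large |x|
  ifelse(x > 35, x, log1p(exp(pmin(x, 35))))
}
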