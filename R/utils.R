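#' @importFrom rlang .data abort warn inform %||%
#' @importFrom stats quantile rnorm runif rbinom rmultinom rlnorm rnbinom
#'   rexp sd median setNames qbinom var acf fft nextn dnorm qnorm rgamma
#' @importFrom utils head tail
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Generalized log binomial coefficient: log C(a, b) for real b >= 0,
# zero (i.e. -Inf) when b > a. Used by the continuous rarefaction formulas.
lchoose_gen <- function(a, b) {
  out <- rep(-Inf, length(a))
  ok <- (a - b > -1 + 1e-12) & a >= 0
  # lgamma poles at non-positive integers handled by the ok mask
  out[ok] <- lgamma(a[ok] + 1) - lgamma(b + 1) - lgamma(a[ok] - b + 1)
  out
}

is_count_vector <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(abs(x - round(x)) < 1e-8)
}
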