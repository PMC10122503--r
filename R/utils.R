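# Internal helpers shared across modules.

SMOKING_CLASSES <- c("current", "ex", "never", "unknown")
KNOWN_CLASSES <- c("current", "ex", "never")

#' @useDynLib smokesurg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Run `code` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

check_prob_vector <- function(p, what, tol = 1e-9) {
  if (any(!is.finite(p)) || any(p < 0))
    stop(what, " must be a vector of non-negative finite probabilities",
         call. = FALSE)
  if (abs(sum(p) - 1) > tol)
    stop(what, " must sum to 1 (got ", format(sum(p)), ")", call. = FALSE)
  invisible(p)
}

# Inverse-CDF draw from a normal truncated to [lo, hi].
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
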