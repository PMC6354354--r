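# Internal numerical and RNG helpers shared across modules.

#' Log-sum-exp
#'
#' Stable computation of \code{log(sum(exp(x)))}.
#'
#' @param x numeric vector of log-scale values (may contain \code{-Inf}).
#' @return a single numeric value.
#' @keywords internal
logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Signed log-sum-exp: sum of terms sign_i * exp(log_i), returned as
# list(log = log|total|, sign = sign(total)). Needed by the
# inclusion-exclusion sums over distinct-SNP assignments.
logsumexp_signed <- function(logs, signs) {
  keep <- is.finite(logs)
  logs <- logs[keep]
  signs <- signs[keep]
  if (length(logs) == 0L) return(list(log = -Inf, sign = 0))
  m <- max(logs)
  s <- sum(signs * exp(logs - m))
  if (s == 0) return(list(log = -Inf, sign = 0))
  list(log = m + log(abs(s)), sign = sign(s))
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Derive independent child seeds from one master seed
#'
#' A single integer seed drives every stochastic operation in the package;
#' stages draw their own sub-streams through this splitter so that adding
#' replicates to one stage never perturbs another.
#'
#' @param seed master integer seed.
#' @param n number of child seeds required.
#' @return integer vector of length \code{n}, each in \[1, 2^31 - 2\].
#' @export
split_seed <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 1)
  with_seed(as.integer(seed), sample.int(2147483646L, n))
}

# Short md5 fingerprint of an arbitrary R object (config provenance).
object_fingerprint <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
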