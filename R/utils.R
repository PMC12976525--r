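# Internal numeric and RNG helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a local RNG seed
#'
#' Sets the seed for the duration of `expr` and restores the caller's RNG
#' state afterwards, so seeded routines (bootstraps, simulations) never
#' perturb the global stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Derive a named sub-seed from a master seed
#'
#' All pipeline randomness flows from one master seed through named
#' sub-streams, so any stage can be re-run in isolation and reproduce its
#' draws exactly. The derived seed is a deterministic 31-bit hash of the
#' master seed and the stream name.
#'
#' @param master integer master seed.
#' @param name character stream name.
#' @return integer seed in [0, 2^31 - 1].
#' @export
derive_seed <- function(master, name) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(name))
  h <- as.double(master) %% 2147483647
  for (k in utf8ToInt(paste(name, collapse = "/"))) {
    h <- (h * 31 + k) %% 2147483647
  }
  as.integer(h)
}

# log(sum(exp(x))) without overflow; -Inf-safe.
logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b; returns -Inf when the difference
# underflows (a ~ b), which is the correct limit for hypothesis sums.
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

# Two-sided normal p-value from an estimate and its standard error.
z_pvalue <- function(estimate, se) {
  2 * stats::pnorm(-abs(estimate / se))
}

# 95% normal CI bounds at the conventional 1.96 multiplier used for
# odds-ratio reporting.
CI_Z <- 1.96

stop_targetmr <- function(msg, class) {
  stop(structure(class = c(class, "targetmr_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

warn_targetmr <- function(msg, class) {
  warning(structure(class = c(class, "targetmr_warning", "warning", "condition"),
                    list(message = msg, call = sys.call(-1))))
}
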