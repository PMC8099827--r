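#' @keywords internal
"_PACKAGE"

#' @importFrom stats pnorm qnorm qlogis plogis rbinom runif rnorm cor var
#'   glm.fit binomial setNames
#' @importFrom utils combn head tail
NULL

# numerically stable log(sum(exp(x)))
logsumexp <- function(x) {
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) stop(sprintf(...), call. = FALSE)

dc_log <- function(verbose, ...) {
  if (isTRUE(verbose)) message("[dualcoloc] ", sprintf(...))
}

# checks a scalar is a finite number within (optionally open) bounds
check_scalar <- function(x, name, lo = -Inf, hi = Inf,
                         open_lo = FALSE, open_hi = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_param("'%s' must be a single finite number", name)
  if (x < lo || (open_lo && x == lo) || x > hi || (open_hi && x == hi))
    stop_param("'%s' = %g outside the allowed range", name, x)
  invisible(x)
}
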