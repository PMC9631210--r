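#' @keywords internal
#' @importFrom stats runif rbinom plogis
#' @importFrom utils head read.delim
#' @importFrom Rcpp evalCpp
#' @useDynLib ldapred, .registration = TRUE
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Leaky rectified linear unit
#'
#' Elementwise `max(x, 0) + slope * min(x, 0)`; preserves matrix dimensions.
#' @param x numeric vector or matrix.
#' @param slope negative-branch slope, default 0.2.
#' @return object of the same shape as `x`.
#' @keywords internal
leaky_relu <- function(x, slope = 0.2) {
  pmax(x, 0) + slope * pmin(x, 0)
}

# derivative of leaky_relu; the kink at 0 takes the positive branch
leaky_relu_grad <- function(x, slope = 0.2) {
  (x >= 0) + slope * (x < 0)
}

sigmoid <- function(x) stats::plogis(x)

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's `.Random.seed` afterwards so that library code
#' consuming explicit seeds never perturbs the user's RNG stream.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- .GlobalEnv$.Random.seed
  on.exit({
    if (is.null(old)) {
      suppressWarnings(rm(".Random.seed", envir = .GlobalEnv))
    } else {
      assign(".Random.seed", old, envir = .GlobalEnv)
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed derivation; keeps results inside 32-bit range.
derive_seed <- function(seed, ...) {
  offs <- c(...)
  s <- (as.double(seed) %% 65011) * 33013
  if (length(offs)) {
    s <- s + sum(as.double(offs) * 1009^seq_along(offs))
  }
  as.integer(s %% 2147483563) + 1L
}

stop_ldapred <- function(msg, class) {
  stop(structure(class = c(class, "ldapred_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
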