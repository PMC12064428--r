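# Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a master seed and a stage label
#'
#' One user-facing seed is expanded into independent per-stage substreams so
#' that each pipeline stage is reproducible in isolation. The derived seed is
#' always a valid 32-bit R integer.
#'
#' @param seed master integer seed.
#' @param label character stage label.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483629)
}

# Dirichlet draws; rows are independent draws over `alpha`.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(rgamma(n * k, shape = alpha, rate = 1), nrow = n, byrow = TRUE)
  zero <- rowSums(x) <= 0
  if (any(zero)) { # numerically degenerate gamma draws at tiny alpha
    x[zero, ] <- t(vapply(which(zero), function(i) {
      v <- numeric(k); v[sample.int(k, 1L, prob = alpha)] <- 1; v
    }, numeric(k)))
  }
  x / rowSums(x)
}

logit <- function(p) qlogis(p)
inv_logit <- function(x) plogis(x)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_prob <- function(x, name, open_upper = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 &&
    (if (open_upper) x < 1 else x <= 1)
  if (!ok) stop(sprintf("`%s` must be a single proportion in [0,%s)", name,
                        if (open_upper) "1" else "1]"), call. = FALSE)
  invisible(x)
}
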