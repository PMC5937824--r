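# Shared validation helpers. All user-facing validation failures are rlang
# conditions with a class of the form "dyadkit_error_<what>" so callers (and
# tests) can catch specific failures rather than matching message strings.

stop_dyadkit <- function(what, msg, ...) {
  abort(msg, class = paste0("dyadkit_error_", what), ...)
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_dyadkit("invalid_argument", sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || x > upper) {
    stop_dyadkit("invalid_argument",
                 sprintf("`%s` must lie in [%s, %s]; got %s.", name, lower, upper, x))
  }
  invisible(x)
}

check_count <- function(x, name, lower = 0L) {
  check_number(x, name, lower = lower)
  if (x != round(x)) {
    stop_dyadkit("invalid_argument", sprintf("`%s` must be an integer.", name))
  }
  invisible(as.integer(x))
}

# Symmetric-matrix check with tolerance relative to the largest entry.
check_symmetric <- function(m, name, tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop_dyadkit("invalid_argument", sprintf("`%s` must be a square matrix.", name))
  }
  scale <- max(abs(m), 1)
  if (max(abs(m - t(m))) > tol * scale) {
    stop_dyadkit("invalid_argument", sprintf("`%s` must be symmetric.", name))
  }
  invisible((m + t(m)) / 2)
}

check_pd <- function(m, name, tol = 1e-10) {
  m <- check_symmetric(m, name)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= tol * max(abs(ev))) {
    stop_dyadkit("not_positive_definite",
                 sprintf("`%s` must be positive definite (smallest eigenvalue %.3e).",
                         name, min(ev)))
  }
  invisible(m)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
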