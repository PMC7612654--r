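# Internal helpers: classed conditions and small numeric utilities.

lp_abort <- function(message, class, ...) {
  rlang::abort(message = message, class = c(class, "lp_error"), ...)
}

# is x a single finite number?
is_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

check_prob <- function(p, what, outcome = NULL) {
  where <- if (is.null(outcome)) "" else paste0(" for outcome '", outcome, "'")
  if (!is_number(p) || p <= 0 || p >= 1) {
    lp_abort(
      paste0(what, where, " must lie strictly in (0, 1); got ",
             format(p)),
      class = "lp_error_prob"
    )
  }
  invisible(p)
}

# equicorrelation matrix
equicorr <- function(K, rho) {
  m <- matrix(rho, K, K)
  diag(m) <- 1
  m
}

# nearest positive semi-definite matrix by eigenvalue clipping
psd_project <- function(m, tol = 1e-10) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, tol)
  out <- e$vectors %*% (vals * t(e$vectors))
  (out + t(out)) / 2
}

min_eigenvalue <- function(m) {
  min(eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values)
}
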