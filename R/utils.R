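# internal numeric helpers shared across modules

# Rotate a p x K loading matrix so its top K x K block is lower
# triangular with a positive diagonal (the identifiability convention
# for factor models: loadings are only determined up to rotation, this
# picks one representative per equivalence class without changing LL').
impose_blt <- function(L) {
  K <- ncol(L)
  if (K == 0) return(L)
  if (nrow(L) < K) stop("need at least K rows to impose the constraint", call. = FALSE)
  M <- L[seq_len(K), , drop = FALSE]
  qr_d <- qr(t(M))
  Q <- qr.Q(qr_d, complete = FALSE)
  L2 <- L %*% Q
  # enforce positive diagonal on the top block
  d <- diag(L2[seq_len(K), , drop = FALSE])
  flip <- which(d < 0)
  if (length(flip)) L2[, flip] <- -L2[, flip]
  L2
}

# TRUE if top KxK block is lower triangular (tol) with positive diagonal
is_blt <- function(L, tol = 1e-8) {
  K <- ncol(L)
  if (K == 0) return(TRUE)
  top <- L[seq_len(K), , drop = FALSE]
  upper_ok <- all(abs(top[upper.tri(top)]) < tol)
  diag_ok <- all(diag(top) > -tol)
  upper_ok && diag_ok
}

# row means honouring the observation mask; NaN only if a row has no
# observed entry in the selection
masked_row_means <- function(x, cols = NULL) {
  v <- x$values
  m <- x$mask
  if (!is.null(cols)) {
    v <- v[, cols, drop = FALSE]
    m <- m[, cols, drop = FALSE]
  }
  v[!m] <- 0
  n_obs <- rowSums(m)
  out <- rowSums(v) / n_obs
  out[n_obs == 0] <- NA_real_
  names(out) <- x$feature_ids
  out
}

# deterministic lexicographic order (C locale) for tie-breaking
c_locale_order <- function(...) order(..., method = "radix")

# newton inversion of trigamma, as used for the moderated-t prior df
trigamma_inverse <- function(y) {
  vapply(y, function(yi) {
    if (!is.finite(yi) || yi <= 0) return(Inf)
    if (yi > 1e7) return(1 / sqrt(yi))
    if (yi < 1e-6) return(1 / yi)
    x <- 0.5 + 1 / yi
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, 2)
      x <- x + dif
      if (abs(dif / x) < 1e-10) break
    }
    x
  }, numeric(1))
}
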