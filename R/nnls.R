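# Non-negative least squares by the Lawson-Hanson active-set algorithm.
# Solves min ||A x - b||^2 subject to x >= 0.  Written for the small, dense,
# well-conditioned design matrices of component fitting (a handful of
# columns, hundreds to thousands of rows).
nnls_solve <- function(A, b, max_iter = 50L + 10L * ncol(A)) {
  A <- as.matrix(A)
  n <- ncol(A)
  x <- numeric(n)
  passive <- rep(FALSE, n)
  g <- as.numeric(crossprod(A, b))          # gradient at x = 0
  tol <- 1e-12 * max(1, max(abs(g)))
  w <- g
  iter <- 0L
  while (any(!passive & w > tol) && iter < max_iter) {
    iter <- iter + 1L
    cand <- which(!passive)
    j <- cand[which.max(w[cand])]
    passive[j] <- TRUE
    repeat {
      s <- numeric(n)
      qrP <- qr(A[, passive, drop = FALSE])
      sp <- qr.coef(qrP, b)
      sp[is.na(sp)] <- 0                    # rank-deficient guard
      s[passive] <- sp
      if (all(s[passive] > tol)) {
        x <- s
        break
      }
      drop_set <- passive & s <= tol
      alpha <- min(x[drop_set] / (x[drop_set] - s[drop_set]))
      x <- x + alpha * (s - x)
      passive <- passive & x > tol
      x[!passive] <- 0
      if (!any(passive)) {                  # everything dropped; restart outer
        x[] <- 0
        break
      }
    }
    w <- as.numeric(crossprod(A, b - A %*% x))
  }
  list(x = x, passive = passive,
       rss = sum((b - A %*% x)^2), iterations = iter)
}
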