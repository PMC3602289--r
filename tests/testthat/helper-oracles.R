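# independent dense assembly of the TPS block system, written as explicit
# loops and solved generically — the oracle for fit_tps coefficients
dense_tps_oracle <- function(source, target, lambda = 0) {
  n <- nrow(source); d <- ncol(source)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    K[i, j] <- sqrt(sum((source[i, ] - source[j, ])^2))
  P <- cbind(1, source)
  A <- matrix(0, n + d + 1, n + d + 1)
  A[1:n, 1:n] <- K + lambda * diag(n)
  A[1:n, n + 1:(d + 1)] <- P
  A[n + 1:(d + 1), 1:n] <- t(P)
  rhs <- rbind(target, matrix(0, d + 1, d))
  qr.solve(A, rhs)
}
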