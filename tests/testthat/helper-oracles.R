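# Independent null-space solver for min w' S w subject to a' w = 1:
# parameterise w = w0 + Z t with w0 = a / (a'a) and Z an orthonormal basis
# of the null space of a', then solve the unconstrained normal equations.
# Entirely separate route from the pseudoinverse closed form under test.
nullspace_lcmv <- function(a, sigma) {
  p <- length(a)
  w0 <- a / sum(a * a)
  Z <- qr.Q(qr(cbind(a, diag(p))))[, 2:p, drop = FALSE]
  t_hat <- -solve(t(Z) %*% sigma %*% Z, t(Z) %*% sigma %*% w0)
  as.numeric(w0 + Z %*% t_hat)
}
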