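# Independent oracles: scalar re-implementations kept deliberately separate
# from the package's vectorized code paths.

KB_EV <- 8.617333e-5
CE_EV_NM <- 1.439964

# plain scalar transcription of the rate expression
oracle_et_rate <- function(rc, dg0, lam, nu0, beta, r0, t_k) {
  gate <- nu0 / (1 + exp(beta * (rc - r0)))
  fc <- exp(-(dg0 + lam)^2 / (4 * lam * KB_EV * t_k))
  gate * fc
}

oracle_lambda <- function(rc, a_d, a_a, eps_opt, eps_stat) {
  CE_EV_NM * (1 / (2 * a_d) + 1 / (2 * a_a) - 1 / rc) *
    (1 / eps_opt - 1 / eps_stat)
}

# explicit normal-equations least squares for y = X b
oracle_polyfit <- function(x, y, degree) {
  X <- outer(x, 0:degree, `^`)
  b <- solve(crossprod(X), crossprod(X, y))
  drop(b) # (intercept, linear, [quadratic])
}

# brute-force pairwise Coulomb sum for the protein-charge term
oracle_net_energy <- function(charges, donor, acceptor, eps) {
  total <- 0
  for (i in seq_len(nrow(charges))) {
    rj <- c(charges$x[i], charges$y[i], charges$z[i])
    qj <- charges$charge[i]
    total <- total +
      CE_EV_NM * qj * (-1) / (eps * sqrt(sum((rj - acceptor)^2))) +
      CE_EV_NM * qj * (+1) / (eps * sqrt(sum((rj - donor)^2)))
  }
  total
}

default_params <- function(...) et_params(...)
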