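# Shared oracle helpers. These deliberately avoid the package's analytic
# derivative and rank-based shortcuts so they stay independent of the code
# paths they check.

# central-finite-difference Jacobian of the complex forward signal with
# respect to (Re A, Im A, theta); rows = stacked (Re, Im) channels
fd_signal_jacobian <- function(make_params, theta_full, schedule, h = 1e-6) {
  eval_signal <- function(p) {
    s <- t2oa:::.signal(make_params(p), schedule)
    c(Re(s), Im(s))
  }
  p <- theta_full
  J <- sapply(seq_along(p), function(j) {
    hp <- h * max(1, abs(p[j]))
    up <- p; up[j] <- up[j] + hp
    dn <- p; dn[j] <- dn[j] - hp
    (eval_signal(up) - eval_signal(dn)) / (2 * hp)
  })
  J
}

# Fisher information from a finite-difference Jacobian under i.i.d. complex
# Gaussian noise with per-channel sd sigma
fd_crlb <- function(make_params, theta_full, schedule, sigma) {
  J <- fd_signal_jacobian(make_params, theta_full, schedule)
  diag(solve(crossprod(J) / sigma^2))
}

# brute-force AUC / Mann-Whitney win count by pair enumeration
pair_win_count <- function(x, y) {
  wins <- 0
  for (a in x) for (b in y) {
    wins <- wins + (a > b) + 0.5 * (a == b)
  }
  wins
}

# a small two-group feature set with a known separation on chosen columns
toy_features <- function(n_per_group = 26, p = 6, shift_cols = integer(0),
                         shift = 0, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n_per_group * p), 2 * n_per_group, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  y <- rep(0:1, each = n_per_group)
  X[y == 1, shift_cols] <- X[y == 1, shift_cols] + shift
  list(X = X, y = y, age = runif(2 * n_per_group, 40, 75))
}
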