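# Independent brute-force oracle for the tray likelihood: written from the
# binomial-Poisson model directly, not via the package's functions.
oracle_loglik <- function(lambda, p_large, p_small, n_large, n_small,
                          v_large, v_small) {
  q_l <- exp(-lambda * v_large)
  term_l <- p_large * log(1 - q_l) + (n_large - p_large) * log(q_l)
  term_s <- if (n_small > 0) {
    q_s <- exp(-lambda * v_small)
    p_small * log(1 - q_s) + (n_small - p_small) * log(q_s)
  } else 0
  term_l + term_s
}

# Grid search over log-spaced lambda followed by golden-section refinement.
oracle_mle <- function(p_large, p_small, n_large = 49, n_small = 48,
                       v_large = 1.86, v_small = 0.186) {
  f <- function(lam) oracle_loglik(lam, p_large, p_small, n_large, n_small,
                                   v_large, v_small)
  grid <- exp(seq(log(1e-6), log(1e3), length.out = 4000))
  vals <- vapply(grid, f, numeric(1))
  i <- which.max(vals)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  stats::optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-12)$maximum
}

# Random informative tray (neither all-negative nor all-positive).
random_tray <- function(geometry) {
  repeat {
    p_l <- sample(0:geometry$n_large, 1)
    p_s <- sample(0:geometry$n_small, 1)
    if (p_l + p_s > 0 && p_l + p_s < geometry$n_large + geometry$n_small) {
      return(list(p_large = p_l, p_small = p_s))
    }
  }
}

random_geometry <- function() {
  tray_geometry(
    n_large = sample(10:60, 1), n_small = sample(10:60, 1),
    v_large = stats::runif(1, 0.5, 5), v_small = stats::runif(1, 0.05, 0.4),
    reference_volume = 100
  )
}
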