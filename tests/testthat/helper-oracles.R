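# Independent oracles used against the package implementations.

# Exhaustive grid search for the Fermi deconvolution RSS. The RSS is
# quadratic in A, so A is profiled in closed form (clamped at 0) and (mu, k)
# are searched on a 0.01-resolution grid.
grid_search_fermi <- function(aif, tissue, mu_range = c(0, 8),
                              k_range = c(0.05, 4), step = 0.01) {
  a <- aif$values
  y <- tissue$values
  dt <- aif$dt
  n <- length(a)
  # lower-triangular Toeplitz operator: (Ta r)_i = dt * sum_{j<=i} a_j r_{i-j+1}
  Ta <- matrix(0, n, n)
  for (i in seq_len(n)) Ta[i, seq_len(i)] <- dt * a[i:1]
  mus <- seq(mu_range[1], mu_range[2], by = step)
  ks <- seq(k_range[1], k_range[2], by = step)
  tt <- (seq_len(n) - 1) * dt
  yy <- sum(y^2)
  best <- list(rss = Inf)
  for (mu in mus) {
    R <- 1 / (exp(outer(tt, ks, function(t, k) (t - mu) / k)) + 1)
    M <- Ta %*% R
    mty <- colSums(M * y)
    mtm <- colSums(M * M)
    A <- pmax(mty / mtm, 0)
    rss <- yy - 2 * A * mty + A^2 * mtm
    j <- which.min(rss)
    if (rss[j] < best$rss)
      best <- list(rss = rss[j], A = A[j], mu = mu, k = ks[j])
  }
  best
}

# AUC by exhaustive pairwise concordance counting (ties = 1/2)
brute_force_auc <- function(values, outcome) {
  cases <- values[outcome == 1]
  ctrls <- values[outcome == 0]
  conc <- 0
  for (x in cases) for (y in ctrls)
    conc <- conc + (x > y) + 0.5 * (x == y)
  conc / (length(cases) * length(ctrls))
}

# small noiseless dual-bolus study used across perfusion tests
toy_study <- function(rest_mbf = 1, stress_mbf = 2, noise_sd = 0,
                      seed = 1L, ...) {
  synth_perfusion_study(
    rest = tissue_gen_params(true_mbf = rest_mbf, noise_sd = noise_sd, ...),
    stress = tissue_gen_params(true_mbf = stress_mbf, noise_sd = noise_sd,
                               ...),
    aif = aif_params(), seed = seed)
}
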