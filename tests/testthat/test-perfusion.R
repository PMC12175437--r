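test_that("fermi_response has the correct limits and monotonicity", {
  expect_equal(fermi_response(0, 1, 0, 1), 0.5)       # exp(0) + 1 = 2
  expect_equal(fermi_response(0, 2, 50, 1), 2, tolerance = 1e-12)
  expect_equal(fermi_response(1e6, 1, 0, 1), 0)
  tt <- seq(0, 20, 0.5)
  expect_true(all(diff(fermi_response(tt, 1.5, 5, 1.2)) < 0))
  expect_error(fermi_response(0, 1, 0, 0), "k")
})

test_that("first-pass extraction finds onset and recirculation valley", {
  grid <- seq(0, 90, by = 1)
  mono <- gamma_variate_aif(aif_params(onset_time = 10), grid)
  fp <- extract_first_pass(mono)
  # monotone tail: window runs to the last sample
  expect_equal(fp$times[length(fp)], 90)
  # two-lobe curve: main bolus plus a recirculation bump; the window must
  # end at the inter-lobe minimum located by exhaustive scan
  lobe1 <- gamma_variate_aif(aif_params(onset_time = 10, amplitude = 1), grid)
  lobe2 <- gamma_variate_aif(aif_params(onset_time = 35, amplitude = 0.4,
                                        scale_beta = 4), grid)
  two <- signal_curve(grid, lobe1$values + lobe2$values,
                      baseline_window = 1:5)
  v <- two$values
  interior_min <- which(v[2:90] < v[3:91] & v[2:90] <= v[1:89]) + 1
  interior_min <- interior_min[grid[interior_min] > 16][1]  # after the peak
  fp2 <- extract_first_pass(two, detect_width = 1)
  expect_equal(fp2$times[length(fp2)], grid[interior_min])
  # flat curve: explicit failure
  expect_error(extract_first_pass(signal_curve(0:19, rep(1, 20))),
               "no first pass")
})

test_that("preprocessing smooths, registers and preserves mass", {
  grid <- seq(0, 60, by = 1)
  aif <- extract_first_pass(gamma_variate_aif(aif_params(), grid))
  delayed <- gamma_variate_aif(aif_params(onset_time = 13), grid)
  tis <- extract_first_pass(delayed)
  pair <- preprocess_pair(aif, tis, smooth_width = 3)
  # constructed 3-sample delay is reported as the registration shift
  expect_equal(pair$shift_samples, 3)
  expect_identical(pair$aif$times, pair$tissue$times)
  # identity smoothing (over the truncated common grid)
  p1 <- preprocess_pair(aif, tis, smooth_width = 1)
  expect_equal(p1$aif$values, aif$values[seq_len(length(p1$aif))])
  # interior mass conservation of the moving average
  expect_equal(sum(pair$aif$values), sum(aif$values), tolerance = 0.01)
  expect_error(preprocess_pair(aif, tis, smooth_width = 2), "odd")
  expect_error(preprocess_pair(aif, tis, smooth_width = 999), "length")
})

test_that("AIF scaling is linear and commutes with integration", {
  sc <- gamma_variate_aif(aif_params(), seq(0, 40, 1))
  expect_equal(scale_aif(sc, 1)$values, sc$values)
  s10 <- scale_aif(sc, 10)
  expect_equal(max(s10$values), 10 * max(sc$values))
  expect_equal(sum(s10$values), 10 * sum(sc$values))
  expect_error(scale_aif(sc, -1), "scaling_factor")
})

test_that("noiseless deconvolution recovers MBF to 0.1% across kinetics", {
  for (mbf in c(0.8, 1.5)) for (mu in c(3, 8)) for (k in c(0.8, 2.5)) {
    st <- toy_study(rest_mbf = mbf, stress_mbf = 2 * mbf,
                    fermi_mu = mu, fermi_k = k)
    res <- quantify_perfusion(st)
    expect_lt(abs(res$rest$mbf - mbf) / mbf, 1e-3)
    expect_lt(abs(res$stress$mbf - 2 * mbf) / (2 * mbf), 1e-3)
    expect_equal(res$mpr, 2, tolerance = 1e-6)
  }
})

test_that("null tissue signal fits to zero flow", {
  grid <- seq(0, 30, 1)
  aif <- extract_first_pass(gamma_variate_aif(aif_params(onset_time = 5),
                                              grid))
  zero <- signal_curve(aif$times, rep(0, length(aif)), baseline_window = 1L)
  fit <- fit_fermi_deconvolution(aif, zero)
  expect_lt(fit$A, 1e-8)
  expect_equal(mbf_from_fit(fit, allow_unconverged = TRUE)$mbf, 0,
               tolerance = 1e-8)
})

test_that("fitted MBF is scale-equivariant in tissue and reciprocal in AIF", {
  st <- toy_study(rest_mbf = 1.1, stress_mbf = 2.2)
  aif <- extract_first_pass(st$aif_low_bolus)
  tis <- extract_first_pass(st$tissue_high_bolus_rest)
  pair <- preprocess_pair(aif, tis)
  a <- scale_aif(pair$aif, st$scaling_factor)
  base <- mbf_from_fit(fit_fermi_deconvolution(a, pair$tissue))$mbf
  for (c_ in c(0.5, 3)) {
    tis_c <- signal_curve(pair$tissue$times, c_ * pair$tissue$values,
                          baseline_window = 1L)
    up <- mbf_from_fit(fit_fermi_deconvolution(a, tis_c))$mbf
    expect_equal(up, c_ * base, tolerance = 1e-6)
    a_c <- scale_aif(a, c_)
    down <- mbf_from_fit(fit_fermi_deconvolution(a_c, pair$tissue))$mbf
    expect_equal(down, base / c_, tolerance = 1e-6)
  }
})

test_that("MBF initial-value arithmetic and MPR follow their definitions", {
  f <- structure(list(A = 1, mu = 0, k = 1, rss = 0, n_iterations = 0L,
                      converged = TRUE, dt = 1), class = "fermi_fit")
  expect_equal(mbf_from_fit(f)$mbf, 0.5)
  f$A <- 2; f$mu <- 50
  expect_equal(mbf_from_fit(f)$mbf, 2, tolerance = 1e-12)
  # MPR invariance under a common unit conversion
  st <- toy_study(rest_mbf = 1, stress_mbf = 2.27)
  r1 <- quantify_perfusion(st, unit_conversion = 1)
  r2 <- quantify_perfusion(st, unit_conversion = 3.7)
  expect_equal(r1$mpr, r2$mpr, tolerance = 1e-9)
  expect_equal(r1$mpr, 2.27, tolerance = 1e-4)
  rest0 <- r1$rest; rest0$mbf <- 0
  expect_error(compute_mpr(r1$stress, rest0), "undefined")
})

test_that("grid-search oracle agrees with the Levenberg-Marquardt optimum", {
  # 16-sample toy with mild noise so the minimum RSS is a meaningful scale
  grid <- seq(0, 15, by = 1)
  aif <- signal_curve(grid, c(0, 0.05, 0.4, 1, 0.9, 0.6, 0.35, 0.2, 0.12,
                              0.07, 0.04, 0.02, 0.01, 0.005, 0, 0),
                      baseline_window = 1L)
  truth <- tissue_gen_params(true_mbf = 1, fermi_mu = 3, fermi_k = 1,
                             noise_sd = 0)
  tis <- synth_tissue_curve(aif, truth)
  set.seed(42)
  tis_n <- signal_curve(grid, tis$values +
                          rnorm(16, 0, 0.05 * max(tis$values)),
                        baseline_window = 1L)
  fit <- fit_fermi_deconvolution(aif, tis_n)
  oracle <- grid_search_fermi(aif, tis_n)
  expect_lt(abs(fit$rss - oracle$rss) / oracle$rss, 0.01)
})

test_that("median MBF error stays under 10% at 5% tissue-peak noise", {
  st <- toy_study(rest_mbf = 1, stress_mbf = 1)
  aif <- extract_first_pass(st$aif_low_bolus)
  tis <- extract_first_pass(st$tissue_high_bolus_rest)
  pair <- preprocess_pair(aif, tis)
  a <- scale_aif(pair$aif, st$scaling_factor)
  pk <- max(pair$tissue$values)
  errs <- vapply(1:200, function(i) {
    set.seed(i)
    noisy <- signal_curve(pair$tissue$times,
                          pair$tissue$values +
                            rnorm(length(pair$tissue), 0, 0.05 * pk),
                          baseline_window = 1L)
    fit <- suppressWarnings(fit_fermi_deconvolution(a, noisy))
    abs(mbf_from_fit(fit, allow_unconverged = TRUE)$mbf - 1)
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})
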