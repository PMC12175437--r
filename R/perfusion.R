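#' Fermi impulse response
#'
#' The tissue impulse response is modelled as a Fermi function
#' `R(t) = A / (exp((t - mu)/k) + 1)`: flat at height ~`A` for `t << mu`,
#' decaying with width `k` around the shoulder `mu`. Its initial value
#' `R(0)` is the myocardial blood flow under model-constrained
#' deconvolution.
#'
#' @param t Time (s), scalar or vector.
#' @param A Response amplitude (>= 0).
#' @param mu Shoulder position (s).
#' @param k Decay width (s, > 0).
#' @return `R(t)`, same length as `t`.
#' @export
fermi_response <- function(t, A, mu, k) {
  if (k <= 0) stop("Fermi width `k` must be > 0")
  A / (exp((t - mu) / k) + 1)
}

#' Extract the first-pass window of a curve
#'
#' Locates the bolus passage: onset is the first sample exceeding the
#' baseline mean by `onset_k` baseline standard deviations; the window ends
#' at the first local minimum after the global peak (the valley before
#' recirculation) or at the last sample when the tail is monotone. The
#' baseline mean is subtracted. Ties in peak and minimum detection are
#' broken toward the earliest sample.
#'
#' @param curve A [signal_curve()] with a valid `baseline_window`.
#' @param onset_k Onset threshold in baseline SDs above the baseline mean
#'   (default 5).
#' @param detect_width Odd moving-average width of the smoothed copy on
#'   which the peak and the post-peak minimum are located, so that
#'   single-sample noise dips do not truncate the window (1 = detect on the
#'   raw curve; the returned values are always the raw ones).
#' @return A baseline-subtracted [signal_curve()] restricted to the
#'   first-pass window, with attribute `onset_index` (index in the input).
#' @export
extract_first_pass <- function(curve, onset_k = 5, detect_width = 5) {
  stopifnot(inherits(curve, "signal_curve"))
  bs <- baseline_stats(curve)
  # absolute fallback keeps noiseless curves (baseline SD = 0) detectable
  thr <- bs$mean + max(onset_k * bs$sd,
                       1e-6 * max(abs(curve$values - bs$mean)))
  above <- which(curve$values > thr)
  if (length(above) == 0 || diff(range(curve$values)) == 0)
    stop("no first pass detected: curve never exceeds the onset threshold")
  # the threshold crossing confirms a bolus; the arrival itself is refined
  # by walking back along a smoothed copy to where the curve leaves the
  # baseline band, so a high crossing (noisy baseline) does not date the
  # onset late
  w <- min(detect_width, length(curve$values))
  if (w %% 2 == 0) w <- w - 1L
  vs <- moving_average(curve$values - bs$mean, w)
  onset <- above[1]
  while (onset > 1 && vs[onset - 1] > bs$sd) onset <- onset - 1
  v <- curve$values[onset:length(curve$values)] - bs$mean
  vd <- vs[onset:length(vs)]
  peak <- which.max(vd)
  end <- length(v)
  if (peak < length(v) - 1) {
    for (i in (peak + 1):(length(v) - 1)) {
      if (vd[i] <= vd[i - 1] && vd[i] < vd[i + 1]) { end <- i; break }
    }
  }
  end <- max(end, min(8L, length(v)))
  out <- signal_curve(curve$times[onset:(onset + end - 1)], v[seq_len(end)],
                      baseline_window = 1L)
  attr(out, "onset_index") <- onset
  out
}

#' Smooth and temporally register an AIF/tissue curve pair
#'
#' Applies centred moving-average smoothing of odd width to both first-pass
#' curves (edges use the shrinking window that fits), then registers the
#' tissue curve to the AIF by an integer-sample shift that aligns the two
#' bolus onsets, and truncates both to a common grid starting at 0.
#'
#' @param aif,tissue First-pass extracted [signal_curve()]s on the same
#'   sampling interval.
#' @param smooth_width Odd moving-average width in samples; 1 = identity.
#' @return A list with `aif`, `tissue` (identical time grids) and
#'   `shift_samples`, the integer registration shift applied to the tissue
#'   curve.
#' @export
preprocess_pair <- function(aif, tissue, smooth_width = 3) {
  stopifnot(inherits(aif, "signal_curve"), inherits(tissue, "signal_curve"))
  if (abs(aif$dt - tissue$dt) > 1e-9 * aif$dt)
    stop("AIF and tissue curves have different sampling intervals")
  if (smooth_width %% 2 != 1)
    stop("`smooth_width` must be odd")
  if (smooth_width > min(length(aif), length(tissue)))
    stop("`smooth_width` exceeds the curve length")
  half <- (smooth_width - 1L) %/% 2L
  # keep the smoother's backward leak: a centred window moves post-onset
  # signal `half` samples before the onset, and the causal convolution in
  # the deconvolution model can only reproduce it if those samples are part
  # of the fitted grid, so both curves keep `half` leading baseline zeros
  av <- moving_average(c(rep(0, half), aif$values), smooth_width)
  tv <- moving_average(c(rep(0, half), tissue$values), smooth_width)
  # first-pass extraction put each curve's onset at its first sample, so the
  # residual shift is the difference of the window start times
  shift <- as.integer(round((tissue$times[1] - aif$times[1]) / aif$dt))
  n <- min(length(av), length(tv))
  grid <- (seq_len(n) - 1) * aif$dt
  list(aif = signal_curve(grid, av[seq_len(n)], baseline_window = 1L),
       tissue = signal_curve(grid, tv[seq_len(n)], baseline_window = 1L),
       shift_samples = shift)
}

# centred moving average; the window start is zero-padded (baseline-
# subtracted first-pass curves vanish before onset, and padding any other
# way biases the convolution model at the onset edge), the end replicated
moving_average <- function(x, width) {
  if (width == 1) return(x)
  half <- (width - 1) %/% 2
  n <- length(x)
  xp <- c(rep(0, half), x, rep(x[n], half))
  vapply(seq_len(n), function(i) mean(xp[i:(i + width - 1)]), numeric(1))
}

#' Rescale a low-bolus AIF to the main-bolus concentration scale
#'
#' @param aif_low A [signal_curve()] measured from the dilute pre-bolus.
#' @param scaling_factor Concentration ratio of the two boluses (> 0).
#' @return The AIF with values multiplied by `scaling_factor`.
#' @export
scale_aif <- function(aif_low, scaling_factor) {
  stopifnot(inherits(aif_low, "signal_curve"))
  if (scaling_factor <= 0) stop("`scaling_factor` must be > 0")
  signal_curve(aif_low$times, aif_low$values * scaling_factor,
               baseline_window = aif_low$baseline_window)
}

fermi_model_curve <- function(aif_values, dt, A, mu, k) {
  n <- length(aif_values)
  r <- fermi_response((seq_len(n) - 1) * dt, A, mu, k)
  dt * discrete_convolve(aif_values, r)
}

#' Fit the Fermi deconvolution model
#'
#' Estimates the Fermi impulse-response parameters (A, mu, k) by damped
#' (Levenberg-Marquardt) nonlinear least squares, minimising
#' `sum_t [tissue(t) - dt * (aif (*) R)(t)]^2` where `(*)` is the causal
#' discrete convolution on the common grid.
#'
#' @param aif_scaled,tissue Preprocessed [signal_curve()]s on identical
#'   grids (see [preprocess_pair()] and [scale_aif()]).
#' @param init Optional named list/vector with starting values `A`, `mu`,
#'   `k`. Defaults: `A = peak(tissue)/integral(aif)`, `mu = 0.25 * T`,
#'   `k = 0.1 * T` with `T` the window length.
#' @param bounds Named list with `lower` and `upper` length-3 vectors
#'   (A, mu, k). Defaults: `A >= 0`, `0 <= mu <= T`, `k >= k_min = dt/10`.
#' @param max_iter Maximum Levenberg-Marquardt iterations.
#' @return An object of class `fermi_fit`: list with `A`, `mu`, `k`, `rss`,
#'   `n_iterations`, `converged` (relative parameter change < 1e-8 or
#'   gradient criterion met) and the grid spacing `dt`.
#' @export
fit_fermi_deconvolution <- function(aif_scaled, tissue, init = NULL,
                                    bounds = NULL, max_iter = 200) {
  stopifnot(inherits(aif_scaled, "signal_curve"),
            inherits(tissue, "signal_curve"))
  if (length(aif_scaled) != length(tissue) ||
      any(abs(aif_scaled$times - tissue$times) > 1e-9 * aif_scaled$dt))
    stop("AIF and tissue curves must share an identical time grid")
  dt <- aif_scaled$dt
  Tlen <- diff(range(tissue$times)) + dt
  a <- aif_scaled$values
  y <- tissue$values
  if (is.null(init)) {
    integ <- sum(a) * dt
    init <- c(A = if (integ > 0) max(y) / integ else 1,
              mu = 0.25 * Tlen, k = 0.1 * Tlen)
  } else {
    init <- c(A = init[["A"]], mu = init[["mu"]], k = init[["k"]])
  }
  if (is.null(bounds))
    bounds <- list(lower = c(0, 0, dt / 10), upper = c(Inf, Tlen, Inf))
  init <- pmin(pmax(init, bounds$lower), bounds$upper)
  resid_fn <- function(p) y - fermi_model_curve(a, dt, p[1], p[2], p[3])
  fit <- minpack.lm::nls.lm(
    par = init, lower = bounds$lower, upper = bounds$upper, fn = resid_fn,
    control = minpack.lm::nls.lm.control(
      maxiter = max_iter, ptol = 1e-8, gtol = 1e-10, ftol = 0))
  converged <- fit$info %in% 1:4
  if (!converged)
    warning("Fermi deconvolution did not converge after ", max_iter,
            " iterations (", fit$message, ")")
  structure(list(A = unname(fit$par[1]), mu = unname(fit$par[2]),
                 k = unname(fit$par[3]), rss = fit$deviance,
                 n_iterations = fit$niter, converged = converged, dt = dt),
            class = "fermi_fit")
}

#' Myocardial blood flow from a Fermi fit
#'
#' MBF is the initial value of the estimated tissue impulse response,
#' `unit_conversion * R(0) = unit_conversion * A / (exp(-mu/k) + 1)`.
#'
#' @param fit A `fermi_fit` from [fit_fermi_deconvolution()].
#' @param unit_conversion Signal-unit to mL/g/min conversion constant
#'   (default 1: one impulse-response signal unit per mL/g/min).
#' @param state `"rest"` or `"stress"`.
#' @param allow_unconverged Set `TRUE` to accept a non-converged fit.
#' @return An object of class `mbf_result`: list with `mbf`, `fit`, `state`.
#' @export
mbf_from_fit <- function(fit, unit_conversion = 1, state = "rest",
                         allow_unconverged = FALSE) {
  stopifnot(inherits(fit, "fermi_fit"))
  if (!fit$converged && !allow_unconverged)
    stop("fit did not converge; pass `allow_unconverged = TRUE` to override")
  state <- match.arg(state, c("rest", "stress"))
  mbf <- unit_conversion * fermi_response(0, fit$A, fit$mu, fit$k)
  structure(list(mbf = mbf, fit = fit, state = state), class = "mbf_result")
}

#' Myocardial perfusion reserve
#'
#' @param stress,rest `mbf_result` objects for the two states.
#' @return An object of class `mpr_result`: `mpr = stress$mbf / rest$mbf`
#'   plus both inputs.
#' @export
compute_mpr <- function(stress, rest) {
  stopifnot(inherits(stress, "mbf_result"), inherits(rest, "mbf_result"))
  if (rest$mbf <= 0)
    stop("MPR undefined: rest MBF is zero")
  structure(list(mpr = stress$mbf / rest$mbf, rest = rest, stress = stress),
            class = "mpr_result")
}

#' Quantify a dual-bolus perfusion study
#'
#' Full single-study chain: first-pass extraction of the low-bolus AIF and
#' both tissue curves, smoothing and temporal registration, AIF rescaling by
#' the bolus concentration ratio, Fermi-constrained deconvolution per state,
#' MBF from the impulse-response initial value, and the stress/rest MPR.
#'
#' @param study A `perfusion_study` (see [synth_perfusion_study()] or
#'   [read_perfusion_study()]).
#' @param smooth_width Moving-average width (odd, samples).
#' @param onset_k Onset threshold in baseline SDs.
#' @param unit_conversion Signal-to-mL/g/min constant.
#' @param allow_unconverged Accept non-converged fits (with their warning).
#' @return An `mpr_result`.
#' @export
quantify_perfusion <- function(study, smooth_width = 3, onset_k = 5,
                               unit_conversion = 1,
                               allow_unconverged = TRUE) {
  stopifnot(inherits(study, "perfusion_study"))
  aif_fp <- extract_first_pass(study$aif_low_bolus, onset_k = onset_k)
  fit_state <- function(tissue, state) {
    t_fp <- extract_first_pass(tissue, onset_k = onset_k)
    pair <- preprocess_pair(aif_fp, t_fp, smooth_width = smooth_width)
    aif_scaled <- scale_aif(pair$aif, study$scaling_factor)
    fit <- fit_fermi_deconvolution(aif_scaled, pair$tissue)
    mbf_from_fit(fit, unit_conversion = unit_conversion, state = state,
                 allow_unconverged = allow_unconverged)
  }
  compute_mpr(fit_state(study$tissue_high_bolus_stress, "stress"),
              fit_state(study$tissue_high_bolus_rest, "rest"))
}
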