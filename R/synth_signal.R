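#' Parameters of a synthetic arterial input function
#'
#' A peak-normalised gamma-variate is used as the parametric family for
#' synthetic first-pass bolus curves: `amplitude` is exactly the height of
#' the peak above baseline, which makes the parameters directly
#' interpretable when constructing dual-bolus studies.
#'
#' @param onset_time Bolus arrival time (s).
#' @param amplitude Peak height above baseline (signal units, >= 0).
#' @param shape_alpha Gamma-variate shape (> 0, dimensionless).
#' @param scale_beta Gamma-variate time scale (s, > 0).
#' @param baseline Pre-contrast signal level (>= 0).
#' @return A list of class `aif_params`.
#' @export
aif_params <- function(onset_time = 10, amplitude = 1, shape_alpha = 3,
                       scale_beta = 2, baseline = 0) {
  stopifnot(onset_time >= 0, amplitude >= 0, shape_alpha > 0,
            scale_beta > 0, baseline >= 0)
  structure(list(onset_time = onset_time, amplitude = amplitude,
                 shape_alpha = shape_alpha, scale_beta = scale_beta,
                 baseline = baseline),
            class = "aif_params")
}

#' Generate a gamma-variate bolus curve
#'
#' Evaluates a peak-normalised gamma-variate on a uniform time grid:
#' the curve equals `baseline` before `onset_time` and
#' `baseline + amplitude * ((t - onset)/(alpha*beta))^alpha *
#' exp(alpha - (t - onset)/beta)` afterwards, so its single interior maximum
#' is `baseline + amplitude`, attained at `onset + alpha*beta`.
#'
#' @param params An [aif_params()] object.
#' @param time_grid Uniformly spaced sample times (s) covering the onset.
#' @return A [signal_curve()] whose baseline window is the pre-onset region.
#' @export
gamma_variate_aif <- function(params, time_grid) {
  stopifnot(inherits(params, "aif_params"))
  time_grid <- as.numeric(time_grid)
  dts <- diff(time_grid)
  if (any(dts <= 0) || any(abs(dts - dts[1]) > 1e-9 * abs(dts[1])))
    stop("`time_grid` must be uniformly spaced and increasing; ",
         "resample the acquisition times before generating curves")
  if (max(time_grid) <= params$onset_time)
    stop("`time_grid` must extend beyond the bolus onset time")
  s <- time_grid - params$onset_time
  v <- rep(params$baseline, length(time_grid))
  pos <- s > 0
  x <- s[pos] / (params$shape_alpha * params$scale_beta)
  v[pos] <- params$baseline + params$amplitude *
    x^params$shape_alpha *
    exp(params$shape_alpha - s[pos] / params$scale_beta)
  bw <- which(time_grid < params$onset_time)
  if (length(bw) == 0) bw <- 1L
  signal_curve(time_grid, v, baseline_window = bw)
}

#' Ground-truth tissue generation parameters
#'
#' @param true_mbf True myocardial blood flow (mL/g/min, > 0 or 0 for the
#'   null-flow case). With the default unit convention 1 signal unit of the
#'   impulse response corresponds to 1 mL/g/min.
#' @param fermi_mu Fermi shoulder position (s, >= 0).
#' @param fermi_k Fermi decay width (s, > 0).
#' @param noise_sd Standard deviation of additive i.i.d. Gaussian noise on
#'   the tissue curve (signal units, >= 0).
#' @return A list of class `tissue_gen_params`.
#' @export
tissue_gen_params <- function(true_mbf = 1, fermi_mu = 5, fermi_k = 1.5,
                              noise_sd = 0) {
  stopifnot(true_mbf >= 0, fermi_mu >= 0, noise_sd >= 0)
  if (fermi_k <= 0) stop("`fermi_k` must be > 0")
  structure(list(true_mbf = true_mbf, fermi_mu = fermi_mu,
                 fermi_k = fermi_k, noise_sd = noise_sd),
            class = "tissue_gen_params")
}

#' Simulate a tissue response curve from an AIF
#'
#' Forward model of contrast kinetics: the tissue curve is the discrete
#' convolution of the baseline-subtracted AIF with a Fermi impulse response
#' `R(t) = A / (exp((t - mu)/k) + 1)` scaled so that `R(0)` equals the true
#' myocardial blood flow, i.e. `tissue(t_i) = dt * sum_j aif(t_j) R(t_i -
#' t_j)`, plus optional i.i.d. Gaussian noise.
#'
#' @param aif A [signal_curve()] (its baseline window mean is subtracted).
#' @param gen A [tissue_gen_params()] object.
#' @param seed Integer seed; the output is deterministic given the seed.
#' @return A [signal_curve()] on the same grid with zero pre-bolus baseline.
#' @export
synth_tissue_curve <- function(aif, gen, seed = 1L) {
  stopifnot(inherits(aif, "signal_curve"), inherits(gen, "tissue_gen_params"))
  a <- aif$values - baseline_stats(aif)$mean
  n <- length(a)
  # R(0) = A / (exp(-mu/k) + 1) = true_mbf fixes the Fermi amplitude
  A <- gen$true_mbf * (exp(-gen$fermi_mu / gen$fermi_k) + 1)
  r <- fermi_response((seq_len(n) - 1) * aif$dt, A, gen$fermi_mu, gen$fermi_k)
  v <- aif$dt * discrete_convolve(a, r)
  if (gen$noise_sd > 0) {
    set.seed(seed)
    v <- v + stats::rnorm(n, 0, gen$noise_sd)
  }
  signal_curve(aif$times, v, baseline_window = aif$baseline_window)
}

# causal discrete convolution, first n samples of the full product
discrete_convolve <- function(x, r) {
  n <- length(x)
  stats::convolve(x, rev(r), type = "open")[seq_len(n)]
}

#' Simulate a dual-bolus perfusion study
#'
#' Builds the three measured curves of a dual-bolus acquisition for one
#' perfusion state pair: the dilute pre-bolus AIF (amplitude reduced by
#' `scaling_factor`, as in the pre-bolus/main-bolus concentration ratio) and
#' the rest and stress tissue responses driven by the full-strength AIF.
#'
#' @param rest,stress [tissue_gen_params()] for the two states.
#' @param aif An [aif_params()] object describing the full-strength bolus.
#' @param time_grid Uniform sample times (s).
#' @param scaling_factor Main-bolus to pre-bolus concentration ratio (> 0);
#'   defaults to the protocol value [dose_scaling_factor()] = 10.
#' @param seed Integer seed (rest uses `seed`, stress `seed + 1`).
#' @return A list of class `perfusion_study` with elements `aif_low_bolus`,
#'   `tissue_high_bolus_rest`, `tissue_high_bolus_stress`, `scaling_factor`.
#' @export
synth_perfusion_study <- function(rest, stress, aif,
                                  time_grid = seq(0, 60, by = 1),
                                  scaling_factor = dose_scaling_factor(),
                                  seed = 1L) {
  stopifnot(inherits(rest, "tissue_gen_params"),
            inherits(stress, "tissue_gen_params"),
            inherits(aif, "aif_params"))
  if (scaling_factor <= 0) stop("`scaling_factor` must be > 0")
  aif_full <- gamma_variate_aif(aif, time_grid)
  low <- aif
  low$amplitude <- aif$amplitude / scaling_factor
  aif_low <- gamma_variate_aif(low, time_grid)
  structure(
    list(aif_low_bolus = aif_low,
         tissue_high_bolus_rest = synth_tissue_curve(aif_full, rest, seed),
         tissue_high_bolus_stress = synth_tissue_curve(aif_full, stress,
                                                       seed + 1L),
         scaling_factor = scaling_factor),
    class = "perfusion_study"
  )
}
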