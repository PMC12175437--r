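#' T1 mapping panel
#'
#' Scalar T1 relaxation times (ms) of septal myocardium and left-ventricular
#' blood pool, native and ~15 min post contrast, together with the
#' hematocrit drawn within 24 h of the scan. Contrast shortens T1, so
#' post-contrast values may not exceed the native ones.
#'
#' @param t1_myo_native,t1_myo_post Myocardial T1 (ms).
#' @param t1_blood_native,t1_blood_post Blood-pool T1 (ms).
#' @param hct Hematocrit as a fraction in (0, 1).
#' @return A list of class `t1_panel`.
#' @export
t1_panel <- function(t1_myo_native, t1_myo_post, t1_blood_native,
                     t1_blood_post, hct) {
  vals <- c(t1_myo_native, t1_myo_post, t1_blood_native, t1_blood_post)
  if (any(vals <= 0)) stop("all T1 values must be positive")
  if (hct <= 0 || hct >= 1) stop("`hct` must lie strictly in (0, 1)")
  if (t1_myo_post > t1_myo_native)
    stop("post-contrast myocardial T1 exceeds native T1")
  if (t1_blood_post > t1_blood_native)
    stop("post-contrast blood T1 exceeds native T1")
  structure(list(t1_myo_native = t1_myo_native, t1_myo_post = t1_myo_post,
                 t1_blood_native = t1_blood_native,
                 t1_blood_post = t1_blood_post, hct = hct),
            class = "t1_panel")
}

#' Extracellular volume fraction from T1 and hematocrit
#'
#' `ECV = (1 - HCT) * (1/T1_myo_post - 1/T1_myo_native) /
#' (1/T1_blood_post - 1/T1_blood_native)`. The relaxation-rate change in
#' myocardium is referenced to that in blood, whose plasma fraction
#' `(1 - HCT)` anchors the contrast distribution volume.
#'
#' @param panel A [t1_panel()].
#' @param plausibility_range Warn (not error) when the result falls outside
#'   this physiologic range, given as a fraction. Set to `NULL` to disable.
#' @return ECV as a fraction in `[0, ...)`; multiply by 100 for percent.
#' @examples
#' compute_ecv(t1_panel(1200, 500, 1800, 350, hct = 0.42))
#' @export
compute_ecv <- function(panel, plausibility_range = c(0.15, 0.60)) {
  stopifnot(inherits(panel, "t1_panel"))
  denom <- 1 / panel$t1_blood_post - 1 / panel$t1_blood_native
  if (denom <= 0)
    stop("no blood contrast effect: post-contrast blood R1 does not exceed native R1")
  num <- 1 / panel$t1_myo_post - 1 / panel$t1_myo_native
  ecv <- (1 - panel$hct) * num / denom
  if (!is.null(plausibility_range) &&
      (ecv < plausibility_range[1] || ecv > plausibility_range[2]))
    warning(sprintf("ECV %.1f%% outside the physiologic range %.0f-%.0f%%",
                    100 * ecv, 100 * plausibility_range[1],
                    100 * plausibility_range[2]))
  ecv
}

#' Synthesise a T1 panel with a prescribed ECV
#'
#' Inverts the ECV relation for the post-contrast myocardial T1: given the
#' target ECV, hematocrit and the three anchor T1s, solves
#' `1/T1_myo_post = 1/T1_myo_native + ECV/(1-HCT) * (1/T1_blood_post -
#' 1/T1_blood_native)` so that [compute_ecv()] on the returned panel equals
#' `target_ecv` exactly (before optional noise).
#'
#' @param target_ecv Target ECV as a fraction in `[0, 1)`.
#' @param hct Hematocrit fraction in (0, 1).
#' @param anchors Named list with `t1_myo_native`, `t1_blood_native`,
#'   `t1_blood_post` in ms (physiologic 3T defaults).
#' @param noise_sd Optional Gaussian perturbation (ms) applied to the solved
#'   post-contrast myocardial T1; 0 keeps the inversion exact.
#' @param seed Integer seed used when `noise_sd > 0`.
#' @return A [t1_panel()].
#' @export
synth_t1_panel <- function(target_ecv, hct,
                           anchors = list(t1_myo_native = 1200,
                                          t1_blood_native = 1800,
                                          t1_blood_post = 350),
                           noise_sd = 0, seed = 1L) {
  if (target_ecv < 0 || target_ecv >= 1)
    stop("`target_ecv` must lie in [0, 1)")
  if (hct <= 0 || hct >= 1) stop("`hct` must lie strictly in (0, 1)")
  an <- anchors
  if (any(unlist(an) <= 0)) stop("anchor T1 values must be positive")
  r1_post <- 1 / an$t1_myo_native + target_ecv / (1 - hct) *
    (1 / an$t1_blood_post - 1 / an$t1_blood_native)
  if (r1_post <= 0)
    stop("target ECV and anchors imply a non-positive post-contrast T1")
  t1_myo_post <- 1 / r1_post
  if (noise_sd > 0) {
    set.seed(seed)
    t1_myo_post <- max(1, t1_myo_post + stats::rnorm(1, 0, noise_sd))
  }
  t1_panel(an$t1_myo_native, t1_myo_post, an$t1_blood_native,
           an$t1_blood_post, hct)
}

#' Compute ECV for a table of panels
#'
#' @param panels Data frame with the [t1_panel()] fields as columns
#'   (`t1_myo_native`, `t1_myo_post`, `t1_blood_native`, `t1_blood_post`,
#'   `hct`).
#' @return The input with columns `ecv` (fraction) and `ecv_pct` appended.
#' @export
compute_ecv_table <- function(panels) {
  need <- c("t1_myo_native", "t1_myo_post", "t1_blood_native",
            "t1_blood_post", "hct")
  if (!all(need %in% names(panels)))
    stop("panel table missing columns: ",
         paste(setdiff(need, names(panels)), collapse = ", "))
  panels$ecv <- vapply(seq_len(nrow(panels)), function(i) {
    compute_ecv(t1_panel(panels$t1_myo_native[i], panels$t1_myo_post[i],
                         panels$t1_blood_native[i], panels$t1_blood_post[i],
                         panels$hct[i]))
  }, numeric(1))
  panels$ecv_pct <- 100 * panels$ecv
  panels
}
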