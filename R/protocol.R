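#' Dual-bolus contrast dosing schedule
#'
#' The dual-bolus stress/rest perfusion protocol administers, per state
#' (stress and rest), a dilute pre-bolus of 0.00375 mmol/kg gadolinium (to
#' sample the arterial input function without signal saturation) followed by
#' a main bolus of 0.0375 mmol/kg (for tissue enhancement). After both
#' perfusion states a final top-up bolus of 0.0675 mmol/kg brings the total
#' to the full clinical dose used for post-contrast T1 mapping.
#'
#' @return A list with the per-injection doses in mmol/kg (`pre_bolus`,
#'   `main_bolus`, `top_up`) and `n_states` (stress and rest).
#' @examples
#' d <- dual_bolus_doses()
#' total_contrast_dose(d)   # 0.15 mmol/kg
#' dose_scaling_factor(d)   # 10
#' @export
dual_bolus_doses <- function() {
  list(pre_bolus = 0.00375, main_bolus = 0.0375, top_up = 0.0675,
       n_states = 2L)
}

#' @rdname dual_bolus_doses
#' @param doses A dosing schedule as returned by [dual_bolus_doses()].
#' @return `total_contrast_dose()`: the summed dose in mmol/kg.
#' @export
total_contrast_dose <- function(doses = dual_bolus_doses()) {
  doses$n_states * (doses$pre_bolus + doses$main_bolus) + doses$top_up
}

#' @rdname dual_bolus_doses
#' @return `dose_scaling_factor()`: the main-bolus to pre-bolus concentration
#'   ratio used to rescale the low-bolus AIF onto the high-bolus scale.
#' @export
dose_scaling_factor <- function(doses = dual_bolus_doses()) {
  doses$main_bolus / doses$pre_bolus
}
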