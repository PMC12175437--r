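#' Left atrial trajectory
#'
#' Per-frame LA geometry from 2- and 4-chamber cine views over one cardiac
#' cycle: long-axis lengths (mm), optionally areas (mm^2) for biplane
#' volumetry, the reference frame (LV end-diastole, where strain is zero)
#' and the pre-atrial-contraction frame. Frames are stored 1-based in R;
#' trajectory files on disk use 0-based frame numbers (see
#' [read_la_trajectory()]).
#'
#' @param lengths_2ch,lengths_4ch LA long-axis length per frame (mm, > 0).
#' @param areas_2ch,areas_4ch LA area per frame (mm^2), optional unless
#'   volumes are requested.
#' @param ref_frame 1-based index of LV end-diastole.
#' @param pre_a_frame 1-based index of the pre-atrial-contraction frame.
#' @param frame_times Optional frame times (s); defaults to frame index.
#' @return A list of class `la_trajectory`.
#' @export
la_trajectory <- function(lengths_2ch, lengths_4ch, ref_frame, pre_a_frame,
                          areas_2ch = NULL, areas_4ch = NULL,
                          frame_times = NULL) {
  n <- length(lengths_2ch)
  if (length(lengths_4ch) != n)
    stop("2- and 4-chamber views must have the same frame count")
  if (any(lengths_2ch <= 0) || any(lengths_4ch <= 0))
    stop("LA lengths must be positive")
  for (a in list(areas_2ch, areas_4ch))
    if (!is.null(a) && length(a) != n)
      stop("areas must have one value per frame")
  if (ref_frame < 1 || ref_frame > n || pre_a_frame < 1 || pre_a_frame > n)
    stop("`ref_frame` and `pre_a_frame` must be valid frame indices")
  if (is.null(frame_times)) frame_times <- seq_len(n)
  structure(list(frame_times = frame_times,
                 lengths_2ch = lengths_2ch, lengths_4ch = lengths_4ch,
                 areas_2ch = areas_2ch, areas_4ch = areas_4ch,
                 ref_frame = as.integer(ref_frame),
                 pre_a_frame = as.integer(pre_a_frame)),
            class = "la_trajectory")
}

#' Biplane area-length volume
#'
#' `V = 8/(3*pi) * A_2ch * A_4ch / L`, the standard biplane area-length
#' estimate from two orthogonal long-axis views, converted mm^3 -> mL.
#'
#' @param area_2ch,area_4ch LA areas (mm^2, >= 0).
#' @param length LA long-axis length (mm, > 0).
#' @return Volume in mL. A zero area yields 0 mL with a warning.
#' @examples
#' biplane_volume(1500, 1600, 50)  # ~40.7 mL
#' @export
biplane_volume <- function(area_2ch, area_4ch, length) {
  if (any(area_2ch < 0) || any(area_4ch < 0) || any(length <= 0))
    stop("areas must be >= 0 and length > 0")
  if (any(area_2ch == 0) || any(area_4ch == 0))
    warning("zero LA area: volume is 0 (degenerate contour)")
  (8 / (3 * pi)) * area_2ch * area_4ch / length / 1000
}

#' Per-frame LA volume curve and extrema
#'
#' Computes the biplane volume for every frame, with the length taken as the
#' mean of the two view lengths, and returns the minimum and maximum over
#' the cycle.
#'
#' @param traj An [la_trajectory()] with areas for both views.
#' @return A list of class `la_volumes`: `min_volume`, `max_volume` (mL) and
#'   the full `volume_curve`.
#' @export
la_volume_extrema <- function(traj) {
  stopifnot(inherits(traj, "la_trajectory"))
  if (is.null(traj$areas_2ch) || is.null(traj$areas_4ch))
    stop("per-frame areas for both views are required for volumetry")
  len <- (traj$lengths_2ch + traj$lengths_4ch) / 2
  vol <- biplane_volume(traj$areas_2ch, traj$areas_4ch, len)
  structure(list(min_volume = min(vol), max_volume = max(vol),
                 volume_curve = vol),
            class = "la_volumes")
}

#' Lagrangian length-strain curve
#'
#' `strain(t) = 100 * (L(t) - L_ref) / L_ref` with `L_ref` the length at the
#' reference frame (LV end-diastole), so the curve is zero there and
#' unit-free.
#'
#' @param lengths Per-frame LA lengths (> 0, any consistent unit).
#' @param ref_frame 1-based reference frame index.
#' @return Strain in percent, one value per frame.
#' @export
strain_curve <- function(lengths, ref_frame) {
  if (any(lengths <= 0)) stop("lengths must be positive")
  if (ref_frame < 1 || ref_frame > length(lengths))
    stop("`ref_frame` out of range")
  100 * (lengths - lengths[ref_frame]) / lengths[ref_frame]
}

#' Phasic decomposition of an LA strain curve
#'
#' Standard feature-tracking convention with the LV end-diastolic reference:
#' reservoir strain is the curve maximum (total atrial expansion during
#' ventricular systole), booster strain is the value at the
#' pre-atrial-contraction frame (active emptying), and conduit strain is
#' their difference (passive early-diastolic emptying), so that
#' `reservoir = conduit + booster` by construction.
#'
#' @param curve Strain curve in percent (from [strain_curve()]).
#' @param pre_a_frame 1-based pre-atrial-contraction frame index.
#' @return A list of class `phasic_strains`: `reservoir`, `conduit`,
#'   `booster` (percent).
#' @export
phasic_strains <- function(curve, pre_a_frame) {
  if (pre_a_frame < 1 || pre_a_frame > length(curve))
    stop("`pre_a_frame` out of range")
  peak <- which.max(curve)
  if (pre_a_frame < peak)
    warning("pre-atrial-contraction frame precedes the strain peak: ",
            "physiologically inverted timing")
  reservoir <- curve[peak]
  booster <- curve[pre_a_frame]
  structure(list(reservoir = reservoir, conduit = reservoir - booster,
                 booster = booster),
            class = "phasic_strains")
}

#' Analyse one LA trajectory
#'
#' Per-view strain curves and phasic strains (averaged across the 2- and
#' 4-chamber views) plus biplane volume extrema.
#'
#' @param traj An [la_trajectory()].
#' @return A list with `strains` (a `phasic_strains`, view-averaged),
#'   `per_view` strains, and `volumes` (an `la_volumes`, or `NULL` when
#'   areas are absent).
#' @export
analyze_la_trajectory <- function(traj) {
  stopifnot(inherits(traj, "la_trajectory"))
  per_view <- lapply(list(`2ch` = traj$lengths_2ch, `4ch` = traj$lengths_4ch),
                     function(L) {
                       phasic_strains(strain_curve(L, traj$ref_frame),
                                      traj$pre_a_frame)
                     })
  avg <- lapply(c("reservoir", "conduit", "booster"), function(ph)
    mean(vapply(per_view, `[[`, numeric(1), ph)))
  names(avg) <- c("reservoir", "conduit", "booster")
  volumes <- if (!is.null(traj$areas_2ch) && !is.null(traj$areas_4ch))
    la_volume_extrema(traj) else NULL
  list(strains = structure(avg, class = "phasic_strains"),
       per_view = per_view, volumes = volumes)
}

#' Average measurements across views and visits
#'
#' Subject-level aggregation: arithmetic mean across available views within
#' a visit, then across visits. Missing entries (`NA`) are skipped; their
#' count is reported.
#'
#' @param x A numeric matrix or data frame, visits in rows and views in
#'   columns (or any per-visit collection of per-view values).
#' @return A list with `value` (the subject-level mean), `n_missing`, and
#'   `n_used`.
#' @export
average_views_and_visits <- function(x) {
  m <- as.matrix(x)
  n_missing <- sum(is.na(m))
  if (all(is.na(m)))
    stop("all entries missing: nothing to average")
  visit_means <- rowMeans(m, na.rm = TRUE)
  visit_means <- visit_means[!is.nan(visit_means)]
  list(value = mean(visit_means), n_missing = n_missing,
       n_used = sum(!is.na(m)))
}

#' Synthesise an LA length/area trajectory with prescribed phasic strains
#'
#' Builds a smooth periodic length curve over one cardiac cycle: starting at
#' `ref_length` at LV end-diastole (frame 1), rising with cosine easing to
#' the reservoir peak `ref_length * (1 + reservoir_pct/100)` at end-systole,
#' falling to `ref_length * (1 + booster_pct/100)` at the
#' pre-atrial-contraction frame, and returning to `ref_length` at the cycle
#' end. Cosine segments are monotone between control points, so the curve
#' maximum is exactly the reservoir point and [phasic_strains()] recovers
#' the prescribed values. Areas scale with length squared so volumes land in
#' a physiologic LA range.
#'
#' @param reservoir_pct,booster_pct Target strains in percent,
#'   `0 <= booster <= reservoir`.
#' @param n_frames Frames per cycle (>= 8).
#' @param ref_length LA length at LV end-diastole (mm).
#' @param peak_frac,pre_a_frac Cycle fractions of the reservoir peak and the
#'   pre-A frame.
#' @param area_coef_2ch,area_coef_4ch Dimensionless area = coef * length^2
#'   coefficients for the two views.
#' @param noise_sd Gaussian length jitter (mm); 0 keeps recovery exact.
#' @param seed Integer seed used when `noise_sd > 0`.
#' @return An [la_trajectory()].
#' @export
synth_la_trajectory <- function(reservoir_pct, booster_pct, n_frames = 30,
                                ref_length = 55, peak_frac = 0.40,
                                pre_a_frac = 0.80, area_coef_2ch = 0.45,
                                area_coef_4ch = 0.50, noise_sd = 0,
                                seed = 1L) {
  if (booster_pct < 0 || booster_pct > reservoir_pct)
    stop("require 0 <= booster_pct <= reservoir_pct")
  if (n_frames < 8) stop("`n_frames` must be >= 8")
  f_peak <- max(2L, round(peak_frac * (n_frames - 1)) + 1L)
  f_pre_a <- min(n_frames - 1L, round(pre_a_frac * (n_frames - 1)) + 1L)
  if (f_pre_a <= f_peak) stop("pre-A frame must follow the reservoir peak")
  L0 <- ref_length
  Lmax <- ref_length * (1 + reservoir_pct / 100)
  Lpre <- ref_length * (1 + booster_pct / 100)
  ease <- function(from, to, m) {
    s <- seq(0, 1, length.out = m)
    from + (to - from) * (1 - cos(pi * s)) / 2
  }
  # segments share their junction frames; n_frames + 1 closes the cycle
  len <- c(ease(L0, Lmax, f_peak),
           ease(Lmax, Lpre, f_pre_a - f_peak + 1L)[-1],
           ease(Lpre, L0, n_frames + 1L - f_pre_a + 1L)[-1])
  len <- len[seq_len(n_frames)]
  if (noise_sd > 0) {
    set.seed(seed)
    len <- pmax(1, len + stats::rnorm(n_frames, 0, noise_sd))
  }
  len4 <- len * 1.05
  la_trajectory(lengths_2ch = len, lengths_4ch = len4,
                ref_frame = 1L, pre_a_frame = f_pre_a,
                areas_2ch = area_coef_2ch * len^2,
                areas_4ch = area_coef_4ch * len4^2)
}

#' Read or write an LA trajectory file
#'
#' Delimited text with columns `frame` (0-based), `length_2ch_mm`,
#' `length_4ch_mm` and optionally `area_2ch_mm2`, `area_4ch_mm2`. The
#' reference and pre-A frames are stored 0-based in the header-like columns
#' `ref_frame`, `pre_a_frame` (constant per file).
#'
#' @param path File path.
#' @param traj An [la_trajectory()].
#' @return `read_la_trajectory()` returns an [la_trajectory()];
#'   `write_la_trajectory()` returns `path` invisibly.
#' @export
read_la_trajectory <- function(path) {
  d <- utils::read.csv(path)
  need <- c("frame", "length_2ch_mm", "length_4ch_mm", "ref_frame",
            "pre_a_frame")
  if (!all(need %in% names(d)))
    stop("trajectory file missing columns: ",
         paste(setdiff(need, names(d)), collapse = ", "))
  d <- d[order(d$frame), ]
  la_trajectory(lengths_2ch = d$length_2ch_mm, lengths_4ch = d$length_4ch_mm,
                ref_frame = d$ref_frame[1] + 1L,
                pre_a_frame = d$pre_a_frame[1] + 1L,
                areas_2ch = if ("area_2ch_mm2" %in% names(d)) d$area_2ch_mm2,
                areas_4ch = if ("area_4ch_mm2" %in% names(d)) d$area_4ch_mm2)
}

#' @rdname read_la_trajectory
#' @export
write_la_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "la_trajectory"))
  n <- length(traj$lengths_2ch)
  d <- data.frame(frame = seq_len(n) - 1L,
                  length_2ch_mm = traj$lengths_2ch,
                  length_4ch_mm = traj$lengths_4ch,
                  ref_frame = traj$ref_frame - 1L,
                  pre_a_frame = traj$pre_a_frame - 1L)
  if (!is.null(traj$areas_2ch)) d$area_2ch_mm2 <- traj$areas_2ch
  if (!is.null(traj$areas_4ch)) d$area_4ch_mm2 <- traj$areas_4ch
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
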