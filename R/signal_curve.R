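#' Time-signal curve
#'
#' Container for a first-pass perfusion time-signal curve: the arterial input
#' function (AIF) sampled in the left-ventricular blood pool, or the total
#' tissue response sampled in myocardium. Times must be uniformly spaced and
#' strictly increasing; at least 8 samples are required so that a bolus
#' passage can actually be resolved.
#'
#' @param times Sample times in seconds, uniformly spaced.
#' @param values Signal intensities (arbitrary units), one per time.
#' @param baseline_window Integer indices of the samples used for baseline
#'   estimation (pre-contrast plateau). Defaults to the first 5 samples.
#' @return An object of class `signal_curve`: a list with elements `times`,
#'   `values`, `baseline_window` and the grid spacing `dt`.
#' @examples
#' sc <- signal_curve(seq(0, 30, by = 1), c(rep(0, 10), dgamma(1:21, 3, 0.5)))
#' @export
signal_curve <- function(times, values, baseline_window = NULL) {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values))
    stop("`times` and `values` must have the same length")
  if (length(times) < 8)
    stop("a signal curve needs at least 8 samples")
  dts <- diff(times)
  if (any(dts <= 0))
    stop("`times` must be strictly increasing")
  dt <- dts[1]
  if (any(abs(dts - dt) > 1e-9 * abs(dt)))
    stop("`times` must be uniformly spaced (relative tolerance 1e-9)")
  if (is.null(baseline_window))
    baseline_window <- seq_len(min(5L, length(times)))
  baseline_window <- as.integer(baseline_window)
  if (any(baseline_window < 1L) || any(baseline_window > length(times)))
    stop("`baseline_window` indices out of range")
  structure(
    list(times = times, values = values,
         baseline_window = baseline_window, dt = dt),
    class = "signal_curve"
  )
}

#' @export
print.signal_curve <- function(x, ...) {
  cat(sprintf("<signal_curve> %d samples, dt = %g s, range [%g, %g]\n",
              length(x$times), x$dt, min(x$values), max(x$values)))
  invisible(x)
}

#' @export
length.signal_curve <- function(x) length(x$times)

baseline_stats <- function(curve) {
  b <- curve$values[curve$baseline_window]
  list(mean = mean(b), sd = stats::sd(b))
}

#' Read or write a curve file
#'
#' Curve files are delimited text with header `time_s,value`, one curve per
#' file.
#'
#' @param path File path.
#' @param curve A `signal_curve`.
#' @param baseline_window Optional baseline index window to attach on read.
#' @return `read_curve()` returns a `signal_curve`; `write_curve()` returns
#'   `path` invisibly.
#' @export
read_curve <- function(path, baseline_window = NULL) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "value") %in% names(d)))
    stop("curve file must have columns `time_s` and `value`: ", path)
  signal_curve(d$time_s, d$value, baseline_window = baseline_window)
}

#' @rdname read_curve
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "signal_curve"))
  utils::write.csv(data.frame(time_s = curve$times, value = curve$values),
                   path, row.names = FALSE)
  invisible(path)
}
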