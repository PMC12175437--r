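#' Specification of one cohort group
#'
#' @param group_name One of `"obese_control"`, `"t2dm"`, `"hfpef_t2dm"`.
#' @param n Number of subjects (>= 2 for any group entering variance-based
#'   statistics).
#' @param variables Named list; each entry is a list with `distribution`
#'   (`"normal"`, `"lognormal"` or `"bernoulli"`), `location`, `scale`
#'   (mean/SD on the observed scale; for bernoulli `location` is the event
#'   probability) and optional `censor_low`/`censor_high` reportable-range
#'   limits.
#' @return A list of class `group_spec`.
#' @export
group_spec <- function(group_name, n, variables) {
  group_name <- match.arg(group_name,
                          c("obese_control", "t2dm", "hfpef_t2dm"))
  if (n < 2) stop("group size must be >= 2")
  for (nm in names(variables)) {
    v <- variables[[nm]]
    v$distribution <- match.arg(v$distribution,
                                c("normal", "lognormal", "bernoulli"))
    if (!is.null(v$censor_low) && !is.null(v$censor_high) &&
        v$censor_low >= v$censor_high)
      stop("censor_low must be < censor_high for variable ", nm)
    variables[[nm]] <- v
  }
  structure(list(group_name = group_name, n = as.integer(n),
                 variables = variables),
            class = "group_spec")
}

#' Test-retest replicate specification
#'
#' Replicates are generated as subject-level plus visit-level Gaussian
#' components: the within-subject variance implied by the target reliability
#' is `between_sd^2 * (1 - target_icc) / target_icc`, and `rater_shift` adds
#' a systematic day-8 offset so that the absolute-agreement ICC(2,1) is
#' penalised relative to a consistency ICC.
#'
#' @param target_icc Target ICC(2,1) in (0, 1].
#' @param between_sd Between-subject SD on the variable's scale; `NULL`
#'   inherits the group spec's `scale`.
#' @param rater_shift Systematic day-8 offset (variable units).
#' @return A list of class `retest_spec`.
#' @export
retest_spec <- function(target_icc, between_sd = NULL, rater_shift = 0) {
  if (target_icc <= 0 || target_icc > 1)
    stop("`target_icc` must lie in (0, 1]")
  structure(list(target_icc = target_icc, between_sd = between_sd,
                 rater_shift = rater_shift),
            class = "retest_spec")
}

# moment-matched log-normal: mean m, sd s on the observed scale
lognormal_pars <- function(m, s) {
  sigma2 <- log(1 + (s / m)^2)
  list(meanlog = log(m) - sigma2 / 2, sdlog = sqrt(sigma2))
}

# truncation-resampling: redraw out-of-range values so the reportable range
# is respected without creating boundary atoms
draw_censored <- function(n, rfun, lo, hi, max_rounds = 1000) {
  x <- rfun(n)
  if (is.null(lo)) lo <- -Inf
  if (is.null(hi)) hi <- Inf
  for (i in seq_len(max_rounds)) {
    bad <- which(x < lo | x > hi)
    if (length(bad) == 0) return(x)
    x[bad] <- rfun(length(bad))
  }
  stop("could not sample within the reportable range after ", max_rounds,
       " rounds; check the censoring limits against the distribution")
}

draw_variable <- function(n, v) {
  rfun <- switch(v$distribution,
    normal = function(m) stats::rnorm(m, v$location, v$scale),
    lognormal = {
      lp <- lognormal_pars(v$location, v$scale)
      function(m) stats::rlnorm(m, lp$meanlog, lp$sdlog)
    },
    bernoulli = function(m) stats::rbinom(m, 1, v$location)
  )
  draw_censored(n, rfun, v$censor_low, v$censor_high)
}

#' Generate a group-structured cohort table
#'
#' Samples one record per subject and visit from the per-group variable
#' specifications. Variables named in `retest` get day-1 and day-8
#' replicates: a subject-level latent value drawn from the group
#' distribution plus independent visit-level noise whose variance is implied
#' by the target ICC (see [retest_spec()]); all other variables are constant
#' across visits. Biomarker values are kept inside their reportable ranges
#' by truncation-resampling.
#'
#' @param specs List of [group_spec()]s (same variable set in each).
#' @param retest Named list mapping variable name -> [retest_spec()]. Empty
#'   means a single visit per subject.
#' @param seed Integer seed; output is deterministic given the seed.
#' @return A data frame of class `cohort_table`, one row per subject-visit,
#'   with columns `subject_id`, `group`, `visit_day` and one column per
#'   variable.
#' @export
synth_cohort <- function(specs, retest = list(), seed = 1L) {
  if (length(specs) == 0) stop("`specs` must contain at least one group")
  varsets <- lapply(specs, function(s) sort(names(s$variables)))
  if (length(unique(vapply(varsets, paste, "", collapse = ","))) != 1)
    stop("all groups must specify the same variable set")
  if (!all(names(retest) %in% varsets[[1]]))
    stop("retest variables absent from the group specs: ",
         paste(setdiff(names(retest), varsets[[1]]), collapse = ", "))
  set.seed(seed)
  visit_days <- if (length(retest)) c(1L, 8L) else 1L
  rows <- list()
  sid <- 0L
  for (s in specs) {
    stopifnot(inherits(s, "group_spec"))
    base <- data.frame(
      subject_id = sprintf("S%03d", sid + seq_len(s$n)),
      group = s$group_name, stringsAsFactors = FALSE)
    sid <- sid + s$n
    draws <- list()
    for (nm in names(s$variables)) {
      v <- s$variables[[nm]]
      if (nm %in% names(retest)) {
        rs <- retest[[nm]]
        bsd <- if (is.null(rs$between_sd)) v$scale else rs$between_sd
        wsd <- bsd * sqrt((1 - rs$target_icc) / rs$target_icc)
        latent <- draw_variable(s$n, v)
        reps <- lapply(visit_days, function(day) {
          val <- latent + stats::rnorm(s$n, 0, wsd) +
            if (day == 8L) rs$rater_shift else 0
          clamp_range(val, v$censor_low, v$censor_high)
        })
        draws[[nm]] <- reps
      } else {
        one <- draw_variable(s$n, v)
        draws[[nm]] <- rep(list(one), length(visit_days))
      }
    }
    for (d in seq_along(visit_days)) {
      rec <- base
      rec$visit_day <- visit_days[d]
      for (nm in names(draws)) rec[[nm]] <- draws[[nm]][[d]]
      rows[[length(rows) + 1L]] <- rec
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$subject_id, out$visit_day), ]
  rownames(out) <- NULL
  class(out) <- c("cohort_table", "data.frame")
  out
}

# visit noise can push a censored variable out of range; clip there (the
# latent draw is already truncation-resampled, so atoms stay negligible)
clamp_range <- function(x, lo, hi) {
  if (!is.null(lo)) x <- pmax(x, lo)
  if (!is.null(hi)) x <- pmin(x, hi)
  x
}

normal_var <- function(location, scale, censor_low = NULL,
                       censor_high = NULL) {
  list(distribution = "normal", location = location, scale = scale,
       censor_low = censor_low, censor_high = censor_high)
}

bern_var <- function(p) list(distribution = "bernoulli", location = p,
                             scale = NA_real_)

#' Study-condition group specifications
#'
#' The three-group cohort structure of the study: 6 obese controls without
#' cardiovascular disease, 16 obese T2DM, 13 obese HFpEF with T2DM, with
#' group means and SDs for demographics, CMR indices and serum biomarkers as
#' reported, Pentraxin-3 log-normal (moment-matched, it is right-skewed),
#' and biomarkers censored to their assay reportable ranges (Galectin-3
#' 3.13-100 ng/mL, Pentraxin-3 0.094-192 ng/mL, IL1RL1 1.6-200 ng/mL).
#' Arrhythmia history is confined to the HFpEF group (3 of 13 subjects in
#' expectation, matching 3 of 35 overall).
#'
#' @param n Group sizes, in the order obese control / T2DM / HFpEF+T2DM.
#' @return A list of three [group_spec()]s.
#' @export
study_group_specs <- function(n = c(obese_control = 6, t2dm = 16,
                                    hfpef_t2dm = 13)) {
  galectin <- function(m, s) normal_var(m, s, 3.13, 100)
  pentraxin <- function(m, s)
    list(distribution = "lognormal", location = m, scale = s,
         censor_low = 0.094, censor_high = 192)
  il1rl1 <- function(m, s) normal_var(m, s, 1.6, 200)
  mk <- function(name, nn, age, bmi, p_female, p_arr, mpr, ecv, lamin, lamax,
                 res, con, boo, gal, ptx, il, ntp, lvedv, lvef) {
    group_spec(name, nn, list(
      age = normal_var(age[1], age[2]),
      female = bern_var(p_female),
      bmi = normal_var(bmi[1], bmi[2]),
      arrhythmia_history = bern_var(p_arr),
      mpr = normal_var(mpr[1], mpr[2]),
      ecv_pct = normal_var(ecv[1], ecv[2]),
      la_min_volume = normal_var(lamin[1], lamin[2]),
      la_max_volume = normal_var(lamax[1], lamax[2]),
      la_reservoir_strain = normal_var(res[1], res[2]),
      la_conduit_strain = normal_var(con[1], con[2]),
      la_booster_strain = normal_var(boo[1], boo[2]),
      galectin3 = galectin(gal[1], gal[2]),
      pentraxin3 = pentraxin(ptx[1], ptx[2]),
      il1rl1 = il1rl1(il[1], il[2]),
      nt_probnp = normal_var(ntp[1], ntp[2], censor_low = 1),
      lvedv = normal_var(lvedv[1], lvedv[2]),
      lvef = normal_var(lvef[1], lvef[2])))
  }
  list(
    mk("obese_control", n[[1]], c(62, 2), c(27.7, 1.3), 2 / 6, 0,
       c(3.63, 1.62), c(26.73, 1.81), c(35, 17), c(63, 21), c(41, 12),
       c(21.2, 6.3), c(19, 7), c(10.6, 3.7), c(0.21, 0.05), c(28, 6),
       c(6, 2), c(133, 27), c(61, 9)),
    mk("t2dm", n[[2]], c(61, 11), c(30.6, 3.1), 1 / 16, 0,
       c(3.05, 1.41), c(25.03, 2.65), c(37, 13), c(65, 16), c(38, 11),
       c(16.1, 4.8), c(22, 8), c(13.8, 3.3), c(0.52, 0.35), c(28, 8),
       c(6, 3), c(127, 30), c(59, 9)),
    mk("hfpef_t2dm", n[[3]], c(68, 4), c(32.3, 4.7), 5 / 13, 3 / 13,
       c(2.27, 1.10), c(26.54, 3.14), c(64, 21), c(90, 25), c(25, 10),
       c(11.0, 4.8), c(15, 5), c(16.1, 3.8), c(0.84, 0.67), c(27, 10),
       c(48, 23), c(127, 36), c(62, 8))
  )
}

#' Default test-retest specifications
#'
#' Target reliabilities chosen to match the reported day-1/day-8 ICC(2)
#' values: MPR 0.94, ECV 0.49, LA maximum volume 0.56, LA reservoir strain
#' 0.84, conduit strain 0.67, booster strain 0.41, Galectin-3 0.90,
#' Pentraxin-3 0.93, IL1RL1 0.87.
#'
#' @return Named list of [retest_spec()]s.
#' @export
study_retest_specs <- function() {
  list(mpr = retest_spec(0.94),
       ecv_pct = retest_spec(0.49),
       la_max_volume = retest_spec(0.56),
       la_min_volume = retest_spec(0.41),
       la_reservoir_strain = retest_spec(0.84),
       la_conduit_strain = retest_spec(0.67),
       la_booster_strain = retest_spec(0.41),
       galectin3 = retest_spec(0.90),
       pentraxin3 = retest_spec(0.93),
       il1rl1 = retest_spec(0.87))
}

#' Read or write a cohort table
#'
#' Delimited text, one row per subject-visit; columns `subject_id`, `group`,
#' `visit_day`, then variables.
#'
#' @param path File path.
#' @param table A `cohort_table` data frame.
#' @return `read_cohort()` returns a `cohort_table`; `write_cohort()`
#'   returns `path` invisibly.
#' @export
read_cohort <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "visit_day")
  if (!all(need %in% names(d)))
    stop("cohort file missing columns: ",
         paste(setdiff(need, names(d)), collapse = ", "))
  if (anyDuplicated(d[, c("subject_id", "visit_day")]))
    stop("duplicate subject_id/visit_day pairs in cohort file")
  class(d) <- c("cohort_table", "data.frame")
  d
}

#' @rdname read_cohort
#' @export
write_cohort <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
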