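test_that("biplane volume matches hand arithmetic and bilinearity", {
  expect_equal(biplane_volume(1500, 1600, 50),
               8 / (3 * pi) * 1500 * 1600 / 50 / 1000, tolerance = 1e-12)
  expect_equal(round(biplane_volume(1500, 1600, 50), 1), 40.7)
  expect_equal(biplane_volume(3000, 3200, 50),
               4 * biplane_volume(1500, 1600, 50))
  expect_warning(v0 <- biplane_volume(0, 1600, 50), "zero LA area")
  expect_equal(v0, 0)
  expect_error(biplane_volume(1500, 1600, 0), "length")
})

test_that("strain curve is referenced, unit-free and size-invariant", {
  expect_equal(strain_curve(rep(80, 10), 1), rep(0, 10))
  expect_equal(strain_curve(c(100, 130, 110), 1), c(0, 30, 10))
  lens <- c(55, 60, 70, 66, 58, 62, 57, 55)
  expect_equal(strain_curve(lens, 1), strain_curve(lens / 10, 1))
  expect_equal(strain_curve(lens, 1), strain_curve(2.2 * lens, 1))
  expect_error(strain_curve(c(-1, 2), 1), "positive")
})

test_that("phasic decomposition satisfies reservoir = conduit + booster", {
  ps <- phasic_strains(c(0, 10, 30, 20, 15, 5), pre_a_frame = 5)
  expect_equal(ps$reservoir, 30)
  expect_equal(ps$booster, 15)
  expect_equal(ps$conduit, 15)
  expect_equal(ps$reservoir, ps$conduit + ps$booster, tolerance = 1e-9)
  # zero pre-A strain: all of the emptying is conduit
  ps0 <- phasic_strains(c(0, 10, 30, 20, 10, 0), pre_a_frame = 6)
  expect_equal(ps0$booster, 0)
  expect_equal(ps0$conduit, ps0$reservoir)
  expect_warning(phasic_strains(c(0, 5, 30, 20, 10), pre_a_frame = 2),
                 "inverted timing")
})

test_that("synthetic trajectories are recovered exactly and in sweeps", {
  flat <- synth_la_trajectory(0, 0)
  expect_true(all(flat$lengths_2ch == flat$lengths_2ch[1]))
  tr <- synth_la_trajectory(30, 15)
  res <- analyze_la_trajectory(tr)
  expect_equal(res$strains$reservoir, 30, tolerance = 1e-9)
  expect_equal(res$strains$conduit, 15, tolerance = 1e-9)
  expect_equal(res$strains$booster, 15, tolerance = 1e-9)
  # oracle sweep: 100 random parameter draws recovered within 0.5% absolute
  set.seed(11)
  for (i in 1:100) {
    r <- runif(1, 5, 55)
    b <- runif(1, 0, r)
    s <- analyze_la_trajectory(synth_la_trajectory(r, b))$strains
    expect_lt(abs(s$reservoir - r), 0.5)
    expect_lt(abs(s$booster - b), 0.5)
    expect_lt(abs(s$conduit - (r - b)), 0.5)
    expect_equal(s$reservoir, s$conduit + s$booster, tolerance = 1e-9)
  }
  expect_error(synth_la_trajectory(10, 20), "booster_pct")
  expect_error(synth_la_trajectory(30, 10, n_frames = 6), "n_frames")
})

test_that("volume extrema are exact on synthetic trajectories", {
  tr <- synth_la_trajectory(28, 12, ref_length = 60)
  vol <- la_volume_extrema(tr)
  len <- (tr$lengths_2ch + tr$lengths_4ch) / 2
  vcurve <- 8 / (3 * pi) * tr$areas_2ch * tr$areas_4ch / len / 1000
  expect_equal(vol$min_volume, min(vcurve))
  expect_equal(vol$max_volume, max(vcurve))
  # constant trajectory: min = max
  cv <- la_volume_extrema(synth_la_trajectory(0, 0))
  expect_equal(cv$min_volume, cv$max_volume)
})

test_that("view/visit averaging handles identity, means and missingness", {
  expect_equal(average_views_and_visits(matrix(24, 1, 1))$value, 24)
  expect_equal(average_views_and_visits(matrix(c(20, 30), 1))$value, 25)
  expect_equal(average_views_and_visits(rbind(c(24, 24), c(26, 26)))$value,
               25)
  withNA <- average_views_and_visits(rbind(c(24, NA), c(26, 26)))
  expect_equal(withNA$value, 25)
  expect_equal(withNA$n_missing, 1)
  expect_error(average_views_and_visits(matrix(NA_real_, 2, 2)),
               "all entries missing")
})

test_that("trajectory files round-trip with 0-based frames", {
  tr <- synth_la_trajectory(25, 10)
  path <- withr::local_tempfile(fileext = ".csv")
  write_la_trajectory(tr, path)
  raw <- utils::read.csv(path)
  expect_equal(raw$frame[1], 0)  # files are 0-based
  back <- read_la_trajectory(path)
  expect_equal(back$lengths_2ch, tr$lengths_2ch)
  expect_equal(back$ref_frame, tr$ref_frame)
  expect_equal(back$pre_a_frame, tr$pre_a_frame)
  s1 <- analyze_la_trajectory(tr)$strains
  s2 <- analyze_la_trajectory(back)$strains
  expect_equal(s1$reservoir, s2$reservoir)
})
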