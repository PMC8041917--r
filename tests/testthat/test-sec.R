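# SEC profile normalization, MW calibration, size classes, peak calling
# and gel-ladder sizing.

test_that("profile normalization is proportional, idempotent and conservative", {
  p <- elution_profile(c(10, 10, 20))
  n <- normalize_profile(p)
  expect_equal(n$concentration, c(25, 25, 50))
  expect_true(n$normalized)
  expect_equal(normalize_profile(n)$concentration, n$concentration)
  set.seed(13)
  for (i in 1:20) {
    q <- normalize_profile(elution_profile(runif(30, 0, 5) + 1e-3))
    expect_equal(sum(q$concentration), 100, tolerance = 1e-9)
  }
  expect_error(normalize_profile(elution_profile(c(0, 0))), "all-zero")
  expect_error(elution_profile(c(-1, 2)), "non-negative")
})

test_that("calibration interpolates log10 MW through the standards", {
  cal <- fit_calibration(sec_standards())
  expect_equal(as.numeric(mw_at(8, cal)), 2500)
  expect_equal(as.numeric(mw_at(14, cal)), 500)
  expect_equal(as.numeric(mw_at(20, cal)), 150)
  # log-midpoint of the 2500-500 segment
  expect_equal(as.numeric(mw_at(11, cal)), sqrt(2500 * 500), tolerance = 1e-9)
  # physically impossible orientation is rejected
  rev_anchors <- data.frame(mw_kda = c(150, 500, 2500), position = c(8, 14, 20))
  expect_error(fit_calibration(rev_anchors), "decrease")
  expect_error(fit_calibration(sec_standards()[1, , drop = FALSE]), "2 anchors")
})

test_that("mw_at and position_of are mutually inverse and clamp out of range", {
  cal <- fit_calibration(sec_standards())
  expect_equal(as.numeric(position_of(500, cal)), 14)
  for (mw in c(151, 200, 499, 500, 501, 1000, 2499)) {
    expect_equal(as.numeric(mw_at(as.numeric(position_of(mw, cal)), cal)),
                 mw, tolerance = 1e-9)
  }
  expect_warning(res <- mw_at(25, cal), "clamped")
  expect_equal(as.numeric(res), 150)
  expect_true(attr(res, "out_of_range"))
  expect_warning(pos <- position_of(5000, cal), "clamped")
  expect_equal(as.numeric(pos), 8)
})

test_that("size-class summary recovers a known mixture and conserves percentages", {
  cal <- fit_calibration(sec_standards())
  sim <- simulate_elution_profile(
    elution_sim_config(hmw_lmw_mixture(), cal, noise_cv = 0, seed = 14))
  s <- size_class_summary(normalize_profile(sim$profile), cal)
  expect_equal(s$pct_hmw + s$pct_mid + s$pct_lmw, 100, tolerance = 1e-6)
  expect_equal(s$hmw_lmw_ratio, 7 / 3, tolerance = 0.05 * 7 / 3)
  # ratio is invariant to rescaling the raw profile
  scaled <- elution_profile(sim$profile$concentration * 37.5)
  s2 <- size_class_summary(normalize_profile(scaled), cal)
  expect_equal(s2$hmw_lmw_ratio, s$hmw_lmw_ratio, tolerance = 1e-12)
})

test_that("discretization error shrinks as fractions grow", {
  # finer fraction grids approach the continuous truth; anchor positions are
  # scaled with the grid so the column geometry is unchanged
  cal30 <- fit_calibration(sec_standards())
  cal300 <- fit_calibration(data.frame(mw_kda = c(2500, 500, 150),
                                       position = c(80, 140, 200)))
  sim30 <- simulate_elution_profile(
    elution_sim_config(hmw_lmw_mixture(), cal30, n_fractions = 30,
                       noise_cv = 0, seed = 15))
  sim300 <- simulate_elution_profile(
    elution_sim_config(hmw_lmw_mixture(), cal300, n_fractions = 300,
                       noise_cv = 0, seed = 15))
  err30 <- abs(size_class_summary(normalize_profile(sim30$profile),
                                  cal30)$hmw_lmw_ratio - 7 / 3)
  err300 <- abs(size_class_summary(normalize_profile(sim300$profile),
                                   cal300)$hmw_lmw_ratio - 7 / 3)
  expect_lte(err300, err30 + 1e-9)
  expect_lt(err300, 0.01)
})

test_that("size-class edge cases: all-HMW profiles, swapped bounds", {
  cal <- fit_calibration(sec_standards())
  conc <- rep(0, 30); conc[6:10] <- c(1, 4, 10, 4, 1)
  s <- size_class_summary(normalize_profile(elution_profile(conc)), cal)
  expect_equal(s$pct_hmw, 100, tolerance = 1e-6)
  expect_true(is.infinite(s$hmw_lmw_ratio))
  expect_true(s$lmw_zero)
  expect_error(size_class_summary(normalize_profile(elution_profile(conc)),
                                  cal, hi = 150, lo = 500), "exceed")
  expect_error(size_class_summary(elution_profile(conc), cal), "normalized")
})

test_that("peak calling uses the modal fraction with an early-fraction tie-break", {
  cal <- fit_calibration(sec_standards())
  conc <- rep(0, 30); conc[8] <- 10
  pk <- peak_mw(normalize_profile(elution_profile(conc)), cal)
  expect_equal(as.numeric(pk), 2500)
  expect_false(attr(pk, "tie"))
  conc2 <- rep(0, 30); conc2[c(10, 14)] <- 5
  pk2 <- peak_mw(normalize_profile(elution_profile(conc2)), cal)
  expect_equal(attr(pk2, "fraction"), 10)  # earlier = larger MW
  expect_true(attr(pk2, "tie"))
  expect_error(peak_mw(elution_profile(rep(0, 5)), cal), "no peak")
})

test_that("unimodal synthetic peak lands within one fraction of the component mode", {
  cal <- fit_calibration(sec_standards())
  one <- data.frame(mean_log10_mw = log10(800), sd_log10_mw = 0.06,
                    mass_fraction = 1)
  sim <- simulate_elution_profile(elution_sim_config(one, cal, noise_cv = 0,
                                                     seed = 16))
  pk <- peak_mw(normalize_profile(sim$profile), cal)
  true_pos <- as.numeric(position_of(800, cal))
  expect_lt(abs(attr(pk, "fraction") - true_pos), 1)
})

test_that("gel bands are sized by log-linear ladder interpolation", {
  lad <- gel_ladder()
  expect_equal(as.numeric(gel_band_size(3.0, lad)), 1260)
  mid <- (lad$position[lad$mw_kda == 400] + lad$position[lad$mw_kda == 1260]) / 2
  expect_equal(as.numeric(gel_band_size(mid, lad)), sqrt(400 * 1260),
               tolerance = 1e-9)
  expect_warning(res <- gel_band_size(0.2, lad), "clamped")
  expect_equal(as.numeric(res), 3900)
  expect_true(attr(res, "out_of_range"))
  bad <- gel_ladder(); bad$mw_kda[2] <- 5000
  expect_error(gel_band_size(2, bad), "decrease")
})
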