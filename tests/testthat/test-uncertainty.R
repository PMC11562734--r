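# From-definition sample standard deviation used as the independent oracle.
sd_oracle <- function(x) sqrt(sum((x - mean(x))^2) / (length(x) - 1))

test_that("MU/RU standard deviations follow the documented convention", {
  expect_equal(sd_oracle(c(5, 5, 5, 5)), 0)
  expect_equal(sd_oracle(c(1, 2, 3, 4)), 1.2909944487, tolerance = 1e-9)
  expect_equal(sd_oracle(c(0.1, 0.2, 0.3, 0.6)), 0.2160246899, tolerance = 1e-9)

  suite <- small_suite()
  probe <- probe_pairs(6)
  prof <- representation_uncertainty(suite, probe)
  expect_true(all(prof$kind == "RU"))
  expect_true(all(prof$source == "cross-representation"))
  member_sds <- vapply(prof$members, sd_oracle, numeric(1))
  expect_equal(prof$sd, member_sds, tolerance = 1e-12)
  expect_equal(prof$mean, vapply(prof$members, mean, numeric(1)),
               tolerance = 1e-12)
  # determinism: recomputation is identical
  prof2 <- representation_uncertainty(suite, probe)
  expect_identical(prof$sd, prof2$sd)

  mu <- model_uncertainty(suite$variant_sets$cmf, probe)
  expect_true(all(mu$kind == "MU"))
  expect_true(all(mu$source == "cmf"))
  expect_equal(mu$sd, vapply(mu$members, sd_oracle, numeric(1)),
               tolerance = 1e-12)
})

test_that("sd is symmetric under member permutation and scales linearly", {
  set.seed(42)
  for (i in 1:200) {
    x <- rnorm(4)
    expect_equal(sd(x), sd(rev(x)), tolerance = 1e-15)
    expect_equal(sd(3.7 * x), 3.7 * sd(x), tolerance = 1e-12)
  }
})

test_that("model_uncertainty rejects mixed representations", {
  suite <- small_suite()
  mixed <- c(suite$variant_sets$cmf[1:3], suite$variant_sets$md[1])
  expect_error(model_uncertainty(mixed, probe_pairs(2)),
               class = "ilscreen_contract_error")
  expect_error(model_uncertainty(suite$variant_sets$cmf[1:3], probe_pairs(2)),
               class = "ilscreen_contract_error")
})

test_that("threshold calibration matches the documented conventions", {
  t1 <- calibrate_threshold(c(0.1, 0.5, 0.3, 0.2), kind = "I")
  expect_equal(t1$value, 0.5)

  # linear-interpolation quartiles: Q3(1..8) = 6.25, IQR = 3.5 -> 11.5
  t2 <- calibrate_threshold(1:8, kind = "II")
  expect_equal(t2$calibration_stats$q3, 6.25)
  expect_equal(t2$calibration_stats$iqr, 3.5)
  expect_equal(t2$value, 11.5)

  t3 <- calibrate_threshold(rep(0.7, 10), kind = "II")
  expect_equal(t3$value, 0.7)

  expect_error(calibrate_threshold(c(0.1, 0.2, 0.3)), class = "ilscreen_value_error")
  expect_error(calibrate_threshold(c(0.1, -0.2, 0.3, 0.4)),
               class = "ilscreen_value_error")
})

test_that("flagging uses strict inequality with reliable ties", {
  thr <- calibrate_threshold(c(0.2, 0.5, 0.4, 0.3), kind = "I")
  expect_equal(thr$value, 0.5)
  expect_identical(flag_unreliable(c(0.4, 0.5, 0.6), thr),
                   c(FALSE, FALSE, TRUE))
  # threshold I flags none of its own calibration set
  expect_false(any(flag_unreliable(c(0.2, 0.5, 0.4, 0.3), thr)))
})

test_that("threshold II flags exactly the Tukey outliers of its calibration set", {
  set.seed(9)
  for (i in 1:20) {
    u <- abs(rnorm(50))
    thr <- calibrate_threshold(u, kind = "II")
    q <- quantile(u, c(0.25, 0.75), type = 7, names = FALSE)
    fence <- q[2] + 1.5 * (q[2] - q[1])
    expect_identical(flag_unreliable(u, thr), u > fence)
  }
})

test_that("raising the threshold never increases the flagged count", {
  set.seed(4)
  u <- abs(rnorm(100))
  thr_a <- calibrate_threshold(u, kind = "II")
  thr_b <- thr_a
  thr_b$value <- thr_a$value * 1.5
  expect_lte(sum(flag_unreliable(u, thr_b)), sum(flag_unreliable(u, thr_a)))
})

test_that("flags are invariant under joint positive rescaling", {
  set.seed(11)
  u <- abs(rnorm(100))
  thr <- calibrate_threshold(u, kind = "II")
  for (c_scale in c(0.01, 3, 1000)) {
    thr_s <- thr
    thr_s$value <- thr$value * c_scale
    expect_identical(flag_unreliable(u * c_scale, thr_s),
                     flag_unreliable(u, thr))
  }
})

test_that("MU thresholds refuse RU profiles without an override", {
  suite <- small_suite()
  probe <- probe_pairs(4)
  mu_prof <- model_uncertainty(suite$variant_sets$cmf, probe)
  ru_prof <- representation_uncertainty(suite, probe)
  thr_mu <- calibrate_threshold(mu_prof, kind = "II")
  expect_error(flag_unreliable(ru_prof, thr_mu), class = "ilscreen_contract_error")
  expect_no_error(flag_unreliable(ru_prof, thr_mu, override = TRUE))
  expect_s3_class(tidy(thr_mu), "tbl_df")
})

test_that("population-sd mode rescales uncertainties by a constant", {
  suite <- small_suite()
  probe <- probe_pairs(5)
  s_samp <- representation_uncertainty(suite, probe)$sd
  s_pop <- representation_uncertainty(suite, probe, sd_mode = "population")$sd
  expect_equal(s_pop, s_samp * sqrt(3 / 4), tolerance = 1e-12)
})
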