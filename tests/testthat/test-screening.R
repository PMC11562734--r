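fixed_threshold <- function(value, kind = "II") {
  thr <- calibrate_threshold(c(0, 0, 0, value), kind = "I")
  thr$value <- value
  thr$kind <- kind
  thr
}

preset_candidates <- function(pred, ru) {
  tibble::tibble(pair_id = sprintf("c%02d", seq_along(pred)),
                 .pred = pred, .ru = ru)
}

test_that("a permissive stage passes everything through, ordered by merit", {
  cand <- preset_candidates(c(3, 1, 2), c(0.1, 0.1, 0.1))
  st <- screening_stage("viscosity", suite = NULL,
                        threshold = fixed_threshold(1),
                        direction = "keep_low",
                        cutoff = cutoff_percentile(99.99))
  res <- run_stage(cand, st)
  expect_equal(res$record$n_survivors, 3L)
  expect_equal(res$survivors$.pred, c(1, 2, 3))
})

test_that("stage tallies match a by-hand fixture with an absolute cutoff", {
  cand <- preset_candidates(pred = c(0.2, 0.8, 0.4, 0.6, 0.3),
                            ru = c(0.1, 0.1, 0.9, 0.1, 0.9))
  st <- screening_stage("viscosity", suite = NULL,
                        threshold = fixed_threshold(0.5),
                        direction = "keep_low",
                        cutoff = cutoff_absolute(0.6))
  res <- run_stage(cand, st)
  # by hand: c03/c05 unreliable (ru 0.9); of c01,c02,c04: c02 fails (0.8 > 0.6)
  expect_equal(res$record$n_unreliable, 2L)
  expect_equal(res$record$n_failed, 1L)
  expect_equal(res$survivors$pair_id, c("c01", "c04"))
  expect_equal(res$record$n_input,
               res$record$n_unreliable + res$record$n_failed + res$record$n_survivors)

  empty <- suppressMessages(run_stage(cand[0, ], st))
  expect_equal(nrow(empty$survivors), 0L)
})

test_that("sequential screens chain survivors and conserve counts", {
  # stage 1 (viscosity, keep_low <= 0.5) keeps 3 of 5; stage 2 keeps 1 of 3
  cand <- tibble::tibble(
    pair_id = sprintf("c%02d", 1:5),
    .pred_viscosity = c(0.2, 0.3, 0.4, 0.8, 0.9),
    .ru_viscosity = 0.1,
    .pred_co2_capacity = c(0.7, 0.2, 0.1, 0.8, 0.9),
    .ru_co2_capacity = c(0.1, 0.9, 0.1, 0.1, 0.1)
  )
  thr <- fixed_threshold(0.5)
  stages <- list(
    screening_stage("viscosity", NULL, thr, "keep_low", cutoff_absolute(0.5)),
    screening_stage("co2_capacity", NULL, thr, "keep_high", cutoff_absolute(0.5))
  )
  rep <- run_sequential_screen(cand, stages)
  expect_equal(rep$stages$n_input, c(5L, 3L))
  expect_equal(rep$stages$n_survivors, c(3L, 1L))
  expect_equal(rep$survivors$pair_id, "c01")
  expect_true(all(rep$stages$n_input ==
                    rep$stages$n_unreliable + rep$stages$n_failed +
                    rep$stages$n_survivors))
  g <- glance(rep)
  expect_equal(g$n_survivors, 1L)
  expect_error(run_sequential_screen(cand, list()), class = "ilscreen_value_error")
  expect_error(run_sequential_screen(cand, list(stages[[1]], stages[[1]])),
               class = "ilscreen_value_error")
})

test_that("loosening a cutoff never shrinks the survivor set", {
  set.seed(3)
  cand <- preset_candidates(runif(50), abs(rnorm(50, 0.3, 0.2)))
  thr <- fixed_threshold(0.5)
  prev <- character()
  for (cut in c(0.2, 0.4, 0.6, 0.8, 1.0)) {
    st <- screening_stage("viscosity", NULL, thr, "keep_low",
                          cutoff_absolute(cut))
    surv <- run_stage(cand, st)$survivors$pair_id
    expect_true(all(prev %in% surv))
    prev <- surv
  }
})

test_that("absolute cutoffs make the final survivor set order-independent", {
  set.seed(14)
  n <- 60
  cand <- tibble::tibble(
    pair_id = sprintf("c%02d", 1:n),
    .pred_viscosity = runif(n),
    .ru_viscosity = abs(rnorm(n, 0.2, 0.15)),
    .pred_log_ec50 = runif(n, 0, 5),
    .ru_log_ec50 = abs(rnorm(n, 0.2, 0.15))
  )
  thr <- fixed_threshold(0.4)
  s_visc <- screening_stage("viscosity", NULL, thr, "keep_low", cutoff_absolute(0.6))
  s_tox <- screening_stage("log_ec50", NULL, thr, "keep_high", cutoff_absolute(2))
  ab <- run_sequential_screen(cand, list(s_visc, s_tox))
  ba <- run_sequential_screen(cand, list(s_tox, s_visc))
  expect_setequal(ab$survivors$pair_id, ba$survivors$pair_id)
  # brute force: survivors are exactly the candidates passing every test
  brute <- cand$pair_id[cand$.ru_viscosity <= 0.4 & cand$.pred_viscosity <= 0.6 &
                          cand$.ru_log_ec50 <= 0.4 & cand$.pred_log_ec50 >= 2]
  expect_setequal(ab$survivors$pair_id, brute)
})

test_that("an end-to-end screen over a trained suite stays conservative", {
  suite <- small_suite()
  ru_train <- representation_uncertainty(suite, small_split()$train)
  thr <- calibrate_threshold(ru_train, kind = "II")
  cand <- probe_pairs(8)[, c("pair_id", "cation_smiles", "anion_smiles")]
  st <- screening_stage("viscosity", suite, thr, "keep_low",
                        cutoff_percentile(50))
  res <- run_stage(cand, st)
  expect_equal(res$record$n_input, 8L)
  expect_equal(res$record$n_input,
               res$record$n_unreliable + res$record$n_failed +
                 res$record$n_survivors)
  expect_true(all(c("pred_viscosity", "ru_viscosity") %in% names(res$survivors)))
})
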