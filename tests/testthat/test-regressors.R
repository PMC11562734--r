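make_constant_dataset <- function(n = 40L, value = 0.5) {
  d <- small_dataset()[rep_len(seq_len(100), n), ]
  d$pair_id <- sprintf("c%03d", seq_len(n))
  d$value <- value
  d
}

test_that("models fit a constant target to within tolerance", {
  d <- make_constant_dataset()
  for (rep in c("cmf", "md", "mg")) {
    m <- train_model(d, rep, seed = 1)
    pred <- predict(m, d)
    expect_true(all(abs(pred$.pred - 0.5) < 0.02),
                label = paste(rep, "constant-target fit"))
  }
})

test_that("variant sets on a constant target agree with near-zero spread", {
  d <- make_constant_dataset()
  models <- train_variant_set(d, "md", seed = 1)
  prof <- model_uncertainty(models, d[1:10, ])
  expect_true(all(abs(prof$mean - 0.5) < 0.02))
  expect_true(all(prof$sd < 0.02))
})

test_that("training is deterministic and guarded by preconditions", {
  d <- small_split()$train[1:60, ]
  probe <- probe_pairs(6)
  for (rep in c("cmf", "mi", "mg")) {
    m1 <- train_model(d, rep, seed = 9)
    m2 <- train_model(d, rep, seed = 9)
    expect_identical(predict(m1, probe)$.pred, predict(m2, probe)$.pred,
                     label = paste(rep, "determinism"))
  }
  expect_error(train_model(d[1:5, ], "cmf"), class = "ilscreen_value_error")
})

test_that("variant sets enforce cardinality and name uniqueness", {
  d <- small_split()$train[1:60, ]
  v <- default_variants("md")
  expect_error(train_variant_set(d, "md", v[1:3]), class = "ilscreen_value_error")
  vdup <- v
  vdup[[2]]$name <- vdup[[1]]$name
  expect_error(train_variant_set(d, "md", vdup), class = "ilscreen_value_error")
  models <- train_variant_set(d, "md", v, seed = 2)
  expect_length(models, 4L)
  expect_length(unique(names(models)), 4L)
})

test_that("prediction is order-equivariant and robust to bad rows", {
  suite <- small_suite()
  m <- suite$best_models$cmf
  probe <- probe_pairs(6)
  p1 <- predict(m, probe)
  perm <- c(4, 2, 6, 1, 3, 5)
  p2 <- predict(m, probe[perm, ])
  expect_identical(p2$.pred, p1$.pred[perm])
  expect_identical(p2$pair_id, p1$pair_id[perm])

  empty <- predict(m, probe[0, ])
  expect_equal(nrow(empty), 0L)

  mixed <- probe[1:3, ]
  mixed$cation_smiles[2] <- "bogus("
  p3 <- predict(m, mixed)
  expect_true(is.na(p3$.pred[2]))
  expect_false(anyNA(p3$.pred[c(1, 3)]))
})

test_that("a deep tree model overfits noiseless data on the training set", {
  spec <- generator_spec("in_domain", n_cations = 12, n_anions = 12,
                         property = "viscosity", noise_sd = 0, seed = 55)
  lib <- generate_ion_library(spec)
  d <- generate_property_dataset(lib, spec, n_records = 50L)
  m <- train_model(d, "cmf",
                   hyperparameter_variant("deep", max_depth = 10L,
                                          learning_rate = 0.3, nrounds = 300L),
                   seed = 1)
  expect_gt(m$training_meta$r_squared, 0.9)
})

test_that("train_suite selects the internally best variant per representation", {
  suite <- small_suite()
  expect_setequal(names(suite$best_models), c("cmf", "md", "mi", "mg"))
  expect_true(all(vapply(suite$variant_sets, length, integer(1)) == 4L))
  sel <- suite$selection
  for (r in unique(sel$representation)) {
    s <- sel[sel$representation == r, ]
    expect_equal(s$validation_rmse[s$selected], min(s$validation_rmse))
  }
  # same seed -> same selected variants
  suite2 <- train_suite(small_split()$train, suite_config(), seed = 42L)
  expect_identical(
    vapply(suite$best_models, function(m) m$variant$name, character(1)),
    vapply(suite2$best_models, function(m) m$variant$name, character(1))
  )
})

test_that("scheme-tag mismatch is blocked at prediction time", {
  suite <- small_suite()
  m <- suite$best_models$cmf
  m$scheme_tag <- "cmf-r9-b9"
  expect_error(predict(m, probe_pairs(2)), class = "ilscreen_contract_error")
  expect_no_error(predict(m, probe_pairs(2), check_scheme = FALSE))
})

test_that("model and suite summaries are tidy", {
  suite <- small_suite()
  g <- glance(suite$best_models$md)
  expect_equal(nrow(g), 1L)
  expect_true(all(c("rmse", "mae", "r_squared") %in% names(g)))
  td <- tidy(suite)
  expect_equal(nrow(td), 16L)  # 4 representations x 4 variants
  expect_true(sum(td$selected) == 4L)
})
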