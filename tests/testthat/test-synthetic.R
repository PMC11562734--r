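# Independent substructure-count oracle: element tallies from the parsed
# atom table (a different code path from the SMARTS matcher the generator
# uses).
element_count_oracle <- function(smiles, symbol) {
  sum(ilscreen:::parse_mol(smiles)$atoms$element == symbol)
}

pair_count_oracle <- function(cation, anion, symbol) {
  element_count_oracle(cation, symbol) + element_count_oracle(anion, symbol)
}

.smarts_symbol <- c("[#6]" = "C", "[#8]" = "O", "[#9]" = "F")

test_that("ion libraries are deterministic with valid charged grammars", {
  spec <- generator_spec("in_domain", n_cations = 10, n_anions = 10, seed = 7)
  lib1 <- generate_ion_library(spec)
  lib2 <- generate_ion_library(spec)
  expect_identical(lib1, lib2)
  for (s in lib1$cations) {
    expect_equal(ilscreen:::parse_mol(s)$net_charge, 1)
  }
  for (s in lib1$anions) {
    expect_equal(ilscreen:::parse_mol(s)$net_charge, -1)
  }
  expect_error(generator_spec("in_domain", n_cations = 0),
               class = "ilscreen_value_error")
})

test_that("in-domain and OOD libraries share no canonical SMILES", {
  for (seed in c(1, 2, 3)) {
    id_spec <- generator_spec("in_domain", n_cations = 25, n_anions = 20,
                              seed = seed)
    ood_spec <- generator_spec("ood", n_cations = 40, n_anions = 40,
                               seed = seed)
    id_lib <- generate_ion_library(id_spec)
    ood_lib <- generate_ion_library(ood_spec)
    expect_length(intersect(unlist(id_lib), unlist(ood_lib)), 0)
  }
})

test_that("noiseless values reproduce the ground-truth formula exactly", {
  spec <- generator_spec("in_domain", n_cations = 8, n_anions = 8,
                         property = "viscosity", noise_sd = 0, seed = 13)
  lib <- generate_ion_library(spec)
  d <- generate_property_dataset(lib, spec, n_records = 40L)
  w <- spec$coefficients$weights
  expected <- vapply(seq_len(nrow(d)), function(i) {
    counts <- vapply(names(w), function(pat) {
      pair_count_oracle(d$cation_smiles[i], d$anion_smiles[i],
                        .smarts_symbol[[pat]])
    }, numeric(1))
    spec$coefficients$intercept + sum(w * counts) +
      spec$condition_weights[["temperature_K"]] * (d$temperature_K[i] - 298.15)
  }, numeric(1))
  expect_equal(d$value, expected, tolerance = 1e-10)
  expect_equal(d$.truth, expected, tolerance = 1e-10)
})

test_that("datasets are reproducible and noise perturbs around the truth", {
  spec <- generator_spec("in_domain", n_cations = 8, n_anions = 8,
                         property = "viscosity", noise_sd = 0.1, seed = 21)
  lib <- generate_ion_library(spec)
  d1 <- generate_property_dataset(lib, spec, n_records = 60L)
  d2 <- generate_property_dataset(lib, spec, n_records = 60L)
  expect_identical(d1$value, d2$value)
  resid <- d1$value - d1$.truth
  expect_gt(sd(resid), 0.05)
  expect_lt(sd(resid), 0.2)
})

test_that("doubling a coefficient doubles that substructure's contribution", {
  base <- generator_spec("in_domain", n_cations = 8, n_anions = 8,
                         property = "viscosity",
                         coefficients = list(intercept = 0,
                                             weights = c("[#9]" = 0.3)),
                         condition_weights = c(temperature_K = 0, pressure_kPa = 0),
                         noise_sd = 0, seed = 33)
  doubled <- base
  doubled$coefficients$weights[["[#9]"]] <- 0.6
  lib <- generate_ion_library(base)
  d1 <- generate_property_dataset(lib, base, n_records = 30L)
  d2 <- generate_property_dataset(lib, doubled, n_records = 30L)
  expect_equal(d2$.truth, 2 * d1$.truth, tolerance = 1e-10)
})

test_that("co2-capacity targets stay in [0, 1] via the logistic map", {
  spec <- generator_spec("in_domain", n_cations = 10, n_anions = 10,
                         property = "co2_capacity", noise_sd = 0.2, seed = 5)
  lib <- generate_ion_library(spec)
  d <- generate_property_dataset(lib, spec, n_records = 80L)
  expect_true(all(d$value >= 0 & d$value <= 1))
  expect_true(all(d$.truth >= 0 & d$.truth <= 1))
  # logistic(linear truth) is recomputable: truth has no noise
  expect_false(identical(d$value, d$.truth))
})

test_that("uncountable coefficient SMARTS are rejected", {
  spec <- generator_spec("in_domain", n_cations = 5, n_anions = 5,
                         coefficients = list(intercept = 0,
                                             weights = c("[[bad" = 1)),
                         seed = 1)
  lib <- generate_ion_library(generator_spec("in_domain", 5, 5, seed = 1))
  expect_error(generate_property_dataset(lib, spec, n_records = 10L),
               class = "ilscreen_value_error")
})
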