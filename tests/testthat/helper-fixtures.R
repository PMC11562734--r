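# Shared fixtures, built in code and memoised for the session so the
# expensive pieces (trained suites, the seeded uncertainty experiments) are
# computed once and reused across test files.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

# A small in-domain viscosity dataset (fast; enough rows to train).
small_dataset <- function() {
  fixture("small_dataset", function() {
    spec <- generator_spec("in_domain", n_cations = 15L, n_anions = 15L,
                           property = "viscosity", seed = 101L)
    lib <- generate_ion_library(spec)
    generate_property_dataset(lib, spec, n_records = 150L)
  })
}

small_split <- function() {
  fixture("small_split", function() split_dataset(small_dataset(), 0.2, seed = 7L))
}

# One trained suite over the small dataset, shared by model-level tests.
small_suite <- function() {
  fixture("small_suite", function() {
    train_suite(small_split()$train, suite_config(), seed = 42L)
  })
}

# A handful of valid candidate pairs for prediction-path tests.
probe_pairs <- function(n = 8L) {
  d <- small_dataset()
  u <- !duplicated(paste(d$cation_smiles, d$anion_smiles))
  out <- d[u, c("pair_id", "cation_smiles", "anion_smiles",
                "temperature_K", "pressure_kPa")]
  out[seq_len(min(n, nrow(out))), ]
}

# The seeded uncertainty/ensemble experiment shared by the synthetic
# acceptance checks: in-domain train (400) + test (100), OOD probe set
# (200), suite, RU/MU thresholds (kind II) and flag tallies.
ood_experiment <- function(seed) {
  fixture(paste0("ood_experiment_", seed), function() {
    spec <- generator_spec("in_domain", n_cations = 20L, n_anions = 20L,
                           property = "viscosity", seed = seed)
    lib <- generate_ion_library(spec)
    d <- generate_property_dataset(lib, spec, n_records = 500L)
    sp <- split_dataset(d, 0.2, seed = seed)
    suite <- train_suite(sp$train, suite_config(), seed = seed)

    ood_spec <- generator_spec("ood", n_cations = 20L, n_anions = 10L,
                               property = "viscosity", seed = seed)
    ood_lib <- generate_ion_library(ood_spec)
    ood <- generate_cross_pairs(ood_lib$cations, ood_lib$anions)
    ood$temperature_K <- 298.15
    ood$pressure_kPa <- 101.325

    ru_train <- representation_uncertainty(suite, sp$train)
    thr_ru <- calibrate_threshold(ru_train, kind = "II")
    ru_test <- representation_uncertainty(suite, sp$test)
    ru_ood <- representation_uncertainty(suite, ood)

    mu <- lapply(c(cmf = "cmf", md = "md", mg = "mg"), function(r) {
      models <- suite$variant_sets[[r]]
      thr <- calibrate_threshold(model_uncertainty(models, sp$train), kind = "II")
      ood_prof <- model_uncertainty(models, ood)
      list(threshold = thr,
           n_flagged_ood = sum(flag_unreliable(ood_prof, thr)$unreliable))
    })

    ens <- ensemble_predict(suite, sp$test)
    list(
      suite = suite, train = sp$train, test = sp$test, ood = ood,
      thr_ru = thr_ru,
      ru_test = flag_unreliable(ru_test, thr_ru),
      ru_ood = flag_unreliable(ru_ood, thr_ru),
      mu = mu,
      ensemble_test = ens
    )
  })
}

experiment_seeds <- function() c(11L, 23L, 37L)

# Oracle for importance-recovery checks: the fingerprint columns that any
# fluorine-containing circular environment of the library hashes into.
# An environment of radius r centred on atom i is fluorine-derived iff some
# atom within r bonds of i is F.
fluorine_fingerprint_features <- function(lib, bits = 1024L, radius = 2L) {
  buckets <- function(smiles) {
    mol <- ilscreen:::parse_mol(smiles)
    n <- mol$n_atoms
    adj <- matrix(FALSE, n, n)
    if (mol$n_bonds) {
      adj[cbind(mol$bonds$a1, mol$bonds$a2)] <- TRUE
      adj[cbind(mol$bonds$a2, mol$bonds$a1)] <- TRUE
    }
    # hop distances by repeated neighbourhood expansion
    within <- list(diag(n) > 0)
    for (r in seq_len(radius)) {
      within[[r + 1L]] <- within[[r]] | (within[[r]] %*% adj) > 0
    }
    ids <- ilscreen:::mol_environment_ids(mol, radius)
    is_f <- mol$atoms$element == "F"
    f_derived <- unlist(lapply(0:radius, function(r) {
      vapply(seq_len(n), function(i) any(is_f[within[[r + 1L]][i, ]]), logical(1))
    }))
    unique((ids[f_derived] %% bits) + 1L)
  }
  feats <- character()
  for (s in lib$cations) {
    feats <- c(feats, sprintf("cat_fp%04d", buckets(s)))
  }
  for (s in lib$anions) {
    feats <- c(feats, sprintf("an_fp%04d", buckets(s)))
  }
  unique(feats)
}
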