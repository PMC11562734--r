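test_that("fingerprints are deterministic, typed, and binary = min(count, 1)", {
  pairs <- probe_pairs(6)
  cfg <- featurizer_config()
  fp1 <- count_fingerprint(pairs, cfg)
  fp2 <- count_fingerprint(pairs, cfg)
  expect_identical(fp1, fp2)
  expect_true(all(fp1 >= 0))
  expect_true(all(fp1 == round(fp1)))

  bf <- binary_fingerprint(pairs, cfg)
  expect_true(all(bf %in% c(0, 1)))
  expect_identical(unname(pmin(fp1, 1)), unname(bf))
  expect_equal(ncol(fp1), 2L * cfg$fp_bits)
})

test_that("count fingerprints separate homologues and double on duplication", {
  a <- parse_ion_pair("CC[N+](C)(C)C.[Cl-]", "a")
  b <- parse_ion_pair("C[N+](C)(C)C.[Cl-]", "b")
  fa <- count_fingerprint(a)
  fb <- count_fingerprint(b)
  expect_gt(sum(fa != fb), 0)

  # a disconnected duplicate substructure doubles its count entries
  one <- tibble::tibble(pair_id = "one", cation_smiles = "[NH4+]",
                        anion_smiles = "CCO")
  two <- tibble::tibble(pair_id = "two", cation_smiles = "[NH4+]",
                        anion_smiles = "CCO.CCO")
  f1 <- count_fingerprint(one)
  f2 <- count_fingerprint(two)
  an <- 1025:2048  # anion sub-vector
  expect_identical(unname(f2[, an]), unname(2 * f1[, an]))
})

test_that("descriptor vector matches hand-computed oracles", {
  p <- parse_ion_pair("[NH4+].[Cl-]")
  d <- descriptor_vector(p)
  # molecular weights from standard atomic masses: N + 4H; Cl
  expect_equal(unname(d[1, "cat_MW"]), 14.007 + 4 * 1.008, tolerance = 1e-3)
  expect_equal(unname(d[1, "an_MW"]), 35.453, tolerance = 1e-3)

  q <- parse_ion_pair("C[N+](C)(C)C.[Cl-]")
  dq <- descriptor_vector(q)
  expect_equal(unname(dq[1, "cat_n_heavy"]), 5)
  expect_equal(unname(dq[1, "cat_net_charge"]), 1)
  expect_identical(descriptor_vector(q), dq)
  expect_true(all(is.finite(d)))
})

test_that("rendered images honour the canvas contract and are deterministic", {
  pairs <- probe_pairs(2)
  cfg <- featurizer_config(image_px = 64)
  im1 <- render_image(pairs, cfg)
  expect_equal(dim(im1), c(2, 64, 64))
  expect_true(all(im1 >= 0 & im1 <= 1))
  im2 <- render_image(pairs, cfg)
  expect_identical(im1, im2)
  # non-degeneracy: a rendered pair deposits ink on the blank canvas
  expect_gt(sum(im1[1, , ]), 0)
  expect_error(featurizer_config(image_px = 8), class = "ilscreen_value_error")
})

test_that("molecular graphs respect component structure and atom features", {
  p <- parse_ion_pair("CC[N+](C)(C)C.CC(=O)[O-]", "p")
  g <- build_graph(p)
  # heavy atoms: 6 cation + 4 anion; edges: 5 + 3, none crossing components
  expect_equal(nrow(g$nodes), 10L)
  expect_equal(nrow(g$edges), 8L)
  comp <- g$nodes$component
  expect_true(all(comp[g$edges$a1] == comp[g$edges$a2]))

  amm <- build_graph(parse_ion_pair("[NH4+].[Cl-]"))
  n_node <- which(amm$nodes$element == "N")
  expect_equal(unname(amm$node_features[n_node, "charge"]), 1)
  expect_equal(nrow(amm$edges), 0L)
})

test_that("graph node count equals heavy-atom count over random pairs", {
  spec <- generator_spec("in_domain", n_cations = 10, n_anions = 10, seed = 3)
  lib <- generate_ion_library(spec)
  set.seed(5)
  for (i in 1:50) {
    cs <- sample(lib$cations, 1)
    as_ <- sample(lib$anions, 1)
    pair <- tibble::tibble(pair_id = "x", cation_smiles = cs, anion_smiles = as_)
    g <- build_graph(pair)
    # oracle: atom enumeration from the two parsed component molecules
    n_expect <- nrow(ilscreen:::parse_mol(cs)$atoms) +
      nrow(ilscreen:::parse_mol(as_)$atoms)
    expect_equal(nrow(g$nodes), n_expect)
    expect_equal(nrow(g$node_features), n_expect)
  }
})

test_that("attach_conditions extends vectors per property and guards types", {
  X <- matrix(rnorm(10), 5, 2)
  cond <- reference_conditions()
  expect_equal(ncol(attach_conditions(X, cond, "viscosity")), 3L)
  expect_equal(ncol(attach_conditions(X, cond, "co2_capacity")), 4L)
  expect_identical(attach_conditions(X, cond, "refractive_index"), X)
  expect_identical(attach_conditions(X, cond, "log_ec50"), X)
  expect_error(attach_conditions(list(), cond, "viscosity"),
               class = "ilscreen_contract_error")
  # standardisation: reference conditions map to zero coordinates
  Xc <- attach_conditions(X, cond, "co2_capacity")
  expect_equal(unname(Xc[, 3:4]), matrix(0, 5, 2))
})

test_that("scheme tags identify featurizer settings", {
  c1 <- featurizer_config()
  c2 <- featurizer_config(fp_bits = 512)
  expect_false(identical(scheme_tag(c1, "cmf"), scheme_tag(c2, "cmf")))
  expect_false(identical(scheme_tag(c1, "cmf"), scheme_tag(c1, "bmf")))
})
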