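# Synthetic ion libraries and property datasets with known ground truth.
#
# The in-domain family is a scaffold grammar of tetraalkylammonium cations
# (four arms drawn from a small alkyl/functionalised-alkyl alphabet) and
# simple organic anions (carboxylates, sulfonates, carbonates, halides).
# The out-of-distribution (OOD) family is a disjoint alphabet of substituted
# fused aromatics and related neutral scaffolds, standing in for "non-IL"
# molecules; the two families share no canonical SMILES by construction
# (the in-domain grammar produces no aromatic atoms).
#
# Ground truth is linear in SMARTS substructure counts plus linear condition
# terms plus Gaussian noise, so that all four representations can partially
# learn it while extrapolation to the disjoint OOD alphabet drives them
# apart — the mechanism representation uncertainty exploits.

# Cation arms: branch form (used inside parentheses) and prefix form (used
# for the first arm, attachment at the string's right end).
.cation_arms <- tibble::tibble(
  branch = c("C", "CC", "CCC", "CCCC", "CCCCC", "CC(C)C", "CCO", "CCF", "CC(F)(F)F"),
  prefix = c("C", "CC", "CCC", "CCCC", "CCCCC", "CC(C)C", "OCC", "FCC", "FC(F)(F)C")
)

.anion_templates <- function() {
  tails <- c("", "C", "CC", "CCC", "CCCC", "CCCCC", "OC", "OCC", "FC",
             "FCC", "FC(F)(F)")
  c(
    paste0(tails, "C(=O)[O-]"),                       # carboxylates
    paste0(c("C", "CC", "CCC", "CCCC", "FC(F)(F)"), "S(=O)(=O)[O-]"),  # sulfonates
    "OC(=O)[O-]", "COC(=O)[O-]", "CCOC(=O)[O-]",      # (alkyl) carbonates
    "[Cl-]", "[Br-]",                                 # halides
    "N#C[N-]C#N"                                      # dicyanamide
  )
}

.ood_templates <- c(
  "c1ccc2ccccc2c1",            # naphthalene
  "c1ccc2ncccc2c1",            # quinoline
  "c1ccc2cc3ccccc3cc2c1",      # anthracene
  "c1ccc(-c2ccccc2)cc1",       # biphenyl
  "C=Cc1ccccc1",               # styrene
  "c1ccc2c(c1)oc1ccccc12"      # dibenzofuran
)

.ood_substituents <- c("", "C", "CC", "CCC", "CCCC", "Cl", "F", "Br", "I",
                       "O", "N", "CO", "OC", "ClC", "FC(F)(F)", "N#C",
                       "CS", "O=[N+]([O-])")

enumerate_in_domain_cations <- function() {
  arms <- .cation_arms
  n <- nrow(arms)
  combos <- utils::combn(seq_len(n + 3L), 4L)  # multisets via stars-and-bars
  combos <- combos - 0:3
  apply(combos, 2L, function(ix) {
    paste0(arms$prefix[ix[1L]], "[N+](", arms$branch[ix[2L]], ")(",
           arms$branch[ix[3L]], ")", arms$branch[ix[4L]])
  })
}

enumerate_ood_family <- function() {
  as.vector(outer(.ood_substituents, .ood_templates, paste0))
}

#' Specification of the synthetic data generator
#'
#' @param family `"in_domain"` (tetraalkylammonium / organic-anion ionic
#'   liquids) or `"ood"` (neutral fused-aromatic "non-IL" molecules).
#' @param n_cations,n_anions Library sizes (for `"ood"`: the sizes of the
#'   non-cation and non-anion pools).
#' @param property One of [il_properties()].
#' @param coefficients Named list `list(intercept =, weights =)` with
#'   `weights` a named numeric vector of SMARTS pattern -> weight; default
#'   [default_coefficients()].
#' @param condition_weights Named numeric `c(temperature_K =, pressure_kPa =)`
#'   weights of the centred condition terms.
#' @param noise_sd Gaussian noise standard deviation (>= 0), on the linear
#'   scale of the property (before the logistic squash for `co2_capacity`).
#' @param seed Integer seed.
#' @return A list of class `il_generator_spec`.
#' @export
generator_spec <- function(family = c("in_domain", "ood"),
                           n_cations = 20L, n_anions = 20L,
                           property = "viscosity",
                           coefficients = default_coefficients(property),
                           condition_weights = default_condition_weights(property),
                           noise_sd = 0.1, seed = 1L) {
  family <- match.arg(family)
  property <- match.arg(property, il_properties())
  if (n_cations < 1L || n_anions < 1L) stop_value("Library counts must be >= 1.")
  if (!is.numeric(noise_sd) || noise_sd < 0) stop_value("`noise_sd` must be >= 0.")
  if (!length(coefficients$weights)) stop_value("Coefficient map must be non-empty.")
  structure(
    list(family = family, n_cations = as.integer(n_cations),
         n_anions = as.integer(n_anions), property = property,
         coefficients = coefficients, condition_weights = condition_weights,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "il_generator_spec"
  )
}

#' Default ground-truth coefficients
#'
#' Substructure weights chosen so the signal spans a realistic range for
#' each property and points in the chemically expected direction (longer
#' alkyl chains raise viscosity and toxicity; oxygen-rich anions and
#' fluorination raise CO2 uptake).
#'
#' @param property One of [il_properties()].
#' @return `list(intercept =, weights = c(<SMARTS> = weight, ...))`.
#' @export
default_coefficients <- function(property) {
  switch(match.arg(property, il_properties()),
    viscosity = list(intercept = 1.2,
                     weights = c("[#6]" = 0.08, "[#9]" = -0.06, "[#8]" = 0.15)),
    co2_capacity = list(intercept = -1.5,
                        weights = c("[#9]" = 0.25, "[#8]" = 0.35, "[#6]" = -0.05)),
    log_ec50 = list(intercept = 4.5,
                    weights = c("[#6]" = -0.15, "[#8]" = 0.30)),
    refractive_index = list(intercept = 1.38,
                            weights = c("[#6]" = 0.004, "[#8]" = -0.003,
                                        "[#9]" = -0.008))
  )
}

#' @rdname default_coefficients
#' @export
default_condition_weights <- function(property) {
  switch(match.arg(property, il_properties()),
    viscosity = c(temperature_K = -0.012, pressure_kPa = 0),
    co2_capacity = c(temperature_K = -0.01, pressure_kPa = 0.002),
    c(temperature_K = 0, pressure_kPa = 0)
  )
}

#' Generate a synthetic ion library
#'
#' Deterministic given the spec's seed. In-domain cations all carry net
#' charge +1 and anions -1; the OOD family consists of neutral molecules
#' from a structurally disjoint aromatic alphabet (its two pools may
#' overlap each other, but never the in-domain family).
#'
#' @param spec An [generator_spec()].
#' @return `list(cations =, anions =)` of canonical SMILES.
#' @export
generate_ion_library <- function(spec) {
  stopifnot(inherits(spec, "il_generator_spec"))
  if (spec$family == "in_domain") {
    cat_all <- enumerate_in_domain_cations()
    an_all <- .anion_templates()
  } else {
    cat_all <- an_all <- enumerate_ood_family()
  }
  if (spec$n_cations > length(cat_all) || spec$n_anions > length(an_all)) {
    stop_value(sprintf("Library supports at most %d cations / %d anions.",
                       length(cat_all), length(an_all)))
  }
  picks <- with_seed(spec$seed, list(
    cations = sample(cat_all, spec$n_cations),
    anions = sample(an_all, spec$n_anions)
  ))
  list(cations = canonical_smiles(picks$cations),
       anions = canonical_smiles(picks$anions))
}

# Ground-truth linear predictor for one pair (counts on cation + anion).
truth_linear <- function(cation, anion, coefficients) {
  w <- coefficients$weights
  total <- coefficients$intercept
  for (pat in names(w)) {
    total <- total + w[[pat]] * (count_smarts(cation, pat) + count_smarts(anion, pat))
  }
  total
}

logistic <- function(z) 1 / (1 + exp(-z))

condition_ranges <- function(property) {
  switch(property,
    viscosity = list(T = c(283, 343), P = c(101.325, 101.325)),
    co2_capacity = list(T = c(283, 343), P = c(50, 500)),
    list(T = c(298.15, 298.15), P = c(101.325, 101.325))
  )
}

#' Generate a synthetic property dataset
#'
#' Samples ion pairs from a library and measurement conditions from
#' documented ranges (T in \[283, 343\] K and P in \[50, 500\] kPa where the
#' property depends on them), then computes
#' `value = intercept + sum(w_s * count(s)) + w_T (T - 298.15) +
#' w_P (P - 101.325) + N(0, noise_sd)`; for `co2_capacity` the linear value
#' (noise included) is squashed through the logistic map to stay in
#' \[0, 1\]. The noiseless ground truth is returned in `.truth` for oracle
#' tests.
#'
#' @param library A library from [generate_ion_library()].
#' @param spec The [generator_spec()] (its seed drives sampling and noise).
#' @param n_records Number of measurement records.
#' @param include_truth Keep the `.truth` column.
#' @return An `il_dataset`.
#' @export
generate_property_dataset <- function(library, spec, n_records = 400L,
                                      include_truth = TRUE) {
  stopifnot(inherits(spec, "il_generator_spec"))
  if (!length(library$cations) || !length(library$anions)) {
    stop_value("Library is empty.")
  }
  for (pat in names(spec$coefficients$weights)) {
    ok <- tryCatch({count_smarts(library$cations[1L], pat); TRUE},
                   error = function(e) FALSE)
    if (!ok) stop_value(paste0("Coefficient SMARTS not countable: ", pat))
  }
  rng <- condition_ranges(spec$property)
  dat <- with_seed(spec$seed, {
    ci <- sample.int(length(library$cations), n_records, replace = TRUE)
    ai <- sample.int(length(library$anions), n_records, replace = TRUE)
    tibble::tibble(
      pair_id = sprintf("il%04d", seq_len(n_records)),
      cation_smiles = library$cations[ci],
      anion_smiles = library$anions[ai],
      temperature_K = stats::runif(n_records, rng$T[1], rng$T[2]),
      pressure_kPa = stats::runif(n_records, rng$P[1], rng$P[2]),
      noise = stats::rnorm(n_records, 0, spec$noise_sd)
    )
  })
  key <- paste(dat$cation_smiles, dat$anion_smiles, sep = ".")
  lin_pair <- vapply(unique(key), function(k) {
    parts <- strsplit(k, ".", fixed = TRUE)[[1L]]
    # anion may itself contain dots in principle; rejoin all but first part
    truth_linear(parts[1L], paste(parts[-1L], collapse = "."),
                 spec$coefficients)
  }, numeric(1))
  lin <- unname(lin_pair[key])
  cw <- spec$condition_weights
  lin <- lin + (cw[["temperature_K"]] %||% 0) * (dat$temperature_K - 298.15) +
    (cw[["pressure_kPa"]] %||% 0) * (dat$pressure_kPa - 101.325)
  if (spec$property == "co2_capacity") {
    dat$value <- logistic(lin + dat$noise)
    dat$.truth <- logistic(lin)
  } else {
    dat$value <- lin + dat$noise
    dat$.truth <- lin
  }
  dat$noise <- NULL
  if (!include_truth) dat$.truth <- NULL
  new_il_dataset(dat, spec$property)
}
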