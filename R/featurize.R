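# The vector representations of an ion pair: hashed circular substructure
# fingerprints (count and binary variants) and physicochemical descriptor
# vectors, plus measurement-condition attachment.

#' Featurizer configuration
#'
#' Bundles the settings of all four featurizers. The `scheme_tag` derived from
#' a config is embedded in every trained model and checked at prediction time
#' so that a model can never silently be applied to features from a different
#' scheme.
#'
#' @param fp_bits Buckets per ion for the hashed circular fingerprint.
#' @param fp_radius Maximum circular-environment radius (bonds).
#' @param descriptor_version Identifier of the descriptor list.
#' @param image_px Side length (pixels) of the square depiction canvas.
#' @param image_augment `"off"` (deterministic) or `"rotations"` (4-fold
#'   right-angle rotation augmentation, applied at training time only).
#' @return An object of class `il_featurizer_config`.
#' @export
featurizer_config <- function(fp_bits = 1024L, fp_radius = 2L,
                              descriptor_version = "v1",
                              image_px = 128L,
                              image_augment = c("off", "rotations")) {
  image_augment <- match.arg(image_augment)
  if (image_px < 16L) stop_value("Depiction canvas must be at least 16 px.")
  structure(
    list(fp_bits = as.integer(fp_bits), fp_radius = as.integer(fp_radius),
         descriptor_version = descriptor_version,
         image_px = as.integer(image_px), image_augment = image_augment),
    class = "il_featurizer_config"
  )
}

#' Scheme tag of a featurizer configuration
#'
#' @param config An `il_featurizer_config`.
#' @param representation One of `"bmf"`, `"cmf"`, `"md"`, `"mi"`, `"mg"`.
#' @return A single string identifying featurizer + settings.
#' @export
scheme_tag <- function(config, representation) {
  switch(representation,
    bmf = sprintf("bmf-r%d-b%d", config$fp_radius, config$fp_bits),
    cmf = sprintf("cmf-r%d-b%d", config$fp_radius, config$fp_bits),
    md = sprintf("md-%s", config$descriptor_version),
    mi = sprintf("mi-%dpx", config$image_px),
    mg = "mg-v1",
    stop_value(paste0("Unknown representation '", representation, "'."))
  )
}

# --- circular count fingerprint --------------------------------------------

# Morgan-style environment identifiers for one molecule: every atom
# contributes one identifier per radius 0..r; identifiers are hashed strings
# built from the atom invariant (element, degree, charge, ring membership)
# and, iteratively, the sorted (bond order, neighbour identifier) multiset.
mol_environment_ids <- function(mol, radius) {
  atoms <- mol$atoms
  ids <- hash_string(paste(atoms$element, atoms$degree, atoms$charge,
                           as.integer(atoms$in_ring), sep = ","))
  nb <- vector("list", mol$n_atoms)
  if (mol$n_bonds > 0) {
    for (i in seq_len(mol$n_bonds)) {
      a <- mol$bonds$a1[i]; b <- mol$bonds$a2[i]; o <- mol$bonds$order[i]
      nb[[a]] <- rbind(nb[[a]], c(b, o))
      nb[[b]] <- rbind(nb[[b]], c(a, o))
    }
  }
  all_ids <- ids
  cur <- ids
  for (r in seq_len(radius)) {
    nxt <- vapply(seq_len(mol$n_atoms), function(i) {
      if (is.null(nb[[i]])) return(hash_string(paste0("t:", cur[i])))
      env <- paste0(nb[[i]][, 2L], ":", cur[nb[[i]][, 1L]])
      hash_string(paste0(cur[i], "|", paste(sort(env), collapse = "|")))
    }, numeric(1))
    all_ids <- c(all_ids, nxt)
    cur <- nxt
  }
  all_ids
}

ion_count_fp <- function(smiles, config) {
  key <- paste0("cfp|", scheme_tag(config, "cmf"), "|", smiles)
  cache_get_or(key, function() {
    mol <- parse_mol(smiles)
    ids <- mol_environment_ids(mol, config$fp_radius)
    bucket <- (ids %% config$fp_bits) + 1L
    v <- numeric(config$fp_bits)
    for (b in bucket) v[b] <- v[b] + 1
    v
  })
}

featurize_pairs_fp <- function(data, config, binary = FALSE) {
  n <- nrow(data)
  out <- matrix(0, n, 2L * config$fp_bits)
  for (i in seq_len(n)) {
    cv <- ion_count_fp(data$cation_smiles[i], config)
    av <- ion_count_fp(data$anion_smiles[i], config)
    out[i, ] <- c(cv, av)
  }
  if (binary) out <- pmin(out, 1)
  colnames(out) <- c(sprintf("cat_fp%04d", seq_len(config$fp_bits)),
                     sprintf("an_fp%04d", seq_len(config$fp_bits)))
  rownames(out) <- data$pair_id
  out
}

#' Count (C-MF) and binary (B-MF) substructure fingerprints of ion pairs
#'
#' A hashed circular substructure fingerprint: each heavy atom contributes
#' one environment identifier per radius 0..`fp_radius`, built from the atom
#' invariant (element, degree, formal charge, ring membership) and its
#' neighbourhood; identifiers are hashed into `fp_bits` buckets per ion and
#' occurrences counted. Cation and anion are hashed separately and the two
#' sub-vectors concatenated, preserving ion identity. The binary variant is
#' the elementwise `min(count, 1)` of the count variant.
#'
#' @param data A tibble with `pair_id`, `cation_smiles`, `anion_smiles`.
#' @param config An [featurizer_config()].
#' @return A numeric matrix, rows = pairs (rownames `pair_id`), columns =
#'   `2 * fp_bits` fingerprint buckets.
#' @export
count_fingerprint <- function(data, config = featurizer_config()) {
  featurize_pairs_fp(data, config, binary = FALSE)
}

#' @rdname count_fingerprint
#' @export
binary_fingerprint <- function(data, config = featurizer_config()) {
  featurize_pairs_fp(data, config, binary = TRUE)
}

# --- descriptor vector ------------------------------------------------------

# Per-ion descriptor list, version "v1": 8 OpenBabel physicochemical
# descriptors (MW, logP, TPSA, MR, HBA1, HBA2, HBD, nF) and 10 constitutional
# / topological descriptors computed from the heavy-atom graph.
ion_descriptors <- function(smiles) {
  key <- paste0("desc|v1|", smiles)
  cache_get_or(key, function() {
    mol <- parse_mol(smiles)
    el <- mol$atoms$element
    phys <- ob_properties(smiles)
    topo <- c(
      n_heavy = mol$n_atoms,
      n_bonds = mol$n_bonds,
      n_rings = mol$n_bonds - mol$n_atoms +
        length(unique(component_labels(mol))),
      n_C = sum(el == "C"), n_N = sum(el == "N"), n_O = sum(el == "O"),
      n_S = sum(el == "S"),
      n_halogen = sum(el %in% c("F", "Cl", "Br", "I")),
      net_charge = mol$net_charge,
      max_degree = if (mol$n_atoms) max(mol$atoms$degree) else 0
    )
    v <- c(phys, topo)
    v[!is.finite(v)] <- 0
    v
  })
}

component_labels <- function(mol) {
  if (mol$n_bonds == 0) return(seq_len(mol$n_atoms))
  g <- igraph::graph_from_edgelist(cbind(mol$bonds$a1, mol$bonds$a2),
                                   directed = FALSE)
  if (igraph::vcount(g) < mol$n_atoms) {
    g <- igraph::add_vertices(g, mol$n_atoms - igraph::vcount(g))
  }
  igraph::components(g)$membership
}

#' Physicochemical descriptor vector (MD) of ion pairs
#'
#' A fixed, versioned list of 18 two-dimensional descriptors per ion
#' (OpenBabel MW, logP, TPSA, molar refractivity, H-bond acceptor/donor
#' counts, fluorine count, plus constitutional and topological counts from
#' the heavy-atom graph), computed for cation and anion separately and
#' concatenated. Descriptors that are undefined for a molecule are imputed
#' as 0.
#'
#' @inheritParams count_fingerprint
#' @return A numeric matrix, rows = pairs, 36 columns.
#' @export
descriptor_vector <- function(data, config = featurizer_config()) {
  n <- nrow(data)
  rows <- lapply(seq_len(n), function(i) {
    c(ion_descriptors(data$cation_smiles[i]), ion_descriptors(data$anion_smiles[i]))
  })
  out <- do.call(rbind, rows)
  colnames(out) <- c(paste0("cat_", names(rows[[1]])[seq_len(ncol(out) / 2)]),
                     paste0("an_", names(rows[[1]])[seq_len(ncol(out) / 2)]))
  rownames(out) <- data$pair_id
  out
}

# --- measurement conditions -------------------------------------------------

#' Conditions required by a property
#'
#' Viscosity depends on temperature; CO2 absorption capacity on temperature
#' and pressure; refractive index and log EC50 are treated as condition-free
#' targets (reference conditions are applied uniformly when needed).
#'
#' @param property One of [il_properties()].
#' @return Character vector: subset of `c("temperature_K", "pressure_kPa")`.
#' @export
condition_requirements <- function(property) {
  switch(match.arg(property, il_properties()),
    viscosity = "temperature_K",
    co2_capacity = c("temperature_K", "pressure_kPa"),
    character()
  )
}

# Standardisation of condition coordinates (documented, fixed):
# (T - 298.15) / 30 K, (P - 101.325) / 100 kPa.
standardize_conditions <- function(conditions, wanted) {
  out <- NULL
  if ("temperature_K" %in% wanted) {
    out <- cbind(out, temperature_K = (conditions$temperature_K - 298.15) / 30)
  }
  if ("pressure_kPa" %in% wanted) {
    out <- cbind(out, pressure_kPa = (conditions$pressure_kPa - 101.325) / 100)
  }
  out
}

#' Attach standardized measurement conditions to a feature matrix
#'
#' Appends the standardized condition coordinates a property requires to a
#' vector-representation feature matrix. For condition-free properties the
#' matrix is returned unchanged. Image and graph representations take
#' conditions through a parallel scalar channel inside their models, not
#' here; passing them raises a contract error.
#'
#' @param features A numeric feature matrix (rows = samples).
#' @param conditions A tibble with `temperature_K` and/or `pressure_kPa`
#'   columns, one row per sample (or one row, recycled).
#' @param property One of [il_properties()].
#' @return The feature matrix with 0, 1 or 2 extra columns.
#' @export
attach_conditions <- function(features, conditions, property) {
  if (!is.matrix(features)) {
    stop_contract(paste0(
      "`attach_conditions()` applies to vector representations only; ",
      "image and graph models take conditions via their scalar side-channel."))
  }
  wanted <- condition_requirements(property)
  if (!length(wanted)) return(features)
  if (nrow(conditions) == 1L && nrow(features) > 1L) {
    conditions <- conditions[rep(1L, nrow(features)), , drop = FALSE]
  }
  if (nrow(conditions) != nrow(features)) {
    stop_contract("`conditions` must have one row per sample.")
  }
  check_conditions(conditions$temperature_K %||% 298.15,
                   conditions$pressure_kPa %||% 101.325)
  cbind(features, standardize_conditions(conditions, wanted))
}
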