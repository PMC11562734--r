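# Cross-product "non-IL" out-of-distribution benchmark: pair pools of
# arbitrary molecules exhaustively, apply the trained suite under uniform
# reference conditions, and count how many candidates each uncertainty
# method flags as unreliable.

#' Exhaustive cross product of two molecule pools
#'
#' Every (cation-like, anion-like) combination exactly once, in
#' deterministic lexicographic order of the sorted input pools. Charge
#' validation is deliberately not applied: the benchmark probes molecules
#' outside the ionic-liquid domain.
#'
#' @param cations,anions Character vectors of SMILES with unique entries.
#' @return A tibble: `pair_id`, `cation_smiles`, `anion_smiles`.
#' @export
generate_cross_pairs <- function(cations, anions) {
  if (!length(cations) || !length(anions)) {
    stop_value("Both pools must be non-empty.")
  }
  if (anyDuplicated(cations)) stop_value("Duplicate entries in the cation pool.")
  if (anyDuplicated(anions)) stop_value("Duplicate entries in the anion pool.")
  cations <- sort(cations)
  anions <- sort(anions)
  grid <- expand.grid(anion_smiles = anions, cation_smiles = cations,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  tibble::tibble(
    pair_id = sprintf("x%05d", seq_len(nrow(grid))),
    cation_smiles = grid$cation_smiles,
    anion_smiles = grid$anion_smiles
  )
}

#' Assemble replicate out-of-distribution benchmark groups
#'
#' Each group is the full cross product of a seeded random sub-sample
#' (without replacement within a group; groups are independent draws and may
#' overlap) of the two pools, with uniform reference conditions attached.
#' Defaults mirror a 5 x (100 x 100) = 5 x 10 000 candidate benchmark.
#'
#' @param cation_pool,anion_pool Character vectors of SMILES.
#' @param n_groups Number of replicate groups.
#' @param cations_per_group,anions_per_group Sub-sample sizes.
#' @param seed Integer seed.
#' @param conditions One-row tibble of conditions applied uniformly.
#' @return A tibble with a `group` column plus the columns of
#'   [generate_cross_pairs()] and the condition columns.
#' @export
assemble_benchmark <- function(cation_pool, anion_pool, n_groups = 5L,
                               cations_per_group = 100L,
                               anions_per_group = 100L, seed = 1L,
                               conditions = reference_conditions()) {
  if (anyDuplicated(cation_pool) || anyDuplicated(anion_pool)) {
    stop_value("Pools must not contain duplicates.")
  }
  if (length(cation_pool) < cations_per_group ||
      length(anion_pool) < anions_per_group) {
    stop_value("Pool too small for the requested per-group sample.")
  }
  check_conditions(conditions$temperature_K, conditions$pressure_kPa)
  groups <- with_seed(seed, {
    lapply(seq_len(n_groups), function(g) {
      cats <- sample(cation_pool, cations_per_group)
      ans <- sample(anion_pool, anions_per_group)
      out <- generate_cross_pairs(cats, ans)
      out$pair_id <- sprintf("g%d_%s", g, out$pair_id)
      out$group <- g
      out
    })
  })
  out <- dplyr::bind_rows(groups)
  out$temperature_K <- conditions$temperature_K
  out$pressure_kPa <- conditions$pressure_kPa
  out
}

#' Count unreliable predictions per uncertainty method and group
#'
#' For each requested method (each representation's MU and/or RU), computes
#' the candidate uncertainties group by group, flags candidates whose
#' uncertainty exceeds the method's threshold, and tallies the counts plus
#' their mean over groups.
#'
#' @param suite An `il_suite`.
#' @param groups A benchmark tibble from [assemble_benchmark()] (must carry a
#'   `group` column).
#' @param thresholds Named list of [calibrate_threshold()] results: one per
#'   requested method, names from `methods`.
#' @param methods Character vector of methods: `"RU"` and/or representation
#'   codes for MU (default `c("cmf", "md", "mg", "RU")`, the reported trio of
#'   MUs plus RU).
#' @return An object of class `il_discrimination`: `by_group` (tibble
#'   method x group with `n_candidates`, `n_flagged`) and `means` (tibble
#'   method, `mean_flagged`).
#' @export
evaluate_discrimination <- function(suite, groups, thresholds,
                                    methods = c("cmf", "md", "mg", "RU")) {
  missing_thr <- setdiff(methods, names(thresholds))
  if (length(missing_thr)) {
    stop_contract(paste0("No threshold supplied for method(s): ",
                         paste(missing_thr, collapse = ", ")))
  }
  bad <- setdiff(methods, c("RU", names(suite$variant_sets)))
  if (length(bad)) {
    stop_contract(paste0("Unknown method(s): ", paste(bad, collapse = ", "),
                         " (use 'RU' or a representation with a variant set)."))
  }
  gids <- unique(groups$group)
  rows <- list()
  for (g in gids) {
    gdat <- groups[groups$group == g, , drop = FALSE]
    for (m in methods) {
      prof <- if (identical(m, "RU")) {
        representation_uncertainty(suite, gdat)
      } else {
        model_uncertainty(suite$variant_sets[[m]], gdat)
      }
      flags <- flag_unreliable(prof, thresholds[[m]])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        method = m, group = g, n_candidates = nrow(gdat),
        n_flagged = sum(flags$unreliable)
      )
    }
  }
  by_group <- dplyr::bind_rows(rows)
  means <- dplyr::summarise(dplyr::group_by(by_group, .data$method),
                            mean_flagged = mean(.data$n_flagged),
                            .groups = "drop")
  structure(list(by_group = by_group, means = means),
            class = "il_discrimination")
}

#' @export
print.il_discrimination <- function(x, ...) {
  cat("<il_discrimination> mean unreliable-candidate counts by method:\n")
  print(as.data.frame(x$means), row.names = FALSE)
  invisible(x)
}

#' Tidy an OOD-discrimination result
#'
#' @param x An `il_discrimination`.
#' @param ... Unused.
#' @return The per-(method, group) count tibble.
#' @method tidy il_discrimination
#' @export
tidy.il_discrimination <- function(x, ...) x$by_group
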