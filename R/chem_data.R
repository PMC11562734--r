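# Data model and I/O for ion pairs, measurement conditions and property
# datasets.  A dataset is a tibble with one row per measurement:
#   pair_id, cation_smiles, anion_smiles, temperature_K, pressure_kPa,
#   value, property, split
# plus optional columns (e.g. `.truth` from the synthetic generator).

#' Supported property names
#'
#' Canonical units: viscosity is modelled as log10 of the viscosity in
#' mPa s (it spans orders of magnitude); `log_ec50` is the log-transformed
#' half-maximal effective concentration (higher = less toxic);
#' `refractive_index` is dimensionless (> 1); `co2_capacity` is the
#' equilibrium CO2 uptake as a mole fraction in \[0, 1\].
#'
#' @return Character vector of property names.
#' @export
il_properties <- function() {
  c("viscosity", "log_ec50", "refractive_index", "co2_capacity")
}

#' Reference measurement conditions
#'
#' Room temperature and standard ambient pressure, applied uniformly when a
#' condition-dependent property is predicted without measured conditions.
#'
#' @return A one-row tibble with `temperature_K = 298.15` and
#'   `pressure_kPa = 101.325`.
#' @export
reference_conditions <- function() {
  tibble::tibble(temperature_K = 298.15, pressure_kPa = 101.325)
}

check_conditions <- function(temperature_K, pressure_kPa) {
  if (any(!is.finite(temperature_K)) || any(temperature_K <= 0)) {
    stop_validation("`temperature_K` must be finite and > 0.")
  }
  if (any(!is.finite(pressure_kPa)) || any(pressure_kPa <= 0)) {
    stop_validation("`pressure_kPa` must be finite and > 0.")
  }
  invisible(TRUE)
}

#' Parse and validate a cation.anion SMILES pair
#'
#' Splits a dot-separated SMILES string into its two components, parses both
#' with OpenBabel, canonicalises them, and checks the ionic-charge rules.
#' In strict mode (default) the first component must carry net formal charge
#' exactly +1 and the second exactly -1, matching 1:1 ionic liquids; in
#' permissive mode any (+, -) pair whose charges sum to zero is accepted.
#' With `validate_charges = FALSE` the charge rules are skipped entirely
#' (used for deliberately out-of-domain candidates).
#'
#' @param text A SMILES string `"cation.anion"` with exactly one top-level dot.
#' @param pair_id Identifier for the pair; defaults to the input text.
#' @param strict If `TRUE`, require charges exactly +1 / -1.
#' @param validate_charges If `FALSE`, skip charge validation.
#' @return A one-row tibble: `pair_id`, `cation_smiles`, `anion_smiles`
#'   (canonical), `cation_charge`, `anion_charge`.
#' @examples
#' \donttest{
#' parse_ion_pair("[NH4+].[Cl-]")
#' }
#' @export
parse_ion_pair <- function(text, pair_id = NULL, strict = TRUE,
                           validate_charges = TRUE) {
  stopifnot(is.character(text), length(text) == 1L)
  parts <- strsplit(text, ".", fixed = TRUE)[[1L]]
  if (length(parts) != 2L || any(!nzchar(parts))) {
    stop_parse("Expected exactly one component-separating dot: 'cation.anion'.")
  }
  cat_mol <- parse_mol(parts[1L])
  an_mol <- parse_mol(parts[2L])
  if (validate_charges) {
    if (strict) {
      if (cat_mol$net_charge != 1L) {
        stop_validation(paste0(
          "Cation net formal charge must be +1 (got ", cat_mol$net_charge, ")."))
      }
      if (an_mol$net_charge != -1L) {
        stop_validation(paste0(
          "Anion net formal charge must be -1 (got ", an_mol$net_charge, ")."))
      }
    } else {
      if (cat_mol$net_charge <= 0) {
        stop_validation("Cation net formal charge must be positive.")
      }
      if (an_mol$net_charge >= 0) {
        stop_validation("Anion net formal charge must be negative.")
      }
      if (cat_mol$net_charge + an_mol$net_charge != 0) {
        stop_validation("Cation and anion charges must sum to zero.")
      }
    }
  }
  tibble::tibble(
    pair_id = pair_id %||% text,
    cation_smiles = cat_mol$smiles,
    anion_smiles = an_mol$smiles,
    cation_charge = cat_mol$net_charge,
    anion_charge = an_mol$net_charge
  )
}

# Vectorised validation used by read_dataset() and the benchmark assembler.
# Returns the input with `.valid` and `.reason` columns appended.
validate_ion_pairs <- function(data, strict = TRUE, validate_charges = TRUE) {
  stopifnot(all(c("cation_smiles", "anion_smiles") %in% names(data)))
  res <- purrr::map2(data$cation_smiles, data$anion_smiles, function(c_smi, a_smi) {
    tryCatch({
      row <- parse_ion_pair(paste0(c_smi, ".", a_smi), strict = strict,
                            validate_charges = validate_charges)
      list(valid = TRUE, reason = NA_character_,
           cation = row$cation_smiles, anion = row$anion_smiles)
    }, ilscreen_error = function(e) {
      list(valid = FALSE, reason = conditionMessage(e),
           cation = NA_character_, anion = NA_character_)
    })
  })
  data$.valid <- vapply(res, `[[`, logical(1), "valid")
  data$.reason <- vapply(res, `[[`, character(1), "reason")
  ok <- data$.valid
  data$cation_smiles[ok] <- vapply(res[ok], `[[`, character(1), "cation")
  data$anion_smiles[ok] <- vapply(res[ok], `[[`, character(1), "anion")
  data
}

check_property_values <- function(value, property) {
  switch(property,
    co2_capacity = is.finite(value) & value >= 0 & value <= 1,
    refractive_index = is.finite(value) & value > 1,
    is.finite(value)
  )
}

new_il_dataset <- function(data, property) {
  property <- match.arg(property, il_properties())
  data$property <- property
  if (!"split" %in% names(data)) data$split <- "unassigned"
  if (anyDuplicated(data$pair_id)) {
    # measurement rows may share an ion pair (different conditions); row ids
    # must still be unique
    data$pair_id <- make.unique(data$pair_id, sep = "#")
  }
  class(data) <- c("il_dataset", class(tibble::tibble()))
  data
}

#' Read a property dataset from CSV
#'
#' Expects columns `cation_smiles`, `anion_smiles`, `temperature_K`,
#' `pressure_kPa`, `value` (renameable via `column_map`), plus optional
#' `pair_id` and `split`. Rows whose SMILES fail parsing or charge validation,
#' or whose value violates the property's range invariant, are skipped with a
#' message reporting the count.
#'
#' @param path CSV file path.
#' @param property One of [il_properties()].
#' @param column_map Optional named character vector mapping expected column
#'   names to the file's column names, e.g. `c(value = "visc_log10")`.
#' @param strict Passed to [parse_ion_pair()].
#' @return An `il_dataset` tibble.
#' @export
read_dataset <- function(path, property, column_map = NULL, strict = TRUE) {
  property <- match.arg(property, il_properties())
  if (!file.exists(path)) stop_value(paste0("File not found: ", path))
  raw <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                           check.names = FALSE))
  needed <- c("cation_smiles", "anion_smiles", "temperature_K", "pressure_kPa", "value")
  if (!is.null(column_map)) {
    for (nm in names(column_map)) {
      if (!column_map[[nm]] %in% names(raw)) {
        stop_schema(paste0("Mapped column '", column_map[[nm]], "' not in file."))
      }
      names(raw)[names(raw) == column_map[[nm]]] <- nm
    }
  }
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    stop_schema(paste0("Missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!"pair_id" %in% names(raw)) {
    raw$pair_id <- sprintf("row%04d", seq_len(nrow(raw)))
  }
  raw <- validate_ion_pairs(raw, strict = strict)
  ok_value <- check_property_values(raw$value, property) &
    is.finite(raw$temperature_K) & raw$temperature_K > 0 &
    is.finite(raw$pressure_kPa) & raw$pressure_kPa > 0
  keep <- raw$.valid & ok_value
  n_skip <- sum(!keep)
  if (n_skip > 0) {
    message(n_skip, " row(s) skipped (invalid SMILES, charge rule, or value range).")
  }
  out <- raw[keep, c("pair_id", "cation_smiles", "anion_smiles",
                     "temperature_K", "pressure_kPa", "value",
                     intersect("split", names(raw)))]
  if (nrow(out) == 0L) stop_value("No valid rows in file.")
  new_il_dataset(out, property)
}

#' Write a property dataset to CSV
#'
#' Round-trips with [read_dataset()]: all text fields and the split labels are
#' preserved exactly, numeric fields to full double precision.
#'
#' @param data An `il_dataset` (or compatible tibble with a `property` column).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  if (nrow(data) == 0L) stop_value("Refusing to write an empty dataset.")
  cols <- c("pair_id", "cation_smiles", "anion_smiles",
            "temperature_K", "pressure_kPa", "value", "split")
  stopifnot(all(cols %in% c(names(data), "split")))
  if (!"split" %in% names(data)) data$split <- "unassigned"
  df <- as.data.frame(data[, cols])
  # full-precision numerics so the round trip is bit-faithful
  for (nm in c("temperature_K", "pressure_kPa", "value")) {
    df[[nm]] <- format(df[[nm]], digits = 17, scientific = FALSE, trim = TRUE)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Split a dataset into train and test partitions
#'
#' Uniform random split without stratification; the test size is
#' `round(test_fraction * n)`. The same seed always yields the same split.
#'
#' @param data An `il_dataset`.
#' @param test_fraction Fraction in (0, 1); default 0.2.
#' @param seed Integer seed.
#' @return A list with elements `train` and `test`, both `il_dataset`s with
#'   their `split` column set.
#' @export
split_dataset <- function(data, test_fraction = 0.2, seed = 1L) {
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1) {
    stop_value("`test_fraction` must lie strictly between 0 and 1.")
  }
  n <- nrow(data)
  if (n < 5L) stop_value("Need at least 5 records to split.")
  n_test <- round(test_fraction * n)
  idx_test <- with_seed(seed, sample.int(n, n_test))
  data$split <- "train"
  data$split[idx_test] <- "test"
  list(
    train = data[data$split == "train", , drop = FALSE],
    test = data[data$split == "test", , drop = FALSE]
  )
}

#' Flag duplicate measurements
#'
#' Marks rows that repeat an earlier (cation, anion, temperature, pressure)
#' combination. Duplicates are kept by default; pass the result through
#' `dplyr::filter(!is_duplicate)` to deduplicate explicitly.
#'
#' @param data A dataset tibble.
#' @return `data` with a logical `is_duplicate` column appended.
#' @export
flag_duplicate_records <- function(data) {
  key <- paste(data$cation_smiles, data$anion_smiles,
               data$temperature_K, data$pressure_kPa, sep = "|")
  data$is_duplicate <- duplicated(key)
  data
}
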