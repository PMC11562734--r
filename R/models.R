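# Training and applying the per-representation regressors.

.il_representations <- c("bmf", "cmf", "md", "mi", "mg")

#' Representation codes
#'
#' `"bmf"`/`"cmf"`: binary/count substructure fingerprint; `"md"`: descriptor
#' vector; `"mi"`: 2D depiction image; `"mg"`: molecular graph. The
#' representation-uncertainty quartet is `c("cmf", "md", "mi", "mg")` — the
#' binary fingerprint is a baseline that the count variant supersedes.
#'
#' @return Character vector of representation codes.
#' @export
il_representations <- function() .il_representations

#' Construct a hyperparameter variant
#'
#' @param name Unique name within a variant set.
#' @param ... Model-family parameters (trees: `max_depth`, `learning_rate`,
#'   `nrounds`; image: `n_filters`, `patch`, `stride`, `lambda`; graph:
#'   `hidden`, `layers`, `lambda`).
#' @return A list of class `il_variant`.
#' @export
hyperparameter_variant <- function(name, ...) {
  structure(list(name = name, params = list(...)), class = "il_variant")
}

#' Default four-variant hyperparameter sets
#'
#' Four variants per model family, used both for model selection and for the
#' model-uncertainty (MU) spread: trees vary depth and learning rate, the
#' convolutional regressor varies filter count and ridge penalty, the
#' message-passing regressor varies hidden size, depth and ridge penalty.
#'
#' @param representation One of [il_representations()].
#' @return A list of four `il_variant`s.
#' @export
default_variants <- function(representation) {
  representation <- match.arg(representation, .il_representations)
  if (representation %in% c("bmf", "cmf", "md")) {
    list(
      hyperparameter_variant("tree_d4_lr10", max_depth = 4L, learning_rate = 0.1, nrounds = 200L),
      hyperparameter_variant("tree_d6_lr10", max_depth = 6L, learning_rate = 0.1, nrounds = 200L),
      hyperparameter_variant("tree_d8_lr05", max_depth = 8L, learning_rate = 0.05, nrounds = 300L),
      hyperparameter_variant("tree_d4_lr30", max_depth = 4L, learning_rate = 0.3, nrounds = 100L)
    )
  } else if (representation == "mi") {
    list(
      hyperparameter_variant("conv_f64_l1", n_filters = 64L, lambda = 1e-1),
      hyperparameter_variant("conv_f96_l1", n_filters = 96L, lambda = 1e-1),
      hyperparameter_variant("conv_f64_l03", n_filters = 64L, lambda = 3e-2),
      hyperparameter_variant("conv_f96_l03", n_filters = 96L, lambda = 3e-2)
    )
  } else {
    list(
      hyperparameter_variant("mp_h16_d2", hidden = 16L, layers = 2L, lambda = 1e-2),
      hyperparameter_variant("mp_h32_d2", hidden = 32L, layers = 2L, lambda = 1e-2),
      hyperparameter_variant("mp_h16_d3", hidden = 16L, layers = 3L, lambda = 1e-1),
      hyperparameter_variant("mp_h32_d3", hidden = 32L, layers = 3L, lambda = 1e-3)
    )
  }
}

# Seed for the fixed random weights of an image/graph model: derived from the
# training seed and the variant name, kept below 2^31.
weight_seed <- function(seed, variant_name) {
  (as.numeric(seed) * 1009 + hash_string(variant_name) %% 1009) %% 2147483647
}

conditions_of <- function(data, property) {
  wanted <- condition_requirements(property)
  out <- reference_conditions()[rep(1L, nrow(data)), ]
  for (nm in intersect(wanted, names(data))) out[[nm]] <- data[[nm]]
  out
}

# Design matrix for the vector representations (fingerprints/descriptors +
# standardized conditions); image/graph models build theirs internally.
vector_design <- function(data, representation, config, property) {
  X <- switch(representation,
    bmf = binary_fingerprint(data, config),
    cmf = count_fingerprint(data, config),
    md = descriptor_vector(data, config)
  )
  attach_conditions(X, conditions_of(data, property), property)
}

side_channel <- function(data, property) {
  wanted <- condition_requirements(property)
  if (!length(wanted)) return(NULL)
  standardize_conditions(conditions_of(data, property), wanted)
}

model_features <- function(model, data) {
  rep <- model$representation
  if (rep %in% c("bmf", "cmf", "md")) {
    return(vector_design(data, rep, model$config, model$property))
  }
  p <- model$variant$params
  if (rep == "mi") {
    imgs <- render_image(data, model$config)
    X <- mi_design(imgs, p$n_filters %||% 64L, model$weight_seed)
  } else {
    graphs <- build_graphs(data)
    X <- mp_features(graphs, p$hidden %||% 16L, p$layers %||% 2L,
                     model$weight_seed)
  }
  sc <- side_channel(data, model$property)
  if (!is.null(sc)) X <- cbind(X, sc)
  X
}

#' Train one representation model
#'
#' Fits the model family of the given representation (gradient-boosted trees
#' for the vector representations, the convolutional random-feature ridge
#' regressor for images, the message-passing random-feature ridge regressor
#' for graphs) on a training dataset. Deterministic given (data, variant,
#' seed). Training-set RMSE/MAE/R-squared are recorded in `training_meta`.
#'
#' @param train An `il_dataset` with at least 20 records.
#' @param representation One of [il_representations()].
#' @param variant An [hyperparameter_variant()]; default: first of
#'   [default_variants()].
#' @param seed Integer seed.
#' @param config An [featurizer_config()].
#' @return An object of class `il_model`.
#' @export
train_model <- function(train, representation, variant = NULL, seed = 1L,
                        config = featurizer_config()) {
  representation <- match.arg(representation, .il_representations)
  if (nrow(train) < 20L) stop_value("Need at least 20 training records.")
  property <- unique(train$property)
  if (length(property) != 1L) stop_contract("Training data mixes properties.")
  variant <- variant %||% default_variants(representation)[[1L]]
  model <- structure(
    list(representation = representation, property = property,
         variant = variant, config = config,
         scheme_tag = scheme_tag(config, representation),
         seed = as.integer(seed),
         weight_seed = weight_seed(seed, variant$name)),
    class = "il_model"
  )
  y <- train$value
  if (representation == "mi" && config$image_augment == "rotations") {
    X <- model_features_augmented(model, train)
    y <- rep(y, 4L)
  } else {
    X <- model_features(model, train)
  }
  if (representation %in% c("bmf", "cmf", "md")) {
    model$fit <- fit_xgb(X, y, variant$params, seed)
    model$fit_kind <- "xgb"
  } else {
    model$fit <- fit_ridge(X, y, variant$params$lambda %||% 1e-2)
    model$fit_kind <- "ridge"
  }
  pred <- predict_model_values(model, train)
  if (!all(is.finite(pred))) stop_value("Training produced non-finite predictions.")
  metrics <- suppressWarnings(evaluate_predictions(train$value, pred))
  model$training_meta <- list(n_train = nrow(train),
                              rmse = metrics$rmse, mae = metrics$mae,
                              r_squared = metrics$r_squared)
  model
}

# 4-fold rotation augmentation for image training.
model_features_augmented <- function(model, data) {
  p <- model$variant$params
  imgs <- render_image(data, model$config)
  blocks <- lapply(0:3, function(k) {
    rot <- imgs
    for (i in seq_len(dim(imgs)[1L])) rot[i, , ] <- rotate_raster(imgs[i, , ], k)
    mi_design(rot, p$n_filters %||% 64L, model$weight_seed)
  })
  X <- do.call(rbind, blocks)
  sc <- side_channel(data, model$property)
  if (!is.null(sc)) X <- cbind(X, do.call(rbind, rep(list(sc), 4L)))
  X
}

# Fast prediction path: assumes `data` rows are already-validated pairs.
predict_model_values <- function(model, data) {
  X <- model_features(model, data)
  if (model$fit_kind == "xgb") predict_xgb(model$fit, X) else predict_ridge(model$fit, X)
}

#' Predict with a trained representation model
#'
#' Order-preserving; rows whose SMILES cannot be parsed get `NA` predictions
#' with the failure reason in `.note` rather than failing the batch. Missing
#' condition columns fall back to [reference_conditions()].
#'
#' @param object An `il_model`.
#' @param newdata A tibble with `cation_smiles`, `anion_smiles`, optional
#'   `pair_id` and condition columns.
#' @param check_scheme Set `FALSE` to override the featurizer scheme-tag
#'   guard (not recommended).
#' @param ... Unused.
#' @return A tibble: `pair_id`, `.pred`, `.note`.
#' @export
predict.il_model <- function(object, newdata, check_scheme = TRUE, ...) {
  if (check_scheme && !identical(object$scheme_tag,
                                 scheme_tag(object$config, object$representation))) {
    stop_contract("Model scheme_tag does not match its featurizer config.")
  }
  if (!"pair_id" %in% names(newdata)) {
    newdata$pair_id <- sprintf("cand%04d", seq_len(nrow(newdata)))
  }
  if (nrow(newdata) == 0L) {
    return(tibble::tibble(pair_id = character(), .pred = numeric(),
                          .note = character()))
  }
  chk <- validate_ion_pairs(newdata, validate_charges = FALSE)
  out <- tibble::tibble(pair_id = newdata$pair_id, .pred = NA_real_,
                        .note = chk$.reason)
  ok <- chk$.valid
  if (any(ok)) {
    out$.pred[ok] <- predict_model_values(object, chk[ok, , drop = FALSE])
  }
  out
}

#' Train the four-variant set of one representation
#'
#' Trains four independent models sharing one featurizer scheme, differing
#' only in hyperparameters — the ingredients of the model-uncertainty (MU)
#' spread.
#'
#' @inheritParams train_model
#' @param variants Exactly four [hyperparameter_variant()]s with distinct
#'   names.
#' @return A named list of four `il_model`s.
#' @export
train_variant_set <- function(train, representation, variants = NULL,
                              seed = 1L, config = featurizer_config()) {
  representation <- match.arg(representation, .il_representations)
  variants <- variants %||% default_variants(representation)
  if (length(variants) != 4L) {
    stop_value("A model-uncertainty variant set needs exactly 4 variants.")
  }
  nms <- vapply(variants, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop_value("Variant names must be unique.")
  models <- lapply(variants, function(v) {
    train_model(train, representation, v, seed = seed, config = config)
  })
  names(models) <- nms
  models
}

#' Suite configuration
#'
#' @param representations Representations entering the suite (the RU quartet
#'   by default).
#' @param variants Optional named list (per representation) of variant lists;
#'   defaults to [default_variants()].
#' @param featurizer An [featurizer_config()].
#' @param internal_split Fraction of the training set held out internally for
#'   variant selection.
#' @return A list of class `il_suite_config`.
#' @export
suite_config <- function(representations = c("cmf", "md", "mi", "mg"),
                         variants = NULL,
                         featurizer = featurizer_config(),
                         internal_split = 0.2) {
  structure(list(representations = representations, variants = variants,
                 featurizer = featurizer, internal_split = internal_split),
            class = "il_suite_config")
}

#' Train a model suite for one property
#'
#' For each representation: the four hyperparameter variants are fitted on an
#' internal training split, scored on the held-out internal validation split,
#' and the variant with the lowest validation RMSE is selected; all four
#' variants are then refitted on the full training set (these form the MU
#' variant set) and the selected variant's full-data refit becomes the
#' representation's best model. The four best models (one per representation)
#' are the ingredients of representation uncertainty and of the equal-weight
#' ensemble.
#'
#' @param train An `il_dataset`.
#' @param config An [suite_config()].
#' @param seed Integer seed governing the internal split and all model fits.
#' @return An object of class `il_suite`: `best_models`, `variant_sets`,
#'   `selection` (per-variant internal-validation RMSE table), `property`,
#'   `config`, `seed`.
#' @export
train_suite <- function(train, config = suite_config(), seed = 1L) {
  property <- unique(train$property)
  if (length(property) != 1L) stop_contract("Training data mixes properties.")
  n <- nrow(train)
  n_val <- max(1L, round(config$internal_split * n))
  idx_val <- with_seed(seed, sample.int(n, n_val))
  inner_train <- train[-idx_val, , drop = FALSE]
  inner_val <- train[idx_val, , drop = FALSE]
  best_models <- list()
  variant_sets <- list()
  selection <- list()
  for (rep in config$representations) {
    variants <- (config$variants[[rep]] %||% default_variants(rep))
    inner_models <- train_variant_set(inner_train, rep, variants, seed = seed,
                                      config = config$featurizer)
    val_rmse <- vapply(inner_models, function(m) {
      pred <- predict_model_values(m, inner_val)
      sqrt(mean((inner_val$value - pred)^2))
    }, numeric(1))
    best_name <- names(val_rmse)[which.min(val_rmse)]
    full_models <- train_variant_set(train, rep, variants, seed = seed,
                                     config = config$featurizer)
    variant_sets[[rep]] <- full_models
    best_models[[rep]] <- full_models[[best_name]]
    selection[[rep]] <- tibble::tibble(
      representation = rep, variant = names(val_rmse),
      validation_rmse = unname(val_rmse), selected = names(val_rmse) == best_name
    )
  }
  structure(
    list(property = property, best_models = best_models,
         variant_sets = variant_sets,
         selection = dplyr::bind_rows(selection),
         config = config, seed = as.integer(seed), n_train = n),
    class = "il_suite"
  )
}

#' @export
print.il_model <- function(x, ...) {
  cat("<il_model> ", x$representation, " / ", x$property,
      " | variant ", x$variant$name,
      " | train RMSE ", signif(x$training_meta$rmse, 4),
      " (n = ", x$training_meta$n_train, ")\n", sep = "")
  invisible(x)
}

#' @export
print.il_suite <- function(x, ...) {
  cat("<il_suite> property:", x$property, "| n_train:", x$n_train, "\n")
  cat("best variants:",
      paste(names(x$best_models),
            vapply(x$best_models, function(m) m$variant$name, character(1)),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' Glance at a trained model
#'
#' @param x An `il_model`.
#' @param ... Unused.
#' @return One-row tibble with representation, variant and training metrics.
#' @method glance il_model
#' @export
glance.il_model <- function(x, ...) {
  tibble::tibble(
    representation = x$representation, property = x$property,
    variant = x$variant$name, n_train = x$training_meta$n_train,
    rmse = x$training_meta$rmse, mae = x$training_meta$mae,
    r_squared = x$training_meta$r_squared
  )
}

#' Tidy a model suite
#'
#' One row per trained model in the suite (best models and variant sets) with
#' training metrics and selection status.
#'
#' @param x An `il_suite`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy il_suite
#' @export
tidy.il_suite <- function(x, ...) {
  rows <- purrr::imap(x$variant_sets, function(models, rep) {
    dplyr::bind_rows(lapply(models, glance))
  })
  out <- dplyr::bind_rows(rows)
  dplyr::left_join(out, x$selection, by = c("representation", "variant"))
}

#' Glance at a model suite
#'
#' @param x An `il_suite`.
#' @param ... Unused.
#' @return One-row tibble summarising the suite.
#' @method glance il_suite
#' @export
glance.il_suite <- function(x, ...) {
  tibble::tibble(
    property = x$property, n_train = x$n_train, seed = x$seed,
    n_representations = length(x$best_models),
    representations = paste(names(x$best_models), collapse = ",")
  )
}
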