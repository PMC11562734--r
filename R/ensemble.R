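# Equal-weight four-model ensemble, evaluation metrics, range-stratified
# error, and permutation feature importance.

#' Equal-weight ensemble prediction
#'
#' The weighted arithmetic mean of the four best representation models'
#' predictions; the default weights are equal (1/4 each), and the result
#' equals the `mean` column of [representation_uncertainty()].
#'
#' @param suite An `il_suite`.
#' @param data Candidate tibble (valid pairs).
#' @param weights Four non-negative weights summing to 1.
#' @return A tibble: `pair_id`, per-representation predictions
#'   (`pred_cmf`, ...), `.pred` (the ensemble mean).
#' @export
ensemble_predict <- function(suite, data, weights = rep(1 / 4, 4L)) {
  need <- c("cmf", "md", "mi", "mg")
  if (!all(need %in% names(suite$best_models))) {
    stop_contract("Suite is missing one of the four representations.")
  }
  if (length(weights) != 4L || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-8) {
    stop_value("`weights` must be 4 non-negative values summing to 1.")
  }
  P <- member_matrix(suite$best_models[need], data)
  out <- tibble::tibble(pair_id = data$pair_id)
  for (i in seq_along(need)) out[[paste0("pred_", need[i])]] <- P[, i]
  out$.pred <- as.numeric(P %*% weights)
  out
}

#' Regression evaluation metrics
#'
#' RMSE, MAE and R-squared (1 - SS_res / SS_tot). When the truth has zero
#' variance R-squared is undefined and reported as `NA` with a warning.
#'
#' @param truth Numeric vector of observed values.
#' @param estimate Numeric vector of predictions, same length (>= 2).
#' @return A one-row tibble: `rmse`, `mae`, `r_squared`, `n`.
#' @export
evaluate_predictions <- function(truth, estimate) {
  if (length(truth) != length(estimate) || length(truth) < 2L) {
    stop_value("`truth` and `estimate` must have equal length >= 2.")
  }
  if (any(!is.finite(truth)) || any(!is.finite(estimate))) {
    stop_value("Metrics require finite values.")
  }
  err <- truth - estimate
  ss_tot <- sum((truth - mean(truth))^2)
  r2 <- if (ss_tot == 0) {
    warning("Zero variance in `truth`: R-squared is undefined.", call. = FALSE)
    NA_real_
  } else {
    1 - sum(err^2) / ss_tot
  }
  tibble::tibble(
    rmse = sqrt(mean(err^2)),
    mae = mean(abs(err)),
    r_squared = r2,
    n = length(truth)
  )
}

#' RMSE stratified by ranges of the observed value
#'
#' Samples are binned on `truth` into half-open bins `[lo, hi)` (last bin
#' closed) defined by strictly increasing edges; per-bin RMSE is reported,
#' `NA` for empty bins.
#'
#' @inheritParams evaluate_predictions
#' @param bin_edges Strictly increasing numeric vector of bin edges.
#' @return A tibble: `bin` (label), `lo`, `hi`, `n`, `rmse`.
#' @export
stratified_rmse <- function(truth, estimate, bin_edges) {
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    stop_value("`bin_edges` must be strictly increasing.")
  }
  k <- length(bin_edges) - 1L
  purrr::map_dfr(seq_len(k), function(i) {
    lo <- bin_edges[i]; hi <- bin_edges[i + 1L]
    inb <- if (i == k) truth >= lo & truth <= hi else truth >= lo & truth < hi
    tibble::tibble(
      bin = paste0("[", lo, ", ", hi, if (i == k) "]" else ")"),
      lo = lo, hi = hi, n = sum(inb),
      rmse = if (any(inb)) sqrt(mean((truth[inb] - estimate[inb])^2)) else NA_real_
    )
  })
}

#' Global permutation feature importance of a vector-representation model
#'
#' The mean increase in RMSE on an evaluation set when one feature column is
#' shuffled (`n_repeats` seeded permutations), ranked descending. Supports
#' fingerprint and descriptor models only; the direction of each top
#' feature's effect is reported as the sign of the correlation between the
#' feature and the model prediction (a documented heuristic, not a causal
#' claim).
#'
#' @param model An `il_model` with a vector representation.
#' @param data Evaluation dataset (>= 20 records) with a `value` column.
#' @param seed Integer seed for the permutations.
#' @param n_repeats Permutations per feature.
#' @param top_k Keep the `top_k` highest-importance features (default 8);
#'   `Inf` keeps all.
#' @return A tibble: `feature`, `importance`, `direction`, `rank`.
#' @export
global_importance <- function(model, data, seed = 1L, n_repeats = 5L,
                              top_k = 8L) {
  if (!model$representation %in% c("bmf", "cmf", "md")) {
    stop_contract("Permutation importance supports vector representations only.")
  }
  if (nrow(data) < 20L) stop_value("Need at least 20 evaluation records.")
  X <- model_features(model, data)
  y <- data$value
  base_pred <- if (model$fit_kind == "xgb") predict_xgb(model$fit, X) else predict_ridge(model$fit, X)
  base_rmse <- sqrt(mean((y - base_pred)^2))
  # skip constant (never-set) columns: shuffling them is a no-op
  varying <- which(apply(X, 2L, function(col) any(col != col[1L])))
  imp <- with_seed(seed, {
    vapply(varying, function(j) {
      deltas <- vapply(seq_len(n_repeats), function(r) {
        Xp <- X
        Xp[, j] <- X[sample.int(nrow(X)), j]
        pred <- if (model$fit_kind == "xgb") predict_xgb(model$fit, Xp) else predict_ridge(model$fit, Xp)
        sqrt(mean((y - pred)^2)) - base_rmse
      }, numeric(1))
      mean(deltas)
    }, numeric(1))
  })
  direction <- vapply(varying, function(j) {
    r <- suppressWarnings(stats::cor(X[, j], base_pred))
    if (!is.finite(r)) 0 else sign(r)
  }, numeric(1))
  out <- tibble::tibble(
    feature = colnames(X)[varying],
    importance = imp,
    direction = direction
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$importance))
  out$rank <- seq_len(nrow(out))
  if (is.finite(top_k)) out <- out[seq_len(min(top_k, nrow(out))), ]
  out
}
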