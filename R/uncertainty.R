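# Model uncertainty (MU), representation uncertainty (RU), reliability
# thresholds and flags.
#
# MU: the standard deviation of the predictions of four models that share a
# representation and differ only in hyperparameters. RU: the standard
# deviation of the predictions of the four best models built on the four
# different representations. Both use the sample standard deviation
# (divisor n - 1) by default; the population convention is available and,
# being a fixed rescaling, is threshold-neutral.

member_sd <- function(P, sd_mode) {
  if (sd_mode == "sample") {
    apply(P, 1L, stats::sd)
  } else {
    sqrt(apply(P, 1L, function(r) mean((r - mean(r))^2)))
  }
}

member_matrix <- function(models, data) {
  P <- vapply(models, function(m) predict_model_values(m, data),
              numeric(nrow(data)))
  if (is.null(dim(P))) P <- matrix(P, nrow = 1L)
  P
}

profile_tibble <- function(data, P, kind, source, sd_mode) {
  tibble::tibble(
    pair_id = data$pair_id,
    members = I(asplit(P, 1L)),
    mean = rowMeans(P),
    sd = member_sd(P, sd_mode),
    kind = kind,
    source = source
  )
}

#' Model uncertainty (MU) of predictions
#'
#' @param models A list of exactly four `il_model`s sharing one
#'   representation and featurizer scheme (e.g. from [train_variant_set()] or
#'   a suite's `variant_sets`).
#' @param data Candidate tibble (`pair_id`, SMILES, optional condition
#'   columns); rows must be valid molecules.
#' @param sd_mode `"sample"` (divisor n-1, default) or `"population"`.
#' @return A tibble with one row per candidate: `pair_id`, `members`
#'   (list-column of the four member predictions), `mean`, `sd`,
#'   `kind = "MU"`, `source` (the representation).
#' @export
model_uncertainty <- function(models, data, sd_mode = c("sample", "population")) {
  sd_mode <- match.arg(sd_mode)
  if (length(models) != 4L) stop_contract("MU requires exactly 4 models.")
  reps <- unique(vapply(models, `[[`, character(1), "representation"))
  tags <- unique(vapply(models, `[[`, character(1), "scheme_tag"))
  if (length(reps) != 1L || length(tags) != 1L) {
    stop_contract("MU models must share one representation and scheme_tag.")
  }
  P <- member_matrix(models, data)
  profile_tibble(data, P, "MU", reps, sd_mode)
}

#' Representation uncertainty (RU) of predictions
#'
#' The spread of the four best models built on the count-fingerprint,
#' descriptor, image and graph representations. The stored `mean` is the
#' equal-weight ensemble prediction.
#'
#' @param suite An `il_suite` with all four best models.
#' @inheritParams model_uncertainty
#' @return A tibble as in [model_uncertainty()] with `kind = "RU"`,
#'   `source = "cross-representation"`, plus one `pred_<rep>` column per
#'   representation.
#' @export
representation_uncertainty <- function(suite, data,
                                       sd_mode = c("sample", "population")) {
  sd_mode <- match.arg(sd_mode)
  need <- c("cmf", "md", "mi", "mg")
  if (!all(need %in% names(suite$best_models))) {
    stop_contract(paste0("Suite is missing representation(s): ",
                         paste(setdiff(need, names(suite$best_models)), collapse = ", ")))
  }
  P <- member_matrix(suite$best_models[need], data)
  out <- profile_tibble(data, P, "RU", "cross-representation", sd_mode)
  for (i in seq_along(need)) out[[paste0("pred_", need[i])]] <- P[, i]
  out
}

#' Calibrate a reliability threshold from training uncertainties
#'
#' Threshold I is the maximal training uncertainty (deems every training
#' prediction reliable); threshold II is the Tukey upper fence
#' Q3 + 1.5 x IQR of the training uncertainties (treats outlying
#' uncertainties as unreliable). Quartiles use linear interpolation between
#' order statistics (R quantile type 7). Threshold II is the default used
#' throughout the screening pipeline.
#'
#' @param uncertainties Numeric vector of training-set uncertainty values
#'   (>= 4, finite, non-negative), or a profile tibble from
#'   [model_uncertainty()] / [representation_uncertainty()] whose `sd` column
#'   is used (and whose `kind` is recorded for the flagging guard).
#' @param kind `"II"` (default) or `"I"`.
#' @return An object of class `il_threshold`: `kind`, `value`,
#'   `calibration_stats` (`q1`, `q3`, `iqr`, `max`, `n`) and, when known,
#'   `uncertainty_kind`.
#' @export
calibrate_threshold <- function(uncertainties, kind = c("II", "I")) {
  kind <- match.arg(kind)
  u_kind <- NA_character_
  if (is.data.frame(uncertainties)) {
    u_kind <- unique(uncertainties$kind) %||% NA_character_
    if (length(u_kind) != 1L) u_kind <- NA_character_
    uncertainties <- uncertainties$sd
  }
  if (length(uncertainties) < 4L) {
    stop_value("Need at least 4 uncertainty values to calibrate.")
  }
  if (any(!is.finite(uncertainties)) || any(uncertainties < 0)) {
    stop_value("Uncertainties must be finite and non-negative.")
  }
  q <- stats::quantile(uncertainties, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2L] - q[1L]
  value <- if (kind == "I") max(uncertainties) else q[2L] + 1.5 * iqr
  structure(
    list(kind = kind, value = value,
         uncertainty_kind = u_kind,
         calibration_stats = list(q1 = q[1L], q3 = q[2L], iqr = iqr,
                                  max = max(uncertainties),
                                  n = length(uncertainties))),
    class = "il_threshold"
  )
}

#' @export
print.il_threshold <- function(x, ...) {
  cat("<il_threshold> kind ", x$kind, ": ", signif(x$value, 6),
      " (calibrated on n = ", x$calibration_stats$n,
      if (!is.na(x$uncertainty_kind)) paste0(", ", x$uncertainty_kind) else "",
      ")\n", sep = "")
  invisible(x)
}

#' Tidy a reliability threshold
#'
#' @param x An `il_threshold`.
#' @param ... Unused.
#' @return A one-row tibble with the threshold and its calibration stats.
#' @method tidy il_threshold
#' @export
tidy.il_threshold <- function(x, ...) {
  s <- x$calibration_stats
  tibble::tibble(kind = x$kind, value = x$value,
                 uncertainty_kind = x$uncertainty_kind,
                 q1 = s$q1, q3 = s$q3, iqr = s$iqr, max = s$max, n = s$n)
}

#' Flag unreliable predictions
#'
#' A prediction is unreliable iff its uncertainty strictly exceeds the
#' threshold (ties are reliable, so a kind-I threshold flags none of its own
#' calibration set). Applying a threshold calibrated on one uncertainty kind
#' (MU/RU) to profiles of the other raises a contract error unless
#' `override = TRUE`.
#'
#' @param profiles A profile tibble (from [model_uncertainty()] or
#'   [representation_uncertainty()]) or a numeric vector of uncertainties.
#' @param threshold An [calibrate_threshold()] result.
#' @param override Allow an MU/RU kind mismatch.
#' @return For a profile tibble: the tibble with a logical `unreliable`
#'   column appended. For a numeric vector: a logical vector.
#' @export
flag_unreliable <- function(profiles, threshold, override = FALSE) {
  stopifnot(inherits(threshold, "il_threshold"))
  if (is.data.frame(profiles)) {
    p_kind <- unique(profiles$kind)
    if (!override && length(p_kind) == 1L && !is.na(threshold$uncertainty_kind) &&
        !identical(p_kind, threshold$uncertainty_kind)) {
      stop_contract(paste0("Threshold was calibrated on ", threshold$uncertainty_kind,
                           " but profiles are ", p_kind,
                           "; pass override = TRUE to force."))
    }
    profiles$unreliable <- profiles$sd > threshold$value
    profiles
  } else {
    profiles > threshold$value
  }
}
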