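# Sequential RU-gated screening: at each stage, candidates with unreliable
# predictions (RU above the stage threshold) are dropped, the remainder are
# filtered on the predicted property in the stated direction, and survivors
# feed the next stage.

#' Property cutoff rules
#'
#' `cutoff_percentile(p)` keeps the best `p` percent of the reliable
#' candidates at a stage (best = lowest prediction under `keep_low`, highest
#' under `keep_high`). `cutoff_absolute(v)` keeps reliable candidates whose
#' prediction is `<= v` (`keep_low`) or `>= v` (`keep_high`); absolute
#' cutoffs make the final survivor set independent of stage order.
#'
#' @param p Percentile in (0, 100).
#' @param value Absolute cutoff value.
#' @return A list of class `il_cutoff`.
#' @export
cutoff_percentile <- function(p) {
  if (!is.numeric(p) || p <= 0 || p >= 100) {
    stop_value("Cutoff percentile must lie strictly between 0 and 100.")
  }
  structure(list(rule = "percentile", p = p), class = "il_cutoff")
}

#' @rdname cutoff_percentile
#' @export
cutoff_absolute <- function(value) {
  if (!is.numeric(value) || !is.finite(value)) {
    stop_value("Absolute cutoff must be a finite number.")
  }
  structure(list(rule = "absolute", value = value), class = "il_cutoff")
}

#' Define a screening stage
#'
#' @param property One of [il_properties()].
#' @param suite An `il_suite` trained for that property, or `NULL` for
#'   precomputed mode (candidates then carry `.pred` and `.ru` columns,
#'   useful for audits and fixtures).
#' @param threshold An RU [calibrate_threshold()] result (kind II default
#'   convention).
#' @param direction `"keep_low"` (viscosity, toxicity screens use the
#'   high-log-EC50-is-safe convention via `keep_high`) or `"keep_high"`.
#' @param cutoff An [cutoff_percentile()] or [cutoff_absolute()] rule.
#' @param conditions Conditions applied to every candidate at this stage.
#' @return A list of class `il_stage`.
#' @export
screening_stage <- function(property, suite = NULL, threshold,
                            direction = c("keep_low", "keep_high"),
                            cutoff = cutoff_percentile(50),
                            conditions = reference_conditions()) {
  property <- match.arg(property, il_properties())
  direction <- match.arg(direction)
  stopifnot(inherits(threshold, "il_threshold"), inherits(cutoff, "il_cutoff"))
  if (!is.null(suite) && !identical(suite$property, property)) {
    stop_contract("Stage suite was trained for a different property.")
  }
  structure(list(property = property, suite = suite, threshold = threshold,
                 direction = direction, cutoff = cutoff,
                 conditions = conditions),
            class = "il_stage")
}

stage_predictions <- function(candidates, stage) {
  if (is.null(stage$suite)) {
    # precomputed mode: property-specific columns win over generic ones
    pc <- paste0(".pred_", stage$property)
    rc <- paste0(".ru_", stage$property)
    if (!pc %in% names(candidates)) pc <- ".pred"
    if (!rc %in% names(candidates)) rc <- ".ru"
    if (!all(c(pc, rc) %in% names(candidates))) {
      stop_contract("Precomputed mode needs `.pred`/`.ru` (or per-property) columns.")
    }
    return(tibble::tibble(pair_id = candidates$pair_id,
                          .pred = candidates[[pc]], .ru = candidates[[rc]]))
  }
  cand <- candidates
  cand$temperature_K <- stage$conditions$temperature_K
  cand$pressure_kPa <- stage$conditions$pressure_kPa
  ru <- representation_uncertainty(stage$suite, cand)
  tibble::tibble(pair_id = cand$pair_id, .pred = ru$mean, .ru = ru$sd)
}

#' Run one screening stage
#'
#' Computes the ensemble prediction and RU for every candidate, drops
#' candidates whose RU exceeds the stage threshold (unreliable), applies the
#' property cutoff to the reliable remainder, and returns survivors ordered
#' by predicted merit. Candidate counts are conserved exactly:
#' inputs = unreliable + cutoff failures + survivors.
#'
#' @param candidates Tibble with `pair_id`, `cation_smiles`, `anion_smiles`
#'   (or `.pred`/`.ru` in precomputed mode).
#' @param stage An [screening_stage()].
#' @return A list: `survivors` (candidate tibble, ordered by merit),
#'   `record` (one-row tibble of stage counts), `audit` (per-candidate
#'   tibble: `pair_id`, `.pred`, `.ru`, `status`).
#' @export
run_stage <- function(candidates, stage) {
  if (nrow(candidates) == 0L) {
    message("Stage '", stage$property, "': empty candidate list.")
    return(list(
      survivors = candidates,
      record = tibble::tibble(property = stage$property, n_input = 0L,
                              n_unreliable = 0L, n_failed = 0L,
                              n_survivors = 0L),
      audit = tibble::tibble(pair_id = character(), .pred = numeric(),
                             .ru = numeric(), status = character())
    ))
  }
  pr <- stage_predictions(candidates, stage)
  unreliable <- flag_unreliable(pr$.ru, stage$threshold)
  keep_low <- stage$direction == "keep_low"
  pass <- rep(FALSE, nrow(pr))
  rel <- which(!unreliable)
  if (length(rel)) {
    if (stage$cutoff$rule == "absolute") {
      v <- stage$cutoff$value
      pass[rel] <- if (keep_low) pr$.pred[rel] <= v else pr$.pred[rel] >= v
    } else {
      n_keep <- ceiling(length(rel) * stage$cutoff$p / 100)
      merit <- if (keep_low) pr$.pred[rel] else -pr$.pred[rel]
      keep_idx <- rel[order(merit)][seq_len(n_keep)]
      pass[keep_idx] <- TRUE
    }
  }
  status <- dplyr::case_when(
    unreliable ~ "unreliable",
    pass ~ "survivor",
    TRUE ~ "failed_cutoff"
  )
  audit <- tibble::tibble(pair_id = pr$pair_id, .pred = pr$.pred,
                          .ru = pr$.ru, status = status)
  surv_idx <- which(status == "survivor")
  merit <- if (keep_low) pr$.pred[surv_idx] else -pr$.pred[surv_idx]
  surv_idx <- surv_idx[order(merit)]
  survivors <- candidates[surv_idx, , drop = FALSE]
  survivors[[paste0("pred_", stage$property)]] <- pr$.pred[surv_idx]
  survivors[[paste0("ru_", stage$property)]] <- pr$.ru[surv_idx]
  record <- tibble::tibble(
    property = stage$property,
    n_input = nrow(candidates),
    n_unreliable = sum(status == "unreliable"),
    n_failed = sum(status == "failed_cutoff"),
    n_survivors = length(surv_idx)
  )
  list(survivors = survivors, record = record, audit = audit)
}

#' Run a sequential multi-property screen
#'
#' Applies the stages in order, each to the previous stage's survivors
#' (candidates in each phase are drawn from the residuals of the previous
#' step), and keeps a full per-candidate audit trail.
#'
#' @param candidates Candidate tibble.
#' @param stages List of [screening_stage()]s with distinct properties.
#' @return An object of class `il_screen_report`: `stages` (per-stage count
#'   tibble), `audit` (candidate x stage status), `survivors` (final
#'   candidate tibble with per-stage predictions).
#' @export
run_sequential_screen <- function(candidates, stages) {
  if (!length(stages)) stop_value("Need at least one screening stage.")
  props <- vapply(stages, `[[`, character(1), "property")
  if (anyDuplicated(props)) stop_value("Stage properties must be distinct.")
  current <- candidates
  records <- list()
  audits <- list()
  for (i in seq_along(stages)) {
    res <- tryCatch(run_stage(current, stages[[i]]), error = function(e) {
      abort_ilscreen(paste0("Stage ", i, " (", props[i], "): ",
                            conditionMessage(e)), "ilscreen_stage_error")
    })
    records[[i]] <- res$record
    a <- res$audit
    a$stage <- i
    a$property <- props[i]
    audits[[i]] <- a
    current <- res$survivors
  }
  structure(
    list(stages = dplyr::bind_rows(records),
         audit = dplyr::bind_rows(audits),
         survivors = current),
    class = "il_screen_report"
  )
}

#' @export
print.il_screen_report <- function(x, ...) {
  cat("<il_screen_report> ", x$stages$n_input[1L], " candidates -> ",
      utils::tail(x$stages$n_survivors, 1L), " survivors over ",
      nrow(x$stages), " stage(s)\n", sep = "")
  print(as.data.frame(x$stages), row.names = FALSE)
  invisible(x)
}

#' Tidy a screening report
#'
#' @param x An `il_screen_report`.
#' @param ... Unused.
#' @return The per-stage count tibble.
#' @method tidy il_screen_report
#' @export
tidy.il_screen_report <- function(x, ...) x$stages

#' Glance at a screening report
#'
#' @param x An `il_screen_report`.
#' @param ... Unused.
#' @return One-row tibble: initial candidates, stages, final survivors.
#' @method glance il_screen_report
#' @export
glance.il_screen_report <- function(x, ...) {
  tibble::tibble(
    n_candidates = x$stages$n_input[1L],
    n_stages = nrow(x$stages),
    n_survivors = utils::tail(x$stages$n_survivors, 1L)
  )
}
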