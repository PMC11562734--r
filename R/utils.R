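# Internal utilities: classed conditions, RNG isolation, string hashing, caches.

#' @importFrom rlang .data
#' @keywords internal
"_PACKAGE"

abort_ilscreen <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "ilscreen_error"), ...)
}

#' @noRd
stop_parse <- function(msg) abort_ilscreen(msg, "ilscreen_parse_error")
stop_validation <- function(msg) abort_ilscreen(msg, "ilscreen_validation_error")
stop_schema <- function(msg) abort_ilscreen(msg, "ilscreen_schema_error")
stop_contract <- function(msg) abort_ilscreen(msg, "ilscreen_contract_error")
stop_value <- function(msg) abort_ilscreen(msg, "ilscreen_value_error")

# Run `expr` under a local RNG state seeded with `seed`; the caller's RNG
# stream is untouched.  All stochastic operations in the package go through
# this so that a recorded seed fully determines the output.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_value("`seed` must be a single finite number.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Deterministic polynomial string hash into [0, 2^31 - 1].  Used to bucket
# circular-substructure identifiers; stable across platforms (pure double
# arithmetic, all intermediates < 2^53).
hash_string <- function(x) {
  m <- 2147483647
  vapply(x, function(s) {
    h <- 0
    for (code in utf8ToInt(s)) h <- (h * 31 + code) %% m
    h
  }, numeric(1), USE.NAMES = FALSE)
}

# Session-scoped memo cache for per-molecule computations (parsing,
# fingerprints, descriptors, rendered images), keyed by SMILES + scheme.
.ilscreen_cache <- new.env(parent = emptyenv())

cache_get_or <- function(key, compute) {
  if (!is.null(.ilscreen_cache[[key]])) return(.ilscreen_cache[[key]])
  val <- compute()
  .ilscreen_cache[[key]] <- val
  val
}

#' Clear the internal molecule cache
#'
#' Parsed molecules, fingerprints, descriptors and rendered depictions are
#' memoised per session keyed by SMILES and featurizer scheme. Clearing is
#' only needed to bound memory in very long sessions.
#'
#' @return Invisibly, the number of entries removed.
#' @export
clear_molecule_cache <- function() {
  n <- length(ls(.ilscreen_cache))
  rm(list = ls(.ilscreen_cache), envir = .ilscreen_cache)
  invisible(n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
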