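#' @keywords internal
`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate code with a temporarily fixed RNG state
#'
#' Sets the seed (when non-NULL), runs `code`, and restores the caller's
#' `.Random.seed`, so library functions never disturb user-level randomness.
#'
#' @param seed integer seed or NULL (run code with the current RNG state).
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1L) # initialise RNG state so it can be saved
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Derive a deterministic sub-seed from a top-level seed and string labels
#'
#' A single user-facing seed governs a whole run; per-feature sub-seeds are
#' derived from it by hashing the feature label, so that adding, removing or
#' reordering features never changes another feature's result.
#'
#' @param seed integer top-level seed.
#' @param ... character labels (feature id, quantity, comparison label, ...).
#' @return integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, "citrate", "abundance")
derive_seed <- function(seed, ...) {
  labels <- paste(c(...), collapse = "\r")
  h <- 0
  for (code in utf8ToInt(labels)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer((as.numeric(seed) %% 2147483647 + h) %% 2147483647)
}

# Format a numeric for tab-delimited output at full double precision
# (%.17g survives a write/read round trip bit-exactly).
fmt_full <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

# Relative difference robust to zeros.
rel_diff <- function(a, b) {
  den <- pmax(abs(a), abs(b))
  d <- abs(a - b) / den
  d[den == 0] <- 0
  d
}

# Abort with a single aggregated message listing all problems at once.
abort_aggregate <- function(problems, header) {
  stop(paste0(header, ":\n", paste0("  - ", problems, collapse = "\n")),
       call. = FALSE)
}
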