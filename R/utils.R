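#' Derive a child RNG seed from a master seed
#'
#' All randomness in the package flows from a single master seed. Per-plate,
#' per-field and per-table seeds are derived deterministically so that
#' independent stages can be regenerated in isolation and remain
#' bit-reproducible. Derived seeds stay strictly below 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param index nonnegative integer stream index (0 = master stream).
#' @return an integer seed.
#' @export
split_seed <- function(seed, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  stopifnot(is.numeric(index), length(index) == 1L, index >= 0)
  # multiplicative mix modulo a Mersenne prime; keeps values in 32-bit range
  as.integer((abs(seed) %% 2147483647 * 48271 + 1009 * (index + 1)) %% 2147483647)
}

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores the caller's RNG state so generators never perturb
#' user code.
#'
#' @param seed integer seed, or NULL to leave the RNG alone.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Polynomial rolling hash over serialized R object, 8 hex digits.
# Used only for provenance stamping of configs (not cryptographic).
config_hash <- function(object) {
  bytes <- as.integer(serialize(object, connection = NULL, version = 2))
  h <- 17
  m <- 2147483647
  for (b in bytes) h <- (h * 131 + b + 1) %% m
  sprintf("%08x", as.integer(h))
}

#' Row letters for plate coordinates
#'
#' Wells are stored 0-based internally and rendered as letter-number pairs
#' (A01 ... P24 on a 384-well plate) in files.
#'
#' @param row 1-based row indices.
#' @return character row letters.
#' @keywords internal
row_letter <- function(row) LETTERS[row]
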