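# Internal helpers shared across modules.

# Locale-independent character ordering (radix = C collation), so that
# canonical row orderings are reproducible across machines.
c_order <- function(...) order(..., method = "radix")

c_sort <- function(x) x[c_order(x)]

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

msgf <- function(fmt, ...) message(sprintf(fmt, ...))

# Deterministic per-stage seed expansion from one top-level seed.
# Keeps results below .Machine$integer.max for 32-bit RNG seeding.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  offsets <- c(
    ppi = 11L, expression = 23L, descriptors = 37L, responses = 53L,
    cells = 71L, drugs = 89L, rf = 101L, folds = 127L, importance = 151L
  )
  off <- if (stage %in% names(offsets)) offsets[[stage]] else
    sum(utf8ToInt(stage)) %% 1000L
  as.integer((as.integer(seed) * 1009L + off) %% 2147483647L)
}

check_square_dist <- function(D, tol = 1e-9) {
  if (!is.matrix(D) || nrow(D) != ncol(D))
    stopf("distance matrix must be square")
  if (max(abs(D - t(D))) > tol)
    stopf("distance matrix must be symmetric (max asymmetry %.3g)",
          max(abs(D - t(D))))
  if (any(D < -tol)) stopf("distance matrix must be nonnegative")
  if (max(abs(diag(D))) > tol) stopf("distance matrix must have zero diagonal")
  invisible(TRUE)
}
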