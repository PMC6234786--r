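# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's `.Random.seed` afterwards, so seeded package
#' functions never disturb the global random stream.  A `NULL` seed means
#' "use the current stream" (no save/restore).
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed derivation; stays below 2^31 - 1.
derive_seed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) %% 1000003) * 1009 + i) %% 2147483647L
}

# Number of set bits for small non-negative integer masks (< 2^16).
popcount <- function(x) {
  n <- rep.int(0L, length(x))
  x <- as.integer(x)
  while (any(x > 0L)) {
    n <- n + (x %% 2L)
    x <- x %/% 2L
  }
  n
}

# Bitmask -> compact area label ("AD") under an area alphabet.
mask_to_label <- function(mask, alphabet) {
  vapply(mask, function(m) {
    paste(alphabet[bitwAnd(m, bitwShiftL(1L, seq_along(alphabet) - 1L)) > 0L],
          collapse = "")
  }, character(1L))
}

# Compact area label ("AD" or "A,D") -> bitmask; NA for unknown codes.
label_to_mask <- function(label, alphabet) {
  vapply(label, function(s) {
    chars <- strsplit(gsub("[ ,;+]", "", s), "")[[1L]]
    idx <- match(chars, alphabet)
    if (length(chars) == 0L || anyNA(idx)) return(NA_integer_)
    Reduce(bitwOr, bitwShiftL(1L, idx - 1L), accumulate = FALSE)
  }, integer(1L), USE.NAMES = FALSE)
}

# stop() with a condition class, so callers can test errors by class.
stop_drydiv <- function(class, msg, ...) {
  stop(structure(class = c(class, "drydiv_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1L))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
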