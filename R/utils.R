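`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half up to a grid
#'
#' Rounds to the nearest multiple of `step`, with exact halves rounded away
#' from zero-adjacent ties upward (half-up), unlike [round()]'s banker's
#' rounding. Used wherever simulated latent scores are discretized to an
#' instrument's scoring grid.
#'
#' @param x numeric vector.
#' @param step positive grid step (e.g. 1 for integer scales, 0.5 for
#'   half-point scales, 4 for the well-being index).
#' @return `x` rounded to the grid.
#' @export
round_half_up <- function(x, step = 1) {
  stopifnot(is.numeric(step), length(step) == 1L, step > 0)
  floor(x / step + 0.5) * step
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stop_field <- function(field, msg) {
  stop(sprintf("invalid field '%s': %s", field, msg), call. = FALSE)
}

assert_prob <- function(x, field) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop_field(field, "must be probabilities in [0, 1]")
  invisible(x)
}

assert_pos <- function(x, field) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    stop_field(field, "must be positive and finite")
  invisible(x)
}

assert_cols <- function(data, cols) {
  miss <- setdiff(cols, names(data))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  invisible(data)
}

assert_complete <- function(data, cols) {
  assert_cols(data, cols)
  bad <- cols[vapply(data[cols], anyNA, logical(1))]
  if (length(bad))
    stop("columns contain missing values (impute first): ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(data)
}

# deterministic 32-bit FNV-1a hash of a character scalar, as hex
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # multiply by 16777619 mod 2^32 using doubles split to stay exact
    lo <- (h %% 65536) * 16777619
    hi <- ((h %/% 65536) * 16777619) %% 65536
    h <- (lo + hi * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
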