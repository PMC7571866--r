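#' @keywords internal
"_PACKAGE"

# dB floor applied before any log so silent inputs never produce -Inf
DB_FLOOR <- 1e-12

#' Convert a linear amplitude to decibels
#'
#' @param x nonnegative linear amplitude(s)
#' @param floor smallest amplitude considered nonzero; values below are
#'   clamped so the result is finite
#' @return `20 * log10(pmax(x, floor))`
#' @export
amp_to_db <- function(x, floor = DB_FLOOR) {
  20 * log10(pmax(x, floor))
}

#' Convert decibels to a linear amplitude ratio
#'
#' @param db value(s) in dB
#' @return `10^(db / 20)`
#' @export
db_to_amp <- function(db) 10^(db / 20)

#' Root-mean-square of a vector
#' @param x numeric vector
#' @return sqrt(mean(x^2))
#' @export
rms <- function(x) sqrt(mean(x^2))

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. Used so every seeded operation is deterministic and side-effect
# free.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Validation helper: stop with a message naming the offending field.
check_that <- function(ok, field, msg) {
  if (!isTRUE(ok)) stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}
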