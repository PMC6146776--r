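#' @keywords internal
"_PACKAGE"

#' @importFrom stats quantile rbeta rnorm runif sd var
#' @importFrom utils read.csv write.csv
NULL

# Run a block with a private RNG stream seeded from `seed`, restoring the
# caller's .Random.seed afterwards. All synthetic-data randomness flows
# through this; nothing touches the global stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stop_domain <- function(...) stop(..., call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Dice overlap coefficient between two binary masks
#'
#' \code{2|A \& B| / (|A| + |B|)}; returns 1 when both masks are empty.
#'
#' @param a,b logical matrices of identical shape.
#' @return Numeric scalar in \[0, 1\].
#' @export
dice_coefficient <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop_domain("mask shape mismatch")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}
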