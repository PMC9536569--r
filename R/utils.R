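#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the random number generator seeded at `seed`, then
#' restores the caller's RNG state, so seeded helpers do not perturb an
#' enclosing simulation stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# length of the common prefix of two strings (used to split indel alignments)
common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- strsplit(substr(a, 1L, n), "", fixed = TRUE)[[1L]]
  bv <- strsplit(substr(b, 1L, n), "", fixed = TRUE)[[1L]]
  neq <- which(av != bv)
  if (length(neq) == 0L) n else neq[1L] - 1L
}

#' Format a count as a percentage the way a methods section prints it
#'
#' @param n Numerator count.
#' @param total Denominator count.
#' @param digits Decimal digits to keep (0 prints whole percents).
#' @return `round(100 * n / total, digits)`.
#' @examples
#' as_percent(50, 1000)          # 5
#' as_percent(60, 7320, digits = 2)
#' @export
as_percent <- function(n, total, digits = 0) {
  stopifnot(is.numeric(n), is.numeric(total), total > 0)
  round(100 * n / total, digits = digits)
}
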