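# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so library users' random streams are not disturbed.
#' @noRd
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# lower-median convention: for an even number of values take the lower of the
# two central order statistics, so integer depths give integer medians
lower_median <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0L) return(0)
  sort(x)[ceiling(n / 2)]
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# split a DNA character string into codons (any trailing partial codon dropped)
split_codons <- function(s) {
  n <- nchar(s) %/% 3L
  if (n == 0L) return(character(0))
  substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
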