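# shared internal helpers

# the four recognised sample compartments
iso_compartments <- c("fauna", "spom", "spom_trap", "sediment")

#' Round half away from zero for display
#'
#' Reporting layer rounding used throughout the package: per-mil values and
#' trophic positions are carried at full precision internally and rounded to
#' two decimals only for display, using round-half-up (the convention of
#' published isotope tables). `round()` in R rounds half to even and, on
#' doubles, values such as 4.225 are stored fractionally below the half-way
#' point, so a small guard (1e-9) is added before truncation.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 2).
#' @return `x` rounded half away from zero to `digits` decimals.
#' @examples
#' round_half_up(c(4.225, 6.045, -20.955))
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample (n-1) standard deviation; undefined (NA) for a single value
sample_sd <- function(v) {
  v <- v[!is.na(v)]
  if (length(v) < 2L) NA_real_ else stats::sd(v)
}

# evaluate `code` under a fixed RNG seed without disturbing the caller's
# stream; a NULL seed just evaluates the code
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a single finite number")
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
  })
  set.seed(as.integer(seed))
  force(code)
}
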