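## Internal utilities shared across modules.

#' Evaluate an expression with a temporary RNG state
#'
#' Runs `expr` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so generators stay pure functions of (config, seed).
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
  }
  force(expr)
}

#' Signal a classed error
#' @noRd
abort <- function(code, msg, ...) {
  stop(errorCondition(msg, ..., class = c(paste0("hypoxiaNMR_", tolower(code)), "hypoxiaNMR_error", "error", "condition")))
}

#' Robust per-point noise estimate from first differences
#'
#' Successive differences cancel smooth signal; the MAD of the differences
#' divided by sqrt(2) estimates the additive noise standard deviation.
#' @noRd
estimate_noise <- function(y) {
  stats::mad(diff(y)) / sqrt(2)
}

## time point levels used throughout
TIME_POINTS <- c("4h", "24h", "48h")
CONDITIONS <- c("hypoxia", "normoxia")
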