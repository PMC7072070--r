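# internal helpers shared across modules

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded generation does not
#' perturb the caller's stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
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
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# round half away from zero (the convention used for reported percentages)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# round to the nearest half-integer; exact ties go to the nearest even half
# (base round() implements IEC 60559 round-half-even)
round_to_half <- function(x) round(x * 2) / 2

# seeded random DNA with a target GC content
rand_dna <- function(n, gc = 0.35) {
  if (n <= 0) return("")
  at <- (1 - gc) / 2
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c(at, at, gc / 2, gc / 2)),
        collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
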