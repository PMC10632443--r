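# Internal helpers shared across modules.

# Run `code` under a local RNG state seeded with `seed`, restoring the
# caller's stream afterwards so that generators never clobber user RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv(), inherits = FALSE)
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

stop_ecoreact <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "ecoreact_error")))
}

assert_square <- function(M, what = "matrix") {
  if (!is.matrix(M) || !is.numeric(M) || nrow(M) != ncol(M)) {
    stop_ecoreact(what, " must be a square numeric matrix",
                  class = "ecoreact_not_square")
  }
  invisible(M)
}

assert_finite <- function(M, what = "matrix") {
  if (any(!is.finite(M))) {
    stop_ecoreact(what, " contains non-finite entries",
                  class = "ecoreact_nonfinite")
  }
  invisible(M)
}

# Unwrap a community_matrix (or accept a bare matrix).
as_matrix_values <- function(M) {
  if (inherits(M, "community_matrix")) M$values else M
}
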