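#' Interaction-strength distributions
#'
#' Pairwise interaction strengths are built from a base random variable
#' `Z` with mean zero and variance `sigma^2`. Signed interaction types
#' (mutualistic, competitive, exploitative, and the structured food-web
#' generators) draw magnitudes from `|Z|`, so the half-distribution moments
#' matter: the first absolute moment `E(|Z|)` controls how common weak
#' interactions are at fixed variance.
#'
#' Two families are provided:
#' \describe{
#'   \item{`normal`}{`Z ~ N(0, sigma^2)`, so `|Z|` is half-normal with
#'     `E(|Z|) = sigma * sqrt(2/pi)`. This is the default used throughout.}
#'   \item{`gamma`}{`|Z| ~ Gamma(shape, scale)` with the scale chosen so that
#'     `E(Z^2) = sigma^2`, and the sign of `Z` a fair coin. Small `shape`
#'     concentrates mass near zero (weak interactions common), giving a
#'     smaller `E(|Z|)` at the same variance.}
#' }
#'
#' @param sigma Scale of the interaction-strength distribution
#'   (`sqrt(E(Z^2))`), in abundance-rate units. Must be non-negative.
#' @param shape Gamma shape parameter (positive); only for `z_gamma()`.
#' @return An object of class `z_dist`: a list with elements `name`,
#'   `sigma` (the root mean square of `Z`), `e_abs` (`E(|Z|)`), and
#'   `sample_abs(n)`, a function drawing `n` magnitudes `|Z|`.
#' @examples
#' zd <- z_normal(0.1)
#' zd$e_abs                     # 0.1 * sqrt(2/pi)
#' zg <- z_gamma(0.1, shape = 0.5)
#' zg$e_abs < zd$e_abs          # weak interactions more common
#' @export
z_normal <- function(sigma) {
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma >= 0)
  structure(list(
    name = "normal",
    sigma = sigma,
    e_abs = sigma * sqrt(2 / pi),
    sample_abs = function(n) abs(stats::rnorm(n, mean = 0, sd = sigma))
  ), class = "z_dist")
}

#' @rdname z_normal
#' @export
z_gamma <- function(sigma, shape = 1) {
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma >= 0,
            is.numeric(shape), length(shape) == 1L, shape > 0)
  # E(|Z|^2) = shape*(shape+1)*scale^2 = sigma^2
  scale <- sigma / sqrt(shape * (shape + 1))
  structure(list(
    name = "gamma",
    sigma = sigma,
    shape = shape,
    e_abs = shape * scale,
    sample_abs = function(n) stats::rgamma(n, shape = shape, scale = scale)
  ), class = "z_dist")
}

as_z_dist <- function(z_dist, sigma) {
  if (inherits(z_dist, "z_dist")) {
    if (abs(z_dist$sigma - sigma) > 1e-12 * max(1, sigma)) {
      stop_ecoreact("z_dist scale does not match spec sigma",
                    class = "ecoreact_bad_zdist")
    }
    return(z_dist)
  }
  if (is.character(z_dist) && length(z_dist) == 1L && z_dist == "normal") {
    return(z_normal(sigma))
  }
  stop_ecoreact("z_dist must be \"normal\" or a z_dist object",
                class = "ecoreact_bad_zdist")
}

# Draw signed Z values (symmetric about 0) from a z_dist.
sample_z <- function(zd, n) {
  zd$sample_abs(n) * sample(c(-1, 1), n, replace = TRUE)
}
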