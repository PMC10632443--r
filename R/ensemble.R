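#' Ensemble specification for community-matrix generators
#'
#' Bundles the parameters that define a random-community ensemble: the
#' species count `S`, the connectance `C` (probability that an unordered
#' species pair interacts), the interaction-strength scale `sigma`, the
#' homogeneous self-regulation strength `d` placed on the diagonal, the
#' interaction type, and -- for mixed communities -- the proportions of
#' mutualistic (+/+), competitive (-/-) and exploitative (+/-) pairs.
#'
#' @param S Species count, integer `>= 2`.
#' @param C Connectance in `[0, 1]`.
#' @param sigma Interaction-strength scale (`sqrt(E(Z^2))`), `>= 0`.
#' @param d Homogeneous self-regulation strength, `>= 0`; the diagonal of
#'   the generated matrix is `-d`.
#' @param interaction_type One of `"random"`, `"exploitative"`,
#'   `"competitive"`, `"mutualistic"`, `"mixed"`, `"cascade"`, `"niche"`.
#' @param mix Named numeric vector `c(ppp = , pmm = , ppm = )` of pair-type
#'   proportions (mutualistic, competitive, exploitative); must sum to 1.
#'   Required when `interaction_type = "mixed"`, ignored otherwise.
#' @param z_dist `"normal"` (default) or a [z_normal()]/[z_gamma()] object
#'   with scale equal to `sigma`.
#' @param seed Integer seed; the same spec and seed reproduce the matrix
#'   bit-identically.
#' @return An object of class `ensemble_spec`.
#' @seealso [generate_community()], [generate_unstructured()]
#' @export
ensemble_spec <- function(S, C, sigma, d,
                          interaction_type = c("random", "exploitative",
                                               "competitive", "mutualistic",
                                               "mixed", "cascade", "niche"),
                          mix = NULL, z_dist = "normal", seed = 1L) {
  interaction_type <- match.arg(interaction_type)
  if (!is.numeric(S) || length(S) != 1L || S < 2 || S != round(S)) {
    stop_ecoreact("S must be an integer >= 2", class = "ecoreact_bad_spec")
  }
  if (!is.numeric(C) || length(C) != 1L || C < 0 || C > 1) {
    stop_ecoreact("C must lie in [0, 1]", class = "ecoreact_bad_spec")
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0) {
    stop_ecoreact("sigma must be >= 0", class = "ecoreact_bad_spec")
  }
  if (!is.numeric(d) || length(d) != 1L || d < 0) {
    stop_ecoreact("d must be >= 0", class = "ecoreact_bad_spec")
  }
  if (interaction_type == "mixed") {
    if (is.null(mix) || !all(c("ppp", "pmm", "ppm") %in% names(mix))) {
      stop_ecoreact("mixed ensembles need mix = c(ppp=, pmm=, ppm=)",
                    class = "ecoreact_bad_spec")
    }
    mix <- mix[c("ppp", "pmm", "ppm")]
    if (any(mix < 0) || abs(sum(mix) - 1) > 1e-12) {
      stop_ecoreact("mix proportions must be non-negative and sum to 1",
                    class = "ecoreact_bad_mix")
    }
  }
  if (interaction_type == "niche" && (C <= 0 || C >= 1)) {
    stop_ecoreact("niche model requires 0 < C < 1",
                  class = "ecoreact_bad_spec")
  }
  structure(list(
    S = as.integer(S), C = C, sigma = sigma, d = d,
    interaction_type = interaction_type,
    mix = mix,
    z_dist = as_z_dist(z_dist, sigma),
    seed = as.integer(seed)
  ), class = "ensemble_spec")
}

#' @export
print.ensemble_spec <- function(x, ...) {
  cat("Ensemble spec:", x$interaction_type,
      sprintf("(S = %d, C = %g, sigma = %g, d = %g, seed = %d)\n",
              x$S, x$C, x$sigma, x$d, x$seed))
  if (!is.null(x$mix)) {
    cat(sprintf("  mix: P+/+ = %g, P-/- = %g, P+/- = %g\n",
                x$mix[["ppp"]], x$mix[["pmm"]], x$mix[["ppm"]]))
  }
  invisible(x)
}

new_community_matrix <- function(values, spec, diagonal_scheme = NULL,
                                 extra = list()) {
  out <- c(list(values = values, spec = spec,
                diagonal_scheme = diagonal_scheme), extra)
  class(out) <- "community_matrix"
  out
}

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf("Community matrix: %d x %d (%s)\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$spec)) "no spec" else x$spec$interaction_type))
  invisible(x)
}

#' @export
as.matrix.community_matrix <- function(x, ...) x$values
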