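#' Symmetric part of a matrix
#'
#' `H = (M + t(M))/2`. The largest eigenvalue of `H` is the numerical
#' abscissa of `M` and equals its reactivity.
#'
#' @param M Square numeric matrix (or `community_matrix`).
#' @return A symmetric matrix of the same dimension.
#' @export
symmetric_part <- function(M) {
  V <- assert_square(as_matrix_values(M))
  (V + t(V)) / 2
}

#' Reactivity of a community matrix
#'
#' Reactivity is the maximum instantaneous amplification rate of
#' perturbations under the linearised dynamics `dx/dt = M x`:
#' the maximum over initial directions of `d log ||x||_2 / dt` at `t = 0`,
#' which equals the largest eigenvalue of the symmetric part
#' `H = (M + t(M))/2`. The spectral abscissa (max real part of the
#' eigenvalues of `M`) governs asymptotic stability. Since the numerical
#' abscissa dominates the spectral abscissa, an unstable system is always
#' reactive, and the three possible states are `stable_nonreactive`,
#' `stable_reactive` and `unstable`.
#'
#' @param M Square numeric matrix (or `community_matrix`) with finite
#'   entries.
#' @param tol Classification tolerance; defaults to
#'   `1e-9 * max(1, norm(M, "I"))`. Values within `tol` of zero set the
#'   `boundary_flag`.
#' @return An object of class `reactivity_report`: list with `reactivity`,
#'   `spectral_abscissa`, `state` and `boundary_flag`.
#' @examples
#' reactivity(matrix(c(-1, 0, 3, -1), 2))  # stable but reactive
#' @export
reactivity <- function(M, tol = NULL) {
  V <- assert_square(as_matrix_values(M))
  assert_finite(V, "community matrix")
  r <- reactivity_value(V)
  a <- spectral_abscissa(V)
  if (is.null(tol)) tol <- 1e-9 * max(1, norm(V, "I"))
  state <- if (a > tol) {
    "unstable"
  } else if (a < -tol && r > tol) {
    "stable_reactive"
  } else if (a < -tol && r < -tol) {
    "stable_nonreactive"
  } else {
    # on a boundary; classify by sign anyway
    if (a > 0) "unstable" else if (r > 0) "stable_reactive" else "stable_nonreactive"
  }
  boundary <- abs(a) <= tol || abs(r) <= tol
  structure(list(reactivity = r, spectral_abscissa = a,
                 state = state, boundary_flag = boundary),
            class = "reactivity_report")
}

#' @export
print.reactivity_report <- function(x, ...) {
  cat(sprintf("Reactivity %.6g, spectral abscissa %.6g -> %s%s\n",
              x$reactivity, x$spectral_abscissa, x$state,
              if (x$boundary_flag) " (boundary)" else ""))
  invisible(x)
}

#' @rdname reactivity
#' @export
reactivity_value <- function(M) {
  H <- symmetric_part(M)
  max(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
}

#' @rdname reactivity
#' @export
spectral_abscissa <- function(M) {
  V <- assert_square(as_matrix_values(M))
  max(Re(eigen(V, only.values = TRUE)$values))
}

#' Classify the dynamical state of a community matrix
#'
#' Three-region classification combining stability (spectral abscissa) and
#' reactivity: `unstable` if the abscissa exceeds `tol`; otherwise
#' `stable_reactive` if reactivity exceeds `tol`, else
#' `stable_nonreactive`.
#'
#' @inheritParams reactivity
#' @return A character scalar.
#' @export
classify_state <- function(M, tol = NULL) {
  reactivity(M, tol = tol)$state
}

new_spectral_prediction <- function(centre, half_length, outlier, R_pred,
                                    branch, extra = list()) {
  structure(c(list(centre = centre, half_length = half_length,
                   outlier = outlier, R_pred = R_pred, branch = branch),
              extra),
            class = "spectral_prediction")
}

#' @export
print.spectral_prediction <- function(x, ...) {
  cat(sprintf(
    "Predicted reactivity %.6g (branch: %s)\n  segment [%.6g, %.6g]%s\n",
    x$R_pred, x$branch, x$centre - x$half_length, x$centre + x$half_length,
    if (is.na(x$outlier)) "" else sprintf(", outlier %.6g", x$outlier)))
  invisible(x)
}

#' Analytic reactivity prediction for single-type unstructured communities
#'
#' Large-community predictions for the eigenvalue support of
#' `H = (M + t(M))/2` and the resulting reactivity:
#' \describe{
#'   \item{random}{eigenvalues of `H` in a segment of half-length
#'     `sigma * sqrt(2 S C)` centred at `-d`;
#'     `R = -d + sigma * sqrt(2SC)`.}
#'   \item{exploitative}{segment of half-length
#'     `sqrt(2SC (sigma^2 - E(|Z|)^2))` centred at `-d`.}
#'   \item{competitive}{segment centred at `-d + C E(|Z|)` with half-length
#'     `sqrt(2 sigma^2 S C + 2 E(|Z|)^2 S C (1 - 2C))`, plus an outlier
#'     (approximately the row sum of `H`) on the left at
#'     `-d - (S-1) C E(|Z|)`; reactivity is the right segment endpoint.}
#'   \item{mutualistic}{same segment shape centred at `-d - C E(|Z|)` but
#'     the outlier sits on the right at `-d + (S-1) C E(|Z|)` and
#'     determines reactivity.}
#' }
#'
#' @param type One of `"random"`, `"exploitative"`, `"competitive"`,
#'   `"mutualistic"`.
#' @param S,C,sigma,d Ensemble parameters (see [ensemble_spec()]).
#' @param e_abs First absolute moment `E(|Z|)` of the strength
#'   distribution; defaults to the half-normal value
#'   `sigma * sqrt(2/pi)`. Must satisfy `e_abs^2 <= sigma^2`.
#' @return A `spectral_prediction`.
#' @export
predict_unstructured <- function(type = c("random", "exploitative",
                                          "competitive", "mutualistic"),
                                 S, C, sigma, d,
                                 e_abs = sigma * sqrt(2 / pi)) {
  type <- match.arg(type)
  if (e_abs^2 > sigma^2 + 1e-12 * sigma^2) {
    stop_ecoreact("impossible moments: E(|Z|)^2 > sigma^2",
                  class = "ecoreact_bad_moments")
  }
  if (type == "random") {
    half <- sigma * sqrt(2 * S * C)
    return(new_spectral_prediction(-d, half, NA_real_, -d + half, "segment"))
  }
  if (type == "exploitative") {
    half <- sqrt(2 * S * C * (sigma^2 - e_abs^2))
    return(new_spectral_prediction(-d, half, NA_real_, -d + half, "segment"))
  }
  inner <- 2 * sigma^2 * S * C + 2 * e_abs^2 * S * C * (1 - 2 * C)
  stopifnot(inner >= 0)  # guaranteed by e_abs^2 <= sigma^2
  half <- sqrt(inner)
  if (type == "competitive") {
    centre <- -d + C * e_abs
    outlier <- -d - (S - 1) * C * e_abs
    return(new_spectral_prediction(centre, half, outlier,
                                   centre + half, "segment"))
  }
  # mutualistic: reactivity set by the right outlier
  centre <- -d - C * e_abs
  outlier <- -d + (S - 1) * C * e_abs
  new_spectral_prediction(centre, half, outlier, outlier, "outlier")
}

#' Analytic reactivity prediction for mixed-interaction communities
#'
#' From the off-diagonal moments `E`, `V`, `rho` of the community matrix
#' (see [ensemble_moments()]), the eigenvalues of `H` lie in a segment of
#' half-length `sqrt(2 S (V + rho - E^2))` centred at `-d - E`. When
#' `|E| > sqrt((V + rho - E^2) / (2S))` a rank-one outlier detaches at
#' approximately `-d + (S - 1) E` and reactivity is the larger of the
#' segment endpoint and the outlier.
#'
#' @param stats An `interaction_stats` object (or list with `E`, `V`,
#'   `rho`).
#' @param S Species count.
#' @param d Homogeneous self-regulation strength.
#' @return A `spectral_prediction`.
#' @export
predict_mixed <- function(stats, S, d) {
  E <- stats$E; V <- stats$V; rho <- stats$rho
  disc <- V + rho - E^2
  if (disc < 0) {
    stop_ecoreact("V + rho - E^2 must be >= 0",
                  class = "ecoreact_bad_moments")
  }
  centre <- -d - E
  half <- sqrt(2 * S * disc)
  seg_R <- centre + half
  if (abs(E) <= sqrt(disc / (2 * S))) {
    return(new_spectral_prediction(centre, half, NA_real_, seg_R, "segment"))
  }
  outlier <- -d + (S - 1) * E
  R <- max(seg_R, outlier)
  new_spectral_prediction(centre, half, outlier, R,
                          if (R == outlier && outlier > seg_R) "outlier"
                          else "segment")
}

# Stable evaluation of the support-edge bracket
#   (d1+d2)/2 + sqrt(((d2-d1)/2)^2 + 1) + (2/u) atanh(u / sqrt(u^2 + 4)),
# u = d2 - d1. The last term -> 1 as u -> 0; a short series avoids the
# cancellation for tiny u.
edge_bracket <- function(d1, d2) {
  u <- d2 - d1
  tail_term <- if (abs(u) < 1e-8) {
    1 - u^2 / 24
  } else {
    (2 / u) * atanh(u / sqrt(u^2 + 4))
  }
  (d1 + d2) / 2 + sqrt((u / 2)^2 + 1) + tail_term
}

#' Reactivity prediction under heterogeneous self-regulation
#'
#' Self-regulation strengths are uniform on
#' `[d_mean - sqrt(3) sigma_d, d_mean + sqrt(3) sigma_d]` (mean `d_mean`,
#' standard deviation `sigma_d`) instead of a common `-d`. With `omega =
#' sqrt(S (V + rho - E^2) / 2)` and rescaled support endpoints
#' `d1 = (-d_mean - sqrt(3) sigma_d)/omega`,
#' `d2 = (-d_mean + sqrt(3) sigma_d)/omega`, the right edge of the
#' eigenvalue support of `H` gives
#' `R = omega * ((d1+d2)/2 + sqrt(((d2-d1)/2)^2 + 1)
#'      + (2/(d2-d1)) atanh((d2-d1)/sqrt((d2-d1)^2+4))) - E`
#' whenever `|E| <= sqrt((V + rho - E^2)/(2S) + sigma_d^2/S^2)`. Otherwise
#' an outlier competes and `R = max(R1, R2)` with `R1` the edge expression
#' above and
#' `R2 = -d_mean + (S-1) E + (V + rho - E^2)/(2E) + sigma_d^2/(S E)`.
#' The limit `sigma_d -> 0` is removable and reproduces the homogeneous
#' formulas ([predict_mixed()]).
#'
#' @param stats An `interaction_stats` object (for a purely random
#'   ensemble, `E = rho = 0`, `V = C sigma^2`).
#' @param S Species count.
#' @param d_mean,sigma_d Mean and standard deviation of the self-regulation
#'   strengths; requires `d_mean - sqrt(3) sigma_d >= 0`.
#' @return A `spectral_prediction` with `d1`, `d2` and (on the outlier
#'   branch) `R1`, `R2` recorded.
#' @export
predict_heterogeneous <- function(stats, S, d_mean, sigma_d) {
  if (sigma_d < 0) {
    stop_ecoreact("sigma_d must be >= 0", class = "ecoreact_bad_spec")
  }
  if (d_mean - sqrt(3) * sigma_d < 0) {
    stop_ecoreact("self-regulation strengths must be non-negative: ",
                  "require d_mean - sqrt(3)*sigma_d >= 0",
                  class = "ecoreact_negative_selfreg")
  }
  E <- stats$E; V <- stats$V; rho <- stats$rho
  disc <- V + rho - E^2
  if (disc < 0) {
    stop_ecoreact("V + rho - E^2 must be >= 0",
                  class = "ecoreact_bad_moments")
  }
  if (sigma_d == 0) {
    # exact homogeneous limit
    out <- predict_mixed(stats, S, d_mean)
    out$d1 <- out$d2 <- if (disc > 0) -d_mean / sqrt(S * disc / 2) else NA_real_
    return(out)
  }
  omega <- sqrt(S * disc / 2)
  if (omega == 0) {
    # no interactions: diagonal matrix, reactivity is the weakest regulator
    R <- -(d_mean - sqrt(3) * sigma_d)
    return(new_spectral_prediction(-d_mean, 0, NA_real_, R, "diagonal",
                                   extra = list(d1 = NA_real_,
                                                d2 = NA_real_)))
  }
  d1 <- (-d_mean - sqrt(3) * sigma_d) / omega
  d2 <- (-d_mean + sqrt(3) * sigma_d) / omega
  R_edge <- omega * edge_bracket(d1, d2) - E
  if (abs(E) <= sqrt(disc / (2 * S) + sigma_d^2 / S^2)) {
    return(new_spectral_prediction(-d_mean - E, 2 * omega, NA_real_,
                                   R_edge, "segment",
                                   extra = list(d1 = d1, d2 = d2)))
  }
  R2 <- -d_mean + (S - 1) * E + disc / (2 * E) + sigma_d^2 / (S * E)
  R <- max(R_edge, R2)
  new_spectral_prediction(-d_mean - E, 2 * omega,
                          -d_mean + (S - 1) * E, R,
                          if (R2 > R_edge) "outlier" else "segment",
                          extra = list(d1 = d1, d2 = d2,
                                       R1 = R_edge, R2 = R2))
}
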