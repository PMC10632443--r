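#' Critical species-count curves for instability and reactivity
#'
#' For a mixed-interaction ensemble parameterised by the pair-type
#' proportions and the strength distribution, the per-connectance moments
#' are `E(C) = C E(|Z|) (P+/+ - P-/-)`, `V(C) = C sigma^2 - E^2`,
#' `rho(C) = C E(|Z|)^2 (P+/+ + P-/- - P+/-)`. Along the segment branch
#' the critical species counts at connectance `C` are
#' `S_stability = V (d + E)^2 / (V + rho - E^2)^2` and
#' `S_reactivity = (d + E)^2 / (2 (V + rho - E^2))`. When the mean
#' interaction `E` is positive a rank-one outlier can govern both
#' transitions at `S_outlier = d / E + 1`; each returned curve takes the
#' smaller of its segment value and `S_outlier`, so for
#' mutualistic-dominant ensembles both curves coincide (a reactive
#' mutualistic community is always unstable).
#'
#' @param sigma Interaction-strength scale.
#' @param d Self-regulation strength.
#' @param mix Pair-type proportions `c(ppp=, pmm=, ppm=)`; single-type
#'   shortcuts: `"random"`, `"exploitative"`, `"competitive"`,
#'   `"mutualistic"` are also accepted.
#' @param e_abs `E(|Z|)`; default half-normal `sigma * sqrt(2/pi)`.
#' @return A list of class `critical_curves` with functions
#'   `reactivity(C)` and `stability(C)` (vectorised over `C`), each
#'   returning the critical `S`.
#' @export
critical_curves <- function(sigma, d, mix = "random",
                            e_abs = sigma * sqrt(2 / pi)) {
  pr <- mix_proportions(mix)
  moments_at <- function(C) {
    if (is.null(pr)) {
      list(E = rep(0, length(C)), V = C * sigma^2, rho = rep(0, length(C)))
    } else {
      E <- C * e_abs * (pr[["ppp"]] - pr[["pmm"]])
      list(E = E, V = C * sigma^2 - E^2,
           rho = C * e_abs^2 * (pr[["ppp"]] + pr[["pmm"]] - pr[["ppm"]]))
    }
  }
  curve_fun <- function(kind) {
    force(kind)
    function(C) {
      m <- moments_at(C)
      disc <- m$V + m$rho - m$E^2
      if (any(disc <= 0)) {
        stop_ecoreact("degenerate ensemble: V + rho - E^2 <= 0",
                      class = "ecoreact_degenerate")
      }
      seg <- if (kind == "reactivity") {
        (d + m$E)^2 / (2 * disc)
      } else {
        m$V * (d + m$E)^2 / disc^2
      }
      out <- ifelse(m$E > 0, pmin(seg, d / m$E + 1), seg)
      unname(out)
    }
  }
  structure(list(reactivity = curve_fun("reactivity"),
                 stability = curve_fun("stability"),
                 sigma = sigma, d = d, mix = pr, e_abs = e_abs),
            class = "critical_curves")
}

mix_proportions <- function(mix) {
  if (is.character(mix)) {
    return(switch(match.arg(mix, c("random", "exploitative", "competitive",
                                   "mutualistic")),
                  random = NULL,
                  exploitative = c(ppp = 0, pmm = 0, ppm = 1),
                  competitive = c(ppp = 0, pmm = 1, ppm = 0),
                  mutualistic = c(ppp = 1, pmm = 0, ppm = 0)))
  }
  stopifnot(all(c("ppp", "pmm", "ppm") %in% names(mix)))
  mix[c("ppp", "pmm", "ppm")]
}

#' Normalised distance between the reactivity and instability transitions
#'
#' The normalised distance (ND) is the area of the reactive-stable region
#' of the species-count/connectance plane divided by the area of the whole
#' stable region. On the segment branch both critical curves scale the
#' same way with connectance and ND reduces to the closed form
#' `ND = 1 - (1 + r)/2` with the pairwise interaction correlation
#' `r = (rho - E^2) / V`: 1/2 for random ensembles (`r = 0`),
#' `1/2 + 1/pi` for exploitative ensembles with half-normal strengths
#' (`r = -2/pi`), and 0 when a positive mean interaction makes the outlier
#' govern both transitions (mutualistic-dominant ensembles).
#'
#' @param stats An `interaction_stats` object (e.g. [ensemble_moments()]
#'   or [empirical_moments()] output).
#' @param d Self-regulation strength.
#' @param C_range Connectance window, recorded in the result (the analytic
#'   segment-branch value does not depend on it).
#' @return An `nd_result` list with `nd`, `r_corr`, `method`
#'   (`"analytic"`) and `connectance_range`.
#' @export
normalized_distance <- function(stats, d, C_range = c(0.01, 0.5)) {
  if (stats$V <= 0) {
    stop_ecoreact("V must be > 0", class = "ecoreact_degenerate")
  }
  r <- (stats$rho - stats$E^2) / stats$V
  disc <- stats$V + stats$rho - stats$E^2
  nd <- 1 - (1 + r) / 2
  if (stats$E > 0 && disc > 0) {
    # outlier governs both transitions when its critical S is the smaller
    S_seg_react <- (d + stats$E)^2 / (2 * disc)
    S_out <- d / stats$E + 1
    if (S_out <= S_seg_react) nd <- 0
  }
  structure(list(nd = nd, r_corr = r, method = "analytic",
                 connectance_range = C_range),
            class = "nd_result")
}

#' Numeric phase-diagram estimate of the normalised distance
#'
#' Builds a grid over species count (log-spaced over `S_range`) and
#' connectance (log-spaced over `C_range`), generates `n_per_cell`
#' community matrices per cell, classifies each cell by the majority state
#' (ties broken toward the less reactive state), and returns the area of
#' stable-reactive cells over the area of all stable cells. Cell widths
#' are taken on the log-connectance axis; cell heights are linear in `S`
#' with geometric-midpoint boundaries, the bottom cell extending to
#' `S = 0` so that the thin always-stable strip below the smallest grid
#' size is not lost from the stable area.
#'
#' @param spec_template An [ensemble_spec()] whose `S` and `C` are
#'   overridden cell by cell (all other fields, including the seed base,
#'   are kept).
#' @param C_range,S_range Ranges of the grid.
#' @param n_C,n_S Grid resolution (at least 10 each recommended).
#' @param n_per_cell Matrices per cell (>= 10 recommended).
#' @return An `nd_result` with `method = "numeric_area"` plus the cell
#'   classification table (`cells`).
#' @export
area_ratio_numeric <- function(spec_template, C_range, S_range,
                               n_C = 10, n_S = 12, n_per_cell = 10) {
  stopifnot(inherits(spec_template, "ensemble_spec"),
            n_per_cell >= 1, n_C >= 2, n_S >= 2)
  C_grid <- exp(seq(log(C_range[1]), log(C_range[2]), length.out = n_C))
  S_grid <- round(exp(seq(log(max(2, S_range[1])), log(S_range[2]),
                          length.out = n_S)))
  S_grid <- unique(S_grid)
  n_S <- length(S_grid)
  # cell widths on the log-C axis
  logC <- log(C_grid)
  wC <- diff(c(logC[1] - diff(logC[1:2]) / 2,
               logC[-n_C] + diff(logC) / 2,
               logC[n_C] + diff(logC[(n_C - 1):n_C]) / 2))
  # cell heights linear in S, geometric midpoints, bottom cell down to 0
  bnd <- c(0, sqrt(S_grid[-n_S] * S_grid[-1]),
           S_grid[n_S] * sqrt(S_grid[n_S] / S_grid[n_S - 1]))
  hS <- diff(bnd)
  cells <- expand.grid(iS = seq_len(n_S), iC = seq_len(n_C))
  state <- character(nrow(cells))
  for (k in seq_len(nrow(cells))) {
    sp <- spec_template
    sp$S <- S_grid[cells$iS[k]]
    sp$C <- C_grid[cells$iC[k]]
    sp$seed <- spec_template$seed + 7919L * k
    states <- vapply(generate_ensemble(sp, n_per_cell),
                     function(m) classify_state(m$values), character(1))
    tab <- c(stable_nonreactive = sum(states == "stable_nonreactive"),
             stable_reactive = sum(states == "stable_reactive"),
             unstable = sum(states == "unstable"))
    # majority, ties toward the less reactive state (listed order)
    state[k] <- names(tab)[which.max(tab)]
  }
  area <- hS[cells$iS] * wC[cells$iC]
  a_sr <- sum(area[state == "stable_reactive"])
  a_st <- sum(area[state != "unstable"])
  if (a_st == 0) {
    stop_ecoreact("no stable cells in the requested range",
                  class = "ecoreact_no_stable_cells")
  }
  structure(list(nd = a_sr / a_st, r_corr = NA_real_,
                 method = "numeric_area", connectance_range = C_range,
                 cells = data.frame(S = S_grid[cells$iS],
                                    C = C_grid[cells$iC],
                                    state = state, area = area)),
            class = "nd_result")
}

#' @export
print.nd_result <- function(x, ...) {
  cat(sprintf("Normalised distance %.4f (%s)\n", x$nd, x$method))
  invisible(x)
}

#' Ensemble estimate of a critical interaction strength
#'
#' Scans a grid of interaction-strength scales `sigma`, generating
#' `n_replicates` matrices at each, and brackets the phase transition:
#' `sigma1` is the largest grid value at which all replicates are still in
#' the pre-transition state (non-reactive for the reactivity transition,
#' stable for the stability transition), `sigma2` the smallest at which
#' all replicates have crossed, and the critical value is estimated as
#' `sigma_r = (sigma1 + sigma2)/2`.
#'
#' @param spec_template An [ensemble_spec()]; its `sigma` is overridden by
#'   each grid value (the `z_dist` is rescaled accordingly).
#' @param transition `"reactivity"` or `"stability"`.
#' @param sigma_grid Ascending grid of sigma values that must bracket the
#'   transition.
#' @param n_replicates Matrices per grid point (>= 20 recommended).
#' @return A `transition_estimate` with `sigma1`, `sigma2`, `sigma_r`, the
#'   grid and the per-sigma fraction of post-transition communities.
#' @export
critical_sigma <- function(spec_template,
                           transition = c("reactivity", "stability"),
                           sigma_grid, n_replicates = 20) {
  transition <- match.arg(transition)
  stopifnot(inherits(spec_template, "ensemble_spec"),
            !is.unsorted(sigma_grid), n_replicates >= 1)
  frac_post <- vapply(seq_along(sigma_grid), function(g) {
    sp <- spec_template
    sp$sigma <- sigma_grid[g]
    if (sp$z_dist$name == "normal") {
      sp$z_dist <- z_normal(sp$sigma)
    } else {
      sp$z_dist <- z_gamma(sp$sigma, shape = sp$z_dist$shape)
    }
    sp$seed <- spec_template$seed + 104729L * g
    post <- vapply(generate_ensemble(sp, n_replicates), function(m) {
      if (transition == "reactivity") {
        reactivity_value(m$values) > 0
      } else {
        spectral_abscissa(m$values) > 0
      }
    }, logical(1))
    mean(post)
  }, numeric(1))
  post_ok <- which(frac_post == 1)
  first_mixed <- which(frac_post > 0)[1]
  pre_cand <- which(frac_post == 0)
  pre_cand <- pre_cand[is.na(first_mixed) | pre_cand < first_mixed]
  sigma1 <- if (length(pre_cand)) sigma_grid[max(pre_cand)] else NA_real_
  sigma2 <- if (length(post_ok)) sigma_grid[min(post_ok)] else NA_real_
  if (is.na(sigma1) || is.na(sigma2)) {
    stop_ecoreact("transition not bracketed by sigma_grid (fractions: ",
                  paste(signif(frac_post, 3), collapse = ", "), ")",
                  class = "ecoreact_not_bracketed")
  }
  structure(list(sigma1 = sigma1, sigma2 = sigma2,
                 sigma_r = (sigma1 + sigma2) / 2,
                 n_replicates = n_replicates, grid = sigma_grid,
                 fraction_post = frac_post, transition = transition),
            class = "transition_estimate")
}

#' @export
print.transition_estimate <- function(x, ...) {
  cat(sprintf("Critical sigma (%s): %.5g  [sigma1 = %.5g, sigma2 = %.5g]\n",
              x$transition, x$sigma_r, x$sigma1, x$sigma2))
  invisible(x)
}
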