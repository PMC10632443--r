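#' Generate an unstructured community matrix of a single interaction type
#'
#' Every unordered species pair interacts with probability `C`
#' (connectance). For a connected pair `(i, j)` the two directed effects
#' `M[i,j]` and `M[j,i]` are drawn according to the interaction type:
#' \describe{
#'   \item{random}{two independent draws of `Z` (mean 0, variance
#'     `sigma^2`), so the two directions are sign-independent.}
#'   \item{exploitative}{opposite signs: one direction is `+|Z|`, the other
#'     `-|Z|` (independent magnitudes); which species benefits is a fair
#'     coin per pair.}
#'   \item{competitive}{both directions `-|Z|`, independent magnitudes.}
#'   \item{mutualistic}{both directions `+|Z|`, independent magnitudes.}
#' }
#' The diagonal (self-regulation) is set to `-d`.
#'
#' @param spec An [ensemble_spec()] with `interaction_type` one of
#'   `"random"`, `"exploitative"`, `"competitive"`, `"mutualistic"`.
#' @return A `community_matrix` object; `$values` holds the `S x S` matrix.
#' @examples
#' spec <- ensemble_spec(50, 0.2, 0.1, d = 1, "exploitative", seed = 7)
#' M <- generate_unstructured(spec)
#' range(diag(M$values))   # both -1
#' @export
generate_unstructured <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  type <- spec$interaction_type
  if (!type %in% c("random", "exploitative", "competitive", "mutualistic")) {
    stop_ecoreact("generate_unstructured handles single-type ensembles only",
                  class = "ecoreact_bad_type")
  }
  S <- spec$S
  zd <- spec$z_dist
  values <- with_seed(spec$seed, {
    M <- matrix(0, S, S)
    pair_idx <- which(upper.tri(M), arr.ind = TRUE)  # i < j
    connected <- stats::runif(nrow(pair_idx)) < spec$C
    n <- sum(connected)
    if (n > 0L) {
      ii <- pair_idx[connected, 1L]
      jj <- pair_idx[connected, 2L]
      ij <- cbind(ii, jj)
      ji <- cbind(jj, ii)
      if (type == "random") {
        M[ij] <- sample_z(zd, n)
        M[ji] <- sample_z(zd, n)
      } else if (type == "exploitative") {
        a <- zd$sample_abs(n)
        b <- zd$sample_abs(n)
        upper_pos <- stats::runif(n) < 0.5
        M[ij] <- ifelse(upper_pos, a, -a)
        M[ji] <- ifelse(upper_pos, -b, b)
      } else if (type == "competitive") {
        M[ij] <- -zd$sample_abs(n)
        M[ji] <- -zd$sample_abs(n)
      } else {                                       # mutualistic
        M[ij] <- zd$sample_abs(n)
        M[ji] <- zd$sample_abs(n)
      }
    }
    diag(M) <- -spec$d
    M
  })
  new_community_matrix(values, spec)
}

#' Generate a community matrix with mixed interaction types
#'
#' As [generate_unstructured()], but each connected pair is first assigned
#' an interaction type -- mutualistic with probability `P+/+`, competitive
#' with `P-/-`, exploitative with `P+/-` -- and the two directed strengths
#' are then drawn as for that type. The off-diagonal moments converge to
#' the closed forms returned by [ensemble_moments()].
#'
#' @param spec An [ensemble_spec()] with `interaction_type = "mixed"` and a
#'   valid `mix`.
#' @return A `community_matrix`.
#' @export
generate_mixed <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  if (spec$interaction_type != "mixed") {
    stop_ecoreact("spec$interaction_type must be \"mixed\"",
                  class = "ecoreact_bad_type")
  }
  S <- spec$S
  zd <- spec$z_dist
  mix <- spec$mix
  values <- with_seed(spec$seed, {
    M <- matrix(0, S, S)
    pair_idx <- which(upper.tri(M), arr.ind = TRUE)
    connected <- stats::runif(nrow(pair_idx)) < spec$C
    n <- sum(connected)
    if (n > 0L) {
      ii <- pair_idx[connected, 1L]
      jj <- pair_idx[connected, 2L]
      ij <- cbind(ii, jj)
      ji <- cbind(jj, ii)
      ptype <- sample(c("mut", "comp", "expl"), n, replace = TRUE,
                      prob = c(mix[["ppp"]], mix[["pmm"]], mix[["ppm"]]))
      a <- zd$sample_abs(n)
      b <- zd$sample_abs(n)
      s_ij <- numeric(n)
      s_ji <- numeric(n)
      mut <- ptype == "mut"; comp <- ptype == "comp"; expl <- ptype == "expl"
      s_ij[mut] <- a[mut];  s_ji[mut] <- b[mut]
      s_ij[comp] <- -a[comp]; s_ji[comp] <- -b[comp]
      coin <- stats::runif(n) < 0.5
      s_ij[expl] <- ifelse(coin[expl], a[expl], -a[expl])
      s_ji[expl] <- ifelse(coin[expl], -b[expl], b[expl])
      M[ij] <- s_ij
      M[ji] <- s_ji
    }
    diag(M) <- -spec$d
    M
  })
  new_community_matrix(values, spec)
}

#' Generate a cascade food web community matrix
#'
#' Species form a strict trophic hierarchy (species index = trophic rank,
#' low index = low rank). For each lower-triangular position (`i > j`,
#' predator `i` above prey `j`) the pair is connected with probability `C`;
#' if connected, the prey-on-predator effect `M[i,j]` is drawn from the
#' half-normal `|N(0, sigma^2)|` (positive: the predator benefits) and the
#' predator-on-prey effect `M[j,i]` from `-|N(0, sigma^2)|`. The diagonal
#' is `-d`.
#'
#' @param spec An [ensemble_spec()] with `interaction_type = "cascade"`.
#' @return A `community_matrix` carrying `trophic = TRUE` (ranks usable by
#'   [apply_self_regulation()] orderings).
#' @export
generate_cascade <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  if (spec$interaction_type != "cascade") {
    stop_ecoreact("spec$interaction_type must be \"cascade\"",
                  class = "ecoreact_bad_type")
  }
  S <- spec$S
  zd <- spec$z_dist
  values <- with_seed(spec$seed, {
    M <- matrix(0, S, S)
    pair_idx <- which(lower.tri(M), arr.ind = TRUE)  # i > j
    connected <- stats::runif(nrow(pair_idx)) < spec$C
    n <- sum(connected)
    if (n > 0L) {
      ii <- pair_idx[connected, 1L]
      jj <- pair_idx[connected, 2L]
      M[cbind(ii, jj)] <- zd$sample_abs(n)
      M[cbind(jj, ii)] <- -zd$sample_abs(n)
    }
    diag(M) <- -spec$d
    M
  })
  new_community_matrix(values, spec, extra = list(trophic = TRUE))
}

#' Generate a niche-model food web community matrix
#'
#' Standard niche-model construction: each species `i` receives a niche
#' value `eta_i ~ U[0, 1]` (species are relabelled in increasing `eta`
#' order), a feeding-range width `r_i = eta_i * B_i` with
#' `B_i ~ Beta(1, 1/C - 1)`, and a range centre
#' `c_i ~ U[r_i/2, min(eta_i, 1 - r_i/2)]`. Species `i` is prey of `j`
#' (`A[i,j] = 1`) when `eta_i` falls inside `j`'s feeding interval.
#' The sign matrix is `P = -A + t(A)` and each interaction strength is
#' `M[i,j] = P[i,j] * |N(0, sigma^2)|` (independent magnitudes); the
#' diagonal is `-d`. Mutual predation (`A[i,j] = A[j,i] = 1`) cancels in
#' `P` and yields no interaction, as does cannibalism (diagonal of `A`).
#'
#' Because `B_i <= 1` the centre interval `[r_i/2, min(eta_i, 1 - r_i/2)]`
#' is never empty; a defensive re-draw (up to 100 times, then `r_i = 0`)
#' guards the degenerate case anyway. Exact ties among `eta` values are
#' re-drawn.
#'
#' @param spec An [ensemble_spec()] with `interaction_type = "niche"` and
#'   `0 < C < 1`.
#' @return A `community_matrix` with a `niche` element (class
#'   `niche_web_spec`) recording `eta`, `radius`, `centre`, `beta_param`,
#'   the 0/1 `adjacency` and the `sign_matrix`.
#' @export
generate_niche <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  if (spec$interaction_type != "niche") {
    stop_ecoreact("spec$interaction_type must be \"niche\"",
                  class = "ecoreact_bad_type")
  }
  S <- spec$S
  zd <- spec$z_dist
  beta_b <- 1 / spec$C - 1
  out <- with_seed(spec$seed, {
    eta <- sort(stats::runif(S))
    while (anyDuplicated(eta)) {              # probability-zero guard
      eta <- sort(stats::runif(S))
    }
    bb <- stats::rbeta(S, 1, beta_b)
    radius <- eta * bb
    for (i in seq_len(S)) {                   # defensive: interval is
      tries <- 0L                             # provably non-empty (B <= 1)
      while (radius[i] / 2 > min(eta[i], 1 - radius[i] / 2) && tries < 100L) {
        bb[i] <- stats::rbeta(1, 1, beta_b)
        radius[i] <- eta[i] * bb[i]
        tries <- tries + 1L
      }
      if (radius[i] / 2 > min(eta[i], 1 - radius[i] / 2)) radius[i] <- 0
    }
    lo <- radius / 2
    hi <- pmin(eta, 1 - radius / 2)
    centre <- lo + stats::runif(S) * (hi - lo)
    # A[i, j] = 1 iff eta_i inside j's feeding interval
    A <- outer(eta, centre - radius / 2, ">=") &
         outer(eta, centre + radius / 2, "<=")
    A <- A * 1L
    P <- -A + t(A)
    M <- matrix(0, S, S)
    nz <- which(P != 0)
    M[nz] <- P[nz] * zd$sample_abs(length(nz))
    diag(M) <- -spec$d
    list(M = M,
         web = structure(list(eta = eta, radius = radius, centre = centre,
                              beta_param = bb, adjacency = A,
                              sign_matrix = P),
                         class = "niche_web_spec"))
  })
  new_community_matrix(out$M, spec,
                       extra = list(trophic = TRUE, niche = out$web))
}

#' Generate a community matrix of any supported type
#'
#' Dispatches on `spec$interaction_type` to the type-specific generator.
#'
#' @param spec An [ensemble_spec()].
#' @return A `community_matrix`.
#' @export
generate_community <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  switch(spec$interaction_type,
         random = ,
         exploitative = ,
         competitive = ,
         mutualistic = generate_unstructured(spec),
         mixed = generate_mixed(spec),
         cascade = generate_cascade(spec),
         niche = generate_niche(spec))
}

#' Generate an ensemble of community matrices
#'
#' Member `k` of the ensemble uses seed `spec$seed + k`, so ensembles are
#' reproducible and members independent.
#'
#' @param spec An [ensemble_spec()].
#' @param n Number of matrices.
#' @return A list of `community_matrix` objects.
#' @export
generate_ensemble <- function(spec, n) {
  lapply(seq_len(n), function(k) {
    sk <- spec
    sk$seed <- spec$seed + k
    generate_community(sk)
  })
}

#' Self-regulation schemes for the community-matrix diagonal
#'
#' Describes how the diagonal entries (self-regulation strengths) of a
#' community matrix are assigned:
#' \describe{
#'   \item{homogeneous}{all diagonal entries `-d`.}
#'   \item{heterogeneous_uniform}{strengths `d_1..d_S` drawn independently
#'     from the uniform distribution on
#'     `[d_mean - sqrt(3) sigma_d, d_mean + sqrt(3) sigma_d]` (mean
#'     `d_mean`, standard deviation `sigma_d`). `ordering` controls the
#'     relation to trophic rank: `"disorganised"` leaves the draws
#'     unsorted, `"positive"` sorts ascending (higher trophic levels
#'     self-regulate more), `"negative"` sorts descending.}
#'   \item{with_nonregulators}{`S_n` species get zero self-regulation and
#'     the rest `-d`. `placement` picks the zero positions: uniformly at
#'     random, the top `S_n` trophic ranks, or the bottom `S_n`.}
#' }
#'
#' @param mode One of `"homogeneous"`, `"heterogeneous_uniform"`,
#'   `"with_nonregulators"`.
#' @param d Strength for the homogeneous mode and for regulating species in
#'   `with_nonregulators` mode.
#' @param d_mean,sigma_d Mean and standard deviation of the uniform
#'   strengths; requires `d_mean - sqrt(3) sigma_d >= 0` so that all
#'   strengths are non-negative.
#' @param ordering `"disorganised"`, `"positive"` or `"negative"`.
#' @param S_n Number of non-self-regulating species.
#' @param placement `"random"`, `"top_trophic"` or `"bottom_trophic"`.
#' @return An object of class `self_regulation_scheme`.
#' @export
self_regulation_scheme <- function(mode = c("homogeneous",
                                            "heterogeneous_uniform",
                                            "with_nonregulators"),
                                   d = 1, d_mean = NULL, sigma_d = NULL,
                                   ordering = c("disorganised", "positive",
                                                "negative"),
                                   S_n = 0L,
                                   placement = c("random", "top_trophic",
                                                 "bottom_trophic")) {
  mode <- match.arg(mode)
  ordering <- match.arg(ordering)
  placement <- match.arg(placement)
  if (mode == "heterogeneous_uniform") {
    if (is.null(d_mean) || is.null(sigma_d) || sigma_d < 0) {
      stop_ecoreact("heterogeneous_uniform needs d_mean and sigma_d >= 0",
                    class = "ecoreact_bad_scheme")
    }
    if (d_mean - sqrt(3) * sigma_d < 0) {
      stop_ecoreact("self-regulation strengths must be non-negative: ",
                    "require d_mean - sqrt(3)*sigma_d >= 0",
                    class = "ecoreact_negative_selfreg")
    }
  }
  structure(list(mode = mode, d = d, d_mean = d_mean, sigma_d = sigma_d,
                 ordering = ordering, S_n = as.integer(S_n),
                 placement = placement),
            class = "self_regulation_scheme")
}

#' Apply a self-regulation scheme to a community matrix
#'
#' Replaces the diagonal of `M` according to `scheme`; off-diagonal entries
#' are untouched. Orderings related to trophic rank (`"positive"`,
#' `"negative"`) and trophic placements of non-regulators require a matrix
#' whose species index is a trophic rank (cascade or niche generator
#' output).
#'
#' @param M A `community_matrix` (or bare square matrix).
#' @param scheme A [self_regulation_scheme()].
#' @param seed Integer seed for the diagonal draws/placements.
#' @return A `community_matrix` with the new diagonal and
#'   `diagonal_scheme` recorded.
#' @export
apply_self_regulation <- function(M, scheme, seed = 1L) {
  stopifnot(inherits(scheme, "self_regulation_scheme"))
  cm <- if (inherits(M, "community_matrix")) M else {
    new_community_matrix(assert_square(M), NULL)
  }
  V <- cm$values
  S <- nrow(V)
  needs_trophic <- (scheme$mode == "heterogeneous_uniform" &&
                      scheme$ordering != "disorganised") ||
                   (scheme$mode == "with_nonregulators" &&
                      scheme$placement != "random")
  if (needs_trophic && !isTRUE(cm$trophic)) {
    stop_ecoreact("trophic ordering/placement requires a matrix with a ",
                  "trophic rank (cascade or niche generator output)",
                  class = "ecoreact_no_trophic")
  }
  diag_new <- with_seed(seed, {
    if (scheme$mode == "homogeneous") {
      rep(-scheme$d, S)
    } else if (scheme$mode == "heterogeneous_uniform") {
      ds <- stats::runif(S, scheme$d_mean - sqrt(3) * scheme$sigma_d,
                            scheme$d_mean + sqrt(3) * scheme$sigma_d)
      ds <- switch(scheme$ordering,
                   disorganised = ds,
                   positive = sort(ds),          # high rank, high strength
                   negative = sort(ds, decreasing = TRUE))
      -ds
    } else {                                     # with_nonregulators
      if (scheme$S_n > S) {
        stop_ecoreact("S_n cannot exceed S", class = "ecoreact_bad_scheme")
      }
      zero_at <- switch(scheme$placement,
                        random = sample.int(S, scheme$S_n),
                        top_trophic = if (scheme$S_n > 0)
                          seq.int(S - scheme$S_n + 1L, S) else integer(),
                        bottom_trophic = seq_len(scheme$S_n))
      dd <- rep(-scheme$d, S)
      dd[zero_at] <- 0
      dd
    }
  })
  diag(V) <- diag_new
  out <- cm
  out$values <- V
  out$diagonal_scheme <- scheme
  out
}

#' Empirical off-diagonal interaction statistics of a community matrix
#'
#' Computes the moments that govern the spectrum of the symmetric part:
#' `E = mean(M[i,j])`, `V = var(M[i,j])` (population variance) and
#' `rho = mean(M[i,j] * M[j,i])`, all over ordered pairs `i != j`, plus
#' the induced statistics of `H = (M + t(M))/2`:
#' `E_H = E`, `V_H = (V + rho - E^2)/2`, `rho_H = (V + rho + E^2)/2`.
#'
#' @param M A `community_matrix` or square matrix, `S >= 2`.
#' @return An `interaction_stats` object.
#' @export
empirical_moments <- function(M) {
  V <- assert_square(as_matrix_values(M))
  S <- nrow(V)
  if (S < 2) stop_ecoreact("need S >= 2", class = "ecoreact_bad_spec")
  off <- row(V) != col(V)
  x <- V[off]
  xt <- t(V)[off]
  E <- mean(x)
  Vv <- mean(x^2) - E^2
  rho <- mean(x * xt)
  interaction_stats(E, Vv, rho)
}

#' Construct an interaction-statistics object
#'
#' @param E Mean off-diagonal interaction.
#' @param V Variance of off-diagonal interactions.
#' @param rho Mean pairwise product `E(M[i,j] M[j,i])`.
#' @param e_abs Optional `E(|Z|)` of the underlying strength distribution.
#' @return An `interaction_stats` list with the derived `H` statistics.
#' @export
interaction_stats <- function(E, V, rho, e_abs = NA_real_) {
  structure(list(E = E, V = V, rho = rho, e_abs = e_abs,
                 E_H = E, V_H = (V + rho - E^2) / 2,
                 rho_H = (V + rho + E^2) / 2),
            class = "interaction_stats")
}

#' Analytic off-diagonal moments of a generator ensemble
#'
#' Closed-form expectation of [empirical_moments()] for an
#' [ensemble_spec()]: with pair-type proportions `(P+/+, P-/-, P+/-)`,
#' `E = C E(|Z|) (P+/+ - P-/-)`, `V = C sigma^2 - E^2`,
#' `rho = C E(|Z|)^2 (P+/+ + P-/- - P+/-)`. Single-type ensembles map to
#' degenerate proportions; the `"random"` type has `E = 0`,
#' `V = C sigma^2`, `rho = 0`. Cascade ensembles share the exploitative
#' moments; niche ensembles are close to exploitative but their realized
#' link density departs slightly from `C` (see the methods vignette).
#'
#' @param spec An [ensemble_spec()].
#' @return An `interaction_stats` object (with `e_abs` filled in).
#' @export
ensemble_moments <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  e_abs <- spec$z_dist$e_abs
  C <- spec$C
  sigma2 <- spec$sigma^2
  pr <- switch(spec$interaction_type,
               random = NULL,
               exploitative = ,
               cascade = ,
               niche = c(ppp = 0, pmm = 0, ppm = 1),
               competitive = c(ppp = 0, pmm = 1, ppm = 0),
               mutualistic = c(ppp = 1, pmm = 0, ppm = 0),
               mixed = spec$mix)
  if (is.null(pr)) {
    return(interaction_stats(0, C * sigma2, 0, e_abs = e_abs))
  }
  E <- C * e_abs * (pr[["ppp"]] - pr[["pmm"]])
  V <- C * sigma2 - E^2
  rho <- C * e_abs^2 * (pr[["ppp"]] + pr[["pmm"]] - pr[["ppm"]])
  interaction_stats(E, V, rho, e_abs = e_abs)
}
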