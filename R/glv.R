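#' Build a generalized Lotka-Volterra system from a community matrix
#'
#' The gLV model is `dX_i/dt = X_i (r_i + sum_j A_ij X_j)`. Given a target
#' community matrix `M` (the Jacobian at the feasible equilibrium) and
#' equilibrium abundances `X* > 0`, the per-capita interaction matrix is
#' `A = diag(X*)^{-1} M` and the growth rates `r = -A X*`, so that
#' `f(X*) = 0` and the Jacobian of the gLV right-hand side at `X*` equals
#' `M` exactly.
#'
#' @param M Community matrix (`community_matrix` or square matrix).
#' @param X_star Strictly positive equilibrium abundances (length `S`, or
#'   a scalar recycled).
#' @return An object of class `glv_system`: list with `A`, `r`, `X_star`
#'   and `M`.
#' @examples
#' M <- matrix(c(-1, 0, 3, -1), 2)
#' sys <- build_glv(M, c(2, 2))
#' max(abs(glv_rhs(sys, sys$X_star)))  # 0: X* is an equilibrium
#' @export
build_glv <- function(M, X_star) {
  V <- assert_square(as_matrix_values(M))
  S <- nrow(V)
  if (length(X_star) == 1L) X_star <- rep(X_star, S)
  if (length(X_star) != S || any(X_star <= 0)) {
    stop_ecoreact("X_star must be strictly positive and of length S",
                  class = "ecoreact_infeasible")
  }
  A <- V / X_star           # diag(1/X*) %*% M
  r <- as.numeric(-A %*% X_star)
  structure(list(A = A, r = r, X_star = X_star, M = V),
            class = "glv_system")
}

#' gLV right-hand side
#'
#' @param system A [build_glv()] system.
#' @param X Abundance vector.
#' @return `dX/dt = X * (r + A X)`.
#' @export
glv_rhs <- function(system, X) {
  X * (system$r + as.numeric(system$A %*% X))
}

#' Pulse-perturbation schedules
#'
#' Describes instantaneous additive perturbations of abundances: either a
#' single pulse or periodic pulses at a fixed frequency. At each pulse
#' instant, `n_targets` species are picked at random (a fresh subset per
#' pulse by default, driven by `target_seed`) and `strength` is added to
#' their abundances (`direction = "increase"`), or added with a random
#' sign per species (`direction = "random_sign"`).
#'
#' @param mode `"single_pulse"` or `"periodic_pulses"`.
#' @param times Pulse instants (strictly increasing). For periodic pulses
#'   you can instead give `frequency` (pulses per time unit) and a
#'   `horizon`; pulses then occur at `1/frequency, 2/frequency, ...`.
#' @param strength Additive abundance increment per pulse (>= 0).
#' @param n_targets Species perturbed per pulse.
#' @param target_seed Integer seed for target draws.
#' @param direction `"increase"` or `"random_sign"`.
#' @param frequency,horizon Convenience parameters generating `times` for
#'   periodic pulses.
#' @param fixed_targets If `TRUE`, the same random subset is perturbed at
#'   every pulse; default is a fresh draw per pulse.
#' @return A `perturbation_schedule` object.
#' @export
perturbation_schedule <- function(mode = c("single_pulse",
                                           "periodic_pulses"),
                                  times = NULL, strength = 0.1,
                                  n_targets = 1L, target_seed = 1L,
                                  direction = c("increase", "random_sign"),
                                  frequency = NULL, horizon = NULL,
                                  fixed_targets = FALSE) {
  mode <- match.arg(mode)
  direction <- match.arg(direction)
  stopifnot(strength >= 0)
  if (is.null(times)) {
    if (mode == "single_pulse") {
      times <- 1
    } else {
      stopifnot(!is.null(frequency), !is.null(horizon), frequency > 0)
      times <- seq(1 / frequency, horizon, by = 1 / frequency)
    }
  }
  if (length(times) && any(diff(times) <= 0)) {
    stop_ecoreact("pulse times must be strictly increasing",
                  class = "ecoreact_bad_schedule")
  }
  structure(list(mode = mode, times = times, strength = strength,
                 n_targets = as.integer(n_targets),
                 target_seed = as.integer(target_seed),
                 direction = direction, fixed_targets = fixed_targets),
            class = "perturbation_schedule")
}

#' Simulate gLV dynamics under a pulse-perturbation schedule
#'
#' Integrates the gLV equations with a stiff-capable adaptive solver
#' (`deSolve::lsoda`) piecewise between pulse instants. A species goes
#' extinct when its abundance crosses `extinction_fraction * X*_i` from
#' above; the crossing is located by the solver's root finding (not by
#' post-hoc thresholding) and the species is then set to zero, which the
#' gLV flow preserves. Pulses that push a species below its extinction
#' threshold (possible with `direction = "random_sign"`) also register an
#' extinction at the pulse time; abundances are never clipped silently.
#'
#' @param system A [build_glv()] system.
#' @param schedule A [perturbation_schedule()], or `NULL` for an
#'   unperturbed run.
#' @param horizon Simulation length (time units).
#' @param extinction_fraction Extinction threshold as a fraction of each
#'   species' equilibrium abundance (default 0.01).
#' @param x0 Initial abundances (default `X*`).
#' @param dt_out Output time step for the stored trajectory.
#' @param rtol,atol Integrator tolerances.
#' @return A `glv_simulation`: list with `time`, `trajectory`
#'   (time x species matrix), `extinctions` (data frame species/time),
#'   `species_loss`, and `recovered` (within `1e-3 * ||X*||` of `X*` at
#'   the horizon).
#' @export
simulate_glv <- function(system, schedule = NULL, horizon = 100,
                         extinction_fraction = 0.01, x0 = NULL,
                         dt_out = 0.5, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(system, "glv_system"), horizon > 0,
            extinction_fraction > 0, extinction_fraction < 1)
  S <- length(system$X_star)
  thr <- extinction_fraction * system$X_star
  X <- if (is.null(x0)) system$X_star else x0
  stopifnot(length(X) == S)
  pulse_times <- if (is.null(schedule)) numeric(0) else {
    schedule$times[schedule$times > 0 & schedule$times < horizon]
  }
  deriv <- function(t, y, parms) {
    alive <- y > 0
    dy <- numeric(S)
    dy[alive] <- y[alive] *
      (system$r[alive] + as.numeric(system$A[alive, , drop = FALSE] %*% y))
    list(dy)
  }
  rootfun <- function(t, y, parms) {
    # one root component per species; extinct species pinned above 0
    ifelse(y > 0, y - thr, 1)
  }
  eventfun <- function(t, y, parms) {
    y[y > 0 & y <= thr * (1 + 1e-6)] <- 0
    y
  }
  extinctions <- data.frame(species = integer(0), time = numeric(0))
  record_extinct <- function(dead, t) {
    dead <- setdiff(dead, extinctions$species)
    if (length(dead)) {
      extinctions <<- rbind(extinctions,
                            data.frame(species = dead, time = t))
    }
  }
  fixed_targets <- NULL
  draw_targets <- function() {
    if (!is.null(schedule) && schedule$fixed_targets) {
      if (is.null(fixed_targets)) {
        fixed_targets <<- sample.int(S, schedule$n_targets)
      }
      return(fixed_targets)
    }
    sample.int(S, schedule$n_targets)
  }
  seg_bounds <- unique(c(0, pulse_times, horizon))
  times_out <- numeric(0)
  traj_out <- NULL
  with_seed(if (is.null(schedule)) NULL else schedule$target_seed, {
    below <- which(X < thr)
    if (length(below)) {
      X[below] <- 0
      record_extinct(below, 0)
    }
    for (seg in seq_len(length(seg_bounds) - 1L)) {
      t0 <- seg_bounds[seg]
      t1 <- seg_bounds[seg + 1L]
      tt <- seq(t0, t1, by = dt_out)
      if (tt[length(tt)] < t1 - 1e-9) tt <- c(tt, t1)
      sol <- deSolve::lsodar(y = X, times = tt, func = deriv, parms = NULL,
                             rtol = rtol, atol = atol,
                             events = list(func = eventfun, root = TRUE),
                             rootfunc = rootfun)
      istate <- attr(sol, "istate")
      if (!is.null(istate) && istate[1] < 0) {
        stop_ecoreact("gLV integrator failed near t = ", t0,
                      class = "ecoreact_integrator")
      }
      sol_t <- sol[, 1]
      sol_y <- unname(sol[, -1, drop = FALSE])
      X_new <- pmax(sol_y[nrow(sol_y), ], 0)
      # species driven to zero in this segment: time-stamp with the first
      # solver root in the segment (the event time), else the segment end
      died <- which(X_new == 0 & X > 0)
      if (length(died)) {
        evt <- attr(sol, "troot")
        record_extinct(died,
                       if (!is.null(evt) && length(evt)) min(evt) else t1)
      }
      times_out <- c(times_out, sol_t[-length(sol_t)])
      traj_out <- rbind(traj_out, sol_y[-nrow(sol_y), , drop = FALSE])
      X <- X_new
      if (t1 %in% pulse_times) {
        targets <- draw_targets()
        kick <- if (schedule$direction == "increase") {
          rep(schedule$strength, length(targets))
        } else {
          schedule$strength * sample(c(-1, 1), length(targets),
                                     replace = TRUE)
        }
        alive_t <- X[targets] > 0
        X[targets[alive_t]] <- X[targets[alive_t]] + kick[alive_t]
        pushed_out <- which(X < thr & X > 0)
        if (length(pushed_out)) {
          X[pushed_out] <- 0
          record_extinct(pushed_out, t1)
        }
      }
    }
  })
  times_out <- c(times_out, seg_bounds[length(seg_bounds)])
  traj_out <- rbind(traj_out, X)
  rownames(traj_out) <- NULL
  recovered <- sqrt(sum((X - system$X_star)^2)) <=
    1e-3 * sqrt(sum(system$X_star^2))
  structure(list(time = times_out, trajectory = traj_out,
                 extinctions = extinctions,
                 species_loss = nrow(extinctions) > 0,
                 recovered = recovered),
            class = "glv_simulation")
}

#' @export
print.glv_simulation <- function(x, ...) {
  cat(sprintf("gLV simulation: %d time points, %d species, %d extinction(s)\n",
              length(x$time), ncol(x$trajectory), nrow(x$extinctions)))
  invisible(x)
}

#' Initial amplification rate of a perturbation direction
#'
#' The instantaneous growth rate of the perturbation norm for a pulse in
#' direction `x` is the Rayleigh quotient `t(x) H x / (t(x) x)` with
#' `H = (M + t(M))/2`; its maximum over directions is the reactivity of
#' `M`, attained at the leading eigenvector of `H`.
#'
#' @param system A [build_glv()] system (or a square matrix `M`).
#' @param x Nonzero perturbation direction.
#' @return The initial amplification rate (scalar).
#' @export
initial_amplification <- function(system, x) {
  M <- if (inherits(system, "glv_system")) system$M else
    as_matrix_values(system)
  M <- assert_square(M)
  x <- as.numeric(x)
  nx2 <- sum(x^2)
  if (nx2 == 0) {
    stop_ecoreact("perturbation direction must be nonzero",
                  class = "ecoreact_zero_direction")
  }
  H <- symmetric_part(M)
  sum(x * (H %*% x)) / nx2
}

#' Species-loss experiment under frequent perturbations
#'
#' Reproduces the frequent-perturbation protocol: generate
#' `n_communities` stable unstructured food-web communities (exploitative
#' interactions by default; unstable draws are discarded and counted),
#' embed each as a gLV system with equilibrium
#' abundance 1 for every species and per-capita self-regulation `s`
#' (diagonal `-s`), and subject each to periodic pulses that add
#' `strength` to the abundances of `n_targets` randomly picked species.
#' For every (strength, frequency) cell the percentage of communities
#' losing at least one species (abundance below
#' `extinction_fraction * X*`) within the horizon is recorded. With weak
#' self-regulation (`s` small) the same communities are reactive and far
#' more vulnerable than with strong self-regulation, although both are
#' asymptotically stable.
#'
#' @param S,C,sigma Ensemble parameters of the generator.
#' @param interaction_type Interaction type of the generated communities;
#'   the default `"exploitative"` (an unstructured food web) is the regime
#'   in which weak self-regulation gives reactive yet stable communities.
#' @param s Per-capita self-regulation strength (`A[i,i] = -s`; with
#'   `X* = 1` this is also the community-matrix diagonal).
#' @param n_communities Number of stable communities per cell (>= 2).
#' @param strength_grid,frequency_grid Pulse strength (in units of the
#'   equilibrium abundance) and frequency (pulses per time unit) grids.
#'   Frequency 0 means a single pulse at `t = 1`. The defaults span the
#'   transition from no species loss to full loss for the reactive
#'   regime.
#' @param horizon Simulation length (default 500).
#' @param n_targets Species perturbed per pulse (default 30).
#' @param extinction_fraction Extinction threshold fraction (default
#'   0.01).
#' @param seed Base seed (communities and pulse targets derive from it).
#' @param max_tries Cap on community draws while searching for stable
#'   ones.
#' @return A `loss_table` data frame with columns `strength`, `frequency`,
#'   `loss_pct`, plus attributes `n_excluded` (unstable draws discarded)
#'   and `communities`.
#' @export
species_loss_experiment <- function(S = 50, C = 0.2, sigma = 0.05, s = 1,
                                    interaction_type = "exploitative",
                                    n_communities = 20,
                                    strength_grid = c(0.25, 0.5, 1, 2),
                                    frequency_grid = c(0, 0.25, 0.5),
                                    horizon = 500, n_targets = 30,
                                    extinction_fraction = 0.01,
                                    seed = 1L, max_tries = 100 * n_communities) {
  stopifnot(n_communities >= 2, all(strength_grid >= 0),
            all(frequency_grid >= 0))
  # stable community matrices with diagonal -s
  communities <- list()
  n_excluded <- 0L
  k <- 0L
  while (length(communities) < n_communities && k < max_tries) {
    k <- k + 1L
    spec <- ensemble_spec(S, C, sigma, d = s, interaction_type,
                          seed = seed + k)
    M <- generate_community(spec)$values
    if (spectral_abscissa(M) < 0) {
      communities[[length(communities) + 1L]] <- M
    } else {
      n_excluded <- n_excluded + 1L
    }
  }
  if (length(communities) < n_communities) {
    stop_ecoreact("could not find ", n_communities, " stable communities ",
                  "in ", max_tries, " draws (", n_excluded, " unstable)",
                  class = "ecoreact_unstable_ensemble")
  }
  grid <- expand.grid(strength = strength_grid, frequency = frequency_grid)
  grid$loss_pct <- NA_real_
  for (g in seq_len(nrow(grid))) {
    losses <- vapply(seq_along(communities), function(ci) {
      sys <- build_glv(communities[[ci]], 1)
      sched <- if (grid$frequency[g] == 0) {
        perturbation_schedule("single_pulse", times = 1,
                              strength = grid$strength[g],
                              n_targets = n_targets,
                              target_seed = seed + 1000L * g + ci)
      } else {
        perturbation_schedule("periodic_pulses",
                              frequency = grid$frequency[g],
                              horizon = horizon,
                              strength = grid$strength[g],
                              n_targets = n_targets,
                              target_seed = seed + 1000L * g + ci)
      }
      sim <- simulate_glv(sys, sched, horizon = horizon,
                          extinction_fraction = extinction_fraction,
                          dt_out = 2, rtol = 1e-8, atol = 1e-10)
      sim$species_loss
    }, logical(1))
    grid$loss_pct[g] <- 100 * mean(losses)
  }
  structure(grid, class = c("loss_table", "data.frame"),
            n_excluded = n_excluded, s = s,
            communities = length(communities))
}
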