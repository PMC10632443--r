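#' Equilibrium of a Lotka-Volterra parameter set
#'
#' Solves `A X* + r = 0` for the interior equilibrium `X* = -solve(A, r)`
#' and reports feasibility (all abundances strictly positive). Infeasible
#' equilibria are returned with `feasible = FALSE` and a warning, never
#' silently accepted.
#'
#' @param A Square, invertible interaction matrix (per-capita effects).
#' @param r Intrinsic growth-rate vector.
#' @return A list with `X_star` and `feasible`.
#' @export
glv_equilibrium <- function(A, r) {
  A <- assert_square(A, "interaction matrix")
  stopifnot(length(r) == nrow(A))
  X_star <- tryCatch(as.numeric(solve(A, -r)),
                     error = function(e) {
                       stop_ecoreact("interaction matrix is singular: ",
                                     conditionMessage(e),
                                     class = "ecoreact_singular")
                     })
  feasible <- all(X_star > 0)
  if (!feasible) {
    warning("equilibrium is infeasible (non-positive abundances for species ",
            paste(which(X_star <= 0), collapse = ", "), ")")
  }
  list(X_star = X_star, feasible = feasible)
}

#' Reactivity of an empirically parameterised community
#'
#' From inferred gLV parameters `(A, r)`: computes the feasible
#' equilibrium, the empirical community matrix
#' `M_e = diag(X*) %*% A`, its symmetric part `H_e`, the reactivity
#' (largest eigenvalue of `H_e`), and the composition of interaction
#' types among species pairs.
#'
#' @inheritParams glv_equilibrium
#' @param threshold Magnitudes `|A[i,j]| <= threshold` are treated as no
#'   interaction when classifying pair types (default 0).
#' @return An object of class `empirical_model` with elements `A`, `r`,
#'   `X_star`, `M_e`, `H_e`, `reactivity`, `spectral_abscissa`, `state`
#'   and `proportions` (see [interaction_proportions()]).
#' @export
empirical_reactivity <- function(A, r, threshold = 0) {
  eq <- glv_equilibrium(A, r)
  if (!eq$feasible) {
    stop_ecoreact("infeasible equilibrium (species ",
                  paste(which(eq$X_star <= 0), collapse = ", "),
                  " non-positive); reactivity analysis requires ",
                  "a feasible equilibrium",
                  class = "ecoreact_infeasible")
  }
  M_e <- eq$X_star * A            # diag(X*) %*% A
  rep_ <- reactivity(M_e)
  structure(list(A = A, r = r, X_star = eq$X_star, M_e = M_e,
                 H_e = symmetric_part(M_e),
                 reactivity = rep_$reactivity,
                 spectral_abscissa = rep_$spectral_abscissa,
                 state = rep_$state,
                 proportions = interaction_proportions(A, threshold)),
            class = "empirical_model")
}

#' @export
print.empirical_model <- function(x, ...) {
  cat(sprintf("Empirical community: S = %d, reactivity %.4g (%s)\n",
              nrow(x$A), x$reactivity, x$state))
  invisible(x)
}

#' Interaction-type composition of an interaction matrix
#'
#' Classifies every unordered species pair with at least one directed
#' effect above `threshold` by the signs of the two effects: (+,+)
#' mutualistic, (-,-) competitive, opposite signs exploitative. Pairs
#' where only one direction is non-zero (commensal/amensal) are counted
#' in a separate bin and excluded from the three-way proportions.
#'
#' @param A Square interaction matrix.
#' @param threshold Non-negative magnitude below which an effect is
#'   treated as absent (default 0).
#' @return A list with `ppp`, `pmm`, `ppm` (proportions over two-sided
#'   pairs), `one_sided` (proportion of interacting pairs with a single
#'   non-zero direction), and the raw counts.
#' @export
interaction_proportions <- function(A, threshold = 0) {
  A <- assert_square(A, "interaction matrix")
  stopifnot(threshold >= 0)
  S <- nrow(A)
  counts <- c(mut = 0L, comp = 0L, expl = 0L, one_sided = 0L)
  for (i in seq_len(S - 1L)) {
    for (j in seq.int(i + 1L, S)) {
      aij <- if (abs(A[i, j]) > threshold) sign(A[i, j]) else 0
      aji <- if (abs(A[j, i]) > threshold) sign(A[j, i]) else 0
      if (aij == 0 && aji == 0) next
      if (aij == 0 || aji == 0) {
        counts["one_sided"] <- counts["one_sided"] + 1L
      } else if (aij > 0 && aji > 0) {
        counts["mut"] <- counts["mut"] + 1L
      } else if (aij < 0 && aji < 0) {
        counts["comp"] <- counts["comp"] + 1L
      } else {
        counts["expl"] <- counts["expl"] + 1L
      }
    }
  }
  two_sided <- sum(counts[c("mut", "comp", "expl")])
  interacting <- two_sided + counts[["one_sided"]]
  list(ppp = if (two_sided > 0) counts[["mut"]] / two_sided else NA_real_,
       pmm = if (two_sided > 0) counts[["comp"]] / two_sided else NA_real_,
       ppm = if (two_sided > 0) counts[["expl"]] / two_sided else NA_real_,
       one_sided = if (interacting > 0)
         counts[["one_sided"]] / interacting else NA_real_,
       counts = counts)
}

#' Generate a small synthetic gLV parameter fixture
#'
#' Emits a few-species gLV parameter set `(A, r)` with a requested
#' pair-type composition and a guaranteed-feasible equilibrium: a positive
#' `X*` is drawn first and `r = -A X*` set afterwards. These synthetic
#' fixtures emulate the file format of empirically inferred parameter
#' sets (small microbial communities of 4-5 taxa) for pipeline testing;
#' they are not fits to any real data.
#'
#' @param n_species 4 or 5 (other small values accepted).
#' @param proportions Pair-type proportions `c(ppp=, pmm=, ppm=)` (summing
#'   to 1); realised counts are the rounded proportions of the
#'   `n (n - 1) / 2` pairs.
#' @param coupling Scale of the off-diagonal interaction magnitudes
#'   relative to the self-limitation (diagonal `-1`); strong coupling
#'   (around 1) typically yields a reactive community matrix.
#' @param seed Integer seed.
#' @return A list of class `glv_fixture` with `A`, `r`, `X_star` and the
#'   generating `meta`.
#' @seealso [write_glv_params()], [read_glv_params()]
#' @export
make_fixture <- function(n_species = 5,
                         proportions = c(ppp = 0.2, pmm = 0.3, ppm = 0.5),
                         coupling = 0.5, seed = 1L) {
  stopifnot(n_species >= 2)
  pr <- proportions[c("ppp", "pmm", "ppm")]
  if (any(pr < 0) || abs(sum(pr) - 1) > 1e-12) {
    stop_ecoreact("proportions must be non-negative and sum to 1",
                  class = "ecoreact_bad_mix")
  }
  out <- with_seed(seed, {
    S <- n_species
    pairs <- which(upper.tri(matrix(0, S, S)), arr.ind = TRUE)
    n_pairs <- nrow(pairs)
    n_mut <- round(pr[["ppp"]] * n_pairs)
    n_comp <- round(pr[["pmm"]] * n_pairs)
    n_expl <- n_pairs - n_mut - n_comp
    types <- sample(rep(c("mut", "comp", "expl"),
                        c(n_mut, n_comp, n_expl)))
    A <- diag(-1, S)
    for (k in seq_len(n_pairs)) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      a <- coupling * (0.5 + stats::runif(2))
      sgn <- switch(types[k],
                    mut = c(1, 1),
                    comp = c(-1, -1),
                    expl = if (stats::runif(1) < 0.5) c(1, -1) else c(-1, 1))
      A[i, j] <- sgn[1] * a[1]
      A[j, i] <- sgn[2] * a[2]
    }
    X_star <- stats::runif(S, 0.5, 1.5)
    r <- as.numeric(-A %*% X_star)
    list(A = A, r = r, X_star = X_star,
         meta = list(n_species = S, proportions = as.list(pr),
                     coupling = coupling, seed = seed,
                     pair_types = types))
  })
  class(out) <- "glv_fixture"
  out
}

#' Read / write gLV parameter files
#'
#' The parameter file is a CSV with a header row `r,A1,...,AS` and `S`
#' rows: column `r` holds the intrinsic growth rate of each species and
#' columns `A1..AS` the rows of the interaction matrix. Doubles are
#' written at full precision so a write/read round trip is exact.
#'
#' @param path File path.
#' @param A,r Interaction matrix and growth-rate vector (or a
#'   `glv_fixture` passed as `A`).
#' @param meta Optional metadata list, written as a JSON sidecar
#'   `<path>.json`.
#' @return `read_glv_params()`: list with `A`, `r` (and `meta` if a
#'   sidecar exists). `write_glv_params()`: the path, invisibly.
#' @export
write_glv_params <- function(path, A, r = NULL, meta = NULL) {
  if (inherits(A, "glv_fixture")) {
    if (is.null(meta)) meta <- A$meta
    r <- A$r
    A <- A$A
  }
  A <- assert_square(A, "interaction matrix")
  S <- nrow(A)
  stopifnot(length(r) == S)
  num <- cbind(r, A)
  txt <- apply(num, 1, function(row) {
    paste(sprintf("%.17g", row), collapse = ",")
  })
  writeLines(c(paste(c("r", paste0("A", seq_len(S))), collapse = ","), txt),
             path)
  if (!is.null(meta)) {
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' @rdname write_glv_params
#' @export
read_glv_params <- function(path) {
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE)
  if (!"r" %in% names(df)) {
    stop_ecoreact("gLV parameter file must have header r,A1,...,AS",
                  class = "ecoreact_bad_params")
  }
  S <- nrow(df)
  acols <- paste0("A", seq_len(S))
  if (!all(acols %in% names(df))) {
    stop_ecoreact("expected columns ", paste(acols, collapse = ","),
                  class = "ecoreact_bad_params")
  }
  out <- list(A = unname(as.matrix(df[, acols])), r = df$r)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    out$meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  out
}
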