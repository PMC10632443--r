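test_that("ensemble_spec validates its arguments", {
  expect_error(ensemble_spec(1, 0.2, 0.1, 1, "random"), "S must be")
  expect_error(ensemble_spec(10, 1.2, 0.1, 1, "random"), "C must")
  expect_error(ensemble_spec(10, 0.2, -0.1, 1, "random"), "sigma")
  expect_error(ensemble_spec(10, 0.2, 0.1, 1, "mixed"), "mix")
  expect_error(ensemble_spec(10, 0.2, 0.1, 1, "mixed",
                             mix = c(ppp = 0.5, pmm = 0.4, ppm = 0.2)),
               "sum to 1")
  expect_error(ensemble_spec(10, 1, 0.1, 1, "niche"), "0 < C < 1")
  expect_error(generate_mixed(ensemble_spec(10, 0.2, 0.1, 1, "random")),
               "mixed")
})

test_that("degenerate networks: C = 0 or sigma = 0 give -d I", {
  for (ty in c("random", "exploitative", "competitive", "mutualistic")) {
    M0 <- generate_unstructured(ensemble_spec(20, 0, 0.3, 2, ty, seed = 1))
    expect_equal(M0$values, diag(-2, 20))
    M1 <- generate_unstructured(ensemble_spec(20, 0.5, 0, 2, ty, seed = 1))
    expect_equal(M1$values, diag(-2, 20))
  }
  Mc <- generate_cascade(ensemble_spec(15, 1, 0, 3, "cascade", seed = 2))
  expect_equal(Mc$values, diag(-3, 15))
})

test_that("generators are deterministic in spec + seed and leave the RNG alone", {
  spec <- ensemble_spec(40, 0.3, 0.1, 1, "mixed",
                        mix = c(ppp = 0.2, pmm = 0.3, ppm = 0.5), seed = 9)
  set.seed(123); before <- runif(1)
  set.seed(123)
  A <- generate_mixed(spec)$values
  after <- runif(1)
  B <- generate_mixed(spec)$values
  expect_identical(A, B)
  expect_identical(before, after)   # user RNG stream untouched
  spec2 <- spec; spec2$seed <- 10L
  expect_false(identical(A, generate_mixed(spec2)$values))
})

test_that("sparsity pattern is pair-symmetric for every generator", {
  specs <- list(
    ensemble_spec(30, 0.3, 0.1, 1, "random", seed = 4),
    ensemble_spec(30, 0.3, 0.1, 1, "exploitative", seed = 5),
    ensemble_spec(30, 0.3, 0.1, 1, "mixed",
                  mix = c(ppp = 0.3, pmm = 0.3, ppm = 0.4), seed = 6),
    ensemble_spec(30, 0.3, 0.1, 1, "cascade", seed = 7),
    ensemble_spec(30, 0.3, 0.1, 1, "niche", seed = 8))
  for (sp in specs) {
    V <- generate_community(sp)$values
    off <- upper.tri(V)
    expect_identical((V != 0)[off], (t(V) != 0)[off], label = sp$interaction_type)
  }
})

test_that("exploitative pair product matches the half-normal moment", {
  # closed-form oracle: E(M_ij M_ji | connected) = -E(|Z|)^2 = -sigma^2 2/pi
  spec <- ensemble_spec(200, 0.3, 0.1, 1, "exploitative", seed = 100)
  mm <- ensemble_mean_moments(spec, 100)
  expect_equal(mm$rho, -0.3 * 0.1^2 * 2 / pi, tolerance = 0.05)
  expect_equal(mm$E, 0, tolerance = 2e-4)
})

test_that("mixed-generator moments converge to the closed forms", {
  e_abs <- 0.05 * sqrt(2 / pi)
  # pure exploitative mix: zero mean, negative pair product
  sp_pm <- ensemble_spec(150, 0.1, 0.05, 1, "mixed",
                         mix = c(ppp = 0, pmm = 0, ppm = 1), seed = 11)
  mm <- ensemble_mean_moments(sp_pm, 200)
  expect_equal(mm$E, 0, tolerance = 2e-5)
  expect_equal(mm$rho, -0.1 * e_abs^2, tolerance = 0.07)
  # pure mutualistic: positive mean C E(|Z|)
  sp_pp <- ensemble_spec(150, 0.1, 0.05, 1, "mixed",
                         mix = c(ppp = 1, pmm = 0, ppm = 0), seed = 12)
  mm_pp <- ensemble_mean_moments(sp_pp, 200)
  expect_equal(mm_pp$E, 0.1 * e_abs, tolerance = 0.02)
  # balanced +/+ and -/-: zero mean but positive correlation
  sp_bal <- ensemble_spec(150, 0.1, 0.05, 1, "mixed",
                          mix = c(ppp = 0.5, pmm = 0.5, ppm = 0), seed = 13)
  mm_b <- ensemble_mean_moments(sp_bal, 200)
  expect_equal(mm_b$E, 0, tolerance = 2e-5)
  expect_equal(mm_b$rho, 0.1 * e_abs^2, tolerance = 0.07)
  # analytic helper agrees with its own definition
  th <- ensemble_moments(sp_bal)
  expect_equal(th$E, 0)
  expect_equal(th$rho, 0.1 * e_abs^2)
})

test_that("cascade matrices have the trophic sign pattern and connectance", {
  sp <- ensemble_spec(200, 0.3, 0.1, 1, "cascade", seed = 21)
  V <- generate_cascade(sp)$values
  low <- V[lower.tri(V)]
  upp <- t(V)[lower.tri(V)]
  expect_true(all(low[low != 0] > 0))   # prey helps predator
  expect_true(all(upp[upp != 0] < 0))   # predator harms prey
  conn <- vapply(generate_ensemble(sp, 50), function(m) {
    mean(m$values[lower.tri(m$values)] != 0)
  }, numeric(1))
  n_pairs <- 200 * 199 / 2
  se <- sqrt(0.3 * 0.7 / (n_pairs * 50))
  expect_lt(abs(mean(conn) - 0.3), 4 * se)
})

test_that("niche webs are interval, sign-consistent, and match connectance", {
  sp <- ensemble_spec(150, 0.3, 0.1, 1, "niche", seed = 31)
  out <- generate_niche(sp)
  A <- out$niche$adjacency
  V <- out$values
  # intervality: prey of each predator are contiguous in niche order
  for (j in seq_len(ncol(A))) {
    prey <- which(A[, j] == 1)
    if (length(prey) > 1) expect_equal(prey, seq(min(prey), max(prey)))
  }
  # one-way predation: prey harmed, predator benefits
  oneway <- which(A == 1 & t(A) == 0, arr.ind = TRUE)
  oneway <- oneway[oneway[, 1] != oneway[, 2], , drop = FALSE]
  expect_true(all(V[oneway] < 0))
  expect_true(all(t(V)[oneway] > 0))
  # link densities across draws: directed ~ C/2 (the construction's
  # systematic bias), unordered-pair connectance ~ C
  sp5 <- ensemble_spec(500, 0.3, 0.1, 1, "niche", seed = 32)
  dens <- t(vapply(generate_ensemble(sp5, 50), function(m) {
    V <- m$values
    c(directed = sum(m$niche$adjacency) / 500^2,
      pairwise = mean((V != 0)[upper.tri(V)]))
  }, numeric(2)))
  expect_equal(mean(dens[, "directed"]), 0.15, tolerance = 0.02)
  expect_equal(mean(dens[, "pairwise"]), 0.3, tolerance = 0.05)
})

test_that("self-regulation schemes set the diagonal as specified", {
  sp <- ensemble_spec(60, 0.3, 0.1, 1, "cascade", seed = 41)
  M <- generate_cascade(sp)
  # all non-regulating
  z <- apply_self_regulation(M, self_regulation_scheme(
    "with_nonregulators", d = 1, S_n = 60), seed = 1)
  expect_identical(diag(z$values), rep(0, 60))
  # off-diagonal untouched
  expect_identical(z$values[upper.tri(z$values)],
                   M$values[upper.tri(M$values)])
  # top-trophic placement
  top <- apply_self_regulation(M, self_regulation_scheme(
    "with_nonregulators", d = 2, S_n = 5, placement = "top_trophic"),
    seed = 1)
  expect_identical(diag(top$values), c(rep(-2, 55), rep(0, 5)))
  # heterogeneous uniform: mean and sd converge
  sch <- self_regulation_scheme("heterogeneous_uniform", d_mean = 6,
                                sigma_d = 1)
  draws <- vapply(1:100, function(k) {
    dd <- -diag(apply_self_regulation(M, sch, seed = k)$values)
    c(mean(dd), stats::sd(dd))
  }, numeric(2))
  expect_equal(mean(draws[1, ]), 6, tolerance = 0.05)
  expect_equal(mean(draws[2, ]), 1, tolerance = 0.05)
  # positive ordering sorts ascending with trophic rank
  pos <- apply_self_regulation(M, self_regulation_scheme(
    "heterogeneous_uniform", d_mean = 6, sigma_d = 1,
    ordering = "positive"), seed = 3)
  expect_true(!is.unsorted(-diag(pos$values)))
  # invalid schemes
  expect_error(self_regulation_scheme("heterogeneous_uniform",
                                      d_mean = 1, sigma_d = 1),
               "non-negative")
  plain <- generate_unstructured(ensemble_spec(10, 0.2, 0.1, 1, "random",
                                               seed = 1))
  expect_error(apply_self_regulation(plain, self_regulation_scheme(
    "heterogeneous_uniform", d_mean = 6, sigma_d = 1,
    ordering = "positive"), seed = 1), "trophic")
})

test_that("empirical_moments computes E, V, rho and the H statistics", {
  expect_equal(unclass(empirical_moments(diag(-2, 5)))[c("E", "V", "rho")],
               list(E = 0, V = 0, rho = 0))
  M2 <- matrix(c(-1, 0, 3, -1), 2)       # off-diagonals 3 and 0
  st <- empirical_moments(M2)
  expect_equal(st$E, 1.5)
  expect_equal(st$V, 2.25)
  expect_equal(st$rho, 0)
  expect_equal(st$V_H, (st$V + st$rho - st$E^2) / 2)
  expect_equal(st$rho_H, (st$V + st$rho + st$E^2) / 2)
})

test_that("gamma strength family lowers E(|Z|) at fixed variance", {
  zg <- z_gamma(0.1, shape = 0.3)
  zn <- z_normal(0.1)
  expect_lt(zg$e_abs, zn$e_abs)
  set.seed(1)
  draws <- zg$sample_abs(2e5)
  expect_equal(mean(draws^2), 0.01, tolerance = 0.02)
  expect_equal(mean(draws), zg$e_abs, tolerance = 0.02)
})
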