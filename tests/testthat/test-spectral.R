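test_that("symmetric_part is the symmetrised matrix", {
  expect_equal(symmetric_part(reactive_2x2()),
               matrix(c(-1, 1.5, 1.5, -1), 2))
  Sym <- matrix(c(2, 1, 1, 2), 2)
  expect_equal(symmetric_part(Sym), Sym)
  Anti <- matrix(c(0, -3, 3, 0), 2)
  expect_equal(symmetric_part(Anti), matrix(0, 2, 2))
  expect_error(symmetric_part(matrix(1, 2, 3)), "square")
})

test_that("reactivity and state classification match closed 2x2 forms", {
  r1 <- reactivity(diag(-1, 3))
  expect_equal(r1$reactivity, -1)
  expect_equal(r1$state, "stable_nonreactive")
  r2 <- reactivity(reactive_2x2())       # eigenvalues of H: -1 +/- 1.5
  expect_equal(r2$reactivity, 0.5)
  expect_equal(r2$spectral_abscissa, -1)
  expect_equal(r2$state, "stable_reactive")
  r3 <- reactivity(nonreactive_2x2())    # -1 +/- 0.15
  expect_equal(r3$reactivity, -0.85)
  expect_equal(r3$state, "stable_nonreactive")
  expect_equal(classify_state(diag(c(1, -1))), "unstable")
  expect_error(reactivity(matrix(c(1, NA, 0, 1), 2)), "non-finite")
})

test_that("single-type reactivity predictions follow the criteria", {
  # criterion boundary: sigma sqrt(2SC) = d
  expect_equal(predict_unstructured("random", 250, 0.2, 0.1, 1)$R_pred, 0)
  # no interactions: R = -d for every type
  for (ty in c("random", "exploitative", "competitive", "mutualistic")) {
    expect_equal(predict_unstructured(ty, 100, 0.3, 0, 5, e_abs = 0)$R_pred,
                 -5)
  }
  # mutualistic outlier = -d + (S-1) C E(|Z|)
  p <- predict_unstructured("mutualistic", 150, 0.1, 0.05, 1)
  expect_equal(p$R_pred, -1 + 149 * 0.1 * 0.05 * sqrt(2 / pi),
               tolerance = 1e-12)
  expect_equal(p$R_pred, -0.40558, tolerance = 1e-4)
  expect_equal(p$branch, "outlier")
  # competitive outlier reported on the left, never used for R
  pc <- predict_unstructured("competitive", 150, 0.25, 0.25, 1)
  expect_lt(pc$outlier, pc$centre - pc$half_length)
  expect_equal(pc$R_pred, pc$centre + pc$half_length)
  expect_error(predict_unstructured("random", 100, 0.2, 0.1, 1, e_abs = 0.2),
               "impossible")
})

test_that("mutualistic prediction oracle: mean row sum of H", {
  # independent oracle for the outlier: the row sum of H averaged over an
  # ensemble equals -d + (S-1) C E(|Z|)
  ms <- generate_ensemble(ensemble_spec(150, 0.1, 0.05, 1, "mutualistic",
                                        seed = 55), 50)
  row_sums <- vapply(ms, function(m) mean(rowSums(symmetric_part(m$values))),
                     numeric(1))
  expect_equal(mean(row_sums),
               predict_unstructured("mutualistic", 150, 0.1, 0.05, 1)$R_pred,
               tolerance = 0.02)
})

test_that("mixed prediction reduces to the single-type formulas", {
  # P+/- = 1 reduces algebraically to the exploitative segment
  st_e <- ensemble_moments(ensemble_spec(150, 0.1, 0.05, 1, "mixed",
                                         mix = c(ppp = 0, pmm = 0, ppm = 1)))
  expect_equal(predict_mixed(st_e, 150, 1)$R_pred,
               predict_unstructured("exploitative", 150, 0.1, 0.05, 1)$R_pred,
               tolerance = 1e-12)
  # P+/+ = 1: outlier branch dominates and equals the mutualistic value
  st_m <- ensemble_moments(ensemble_spec(150, 0.1, 0.05, 1, "mixed",
                                         mix = c(ppp = 1, pmm = 0, ppm = 0)))
  pm <- predict_mixed(st_m, 150, 1)
  expect_equal(pm$branch, "outlier")
  expect_equal(pm$R_pred,
               predict_unstructured("mutualistic", 150, 0.1, 0.05, 1)$R_pred,
               tolerance = 1e-12)
  expect_error(predict_mixed(interaction_stats(0.5, 0.1, -0.1), 100, 1),
               "V \\+ rho")
})

test_that("segment/outlier branches join continuously at the threshold", {
  S <- 100; V <- 0.01; rho <- 0
  # threshold |E| = sqrt((V + rho - E^2)/(2S)): solve for E
  E_star <- sqrt((V + rho) / (2 * S + 1))
  below <- predict_mixed(interaction_stats(E_star * (1 - 1e-7), V, rho), S, 1)
  above <- predict_mixed(interaction_stats(E_star * (1 + 1e-7), V, rho), S, 1)
  expect_equal(below$branch, "segment")
  expect_equal(below$R_pred, above$R_pred, tolerance = 1e-6)
})

test_that("heterogeneous self-regulation prediction has the right limits", {
  stats <- interaction_stats(0, 0.3 * 0.01, 0)   # random, C=0.3, sigma=0.1
  # sigma_d -> 0 limit equals the homogeneous closed form to 6 sig figs
  R_lim <- predict_heterogeneous(stats, 200, 6, 1e-6 * 0.1)$R_pred
  expect_rel(R_lim, -6 + 0.1 * sqrt(2 * 200 * 0.3), 1e-6)
  # sigma_d = 0 exactly: no division by zero, delegates to predict_mixed
  expect_equal(predict_heterogeneous(stats, 200, 6, 0)$R_pred,
               predict_mixed(stats, 200, 6)$R_pred)
  # monotone increasing in heterogeneity
  Rs <- vapply(c(0, 1, 2, 3),
               function(sd_) predict_heterogeneous(stats, 200, 6, sd_)$R_pred,
               numeric(1))
  expect_true(all(diff(Rs) > 0))
  expect_error(predict_heterogeneous(stats, 200, 1, 3), "non-negative")
})

test_that("weak interactions shift the criteria in opposite directions", {
  sigma <- 0.1
  e_weak <- z_gamma(sigma, shape = 0.3)$e_abs   # smaller E(|Z|)
  e_half <- sigma * sqrt(2 / pi)
  expect_lt(e_weak, e_half)
  args <- list(S = 200, C = 0.2, sigma = sigma, d = 1)
  for (ty in c("exploitative", "competitive", "mutualistic", "random")) {
    Rw <- do.call(predict_unstructured, c(list(ty), args,
                                          list(e_abs = e_weak)))$R_pred
    Rh <- do.call(predict_unstructured, c(list(ty), args,
                                          list(e_abs = e_half)))$R_pred
    if (ty == "exploitative") expect_gt(Rw, Rh)
    if (ty %in% c("competitive", "mutualistic")) expect_lt(Rw, Rh)
    if (ty == "random") expect_equal(Rw, Rh)
  }
})

test_that("cascade reactivity is indistinguishable from unstructured exploitative", {
  r_casc <- vapply(generate_ensemble(
    ensemble_spec(120, 0.25, 0.1, 1, "cascade", seed = 61), 50),
    function(m) reactivity_value(m$values), numeric(1))
  r_expl <- vapply(generate_ensemble(
    ensemble_spec(120, 0.25, 0.1, 1, "exploitative", seed = 62), 50),
    function(m) reactivity_value(m$values), numeric(1))
  expect_gt(stats::t.test(r_casc, r_expl)$p.value, 0.01)
})

test_that("numerical abscissa dominates the spectral abscissa", {
  set.seed(7)
  for (k in 1:20) {
    ty <- sample(c("random", "exploitative", "competitive", "mutualistic",
                   "cascade", "niche"), 1)
    sp <- ensemble_spec(sample(5:40, 1), runif(1, 0.1, 0.6),
                        runif(1, 0, 0.4), runif(1, 0, 2), ty, seed = k)
    V <- generate_community(sp)$values
    rep_ <- reactivity(V)
    expect_gte(rep_$reactivity, rep_$spectral_abscissa - 1e-10)
    if (rep_$state == "unstable") expect_gt(rep_$reactivity, 0)
  }
})
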