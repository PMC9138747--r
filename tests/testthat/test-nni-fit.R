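test_that("fitting interaction-free observations recovers zero couplings", {
  intr <- intrinsic_energies(make_fractions(gag_profile, 2))
  obs <- marginal_fractions(enumerate_conformers(intr, NULL))
  fit <- fit_nni(obs, intr, stages = 1, multistart = 6)
  expect_true(all(abs(fit$combined$dG_kJmol) < 0.05))
  expect_lt(fit$chi2, 1e-8)
})

test_that("a known combined coupling is recovered from noiseless observations", {
  intr <- intrinsic_energies(make_fractions(gag_profile, 2))
  truth <- nni_params(j = 2, i = 1, L = "beta", K = "pPII", dG_kJmol = 2)
  obs <- marginal_fractions(enumerate_conformers(intr, truth))
  fit <- fit_nni(obs, intr, stages = 1, multistart = 6)
  est <- fit$combined
  expect_equal(
    est$dG_kJmol[est$state_lo == "pPII" & est$state_hi == "beta"], 2,
    tolerance = 0.1
  )
  # directional report splits the identifiable sum evenly
  dir21 <- fit$params
  expect_equal(
    sum(dir21$dG_kJmol[dir21$L == "beta" | dir21$K == "beta"]), 2,
    tolerance = 0.1
  )
})

test_that("stage 2 never increases the objective", {
  intr <- table1_intrinsic(c("A", "F"))
  fit <- fit_nni(table1_observed("GAFG"), intr, stages = 2, multistart = 8)
  expect_equal(length(fit$chi2_stages), 2)
  expect_lte(fit$chi2_stages[2], fit$chi2_stages[1] + 1e-12)
  expect_true(fit$converged)
  # same-state couplings are never freed
  expect_false(any(
    fit$free$state_lo == fit$free$state_hi &
      fit$free$state_lo %in% c("pPII", "beta")
  ))
})

test_that("grossly unnormalized observations are rejected", {
  intr <- intrinsic_energies(make_fractions(gag_profile, 2))
  bad <- make_fractions(gag_profile, 2)
  bad$fraction <- bad$fraction * 2
  expect_error(fit_nni(bad, intr), "not normalized")
})

test_that("pentapeptide staging recovers the 2-3 dimer with the 1-2 dimer fixed at truth", {
  sc <- synthetic_scenario(seed = 17, n_residues = 3, coupling_magnitude = 2)
  truth <- make_truth(sc)
  obs <- observe_fractions(truth, noise_sd_fraction = 0)
  comb_truth <- combine_directional(truth$params, 3)
  fixed_12 <- comb_truth[comb_truth$pair == 1, ]
  fit <- fit_nni_penta(obs, truth$intrinsic, fixed_12,
    stages = 1, multistart = 6)
  truth_comb <- combine_directional(truth$params, 3)
  for (sp in list(c("pPII", "beta"), c("beta", "pPII"))) {
    est <- fit$combined$dG_kJmol[
      fit$combined$pair == 2 & fit$combined$state_lo == sp[1] &
        fit$combined$state_hi == sp[2]
    ]
    tru <- truth_comb$dG_kJmol[
      truth_comb$pair == 2 & truth_comb$state_lo == sp[1] &
        truth_comb$state_hi == sp[2]
    ]
    expect_equal(est, tru, tolerance = 0.1)
  }
  # upstream adjustment stays near zero when no second-neighbor terms exist
  expect_true(all(abs(
    fit$combined$dG_kJmol[fit$combined$pair == 1]
  ) < 0.1))
})

test_that("an all-zero pentapeptide truth yields near-zero free couplings", {
  intr <- intrinsic_energies(make_fractions(c(0.4, 0.35, 0.15, 0.1), 3))
  obs <- marginal_fractions(enumerate_conformers(intr, NULL))
  fixed <- tibble::tibble(
    pair = 1L, state_lo = "pPII", state_hi = "beta", dG_kJmol = 0
  )
  fit <- fit_nni_penta(obs, intr, fixed, stages = 1, multistart = 4)
  expect_true(all(abs(fit$combined$dG_kJmol) < 0.05))
})

test_that("chi-square profiles match a local parabola and flag flat directions", {
  intr <- intrinsic_energies(make_fractions(gag_profile, 2))
  truth <- nni_params(j = 2, i = 1, L = "beta", K = "pPII", dG_kJmol = 1.5)
  obs <- marginal_fractions(enumerate_conformers(intr, truth))
  fit <- fit_nni(obs, intr, stages = 1, multistart = 4)

  grid <- seq(0, 3, by = 0.1)
  threshold <- 0.002
  prof <- scan_uncertainty(fit, 1, "pPII", "beta",
    grid = grid, threshold = threshold)
  interval <- attr(prof, "interval")
  expect_gte(attr(prof, "estimate"), interval[1])
  expect_lte(attr(prof, "estimate"), interval[2])
  # compare against the parabola implied by the profile's own curvature
  pmin <- grid[which.min(prof$chi2)]
  curv <- (prof$chi2[which.min(prof$chi2) + 2] +
    prof$chi2[which.min(prof$chi2) - 2] -
    2 * min(prof$chi2)) / (2 * 0.2^2)
  half_width <- sqrt(threshold / curv)
  expect_equal(diff(interval) / 2, half_width, tolerance = 0.15)

  # pinning one direction while the sum stays free is a gauge direction
  gprof <- scan_uncertainty(fit, 1, "pPII", "beta",
    grid = seq(-5, 5, by = 1), threshold = 0.002, mode = "directional")
  expect_true(attr(gprof, "flat"))
  expect_equal(attr(gprof, "interval"), c(-5, 5))
  expect_lt(diff(range(gprof$chi2)), 1e-6)

  # threshold 0 degenerates to the grid point nearest the estimate
  zprof <- scan_uncertainty(fit, 1, "pPII", "beta",
    grid = grid, threshold = 0)
  expect_lte(diff(attr(zprof, "interval")), 0.1 + 1e-12)

  expect_error(
    scan_uncertainty(fit, 1, "pPII", "beta", grid = seq(-20, 20, 5)),
    "bounds"
  )
  expect_error(
    scan_uncertainty(fit, 1, "t_l", "t_r", grid = grid),
    "not free"
  )
})

test_that("tidy and glance summarize fits with the significance convention", {
  intr <- table1_intrinsic(c("A", "F"))
  fit <- fit_nni(table1_observed("GAFG"), intr, stages = 1, multistart = 6)
  td <- tidy(fit)
  expect_named(td,
    c("pair", "state_lo", "state_hi", "estimate", "free", "significant"))
  expect_equal(td$significant, abs(td$estimate) > 1.25)
  gl <- glance(fit)
  expect_equal(gl$n_residues, 2)
  expect_equal(gl$chi2, fit$chi2)
})
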