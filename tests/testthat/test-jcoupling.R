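test_that("Karplus curves are periodic and match the closed form", {
  kar <- karplus_default()
  angles <- seq(-180, 180, by = 15)
  for (r in seq_len(nrow(kar))) {
    j1 <- karplus_value(kar$coupling_type[r], angles)
    j2 <- karplus_value(kar$coupling_type[r], angles + 360)
    expect_equal(j1, j2, tolerance = 1e-12)
    th <- (angles + kar$phase_deg[r]) * pi / 180
    expect_equal(j1, kar$A[r] * cos(th)^2 + kar$B[r] * cos(th) + kar$C[r],
      tolerance = 1e-12)
  }
  expect_error(karplus_value("2J(N,C)", 0), "Unknown coupling")
})

test_that("delta-like basins reproduce the pointwise Karplus values exactly", {
  b <- basin_set("pPII", -70, 150, 1e-9, 1e-9, 1)
  pred <- predict_coupling(b)
  kar <- karplus_default()
  for (r in seq_len(nrow(kar))) {
    ang <- if (kar$angle[r] == "phi") -70 else 150
    expect_identical(
      pred$J_Hz[pred$coupling_type == kar$coupling_type[r]],
      karplus_value(kar$coupling_type[r], ang)
    )
  }

  # two equal-weight delta basins average arithmetically
  b2 <- basin_set(c("pPII", "beta"), c(-70, -120), c(150, 130),
    1e-9, 1e-9, c(0.5, 0.5))
  p2 <- predict_coupling(b2)
  expect_equal(
    p2$J_Hz[p2$coupling_type == "3J(HN,HA)"],
    mean(karplus_value("3J(HN,HA)", c(-70, -120))),
    tolerance = 1e-12
  )
})

test_that("grid averaging matches 1D quadrature and converges with the step", {
  b <- basin_set("pPII", -70, 150, 30, 15, 1)
  pred <- predict_coupling(b, grid_step = 2)
  # independent oracle: adaptive quadrature over the wrapped phi density
  orc <- integrate(function(phi) {
    dens <- 0
    for (k in -2:2) dens <- dens + dnorm(phi, -70 + 360 * k, 30)
    dens * karplus_value("3J(HN,HA)", phi)
  }, -180, 180, rel.tol = 1e-10)$value /
    integrate(function(phi) {
      dens <- 0
      for (k in -2:2) dens <- dens + dnorm(phi, -70 + 360 * k, 30)
      dens
    }, -180, 180, rel.tol = 1e-10)$value
  expect_equal(pred$J_Hz[pred$coupling_type == "3J(HN,HA)"], orc,
    tolerance = 1e-3)

  b5 <- basin_set("pPII", -70, 150, 5, 5, 1)
  p_coarse <- predict_coupling(b5, grid_step = 2)
  p_fine <- predict_coupling(b5, grid_step = 1)
  expect_true(all(abs(p_coarse$J_Hz - p_fine$J_Hz) < 0.01))
})

test_that("reduced chi-square normalizes by the remaining degrees of freedom", {
  expect_equal(reduced_chi_square(1:5, 1:5, rep(0.2, 5)), 0)
  expect_equal(
    reduced_chi_square(rep(1, 4), rep(0.8, 4), rep(0.2, 4), n_free = 0), 1
  )
  obs <- c(1, 2, 3, 4, 5)
  calc <- obs - c(0.2, 0.4, 0, 0, 0)
  expect_equal(reduced_chi_square(obs, calc, rep(0.2, 5), n_free = 2),
    5 / 3)
  expect_error(reduced_chi_square(1:3, 1:3, rep(0.2, 3), n_free = 3),
    "freedom")
  expect_error(reduced_chi_square(1, 1, 0), "positive")
})

test_that("weights are recovered from couplings the initial basins explain", {
  b <- example_basins("alanine-like")
  obs <- tibble::tibble(
    coupling_type = predict_coupling(b)$coupling_type,
    value_Hz = predict_coupling(b)$J_Hz,
    sigma_Hz = 0.2
  )
  # start from a different weight profile: only the geometry is shared
  fit <- fit_basins(obs, example_basins("phenylalanine-like"))
  expect_equal(fit$basins$weight, b$weight, tolerance = 1e-6)
  expect_lt(fit$chi2, 1e-10)
  expect_equal(fit$chi2_reduced, fit$chi2 / 1)
})

test_that("noiseless synthetic weights are recovered within 0.03", {
  true_b <- example_basins("phenylalanine-like")
  obs <- tibble::tibble(
    coupling_type = predict_coupling(true_b)$coupling_type,
    value_Hz = predict_coupling(true_b)$J_Hz,
    sigma_Hz = 0.2
  )
  fit <- fit_basins(obs, example_basins("alanine-like"))
  expect_true(all(abs(fit$basins$weight - true_b$weight) < 0.03))
})

test_that("the position stage can only improve the fit and honors freeze_psi", {
  true_b <- example_basins("alanine-like")
  true_b$phi0[1] <- -80 # shifted pPII basin relative to the initial guess
  obs <- observe_couplings(true_b, noise_sd_hz = 0.1, seed = 9)
  init <- example_basins("alanine-like")
  suppressWarnings({
    fa <- fit_basins(obs, init, stage = "weights", grid_step = 6)
    fb <- fit_basins(obs, init, stage = "positions", freeze_psi = TRUE,
      grid_step = 6, multistart = 2)
  })
  expect_lte(fb$chi2, fa$chi2 + 1e-9)
  expect_equal(fb$basins$psi0, init$psi0)
  expect_false(isTRUE(all.equal(fb$basins$phi0, init$phi0)))
})

test_that("observations below the Karplus minimum are flagged as irreducible", {
  b <- example_basins("alanine-like")
  kar <- karplus_default()
  jmin <- min(karplus_value("3J(HN,C)", seq(-180, 180, 0.5)))
  obs <- tibble::tibble(
    coupling_type = c("3J(HN,HA)", "3J(HN,C)"),
    value_Hz = c(6, jmin - 0.3),
    sigma_Hz = 0.2
  )
  suppressWarnings(fit <- fit_basins(obs, b))
  expect_equal(fit$observations$below_minimum,
    c(FALSE, TRUE)[match(fit$observations$coupling_type, obs$coupling_type)])
  expect_gt(fit$chi2, 1) # the impossible observation leaves a residual
})

test_that("coupling fits validate their inputs", {
  b <- example_basins("alanine-like")
  expect_error(
    fit_basins(tibble::tibble(coupling_type = character(),
      value_Hz = numeric(), sigma_Hz = numeric()), b),
    "No coupling"
  )
  expect_error(
    fit_basins(tibble::tibble(coupling_type = "3J(HN,HA)", value_Hz = 6,
      sigma_Hz = 0), b),
    "positive"
  )
  expect_warning(
    fit_basins(tibble::tibble(coupling_type = "3J(HN,HA)", value_Hz = 6,
      sigma_Hz = 0.2), b),
    "Fewer observations"
  )
})

test_that("Ramachandran grids are normalized, basin-resolved and round-trippable", {
  b <- example_basins("alanine-like")
  g <- ramachandran_grid(b, grid_step = 4, per_basin = TRUE)
  expect_equal(sum(g$density), 1, tolerance = 1e-9)
  for (k in seq_len(nrow(b))) {
    expect_equal(sum(g[[b$basin[k]]]), b$weight[k], tolerance = 1e-6)
  }

  # a delta-like basin concentrates in a single cell
  bd <- basin_set("pPII", -72, 152, 0.3, 0.3, 1)
  gd <- ramachandran_grid(bd, grid_step = 4)
  expect_gt(max(gd$density), 0.99)

  # a huge-width basin approaches the flat distribution
  bu <- basin_set("flat", 0, 0, 2000, 2000, 1)
  gu <- ramachandran_grid(bu, grid_step = 10)
  expect_lt(max(gu$density) / min(gu$density), 1.01)

  tf <- tempfile(fileext = ".txt")
  write_ramachandran_grid(g, tf)
  g2 <- read_ramachandran_grid(tf)
  expect_equal(g2$density, g$density, tolerance = 1e-9)
  expect_equal(g2$phi, g$phi)

  # headerless whitespace-separated dialect
  tf2 <- tempfile(fileext = ".txt")
  writeLines(c("# comment", paste(g$phi, g$psi, g$density)), tf2)
  g3 <- read_ramachandran_grid(tf2)
  expect_equal(g3$density, g$density, tolerance = 1e-9)

  empty <- tempfile()
  writeLines("# only a comment", empty)
  expect_error(read_ramachandran_grid(empty), "Empty")
})
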