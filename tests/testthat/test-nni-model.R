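flat_intrinsic <- function(n) {
  tibble::tibble(
    residue = rep(seq_len(n), each = 4),
    state = rep(conformer_states(), n), G_kJmol = 0
  )
}

test_that("conformer weights carry each intrinsic energy once and both directional couplings", {
  expect_equal(
    conformer_weight(flat_intrinsic(2), NULL, c("pPII", "pPII")), 1
  )
  expect_equal(
    conformer_weight(flat_intrinsic(3), NULL, rep("pPII", 3)), 1
  )

  # second residue beta-disfavored, one directional coupling compensating
  g <- flat_intrinsic(2)
  g$G_kJmol[g$residue == 2 & g$state == "beta"] <- -5.19
  p <- nni_params(j = 2, i = 1, L = "beta", K = "pPII", dG_kJmol = 2)
  w <- conformer_weight(g, p, c("pPII", "beta"))
  expect_equal(w, exp((-5.19 + 2) / rt_kj(300)))
  expect_equal(w, 0.278, tolerance = 2e-3)

  expect_error(conformer_weight(g, p, "pPII"), "length")
})

test_that("enumeration normalizes and matches hand-counted small cases", {
  # uniform intrinsic, one pair coupling of RT log 2: that conformer
  # doubles its weight -> 2/17
  p <- nni_params(j = 2, i = 1, L = "beta", K = "pPII",
    dG_kJmol = rt_kj(300) * log(2))
  d <- enumerate_conformers(flat_intrinsic(2), p)
  expect_equal(sum(d$population), 1, tolerance = 1e-12)
  hit <- d$state_1 == "pPII" & d$state_2 == "beta"
  expect_equal(d$population[hit], 2 / 17, tolerance = 1e-12)
  expect_equal(attr(d, "Z"), 17, tolerance = 1e-12)
})

test_that("without couplings the joint factorizes into single-residue fractions", {
  intr <- intrinsic_energies(make_fractions(gag_profile, n = 2))
  d <- enumerate_conformers(intr, NULL)
  marg <- intrinsic_fractions(intr)
  for (r in seq_len(nrow(d))) {
    expect_equal(
      d$population[r],
      marg$fraction[marg$residue == 1 & marg$state == d$state_1[r]] *
        marg$fraction[marg$residue == 2 & marg$state == d$state_2[r]],
      tolerance = 1e-14
    )
  }
  expect_equal(
    d$population[d$state_1 == "pPII" & d$state_2 == "pPII"], 0.64,
    tolerance = 1e-12
  )
  expect_equal(
    marginal_fractions(d)$fraction, marg$fraction,
    tolerance = 1e-12
  )
})

test_that("enumeration marginals agree with the brute-force oracle", {
  set.seed(21)
  for (n in 2:3) {
    intr <- intrinsic_energies(make_fractions(c(0.5, 0.3, 0.15, 0.05), n))
    gmat <- matrix(intr$G_kJmol, n, 4, byrow = TRUE,
      dimnames = list(NULL, conformer_states()))
    for (k in 1:10) {
      params <- random_params(n, magnitude = 4)
      d <- enumerate_conformers(intr, params)
      joint <- oracle_joint(gmat, as.data.frame(params))
      for (r in seq_len(n)) {
        expect_equal(
          marginal_fractions(d, r)$fraction,
          unname(oracle_marginal(joint, paste0("Var", r))),
          tolerance = 1e-12
        )
      }
    }
  }
})

test_that("the joint distribution is gauge-invariant under directional redistribution", {
  intr <- intrinsic_energies(make_fractions(gag_profile, 2))
  set.seed(5)
  for (k in 1:10) {
    total <- runif(1, -4, 4)
    split <- runif(1)
    a <- nni_params(
      j = c(2, 1), i = c(1, 2), L = c("beta", "pPII"),
      K = c("pPII", "beta"),
      dG_kJmol = c(total * split, total * (1 - split))
    )
    b <- nni_params(j = 2, i = 1, L = "beta", K = "pPII", dG_kJmol = total)
    da <- enumerate_conformers(intr, a)
    db <- enumerate_conformers(intr, b)
    expect_equal(da$population, db$population, tolerance = 1e-12)
  }
})

test_that("directional couplings combine by mutual summation", {
  p <- nni_params(
    j = c(2, 1), i = c(1, 2), L = c("pPII", "beta"), K = c("beta", "pPII"),
    dG_kJmol = c(1, 2)
  )
  comb <- combine_directional(p)
  # lower residue beta, upper residue pPII picks up both directions
  expect_equal(
    comb$dG_kJmol[comb$state_lo == "beta" & comb$state_hi == "pPII"], 3
  )
  expect_true(all(
    comb$dG_kJmol[!(comb$state_lo == "beta" & comb$state_hi == "pPII")] == 0
  ))
  empty <- combine_directional(nni_params(), n_residues = 2)
  expect_true(all(empty$dG_kJmol == 0))
})

test_that("marginals require a valid residue index and reflect asymmetric couplings", {
  intr <- intrinsic_energies(make_fractions(gag_profile, 2))
  d <- enumerate_conformers(intr, NULL)
  expect_error(marginal_fractions(d, 3), "residue")

  # a one-sided state pair coupling breaks the homodimer marginal symmetry
  asym <- nni_params(j = 2, i = 1, L = "beta", K = "pPII", dG_kJmol = 3)
  da <- enumerate_conformers(intr, asym)
  m1 <- marginal_fractions(da, 1)$fraction
  m2 <- marginal_fractions(da, 2)$fraction
  expect_gt(max(abs(m1 - m2)), 0.05)

  # direction-symmetric couplings on symmetric state pairs keep it
  sym <- nni_params(
    j = c(2, 1), i = c(1, 2), L = c("beta", "beta"), K = c("pPII", "pPII"),
    dG_kJmol = c(1.5, 1.5)
  )
  ds <- enumerate_conformers(intr, sym)
  expect_equal(
    marginal_fractions(ds, 1)$fraction,
    marginal_fractions(ds, 2)$fraction, tolerance = 1e-12
  )
})

test_that("adjacency and duplicates are rejected", {
  expect_error(
    nni_params(j = 3, i = 1, L = "pPII", K = "beta", dG_kJmol = 1),
    "adjacent"
  )
  expect_error(
    nni_params(j = c(2, 2), i = c(1, 1), L = c("pPII", "pPII"),
      K = c("beta", "beta"), dG_kJmol = c(1, 2)),
    "Duplicate"
  )
})
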