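# Intrinsic four-state propensity presets used by the synthetic
# generator: a pPII-dominated residue, a beta-dominated branched residue
# and a turn-rich hydrogen-bonding residue.
intrinsic_profiles <- function() {
  list(
    "alanine-like" = c(0.80, 0.10, 0.05, 0.05),
    "valine-like" = c(0.20, 0.65, 0.10, 0.05),
    "aspartate-like" = c(0.30, 0.30, 0.30, 0.10)
  )
}

#' Define a synthetic ground-truth scenario
#'
#' Bundles the knobs of the synthetic-data generator: system size,
#' intrinsic propensity profile, coupling magnitude and observation
#' noise. Couplings of magnitude 0-4 kJ/mol span the experimentally
#' observed range (up to and beyond the thermal energy of ~2.5 kJ/mol).
#'
#' @param seed Integer seed; every draw derived from the scenario is
#'   reproducible given it.
#' @param n_residues 2 (tetrapeptide) or 3 (pentapeptide).
#' @param intrinsic_profile Name of a preset (`"alanine-like"`,
#'   `"valine-like"`, `"aspartate-like"`) or a numeric vector of four
#'   fractions.
#' @param coupling_magnitude Couplings are drawn uniformly in
#'   `±coupling_magnitude` kJ/mol.
#' @param noise_sd_fraction Gaussian noise SD on observed mole fractions.
#' @param noise_sd_hz Gaussian noise SD on observed couplings, Hz.
#' @return List of class `nni_scenario`.
#' @export
synthetic_scenario <- function(seed = 1, n_residues = 2,
                               intrinsic_profile = "alanine-like",
                               coupling_magnitude = 2,
                               noise_sd_fraction = 0.02,
                               noise_sd_hz = 0.2) {
  stopifnot(n_residues %in% 2:3, coupling_magnitude >= 0,
    coupling_magnitude <= 10)
  if (is.character(intrinsic_profile)) {
    profile <- intrinsic_profiles()[[intrinsic_profile]]
    if (is.null(profile)) {
      abort(paste0("Unknown intrinsic profile: ", intrinsic_profile))
    }
  } else {
    profile <- as.numeric(intrinsic_profile)
    stopifnot(length(profile) == 4, all(profile >= 0))
    profile <- profile / sum(profile)
  }
  structure(
    list(
      seed = as.integer(seed), n_residues = as.integer(n_residues),
      profile = profile, coupling_magnitude = coupling_magnitude,
      noise_sd_fraction = noise_sd_fraction, noise_sd_hz = noise_sd_hz
    ),
    class = "nni_scenario"
  )
}

#' Draw a ground-truth system from a scenario
#'
#' Builds the intrinsic energies from the scenario's propensity profile
#' and draws directional pPII/beta cross couplings (the dominant
#' interaction channel) uniformly within the scenario magnitude for every
#' adjacent dimer. Same-state pPII-pPII and beta-beta couplings are never
#' generated, matching the fitting convention.
#'
#' @param scenario An [synthetic_scenario()].
#' @return List with elements `intrinsic` (tibble), `params`
#'   ([nni_params()]), `temperature` and `scenario`.
#' @export
make_truth <- function(scenario) {
  stopifnot(inherits(scenario, "nni_scenario"))
  set.seed(scenario$seed)
  n <- scenario$n_residues
  fractions <- tibble(
    residue = rep(seq_len(n), each = 4),
    state = rep(conformer_states(), n),
    fraction = rep(scenario$profile, n)
  )
  intrinsic <- intrinsic_energies(fractions)
  cross <- tibble(
    state_lo = c("pPII", "beta"), state_hi = c("beta", "pPII")
  )
  draws <- tidyr::expand_grid(pair = seq_len(n - 1L), cross)
  m <- scenario$coupling_magnitude
  params <- nni_params(
    j = c(draws$pair + 1L, draws$pair),
    i = c(draws$pair, draws$pair + 1L),
    L = c(draws$state_hi, draws$state_lo),
    K = c(draws$state_lo, draws$state_hi),
    dG_kJmol = runif(2 * nrow(draws), -m, m),
    free = TRUE
  )
  list(
    intrinsic = intrinsic, params = params,
    temperature = 300, scenario = scenario
  )
}

#' Observe noisy residue mole fractions from a ground truth
#'
#' Computes the exact single-residue marginals of the truth's joint
#' conformer distribution, adds truncated Gaussian noise (redrawn until
#' each fraction stays in \[0, 1\]) and renormalizes each residue back to
#' the simplex.
#'
#' @param truth Output of [make_truth()].
#' @param noise_sd_fraction Noise SD; defaults to the scenario's value.
#' @param seed Seed for the noise draw; defaults to `scenario$seed + 1`.
#' @return Tibble (`residue`, `state`, `fraction`).
#' @export
observe_fractions <- function(truth,
                              noise_sd_fraction = NULL, seed = NULL) {
  sd <- noise_sd_fraction %||% truth$scenario$noise_sd_fraction
  seed <- seed %||% (truth$scenario$seed + 1L)
  dist <- enumerate_conformers(truth$intrinsic, truth$params,
    truth$temperature)
  marg <- marginal_fractions(dist)
  if (sd == 0) return(marg)
  set.seed(seed)
  noisy <- vapply(marg$fraction, function(p) {
    repeat {
      x <- p + rnorm(1, 0, sd)
      if (x >= 0 && x <= 1) return(x)
    }
  }, numeric(1))
  marg$fraction <- noisy
  validate_fractions(marg)
}

#' Observe noisy scalar couplings from a basin set
#'
#' Predicts the ensemble-averaged couplings of the basin set and adds
#' independent Gaussian noise.
#'
#' @param basins A [basin_set()].
#' @param karplus Karplus coefficient table.
#' @param noise_sd_hz Noise SD in Hz.
#' @param seed Integer seed.
#' @param sigma_Hz Uncertainty attached to each observation (defaults to
#'   the noise SD).
#' @param grid_step Quadrature step for the prediction, degrees.
#' @return Tibble (`coupling_type`, `value_Hz`, `sigma_Hz`).
#' @export
observe_couplings <- function(basins, karplus = karplus_default(),
                              noise_sd_hz = 0.2, seed = 1,
                              sigma_Hz = NULL, grid_step = 2) {
  pred <- predict_coupling(basins, karplus, grid_step)
  set.seed(seed)
  tibble(
    coupling_type = pred$coupling_type,
    value_Hz = pred$J_Hz + rnorm(nrow(pred), 0, noise_sd_hz),
    sigma_Hz = sigma_Hz %||% max(noise_sd_hz, 1e-6)
  )
}
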