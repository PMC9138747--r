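#' Thermal energy RT in kJ/mol
#'
#' @param temperature Temperature in kelvin.
#' @return RT in kJ/mol (R = 8.314 J mol-1 K-1).
#' @export
#' @examples
#' rt_kj(300) # ~2.494 kJ/mol, the thermal-energy benchmark
rt_kj <- function(temperature = 300) {
  stopifnot(is.numeric(temperature), temperature > 0)
  8.314 * temperature / 1000
}

#' Intrinsic Gibbs energies from residue mole fractions
#'
#' Inverts the propensity relation chi_K = exp(+G_K/RT) / sum_K'
#' exp(+G_K'/RT): given the observed mole fractions of the four
#' conformational classes of a residue (typically from its GxG reference
#' peptide), returns G_K = RT log(chi_K / chi_pPII) in kJ/mol, with pPII
#' as the zero-energy reference state.
#'
#' Note the sign convention used throughout this package: statistical
#' weights are proportional to exp(+G/RT), so a *more* populated state has
#' a *higher* G. This is opposite to the usual Boltzmann convention but is
#' the native convention of the interaction model (positive coupling
#' energies stabilize a pair of states).
#'
#' Fractions that are exactly zero (or below `eps_floor`) are floored at
#' `eps_floor` before the logarithm so that unobserved classes map to a
#' large negative, but finite, energy.
#'
#' @param fractions Tibble with columns `residue`, `state`, `fraction`
#'   (four-state or five-basin dialect; the latter is collapsed).
#' @param temperature Kelvin.
#' @param eps_floor Floor applied to zero fractions before the log.
#' @return Tibble with columns `residue`, `state`, `G_kJmol`.
#' @seealso [intrinsic_fractions()] for the inverse map.
#' @export
#' @examples
#' gag <- tibble::tibble(
#'   residue = 1, state = conformer_states(),
#'   fraction = c(0.8, 0.1, 0.06, 0.04)
#' )
#' intrinsic_energies(gag) # G[beta] = RT log(0.125) ~ -5.19 kJ/mol
intrinsic_energies <- function(fractions, temperature = 300,
                               eps_floor = 1e-4) {
  fractions <- validate_fractions(fractions)
  rt <- rt_kj(temperature)
  out <- group_by(fractions, .data$residue)
  out <- mutate(out,
    .ref = .data$fraction[.data$state == "pPII"],
    .chi = pmax(.data$fraction, eps_floor)
  )
  out <- ungroup(out)
  if (any(out$.ref <= 0)) {
    abort("Reference state pPII has zero mole fraction; intrinsic energies are undefined.")
  }
  out <- mutate(out,
    G_kJmol = ifelse(.data$state == "pPII", 0, rt * log(.data$.chi / .data$.ref))
  )
  select(out, "residue", "state", "G_kJmol")
}

#' Residue mole fractions from intrinsic Gibbs energies
#'
#' Forward propensity relation: chi_K = exp(+G_K/RT) normalized over the
#' four classes (the single-residue, interaction-free limit).
#'
#' @param energies Tibble with columns `residue`, `state`, `G_kJmol`.
#' @param temperature Kelvin.
#' @return Tibble with columns `residue`, `state`, `fraction`.
#' @export
#' @examples
#' g <- tibble::tibble(
#'   residue = 1, state = conformer_states(),
#'   G_kJmol = c(0, rt_kj(300) * log(2), 0, 0)
#' )
#' intrinsic_fractions(g) # beta = 2/5, others 1/5
intrinsic_fractions <- function(energies, temperature = 300) {
  stopifnot(all(c("residue", "state", "G_kJmol") %in% names(energies)))
  if (any(!is.finite(energies$G_kJmol))) {
    abort("Intrinsic energies must be finite.")
  }
  rt <- rt_kj(temperature)
  out <- group_by(energies, .data$residue)
  out <- mutate(out, fraction = {
    w <- exp(.data$G_kJmol / rt)
    w / sum(w)
  })
  out <- ungroup(out)
  out <- select(out, "residue", "state", "fraction")
  arrange(out, .data$residue, match(.data$state, conformer_states()))
}

# Intrinsic-energy tibble -> n x 4 matrix, rows in residue order, columns
# in the fixed state order.
energies_matrix <- function(energies) {
  residues <- sort(unique(energies$residue))
  m <- matrix(0, length(residues), 4,
    dimnames = list(residues, conformer_states())
  )
  m[cbind(
    match(energies$residue, residues),
    match(energies$state, conformer_states())
  )] <- energies$G_kJmol
  m
}
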