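#' The four coarse conformational classes
#'
#' Residue backbone conformations are coarse-grained into four classes:
#' polyproline II (`pPII`), beta-strand (`beta`), and two aggregated
#' turn/helix classes. `t_l` pools the non-extended basins in the left half
#' of the Ramachandran plot (right-handed helical, type I/II' beta-turn
#' i+2 and inverse gamma-turn conformations); `t_r` pools the right-half
#' basins (left-handed helical, asx-turn and gamma-turn conformations).
#' The ordering is fixed and used for every vector and matrix layout in
#' the package.
#'
#' @return Character vector `c("pPII", "beta", "t_l", "t_r")`.
#' @export
#' @examples
#' conformer_states()
conformer_states <- function() {
  c("pPII", "beta", "t_l", "t_r")
}

# Five-basin dialect used by the Gaussian Ramachandran analysis; collapsed
# to the four classes as t_l = igamma_typeII + rh, t_r = lh.
basin_labels <- function() {
  c("pPII", "beta", "igamma_typeII", "rh", "lh")
}

# Canonicalize free-text state/basin labels from input tables.
normalize_state_labels <- function(x) {
  key <- tolower(gsub("[^a-z2]", "", tolower(x)))
  map <- c(
    "ppii" = "pPII", "pii" = "pPII", "polyprolineii" = "pPII",
    "beta" = "beta", "b" = "beta", "betastrand" = "beta", "strand" = "beta",
    "tl" = "t_l", "tr" = "t_r", "turnl" = "t_l", "turnr" = "t_r",
    "igammatypeii" = "igamma_typeII", "igamma" = "igamma_typeII",
    "igtype2" = "igamma_typeII", "igammatype2" = "igamma_typeII",
    "igtypeii" = "igamma_typeII", "type2beta" = "igamma_typeII",
    "typeiibeta" = "igamma_typeII", "invgamma" = "igamma_typeII",
    "inversegamma" = "igamma_typeII",
    "rh" = "rh", "righthanded" = "rh", "righthandedhelical" = "rh",
    "lh" = "lh", "lefthanded" = "lh", "lefthandedhelical" = "lh"
  )
  # the unicode beta glyph survives gsub as an empty match; handle directly
  key[trimws(x) %in% c("β", "β-strand")] <- "beta"
  out <- unname(map[key])
  if (anyNA(out)) {
    abort(paste0(
      "Unknown conformational state label(s): ",
      paste(unique(x[is.na(out)]), collapse = ", ")
    ))
  }
  out
}

#' Collapse a five-basin mole-fraction table to the four coarse classes
#'
#' Gaussian-basin Ramachandran analyses resolve five basins (`pPII`,
#' `beta`, `igamma_typeII`, `rh`, `lh`). The four-state interaction model
#' pools basins with similar phi: `t_l = igamma_typeII + rh` and
#' `t_r = lh`. Tables already using the four class labels pass through
#' unchanged.
#'
#' @param fractions Tibble with columns `residue`, `state`, `fraction`
#'   (additional columns such as `peptide` are preserved as grouping keys).
#' @return Tibble with the same grouping columns and four states per
#'   residue.
#' @export
#' @examples
#' five <- tibble::tibble(
#'   residue = 1, state = c("pPII", "beta", "igamma_typeII", "rh", "lh"),
#'   fraction = c(0.45, 0.45, 0, 0.05, 0.05)
#' )
#' collapse_basins(five)
collapse_basins <- function(fractions) {
  stopifnot(all(c("residue", "state", "fraction") %in% names(fractions)))
  fractions <- mutate(fractions, state = normalize_state_labels(.data$state))
  if (all(fractions$state %in% conformer_states())) {
    return(as_tibble(fractions))
  }
  fractions <- mutate(fractions, state = dplyr::case_match(
    .data$state,
    c("igamma_typeII", "rh") ~ "t_l",
    "lh" ~ "t_r",
    .default = .data$state
  ))
  keys <- setdiff(names(fractions), "fraction")
  out <- summarise(
    group_by(fractions, across(all_of(keys))),
    fraction = sum(.data$fraction), .groups = "drop"
  )
  arrange(out, .data$residue, match(.data$state, conformer_states()))
}

# Validate a long-format fraction table for one or more residues and
# return it complete (all four states present, ordered).
validate_fractions <- function(fractions, renormalize = TRUE) {
  stopifnot(all(c("residue", "state", "fraction") %in% names(fractions)))
  fractions <- mutate(fractions, state = normalize_state_labels(.data$state))
  if (!all(fractions$state %in% conformer_states())) {
    fractions <- collapse_basins(fractions)
  }
  if (any(fractions$fraction < 0)) {
    abort("Mole fractions must be non-negative.")
  }
  full <- tidyr::complete(
    fractions,
    residue = unique(fractions$residue),
    state = conformer_states(),
    fill = list(fraction = 0)
  )
  if (anyDuplicated(full[c("residue", "state")])) {
    abort("Duplicate (residue, state) rows in fraction table.")
  }
  full <- group_by(full, .data$residue)
  if (renormalize) {
    full <- mutate(full, fraction = .data$fraction / sum(.data$fraction))
  }
  full <- ungroup(full)
  arrange(full, .data$residue, match(.data$state, conformer_states()))
}
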