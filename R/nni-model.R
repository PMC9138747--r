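#' Directional nearest-neighbor interaction parameters
#'
#' Builds a validated table of directional NNI Gibbs energies
#' dG[L,K; j,i]: the coupling felt by residue `j` in state `L` when its
#' adjacent neighbor `i` is in state `K`. Only adjacent pairs
#' (|j - i| = 1) are allowed; entries not listed are exactly zero.
#'
#' The joint conformer distribution depends on directional entries only
#' through the mutual pairwise sums dG[L,K; j,i] + dG[K,L; i,j] (see
#' [combine_directional()]); the directional split is a bookkeeping
#' convention, not an identifiable quantity.
#'
#' @param j,i Integer vectors of adjacent residue indices (1-based among
#'   non-terminal residues).
#' @param L,K Conformational states of residues `j` and `i`.
#' @param dG_kJmol Coupling energies in kJ/mol (positive = stabilizing).
#' @param free Logical; whether the entry is free in fitting. By
#'   convention pPII-pPII and beta-beta couplings are not fitted.
#' @return Tibble of class `nni_params` with columns
#'   `j, i, L, K, dG_kJmol, free`.
#' @export
#' @examples
#' nni_params(j = 2, i = 1, L = "beta", K = "pPII", dG_kJmol = 2)
nni_params <- function(j = integer(), i = integer(), L = character(),
                       K = character(), dG_kJmol = numeric(),
                       free = TRUE) {
  out <- tibble(
    j = as.integer(j), i = as.integer(i),
    L = normalize_state_labels_allow_empty(L),
    K = normalize_state_labels_allow_empty(K),
    dG_kJmol = as.numeric(dG_kJmol), free = free
  )
  if (nrow(out) && any(abs(out$j - out$i) != 1)) {
    abort("NNI parameters are defined for adjacent residues only (|j - i| == 1).")
  }
  if (anyDuplicated(out[c("j", "i", "L", "K")])) {
    abort("Duplicate directional NNI entries.")
  }
  class(out) <- c("nni_params", class(out))
  out
}

normalize_state_labels_allow_empty <- function(x) {
  if (length(x) == 0) return(character())
  normalize_state_labels(x)
}

#' Combine directional couplings into mutual pair sums
#'
#' The quantity the joint distribution actually depends on, and the one
#' reported in bar-chart summaries, is the sum of the two directional
#' entries acting on the same ordered state pair of a residue dimer:
#' for the pair of residues (p, p+1) with the lower-index residue in
#' `state_lo` and the higher-index residue in `state_hi`,
#' `dG_sum = dG[state_hi, state_lo; p+1, p] + dG[state_lo, state_hi; p, p+1]`.
#'
#' @param params An `nni_params` tibble.
#' @param n_residues Number of non-terminal residues (defaults to the
#'   largest index present).
#' @return Tibble with columns `pair` (lower residue index of the dimer),
#'   `state_lo`, `state_hi`, `dG_kJmol` — one row per ordered state pair
#'   and adjacent dimer.
#' @export
#' @examples
#' p <- nni_params(
#'   j = c(2, 1), i = c(1, 2), L = c("pPII", "beta"),
#'   K = c("beta", "pPII"), dG_kJmol = c(1, 2)
#' )
#' # dimer in (beta, pPII): combined coupling 1 + 2 = 3 kJ/mol
#' combine_directional(p)
combine_directional <- function(params, n_residues = NULL) {
  n_residues <- n_residues %||% max(c(params$j, params$i, 2L))
  states <- conformer_states()
  grid <- tidyr::expand_grid(
    pair = seq_len(n_residues - 1L),
    state_lo = states, state_hi = states
  )
  lookup <- function(jj, ii, LL, KK) {
    hit <- params$j == jj & params$i == ii & params$L == LL & params$K == KK
    if (any(hit)) sum(params$dG_kJmol[hit]) else 0
  }
  grid$dG_kJmol <- purrr::pmap_dbl(grid, function(pair, state_lo, state_hi) {
    lookup(pair + 1L, pair, state_hi, state_lo) +
      lookup(pair, pair + 1L, state_lo, state_hi)
  })
  grid
}

# Combined couplings as a list of 4x4 matrices, one per adjacent dimer:
# D[[p]][s_lo, s_hi] in kJ/mol.
delta_matrices <- function(params, n_residues) {
  states <- conformer_states()
  if (is.null(params) || nrow(params) == 0) {
    return(replicate(n_residues - 1L,
      matrix(0, 4, 4, dimnames = list(states, states)),
      simplify = FALSE
    ))
  }
  comb <- combine_directional(params, n_residues)
  lapply(seq_len(n_residues - 1L), function(p) {
    m <- matrix(0, 4, 4, dimnames = list(states, states))
    sub <- comb[comb$pair == p, ]
    m[cbind(match(sub$state_lo, states), match(sub$state_hi, states))] <-
      sub$dG_kJmol
    m
  })
}

# All 4^n state-index sequences as a matrix (rows = conformers).
state_grid <- function(n_residues) {
  as.matrix(rev(tidyr::expand_grid(!!!rev(setNames(
    replicate(n_residues, 1:4, simplify = FALSE),
    paste0("r", seq_len(n_residues))
  )))))
}

# Log Boltzmann exponents (already divided by RT) for every conformer.
conformer_log_weights <- function(gmat, dmats, seqs, rt) {
  n <- ncol(seqs)
  lw <- rowSums(matrix(gmat[cbind(rep(seq_len(n), each = nrow(seqs)),
    as.vector(seqs))], nrow(seqs), n))
  for (p in seq_len(n - 1L)) {
    lw <- lw + dmats[[p]][cbind(seqs[, p], seqs[, p + 1L])]
  }
  lw / rt
}

#' Statistical weight of one peptide conformer
#'
#' The Boltzmann weight of a full conformer sequence is
#' `exp((sum_j G[state_j, j] + sum_pairs (dG forward + dG backward)) / RT)`:
#' each residue contributes its intrinsic energy once and each adjacent
#' dimer contributes both directional coupling terms.
#'
#' @param intrinsic Tibble with columns `residue`, `state`, `G_kJmol`.
#' @param params An `nni_params` tibble (or `NULL` for no couplings).
#' @param sequence Character vector of states, one per residue in order.
#' @param temperature Kelvin.
#' @return Positive scalar weight (dimensionless).
#' @export
#' @examples
#' g <- tibble::tibble(
#'   residue = rep(1:2, each = 4),
#'   state = rep(conformer_states(), 2), G_kJmol = 0
#' )
#' conformer_weight(g, NULL, c("pPII", "pPII")) # reference state: 1
conformer_weight <- function(intrinsic, params, sequence,
                             temperature = 300) {
  sequence <- normalize_state_labels(sequence)
  gmat <- energies_matrix(intrinsic)
  n <- nrow(gmat)
  if (length(sequence) != n) {
    abort("Sequence length must equal the number of residues.")
  }
  dmats <- delta_matrices(params, n)
  idx <- matrix(match(sequence, conformer_states()), nrow = 1)
  exp(conformer_log_weights(gmat, dmats, idx, rt_kj(temperature)))
}

#' Joint conformer distribution by exhaustive enumeration
#'
#' Enumerates all 4^n conformer sequences of a peptide with n
#' non-terminal residues (n = 2 for tetrapeptides, 3 for pentapeptides),
#' computes their Boltzmann weights under the intrinsic energies and NNI
#' couplings, and normalizes by the partition sum. Exponents are handled
#' in log space, so large couplings cannot overflow.
#'
#' With all couplings zero the joint distribution factorizes exactly into
#' the product of the single-residue fractions (the isolated pair
#' hypothesis limit).
#'
#' @inheritParams conformer_weight
#' @return Tibble of class `conformer_tbl` with one row per conformer:
#'   state columns `state_1 ... state_n`, `weight` and `population`.
#'   The partition sum is attached as attribute `"Z"` (and `"logZ"`), the
#'   temperature as `"temperature"`.
#' @export
#' @examples
#' g <- intrinsic_energies(tibble::tibble(
#'   residue = rep(1:2, each = 4), state = rep(conformer_states(), 2),
#'   fraction = rep(c(0.8, 0.1, 0.06, 0.04), 2)
#' ))
#' d <- enumerate_conformers(g)
#' d[which.max(d$population), ] # chi(pPII, pPII) = 0.64
enumerate_conformers <- function(intrinsic, params = NULL,
                                 temperature = 300) {
  gmat <- energies_matrix(intrinsic)
  n <- nrow(gmat)
  stopifnot(n >= 2)
  seqs <- state_grid(n)
  dmats <- delta_matrices(params, n)
  lw <- conformer_log_weights(gmat, dmats, seqs, rt_kj(temperature))
  m <- max(lw)
  logZ <- m + log(sum(exp(lw - m)))
  out <- as_tibble(setNames(
    lapply(seq_len(n), function(r) conformer_states()[seqs[, r]]),
    paste0("state_", seq_len(n))
  ))
  out$weight <- exp(lw)
  out$population <- exp(lw - logZ)
  attr(out, "Z") <- exp(logZ)
  attr(out, "logZ") <- logZ
  attr(out, "temperature") <- temperature
  class(out) <- c("conformer_tbl", class(out))
  out
}

#' Single-residue marginals of a joint conformer distribution
#'
#' @param distribution A `conformer_tbl` from [enumerate_conformers()].
#' @param residue Residue index, or `NULL` for all residues.
#' @return Tibble with columns `residue`, `state`, `fraction`.
#' @export
marginal_fractions <- function(distribution, residue = NULL) {
  scols <- grep("^state_", names(distribution), value = TRUE)
  n <- length(scols)
  residues <- residue %||% seq_len(n)
  if (any(!residues %in% seq_len(n))) {
    abort("Unknown residue index for this distribution.")
  }
  out <- purrr::map_dfr(residues, function(r) {
    agg <- tapply(distribution$population, factor(distribution[[scols[r]]],
      levels = conformer_states()
    ), sum, default = 0)
    tibble(residue = r, state = conformer_states(), fraction = as.numeric(agg))
  })
  out
}

# Marginals as a flat vector in (residue, state) order; fast path used by
# the fitting objective.
marginal_vector <- function(pop, seqs) {
  n <- ncol(seqs)
  out <- numeric(4L * n)
  for (r in seq_len(n)) {
    for (k in 1:4) out[(r - 1L) * 4L + k] <- sum(pop[seqs[, r] == k])
  }
  out
}

#' @export
print.nni_params <- function(x, ...) {
  cat("Directional NNI parameters (", nrow(x), " entries)\n", sep = "")
  NextMethod()
}
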