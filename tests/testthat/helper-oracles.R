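# Independent brute-force oracle for the joint conformer distribution:
# plain nested evaluation of the Boltzmann exponent, direct exp
# arithmetic (no log space), no shared code with the package internals.
oracle_joint <- function(gmat, params, temperature = 300) {
  states <- c("pPII", "beta", "t_l", "t_r")
  n <- nrow(gmat)
  rt <- 8.314 * temperature / 1000
  combis <- expand.grid(rep(list(states), n), stringsAsFactors = FALSE)
  w <- apply(combis, 1, function(sq) {
    e <- 0
    for (r in seq_len(n)) e <- e + gmat[r, sq[[r]]]
    if (!is.null(params) && nrow(params) > 0) {
      for (rr in seq_len(nrow(params))) {
        p <- params[rr, ]
        if (sq[[p$j]] == p$L && sq[[p$i]] == p$K) e <- e + p$dG_kJmol
      }
    }
    exp(e / rt)
  })
  combis$population <- w / sum(w)
  combis
}

oracle_marginal <- function(joint, residue) {
  states <- c("pPII", "beta", "t_l", "t_r")
  vapply(states, function(s) {
    sum(joint$population[joint[[residue]] == s])
  }, numeric(1))
}

# Long-format fraction tibble for n residues sharing one profile.
make_fractions <- function(profile, n = 1) {
  tibble::tibble(
    residue = rep(seq_len(n), each = 4),
    state = rep(conformer_states(), n),
    fraction = rep(profile / sum(profile), n)
  )
}

gag_profile <- c(0.8, 0.1, 0.06, 0.04)

# Random directional parameter set on the pPII/beta cross channel plus a
# couple of turn couplings, bounded in magnitude.
random_params <- function(n_residues, magnitude = 3) {
  pairs <- seq_len(n_residues - 1)
  rows <- do.call(rbind, lapply(pairs, function(p) {
    data.frame(
      j = c(p + 1, p, p + 1, p),
      i = c(p, p + 1, p, p + 1),
      L = c("pPII", "beta", "t_l", "pPII"),
      K = c("beta", "pPII", "pPII", "t_r"),
      stringsAsFactors = FALSE
    )
  }))
  nni_params(rows$j, rows$i, rows$L, rows$K,
    dG_kJmol = runif(nrow(rows), -magnitude, magnitude))
}

# Intrinsic tibbles for the bundled worked example, built once.
table1_intrinsic <- function(codes) {
  tab <- suppressWarnings(example_fraction_table())
  refs <- list(A = "GAG", F = "GFG")
  dplyr::bind_rows(lapply(seq_along(codes), function(k) {
    ref <- tab[tab$peptide == refs[[codes[k]]], ]
    g <- intrinsic_energies(ref[c("residue", "state", "fraction")])
    g$residue <- k
    g
  }))
}

table1_observed <- function(peptide) {
  tab <- suppressWarnings(example_fraction_table())
  tab[tab$peptide == peptide, c("residue", "state", "fraction")]
}
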