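# Ordered state pairs freed at each fitting stage. Stage 1: pPII/beta
# cross terms only (the dominant couplings). Stage 2 additionally frees
# couplings between the turn/helix classes and pPII/beta. Same-state
# pPII-pPII and beta-beta couplings are never fitted.
stage_state_pairs <- function(stage) {
  s1 <- list(c("pPII", "beta"), c("beta", "pPII"))
  if (stage == 1) return(s1)
  s2 <- c(s1, purrr::flatten(purrr::map(
    c("t_l", "t_r"),
    function(t) list(c(t, "pPII"), c("pPII", t), c(t, "beta"), c("beta", t))
  )))
  s2
}

free_table <- function(pairs, stage) {
  sp <- stage_state_pairs(stage)
  tidyr::expand_grid(
    pair = pairs,
    tibble(
      state_lo = purrr::map_chr(sp, 1),
      state_hi = purrr::map_chr(sp, 2)
    )
  )
}

# Combined-parameter least-squares engine. `free_tbl` lists the combined
# (pair, state_lo, state_hi) entries to vary; `base` is a combined
# coupling table of fixed contributions added to every evaluation.
# Observed tables must arrive (near-)normalized; the readers renormalize
# with a warning, but a grossly unnormalized table passed directly is a
# user error, not noise.
check_observed_normalized <- function(observed, tol = 0.02) {
  sums <- tapply(observed$fraction, observed$residue, sum)
  if (any(abs(sums - 1) > tol)) {
    abort(paste0(
      "Observed mole fractions are not normalized (residue sums: ",
      paste(signif(sums, 3), collapse = ", "), ")."
    ))
  }
}

nni_fit_engine <- function(observed, intrinsic, free_tbl, base = NULL,
                           temperature = 300, bounds = 10,
                           multistart = 16, start_range = 5, seed = 1,
                           starts_extra = NULL) {
  observed <- validate_fractions(observed)
  gmat <- energies_matrix(intrinsic)
  n <- nrow(gmat)
  if (length(unique(observed$residue)) != n) {
    abort("Observed fractions and intrinsic energies must cover the same residues.")
  }
  rt <- rt_kj(temperature)
  seqs <- state_grid(n)
  states <- conformer_states()
  base_d <- replicate(n - 1L, matrix(0, 4, 4, dimnames = list(states, states)),
    simplify = FALSE
  )
  if (!is.null(base) && nrow(base)) {
    for (r in seq_len(nrow(base))) {
      base_d[[base$pair[r]]][base$state_lo[r], base$state_hi[r]] <-
        base_d[[base$pair[r]]][base$state_lo[r], base$state_hi[r]] +
        base$dG_kJmol[r]
    }
  }
  obs_vec <- observed$fraction[order(
    observed$residue, match(observed$state, states)
  )]
  lo <- match(free_tbl$state_lo, states)
  hi <- match(free_tbl$state_hi, states)
  pr <- free_tbl$pair
  npar <- nrow(free_tbl)

  objective <- function(par) {
    d <- base_d
    for (k in seq_len(npar)) {
      d[[pr[k]]][lo[k], hi[k]] <- d[[pr[k]]][lo[k], hi[k]] + par[k]
    }
    lw <- conformer_log_weights(gmat, d, seqs, rt)
    m <- max(lw)
    w <- exp(lw - m)
    pop <- w / sum(w)
    sum((marginal_vector(pop, seqs) - obs_vec)^2)
  }

  if (!is.null(seed)) set.seed(seed)
  starts <- c(
    list(rep(0, npar)), starts_extra,
    replicate(max(multistart - 1L - length(starts_extra), 0),
      runif(npar, -start_range, start_range),
      simplify = FALSE
    )
  )
  best <- NULL
  for (st in starts) {
    fit <- optim(st, objective,
      method = "L-BFGS-B", lower = -bounds, upper = bounds,
      control = list(maxit = 500)
    )
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  list(
    par = best$par, chi2 = best$value,
    converged = best$convergence == 0, objective = objective
  )
}

# Assemble the user-facing fit object shared by tetra- and pentapeptide
# fits.
new_nni_fit <- function(engine, free_tbl, base, observed, intrinsic,
                        temperature, bounds, chi2_stages, stages,
                        directional) {
  combined <- mutate(free_tbl, dG_kJmol = engine$par, free = TRUE)
  n <- length(unique(observed$residue))
  full <- combine_directional(directional, n_residues = n)
  dist <- enumerate_conformers(intrinsic, directional, temperature)
  structure(
    list(
      combined = combined,
      combined_full = full,
      params = directional,
      chi2 = engine$chi2,
      chi2_stages = chi2_stages,
      converged = engine$converged,
      fitted = marginal_fractions(dist),
      observed = validate_fractions(observed),
      intrinsic = intrinsic,
      base = base,
      free = free_tbl[c("pair", "state_lo", "state_hi")],
      temperature = temperature,
      bounds = bounds,
      n_residues = n,
      stages = stages
    ),
    class = "nni_fit"
  )
}

# Split fitted combined sums into a directional table. Fitted sums are
# split 50/50 between the two directions (only the sum is identifiable);
# `fixed_directional` rows (pentapeptide staging) are kept as given.
split_directional <- function(combined, fixed_directional = NULL) {
  est <- combined
  half <- bind_rows(
    tibble(
      j = est$pair + 1L, i = est$pair, L = est$state_hi, K = est$state_lo,
      dG_kJmol = est$dG_kJmol / 2, free = TRUE
    ),
    tibble(
      j = est$pair, i = est$pair + 1L, L = est$state_lo, K = est$state_hi,
      dG_kJmol = est$dG_kJmol / 2, free = TRUE
    )
  )
  half <- half[half$dG_kJmol != 0 | half$free, ]
  out <- bind_rows(fixed_directional, half)
  out <- summarise(
    group_by(out, .data$j, .data$i, .data$L, .data$K),
    dG_kJmol = sum(.data$dG_kJmol), free = any(.data$free), .groups = "drop"
  )
  nni_params(out$j, out$i, out$L, out$K, out$dG_kJmol, out$free)
}

#' Fit NNI couplings of a tetrapeptide (two guest residues)
#'
#' Staged least-squares estimation of the nearest-neighbor interaction
#' Gibbs energies from the observed residue mole fractions of a GxyG
#' peptide, using intrinsic energies derived from the residues' GxG
#' reference peptides. Stage 1 frees only the pPII/beta cross couplings
#' in both directions; stage 2 additionally frees couplings between the
#' turn/helix classes and pPII/beta. pPII-pPII and beta-beta couplings
#' stay fixed at zero throughout. The minimized objective is the
#' unweighted sum of squared differences between calculated and observed
#' residue-state mole fractions.
#'
#' Only the mutual sum of the two directional couplings acting on a state
#' pair affects the distribution, so the fit parameterizes combined sums
#' directly and reports directions as half the sum each.
#'
#' @param observed Tibble of observed fractions (`residue`, `state`,
#'   `fraction`) for the two guest residues.
#' @param intrinsic Intrinsic energies for the same residues (from
#'   [intrinsic_energies()] on the GxG references).
#' @param stages 1 or 2 fitting stages.
#' @param temperature Kelvin.
#' @param bounds Box bound (kJ/mol) on every coupling.
#' @param multistart Number of optimizer starts (the zero start plus
#'   random starts drawn uniformly in `±start_range`).
#' @param start_range Range (kJ/mol) for random starts.
#' @param seed Integer seed for the random starts.
#' @return An object of class `nni_fit`; see [tidy.nni_fit()] and
#'   [glance.nni_fit()].
#' @export
fit_nni <- function(observed, intrinsic, stages = 2, temperature = 300,
                    bounds = 10, multistart = 16, start_range = 5,
                    seed = 1) {
  stopifnot(stages %in% 1:2)
  check_observed_normalized(observed)
  observed <- validate_fractions(observed)
  n <- length(unique(observed$residue))
  stopifnot(n %in% 2:3)
  pairs <- seq_len(n - 1L)
  chi2_stages <- numeric(0)
  eng <- NULL
  free_tbl <- NULL
  for (s in seq_len(stages)) {
    free_s <- free_table(pairs, s)
    starts_extra <- NULL
    if (!is.null(eng)) {
      carry <- rep(0, nrow(free_s))
      idx <- match(
        paste(free_tbl$pair, free_tbl$state_lo, free_tbl$state_hi),
        paste(free_s$pair, free_s$state_lo, free_s$state_hi)
      )
      carry[idx] <- eng$par
      starts_extra <- list(carry)
    }
    eng <- nni_fit_engine(observed, intrinsic, free_s,
      temperature = temperature, bounds = bounds, multistart = multistart,
      start_range = start_range, seed = seed + s,
      starts_extra = starts_extra
    )
    free_tbl <- free_s
    chi2_stages <- c(chi2_stages, eng$chi2)
  }
  combined <- mutate(free_tbl, dG_kJmol = eng$par, free = TRUE)
  directional <- split_directional(combined)
  new_nni_fit(eng, free_tbl, NULL, observed, intrinsic, temperature,
    bounds, chi2_stages, stages, directional)
}

#' Fit NNI couplings of a pentapeptide with fixed first-dimer parameters
#'
#' For GxyzG peptides the couplings between the first and second guest
#' residues are taken from the corresponding GxyG fit and held fixed,
#' while the couplings between the second and third residues are fitted,
#' together with an adjustment representing the influence of the central
#' residue on its upstream neighbor. A non-zero upstream adjustment (and
#' residual misfit) signals interactions beyond nearest neighbors, which
#' the model does not represent explicitly.
#'
#' @param observed Observed fractions for the three guest residues.
#' @param intrinsic Intrinsic energies for the same residues.
#' @param fixed_12 First-dimer couplings: an `nni_fit`, an `nni_params`
#'   table, or a combined table (`pair`, `state_lo`, `state_hi`,
#'   `dG_kJmol`).
#' @param stages Stage mask applied to the 2-3 dimer (1 or 2); the
#'   upstream adjustment on the 1-2 dimer always uses the stage-1
#'   (pPII/beta) mask.
#' @inheritParams fit_nni
#' @return An object of class `nni_fit`.
#' @export
fit_nni_penta <- function(observed, intrinsic, fixed_12, stages = 1,
                          temperature = 300, bounds = 10, multistart = 16,
                          start_range = 5, seed = 1) {
  check_observed_normalized(observed)
  observed <- validate_fractions(observed)
  stopifnot(length(unique(observed$residue)) == 3)
  if (inherits(fixed_12, "nni_fit")) fixed_12 <- fixed_12$combined
  if (inherits(fixed_12, "nni_params")) {
    fixed_12 <- combine_directional(fixed_12, n_residues = 2)
  }
  stopifnot(all(c("pair", "state_lo", "state_hi", "dG_kJmol") %in%
    names(fixed_12)))
  base <- fixed_12[fixed_12$pair == 1 & fixed_12$dG_kJmol != 0, ]
  free_tbl <- bind_rows(
    free_table(1L, 1),          # upstream influence of residue 2 on 1
    free_table(2L, stages)      # 2-3 dimer couplings
  )
  eng <- nni_fit_engine(observed, intrinsic, free_tbl,
    base = base, temperature = temperature, bounds = bounds,
    multistart = multistart, start_range = start_range, seed = seed
  )
  combined <- mutate(free_tbl, dG_kJmol = eng$par, free = TRUE)
  # report the fixed first-dimer couplings in the 1->2-influence direction
  # and the fitted upstream adjustment in the 2->1 direction
  fixed_dir <- tibble(
    j = base$pair + 1L, i = base$pair, L = base$state_hi, K = base$state_lo,
    dG_kJmol = base$dG_kJmol, free = FALSE
  )
  up <- combined$pair == 1L
  directional <- bind_rows(
    fixed_dir,
    tibble(
      j = 1L, i = 2L, L = combined$state_lo[up], K = combined$state_hi[up],
      dG_kJmol = combined$dG_kJmol[up], free = TRUE
    ),
    {
      dn <- combined[!up, ]
      bind_rows(
        tibble(
          j = dn$pair + 1L, i = dn$pair, L = dn$state_hi, K = dn$state_lo,
          dG_kJmol = dn$dG_kJmol / 2, free = TRUE
        ),
        tibble(
          j = dn$pair, i = dn$pair + 1L, L = dn$state_lo, K = dn$state_hi,
          dG_kJmol = dn$dG_kJmol / 2, free = TRUE
        )
      )
    }
  )
  directional <- summarise(
    group_by(directional, .data$j, .data$i, .data$L, .data$K),
    dG_kJmol = sum(.data$dG_kJmol), free = any(.data$free), .groups = "drop"
  )
  directional <- nni_params(
    directional$j, directional$i, directional$L, directional$K,
    directional$dG_kJmol, directional$free
  )
  new_nni_fit(eng, free_tbl, base, observed, intrinsic, temperature,
    bounds, eng$chi2, stages, directional)
}

#' Profile a fitted coupling by a flat-chi-square scan
#'
#' Pins one coupling at each value of a grid, re-minimizes the objective
#' over the remaining free couplings, and reports the interval where the
#' profile stays within `threshold` of the minimum. Couplings whose
#' interval spans more than `flat_span` kJ/mol (the thermal-energy
#' benchmark at room temperature) are flagged as flat, i.e. poorly
#' determined by the data.
#'
#' With `mode = "directional"` the scan pins one directional component
#' while the mutual combined sum remains free: because the distribution
#' depends only on the sum, the profile is exactly flat — the gauge
#' freedom of the directional bookkeeping, surfaced to the user.
#'
#' @param fit An `nni_fit`.
#' @param pair Lower residue index of the dimer.
#' @param state_lo,state_hi States of the lower and higher residue.
#' @param grid Grid of coupling values (kJ/mol) to scan.
#' @param threshold Chi-square increase defining the interval.
#' @param flat_span Interval width (kJ/mol) above which the coupling is
#'   flagged flat.
#' @param mode `"combined"` (default) scans the identifiable mutual sum;
#'   `"directional"` scans one direction with the sum free.
#' @param multistart Optimizer starts per grid point.
#' @return Tibble with columns `dG_kJmol`, `chi2`, with attributes
#'   `interval` (numeric length-2), `flat` (logical), `threshold` and
#'   `estimate`.
#' @export
scan_uncertainty <- function(fit, pair, state_lo, state_hi,
                             grid = seq(-6, 6, by = 0.5), threshold = 1,
                             flat_span = 2.5,
                             mode = c("combined", "directional"),
                             multistart = 2) {
  stopifnot(inherits(fit, "nni_fit"))
  mode <- match.arg(mode)
  if (any(abs(grid) > fit$bounds)) {
    abort("Scan grid exceeds the fitting bounds.")
  }
  state_lo <- normalize_state_labels(state_lo)
  state_hi <- normalize_state_labels(state_hi)
  hit <- fit$free$pair == pair & fit$free$state_lo == state_lo &
    fit$free$state_hi == state_hi
  if (!any(hit)) {
    abort("The requested coupling is not free in this fit.")
  }
  free_rest <- if (mode == "combined") fit$free[!hit, ] else fit$free
  start_rest <- if (mode == "combined") {
    fit$combined$dG_kJmol[!hit]
  } else {
    fit$combined$dG_kJmol
  }
  chi2 <- purrr::map_dbl(grid, function(v) {
    base <- bind_rows(
      fit$base,
      tibble(pair = pair, state_lo = state_lo, state_hi = state_hi,
        dG_kJmol = v)
    )
    eng <- nni_fit_engine(fit$observed, fit$intrinsic, free_rest,
      base = base, temperature = fit$temperature, bounds = fit$bounds,
      multistart = multistart, start_range = 3, seed = 7,
      starts_extra = list(start_rest)
    )
    eng$chi2
  })
  inside <- chi2 <= min(chi2) + threshold
  interval <- range(grid[inside])
  out <- tibble(dG_kJmol = grid, chi2 = chi2)
  attr(out, "interval") <- interval
  attr(out, "flat") <- diff(interval) > flat_span
  attr(out, "threshold") <- threshold
  attr(out, "estimate") <- fit$combined$dG_kJmol[hit]
  out
}

#' @export
print.nni_fit <- function(x, ...) {
  cat("Four-state NNI fit (", x$n_residues, " guest residues, ",
    x$stages, " stage(s))\n", sep = "")
  cat("  chi2 per stage:", format(signif(x$chi2_stages, 4)), "\n")
  cat("  converged:", x$converged, "\n")
  sig <- x$combined[abs(x$combined$dG_kJmol) > 1.25, ]
  cat("  significant combined couplings (|dG| > 1.25 kJ/mol):",
    nrow(sig), "\n")
  invisible(x)
}
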