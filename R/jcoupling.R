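#' Default Karplus parameterizations for the five backbone couplings
#'
#' One named coefficient set per coupling type, shipped as editable data
#' (swap in any other published parameterization by passing a modified
#' table to the prediction and fitting functions). Each coupling obeys
#' `J(theta) = A cos^2(theta + phase) + B cos(theta + phase) + C`, where
#' `theta` is the backbone phi angle for the four 3J couplings and psi
#' for 1J(N,CA). The reported prediction depends on the chosen set, so
#' the set travels with every result that uses it.
#'
#' @return Tibble with columns `coupling_type`, `A`, `B`, `C` (Hz),
#'   `angle` (`"phi"` or `"psi"`) and `phase_deg`.
#' @export
#' @examples
#' karplus_default()
karplus_default <- function() {
  tibble(
    coupling_type = c(
      "3J(HN,HA)", "3J(HN,C)", "3J(HA,C)", "3J(HN,CB)", "1J(N,CA)"
    ),
    A = c(7.09, 4.29, 3.72, 3.06, 1.70),
    B = c(-1.42, -1.01, -2.18, -0.74, -0.98),
    C = c(1.55, 0.00, 1.28, 0.13, 9.51),
    angle = c("phi", "phi", "phi", "phi", "psi"),
    phase_deg = c(-60, 180, 120, 60, 0)
  )
}

#' Evaluate a Karplus curve
#'
#' @param coupling_type One of the types in the Karplus table.
#' @param angle_deg Backbone dihedral (phi or psi as appropriate for the
#'   coupling), degrees; vectorized.
#' @param karplus Karplus coefficient table (see [karplus_default()]).
#' @return Coupling value(s) in Hz.
#' @export
#' @examples
#' karplus_value("3J(HN,HA)", -120)
karplus_value <- function(coupling_type, angle_deg,
                          karplus = karplus_default()) {
  row <- karplus[karplus$coupling_type == coupling_type, ]
  if (nrow(row) != 1) {
    abort(paste0("Unknown coupling type: ", coupling_type))
  }
  th <- (angle_deg + row$phase_deg) * pi / 180
  row$A * cos(th)^2 + row$B * cos(th) + row$C
}

#' Construct a Gaussian basin set
#'
#' A residue's Ramachandran distribution is modeled as a weighted
#' superposition of axis-aligned two-dimensional Gaussian basins, wrapped
#' periodically at ±180 degrees. The five basin labels follow the
#' Gaussian-model convention (`pPII`, `beta`, `igamma_typeII`, `rh`,
#' `lh`), but any labels are accepted.
#'
#' @param basin Basin labels.
#' @param phi0,psi0 Basin centers, degrees in \[-180, 180).
#' @param sigma_phi,sigma_psi Halfwidths (Gaussian sigmas), degrees, > 0.
#' @param weight Statistical weights; must sum to 1.
#' @return Tibble of class `basin_set`.
#' @export
basin_set <- function(basin, phi0, psi0, sigma_phi, sigma_psi, weight) {
  out <- tibble(
    basin = as.character(basin), phi0 = phi0, psi0 = psi0,
    sigma_phi = sigma_phi, sigma_psi = sigma_psi, weight = weight
  )
  if (any(out$sigma_phi <= 0) || any(out$sigma_psi <= 0)) {
    abort("Basin halfwidths must be positive.")
  }
  if (any(out$weight < 0) || abs(sum(out$weight) - 1) > 1e-6) {
    abort("Basin weights must be non-negative and sum to 1.")
  }
  class(out) <- c("basin_set", class(out))
  out
}

#' Representative five-basin Ramachandran models
#'
#' Synthetic basin geometries at canonical secondary-structure positions
#' (pPII, beta-strand, inverse-gamma/type-II beta-turn, right- and
#' left-handed helical), with weight profiles typical of a
#' pPII-dominated residue (`"alanine-like"`), a mixed pPII/beta residue
#' (`"phenylalanine-like"`) or a turn-rich residue (`"aspartate-like"`).
#' These are package-constructed stand-ins for residue-specific fitted
#' geometries, intended for simulation and examples.
#'
#' @param profile Weight profile preset.
#' @return A [basin_set()].
#' @export
example_basins <- function(profile = c("alanine-like",
                                       "phenylalanine-like",
                                       "aspartate-like")) {
  profile <- match.arg(profile)
  w <- switch(profile,
    "alanine-like" = c(0.80, 0.10, 0.03, 0.03, 0.04),
    "phenylalanine-like" = c(0.45, 0.45, 0.00, 0.05, 0.05),
    "aspartate-like" = c(0.35, 0.30, 0.20, 0.05, 0.10)
  )
  basin_set(
    basin = basin_labels(),
    phi0 = c(-70, -120, -85, -60, 55),
    psi0 = c(150, 130, 65, -50, 45),
    sigma_phi = rep(10, 5), sigma_psi = rep(10, 5),
    weight = w
  )
}

# Wrapped-normal density evaluated at grid points (degrees), normalized
# so the cells sum to 1.
wrapped_density <- function(grid, center, sigma) {
  d <- 0
  for (k in -2:2) d <- d + dnorm(grid, center + 360 * k, sigma)
  d / sum(d)
}

# Per-basin mean couplings: matrix (coupling types x basins) of
# E_b[J] computed on a periodic 2D rectangular grid. Basins narrower
# than half a grid step are treated as point masses at their center
# (the delta limit of the Gaussian).
basin_coupling_matrix <- function(basins, karplus, grid_step = 2) {
  grid <- seq(-180, 180 - grid_step, by = grid_step)
  jmat <- matrix(0, nrow(karplus), nrow(basins), dimnames = list(
    karplus$coupling_type, basins$basin
  ))
  for (b in seq_len(nrow(basins))) {
    delta <- basins$sigma_phi[b] < grid_step / 2 ||
      basins$sigma_psi[b] < grid_step / 2
    if (!delta) {
      dphi <- wrapped_density(grid, basins$phi0[b], basins$sigma_phi[b])
      dpsi <- wrapped_density(grid, basins$psi0[b], basins$sigma_psi[b])
      dens <- outer(dphi, dpsi) # cells sum to 1
    }
    for (t in seq_len(nrow(karplus))) {
      if (delta) {
        ang0 <- if (karplus$angle[t] == "phi") basins$phi0[b] else
          basins$psi0[b]
        jmat[t, b] <- karplus_value(karplus$coupling_type[t], ang0, karplus)
      } else {
        jgrid <- karplus_value(karplus$coupling_type[t], grid, karplus)
        jmat[t, b] <- if (karplus$angle[t] == "phi") {
          sum(rowSums(dens) * jgrid)
        } else {
          sum(colSums(dens) * jgrid)
        }
      }
    }
  }
  jmat
}

#' Ensemble-averaged scalar couplings of a basin set
#'
#' Averages each Karplus curve over the weighted superposition of wrapped
#' two-dimensional Gaussian basins, by rectangular quadrature on a
#' periodic (phi, psi) grid. At the default 2-degree step the result is
#' converged to well under 0.01 Hz for basin halfwidths of 5 degrees or
#' more; basins much narrower than the grid are evaluated exactly in the
#' delta limit.
#'
#' @param basins A [basin_set()].
#' @param karplus Karplus coefficient table.
#' @param grid_step Grid spacing in degrees.
#' @return Tibble with columns `coupling_type`, `J_Hz`.
#' @export
predict_coupling <- function(basins, karplus = karplus_default(),
                             grid_step = 2) {
  if (abs(sum(basins$weight) - 1) > 1e-6) {
    abort("Basin weights must sum to 1.")
  }
  jmat <- basin_coupling_matrix(basins, karplus, grid_step)
  tibble(
    coupling_type = karplus$coupling_type,
    J_Hz = as.numeric(jmat %*% basins$weight)
  )
}

#' Reduced chi-square of a coupling fit
#'
#' `chi2_r = (1/dof) sum ((obs - calc) / sigma)^2` with
#' `dof = N - n_free`.
#'
#' @param observed,calculated Coupling values, Hz.
#' @param sigma Observation uncertainties, Hz (> 0).
#' @param n_free Number of free parameters in the fit.
#' @return Dimensionless scalar.
#' @export
reduced_chi_square <- function(observed, calculated, sigma, n_free = 0) {
  stopifnot(length(observed) == length(calculated))
  if (any(sigma <= 0)) abort("Uncertainties must be positive.")
  dof <- length(observed) - n_free
  if (dof <= 0) abort("Degrees of freedom must be positive.")
  sum(((observed - calculated) / sigma)^2) / dof
}

#' Fit basin weights (and optionally positions) to observed couplings
#'
#' Stage `"weights"` keeps the basin geometry fixed and estimates the
#' statistical weights on the probability simplex. Because the predicted
#' couplings are linear in the weights, this stage is solved exactly as
#' an equality/bound-constrained least-squares problem (weighted by the
#' observation uncertainties) — no starting values, no local minima.
#' Stage `"positions"` additionally varies the basin centers (phi0, and
#' psi0 unless `freeze_psi`) within `max_shift` degrees of their initial
#' values, re-solving the weight problem at every trial geometry.
#'
#' Observations whose value lies below the minimum of the corresponding
#' Karplus curve cannot be matched by any conformational average; they
#' are flagged `below_minimum` and contribute an irreducible residual.
#'
#' @param observations Tibble with columns `coupling_type`, `value_Hz`,
#'   `sigma_Hz`. Coupling types absent from the table are simply omitted
#'   from the objective.
#' @param basins Initial [basin_set()] (typically the residue's GxG
#'   reference geometry).
#' @param karplus Karplus coefficient table.
#' @param stage `"weights"` or `"positions"`.
#' @param freeze_psi Keep psi centers fixed in stage `"positions"`.
#' @param grid_step Quadrature grid step, degrees.
#' @param max_shift Box bound on center shifts, degrees.
#' @param multistart Optimizer starts for the position stage.
#' @param seed Seed for the position-stage starts.
#' @return Object of class `basin_fit`: the fitted basin set, per-
#'   observation fit table, chi-square and reduced chi-square.
#' @export
fit_basins <- function(observations, basins, karplus = karplus_default(),
                       stage = c("weights", "positions"),
                       freeze_psi = FALSE, grid_step = 2, max_shift = 30,
                       multistart = 3, seed = 1) {
  stage <- match.arg(stage)
  stopifnot(all(c("coupling_type", "value_Hz", "sigma_Hz") %in%
    names(observations)))
  if (nrow(observations) == 0) abort("No coupling observations supplied.")
  if (any(observations$sigma_Hz <= 0)) {
    abort("All observation uncertainties must be positive.")
  }
  karplus <- karplus[karplus$coupling_type %in%
    observations$coupling_type, ]
  observations <- observations[
    match(karplus$coupling_type, observations$coupling_type),
  ]
  nb <- nrow(basins)
  n_free <- (nb - 1) +
    if (stage == "positions") nb * (2 - freeze_psi) else 0
  if (nrow(observations) < n_free) {
    warn(paste0(
      "Fewer observations (", nrow(observations),
      ") than effective free parameters (", n_free, ")."
    ))
  }

  solve_weights <- function(bs) {
    jmat <- basin_coupling_matrix(bs, karplus, grid_step)
    cw <- jmat / observations$sigma_Hz
    dw <- observations$value_Hz / observations$sigma_Hz
    # tiny ridge toward the initial weights keeps the quadratic program
    # positive definite when fewer couplings than basins are observed;
    # its contribution to the objective is O(1e-8) and never material
    ridge <- 1e-4
    caug <- rbind(cw, ridge * diag(nb))
    daug <- c(dw, ridge * basins$weight)
    w <- if (nb == 1) 1 else {
      pracma::lsqlincon(caug, daug,
        Aeq = matrix(1, 1, nb), beq = 1,
        lb = rep(0, nb), ub = rep(1, nb)
      )
    }
    list(w = as.numeric(w), chi2 = sum((cw %*% w - dw)^2), jmat = jmat)
  }

  fitted_basins <- basins
  if (stage == "weights") {
    sol <- solve_weights(basins)
  } else {
    centers0 <- c(basins$phi0, if (!freeze_psi) basins$psi0)
    obj <- function(cen) {
      bs <- basins
      bs$phi0 <- cen[seq_len(nb)]
      if (!freeze_psi) bs$psi0 <- cen[nb + seq_len(nb)]
      solve_weights(bs)$chi2
    }
    set.seed(seed)
    best <- NULL
    starts <- c(list(centers0), replicate(multistart - 1,
      centers0 + runif(length(centers0), -max_shift / 2, max_shift / 2),
      simplify = FALSE
    ))
    for (st in starts) {
      r <- optim(st, obj,
        method = "L-BFGS-B",
        lower = centers0 - max_shift, upper = centers0 + max_shift,
        control = list(maxit = 200)
      )
      if (is.null(best) || r$value < best$value) best <- r
    }
    fitted_basins$phi0 <- best$par[seq_len(nb)]
    if (!freeze_psi) fitted_basins$psi0 <- best$par[nb + seq_len(nb)]
    sol <- solve_weights(fitted_basins)
  }
  fitted_basins$weight <- sol$w / sum(sol$w)

  jfit <- as.numeric(sol$jmat %*% fitted_basins$weight)
  jmin <- purrr::map_dbl(karplus$coupling_type, function(ct) {
    min(karplus_value(ct, seq(-180, 180, by = 0.5), karplus))
  })
  obs_out <- mutate(observations,
    J_fit_Hz = jfit,
    below_minimum = .data$value_Hz < jmin
  )
  dof <- nrow(observations) - n_free
  structure(
    list(
      basins = fitted_basins,
      observations = obs_out,
      chi2 = sol$chi2,
      chi2_reduced = if (dof > 0) sol$chi2 / dof else NA_real_,
      n_free = n_free, dof = dof,
      stage = stage, freeze_psi = freeze_psi,
      karplus = karplus, grid_step = grid_step
    ),
    class = "basin_fit"
  )
}

#' @export
print.basin_fit <- function(x, ...) {
  cat("Gaussian-basin coupling fit (stage: ", x$stage, ")\n", sep = "")
  cat("  chi2 =", signif(x$chi2, 4), " reduced chi2 =",
    signif(x$chi2_reduced, 4), "\n")
  if (any(x$observations$below_minimum)) {
    cat("  note: observation(s) below the Karplus minimum (irreducible residual):",
      paste(x$observations$coupling_type[x$observations$below_minimum],
        collapse = ", "), "\n")
  }
  print(x$basins)
  invisible(x)
}

#' Ramachandran probability grid of a basin set
#'
#' Evaluates the weighted wrapped-Gaussian density on a periodic
#' rectangular (phi, psi) grid. Cell probabilities sum to 1; with
#' `per_basin = TRUE` the per-basin contributions are kept separate and
#' the cells of each basin sum to its weight.
#'
#' @param basins A [basin_set()].
#' @param grid_step Degrees.
#' @param per_basin Keep per-basin columns.
#' @return Tibble with columns `phi`, `psi`, `density` (and one column
#'   per basin when `per_basin`).
#' @export
ramachandran_grid <- function(basins, grid_step = 2, per_basin = FALSE) {
  grid <- seq(-180, 180 - grid_step, by = grid_step)
  out <- tidyr::expand_grid(phi = grid, psi = grid)
  total <- 0
  for (b in seq_len(nrow(basins))) {
    dphi <- wrapped_density(grid, basins$phi0[b], basins$sigma_phi[b])
    dpsi <- wrapped_density(grid, basins$psi0[b], basins$sigma_psi[b])
    dens <- basins$weight[b] *
      as.vector(outer(dphi, dpsi)[
        cbind(match(out$phi, grid), match(out$psi, grid))
      ])
    if (per_basin) out[[basins$basin[b]]] <- dens
    total <- total + dens
  }
  out$density <- total
  out
}

#' Write / read a Ramachandran density grid as plain text
#'
#' The text format is header comment lines starting with `#`, an optional
#' column-name line, then tab- or whitespace-separated
#' `phi psi density` rows. The reader skips comments and sniffs whether a
#' column-name line is present, so deposited grids in this general
#' dialect load as well.
#'
#' @param grid Tibble from [ramachandran_grid()].
#' @param path File path.
#' @return `read_ramachandran_grid()` returns a tibble with columns
#'   `phi`, `psi`, `density`; the writer returns `path` invisibly.
#' @export
write_ramachandran_grid <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# Ramachandran probability density grid (cells sum to 1)",
    "# columns: phi psi density (degrees, degrees, probability)",
    "phi\tpsi\tdensity"
  ), con)
  utils::write.table(grid[c("phi", "psi", "density")], con,
    sep = "\t", col.names = FALSE, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ramachandran_grid
#' @export
read_ramachandran_grid <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) abort("Empty Ramachandran grid file.")
  first <- strsplit(trimws(lines[[1]]), "[\t ,;]+")[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(first))))
  dat <- utils::read.table(
    text = paste(lines, collapse = "\n"),
    header = has_header
  )
  if (ncol(dat) < 3) abort("Expected at least three columns: phi, psi, density.")
  names(dat)[1:3] <- c("phi", "psi", "density")
  as_tibble(dat[1:3])
}
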