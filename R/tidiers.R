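#' Tidy a fitted NNI model
#'
#' One row per fitted combined coupling (the identifiable directional
#' sum), with the significance call at the half-thermal-energy
#' convention: couplings larger in magnitude than 1.25 kJ/mol (half of
#' RT at 300 K) are labeled significant.
#'
#' @param x An `nni_fit`.
#' @param ... Unused.
#' @return Tibble with columns `pair`, `state_lo`, `state_hi`,
#'   `estimate`, `free`, `significant`.
#' @export
tidy.nni_fit <- function(x, ...) {
  mutate(
    rename(x$combined, estimate = "dG_kJmol"),
    significant = abs(.data$estimate) > 1.25
  )
}

#' @rdname tidy.nni_fit
#' @return `glance()` returns a one-row tibble with the fit summary.
#' @export
glance.nni_fit <- function(x, ...) {
  tibble(
    chi2 = x$chi2,
    chi2_stage1 = x$chi2_stages[1],
    n_stages = length(x$chi2_stages),
    n_residues = x$n_residues,
    n_free = nrow(x$free),
    converged = x$converged,
    temperature = x$temperature
  )
}

#' @export
tidy.basin_fit <- function(x, ...) {
  rename(as_tibble(x$basins), estimate = "weight")
}

#' @export
glance.basin_fit <- function(x, ...) {
  tibble(
    chi2 = x$chi2, chi2_reduced = x$chi2_reduced,
    n_obs = nrow(x$observations), n_free = x$n_free, dof = x$dof,
    stage = x$stage,
    n_below_minimum = sum(x$observations$below_minimum)
  )
}

#' Plot observed versus fitted residue mole fractions
#'
#' @param object An `nni_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nni_fit <- function(object, ...) {
  dat <- bind_rows(
    mutate(object$observed, source = "observed"),
    mutate(object$fitted, source = "fitted")
  )
  dat$state <- factor(dat$state, levels = conformer_states())
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$state, y = .data$fraction, fill = .data$source
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~residue, labeller = ggplot2::label_both) +
    ggplot2::labs(
      x = "conformational class", y = "mole fraction",
      title = "Observed vs. fitted residue mole fractions"
    )
}

#' Plot the leading joint conformer populations
#'
#' @param object A `conformer_tbl` from [enumerate_conformers()].
#' @param n_top Number of conformers shown.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.conformer_tbl <- function(object, n_top = 12, ...) {
  scols <- grep("^state_", names(object), value = TRUE)
  dat <- tibble(
    sequence = do.call(paste, c(object[scols], sep = "-")),
    population = object$population
  )
  dat <- head(arrange(dat, dplyr::desc(.data$population)), n_top)
  dat$sequence <- factor(dat$sequence, levels = rev(dat$sequence))
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$population, y = .data$sequence
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "population", y = NULL,
      title = "Leading peptide conformers"
    )
}

#' Plot a Ramachandran density
#'
#' @param object A `basin_fit` or [basin_set()].
#' @param grid_step Degrees.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.basin_fit <- function(object, grid_step = 2, ...) {
  plot_ramachandran(object$basins, grid_step)
}

#' @rdname autoplot.basin_fit
#' @param basins A [basin_set()].
#' @export
plot_ramachandran <- function(basins, grid_step = 2) {
  grid <- ramachandran_grid(basins, grid_step)
  ggplot2::ggplot(grid, ggplot2::aes(
    x = .data$phi, y = .data$psi, fill = .data$density
  )) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(x = expression(phi), y = expression(psi))
}
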