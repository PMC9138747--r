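read_delim_sniff <- function(path) {
  first <- readLines(path, n = 1)
  if (length(first) == 0) abort(paste0("Empty input file: ", path))
  delim <- if (grepl("\t", first)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
    progress = FALSE)
}

#' Read a residue mole-fraction table
#'
#' Reads a TSV/CSV table with columns `peptide` (optional),
#' `residue_index` (or `residue`), `residue_code` (optional), `state`,
#' `fraction`. Both the four-state dialect (`pPII, beta, t_l, t_r`) and
#' the five-basin dialect (`pPII, beta, igamma_typeII, rh, lh`) are
#' accepted; five-basin rows are collapsed to the four classes
#' (`t_l = igamma_typeII + rh`, `t_r = lh`). Fractions are renormalized
#' per residue, with a warning when a residue's raw sum deviates from 1
#' by more than 0.02.
#'
#' @param path File path.
#' @return Tibble with columns `peptide` (if present), `residue`,
#'   `residue_code` (if present), `state`, `fraction`.
#' @export
read_fraction_table <- function(path) {
  dat <- read_delim_sniff(path)
  if ("residue_index" %in% names(dat)) {
    dat <- rename(dat, residue = "residue_index")
  }
  need <- c("residue", "state", "fraction")
  if (!all(need %in% names(dat))) {
    abort(paste0(
      "Fraction table must have columns residue_index (or residue), ",
      "state, fraction; missing: ",
      paste(setdiff(need, names(dat)), collapse = ", ")
    ))
  }
  if (any(dat$fraction < 0)) abort("Negative mole fractions in input.")
  dat <- mutate(dat, state = normalize_state_labels(.data$state))
  keys <- intersect(c("peptide", "residue"), names(dat))
  sums <- summarise(group_by(dat, across(all_of(keys))),
    s = sum(.data$fraction), .groups = "drop")
  off <- sums[abs(sums$s - 1) > 0.02, ]
  if (nrow(off)) {
    warn(paste0(
      "Renormalizing residue fractions deviating from unit sum: ",
      paste(apply(off, 1, function(r) paste(r[-length(r)], collapse = "/")),
        collapse = ", ")
    ))
  }
  groups <- if ("peptide" %in% names(dat)) split(dat, dat$peptide) else
    list(dat)
  purrr::map_dfr(groups, function(g) {
    codes <- if ("residue_code" %in% names(g)) {
      distinct(g, .data$residue, .data$residue_code)
    } else {
      NULL
    }
    out <- validate_fractions(g[c("residue", "state", "fraction")])
    if (!is.null(codes)) out <- left_join(out, codes, by = "residue")
    if ("peptide" %in% names(g)) out$peptide <- g$peptide[[1]]
    select(out, any_of(c("peptide", "residue", "residue_code")),
      "state", "fraction")
  })
}

#' Write a residue mole-fraction table
#'
#' @param fractions Tibble with at least `residue`, `state`, `fraction`.
#' @param path File path (TSV).
#' @export
write_fraction_table <- function(fractions, path) {
  readr::write_tsv(fractions, path)
  invisible(path)
}

#' Read / write a directional NNI parameter table
#'
#' TSV with columns `peptide` (optional), `j`, `i`, `L`, `K`,
#' `dG_kJmol`, `free`.
#'
#' @param path File path.
#' @return `read_nni_table()` returns an [nni_params()] table.
#' @export
read_nni_table <- function(path) {
  dat <- read_delim_sniff(path)
  need <- c("j", "i", "L", "K", "dG_kJmol")
  if (!all(need %in% names(dat))) {
    abort(paste0("NNI table missing columns: ",
      paste(setdiff(need, names(dat)), collapse = ", ")))
  }
  nni_params(dat$j, dat$i, dat$L, dat$K, dat$dG_kJmol,
    if ("free" %in% names(dat)) as.logical(dat$free) else TRUE)
}

#' @rdname read_nni_table
#' @param params An [nni_params()] table.
#' @export
write_nni_table <- function(params, path) {
  readr::write_tsv(as_tibble(params), path)
  invisible(path)
}

#' Read a J-coupling observation table
#'
#' TSV/CSV with columns `peptide` (optional), `residue_index` (optional),
#' `coupling_type`, `value_Hz`, `sigma_Hz`.
#'
#' @param path File path.
#' @return Tibble of observations.
#' @export
read_coupling_table <- function(path) {
  dat <- read_delim_sniff(path)
  need <- c("coupling_type", "value_Hz", "sigma_Hz")
  if (!all(need %in% names(dat))) {
    abort(paste0("Coupling table missing columns: ",
      paste(setdiff(need, names(dat)), collapse = ", ")))
  }
  as_tibble(dat)
}

#' Write joint conformer populations to TSV
#'
#' @param distribution A `conformer_tbl`.
#' @param path File path.
#' @export
write_populations <- function(distribution, path) {
  scols <- grep("^state_", names(distribution), value = TRUE)
  out <- tibble(
    sequence = do.call(paste, c(distribution[scols], sep = "-")),
    fraction = distribution$population
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Bundled phenylalanine/alanine tetrapeptide worked example
#'
#' Five-basin mole-fraction table for the GAG and GFG reference peptides
#' and the GAFG and GFAG tetrapeptides, as determined by the
#' Gaussian-basin J-coupling analysis of those peptides.
#'
#' @return Path to the installed TSV (`example_fraction_path()`) or the
#'   parsed tibble (`example_fraction_table()`).
#' @export
example_fraction_path <- function() {
  system.file("extdata", "phe_ala_tetrapeptides.tsv", package = "pepnni",
    mustWork = TRUE)
}

#' @rdname example_fraction_path
#' @export
example_fraction_table <- function() {
  read_fraction_table(example_fraction_path())
}

#' Run the full tetrapeptide analysis pipeline
#'
#' Reads an observed mole-fraction table and a GxG reference table,
#' derives intrinsic energies for each guest residue by matching
#' `residue_code` against the reference peptides, fits the NNI couplings
#' (staged least squares; pentapeptides additionally require the fixed
#' first-dimer parameters), enumerates the joint conformer populations
#' and the entropy change, and writes `params.tsv`, `populations.tsv`,
#' `entropy.json` and `report.json` to `out_dir`. Runs are deterministic
#' for a fixed seed.
#'
#' @param peptide_table Path to the observed fractions of the target
#'   peptide (columns `peptide`, `residue_index`, `residue_code`,
#'   `state`, `fraction`).
#' @param reference_table Path to the GxG reference fractions (same
#'   format, one residue per reference peptide).
#' @param out_dir Output directory (created if needed).
#' @param peptide Target peptide name; required when `peptide_table`
#'   holds several peptides.
#' @param fixed_params Path to a directional NNI table (or an
#'   `nni_params` object) holding the fixed 1-2 dimer couplings; required
#'   for three-residue targets.
#' @param stages,temperature,eps_floor,multistart,seed Passed to the
#'   fitting and energetics layers.
#' @return Invisibly, a list with the fit object, the entropy tibble and
#'   the artifact paths.
#' @export
run_pipeline <- function(peptide_table, reference_table, out_dir,
                         peptide = NULL, fixed_params = NULL, stages = 2,
                         temperature = 300, eps_floor = 1e-4,
                         multistart = 16, seed = 1) {
  obs_all <- read_fraction_table(peptide_table)
  ref_all <- read_fraction_table(reference_table)
  if (!"residue_code" %in% names(obs_all) ||
    !"residue_code" %in% names(ref_all)) {
    abort("Pipeline tables must carry a residue_code column for reference matching.")
  }
  if (is.null(peptide)) {
    peptide <- unique(obs_all$peptide)
    if (length(peptide) != 1) {
      abort("peptide_table holds several peptides; name one via `peptide`.")
    }
  }
  obs <- filter(obs_all, .data$peptide == !!peptide)
  if (nrow(obs) == 0) abort(paste0("Peptide not found in table: ", peptide))

  codes <- distinct(obs, .data$residue, .data$residue_code)
  intrinsic <- purrr::map_dfr(seq_len(nrow(codes)), function(k) {
    ref <- filter(ref_all, .data$residue_code == codes$residue_code[k])
    if (nrow(ref) == 0) {
      abort(paste0(
        "No GxG reference fractions for residue ", codes$residue[k],
        " (code ", codes$residue_code[k], ") of ", peptide, "."
      ))
    }
    if (length(unique(ref$peptide)) > 1) {
      ref <- filter(ref, .data$peptide == sort(unique(ref$peptide))[1])
    }
    g <- intrinsic_energies(
      mutate(ref[c("residue", "state", "fraction")], residue = 1L),
      temperature = temperature, eps_floor = eps_floor
    )
    mutate(g, residue = codes$residue[k])
  })

  n <- nrow(codes)
  fit <- if (n == 2) {
    fit_nni(obs[c("residue", "state", "fraction")], intrinsic,
      stages = stages, temperature = temperature,
      multistart = multistart, seed = seed)
  } else {
    if (is.null(fixed_params)) {
      abort("Three-residue targets need `fixed_params` (the fitted 1-2 dimer couplings).")
    }
    if (is.character(fixed_params)) fixed_params <- read_nni_table(fixed_params)
    fit_nni_penta(obs[c("residue", "state", "fraction")], intrinsic,
      fixed_12 = fixed_params, stages = min(stages, 2),
      temperature = temperature, multistart = multistart, seed = seed)
  }
  dist <- enumerate_conformers(intrinsic, fit$params, temperature)
  ent <- entropy_gibbs_difference(intrinsic, fit$params, temperature)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    params = file.path(out_dir, "params.tsv"),
    populations = file.path(out_dir, "populations.tsv"),
    entropy = file.path(out_dir, "entropy.json"),
    report = file.path(out_dir, "report.json")
  )
  write_nni_table(fit$params, paths$params)
  write_populations(dist, paths$populations)
  jsonlite::write_json(c(
    as.list(ent),
    note = "Entropies are over the four coarse conformational classes; only differences are meaningful."
  ), paths$entropy, auto_unbox = TRUE, digits = NA)
  report <- list(
    peptide = peptide,
    n_residues = n,
    stages = fit$stages,
    chi2_per_stage = fit$chi2_stages,
    converged = fit$converged,
    temperature = temperature,
    seed = seed,
    significance_threshold_kJmol = 1.25,
    combined_couplings = mutate(tidy(fit), estimate = .data$estimate),
    inputs = list(
      peptide_table = unname(tools::md5sum(peptide_table)),
      reference_table = unname(tools::md5sum(reference_table))
    ),
    package_version = as.character(utils::packageVersion("pepnni"))
  )
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE, digits = NA)
  invisible(list(fit = fit, entropy = ent, distribution = dist,
    paths = paths))
}
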