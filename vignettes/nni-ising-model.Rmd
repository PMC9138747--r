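---
title: "A four-state Ising model for nearest-neighbor coupling in unfolded peptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A four-state Ising model for nearest-neighbor coupling in unfolded peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepnni)
library(dplyr)
```

## The problem

Flory's random-coil picture treats the backbone dihedral sampling of each
residue in an unfolded peptide as statistically independent of its
neighbors (the *isolated pair hypothesis*, IPH). Under the IPH,
conformational energies and entropies are additive and a protein's
unfolded-state ensemble can be assembled from single-residue Ramachandran
distributions. A growing body of NMR work on short glycine-flanked
host–guest peptides (GxG, GxyG, GxyzG) shows that this fails: the
propensity of a residue for polyproline II (pPII) versus β-strand
depends measurably on the conformation its neighbors adopt.

`pepnni` implements a quantitative model of that coupling: a
one-dimensional, four-state Ising-type description of the two or three
non-terminal ("guest") residues of tetra- and pentapeptides, in which
nearest-neighbor interaction (NNI) Gibbs energies perturb the intrinsic,
GxG-derived propensities. The package covers the full analysis chain:

1. intrinsic Gibbs energies from reference mole fractions
   (`intrinsic_energies()`),
2. joint conformer populations under NNI couplings
   (`enumerate_conformers()`, `marginal_fractions()`),
3. the inverse problem — fitting couplings to observed residue mole
   fractions (`fit_nni()`, `fit_nni_penta()`, `scan_uncertainty()`),
4. the entropic consequence of the couplings
   (`entropy_gibbs_difference()`),
5. the upstream Gaussian-basin/Karplus analysis that produces mole
   fractions from scalar J-couplings (`predict_coupling()`,
   `fit_basins()`), and
6. a synthetic-data generator so each stage is testable end to end
   (`synthetic_scenario()`, `make_truth()`, `observe_fractions()`,
   `observe_couplings()`).

## The four states and the sign convention

Each residue occupies one of four coarse conformational classes:
`pPII`, `beta`, and two aggregated turn/helix classes — `t_l` pooling the
left-hand-side non-extended basins (right-handed helical, type I/II′
β-turn *i+2*, inverse γ) and `t_r` pooling the right-hand-side basins
(left-handed helical, asx- and γ-turn). Five-basin tables from the
Gaussian Ramachandran analysis collapse as `t_l = iγ/typeII′β + rh`,
`t_r = lh` (`collapse_basins()`).

**The sign convention deserves emphasis because it is opposite to the
usual Boltzmann habit.** Statistical weights are proportional to
`exp(+G/RT)`: a more populated conformation has a *higher* Gibbs energy
coordinate, pPII is pinned at `G = 0`, and a *positive* coupling δG
*stabilizes* the state pair it acts on. All energies are in kJ/mol with
`R = 8.314 J mol⁻¹ K⁻¹` and a default temperature of 300 K
(`rt_kj(300)` ≈ 2.494 kJ/mol, the thermal-energy yardstick used for
significance calls).

Observed mole fractions of exactly zero would map to `G = −∞`; they are
floored at a configurable `eps_floor = 1e-4` before the logarithm. The
value is a package choice (real tables do contain exact zeros, and the
optimizer needs finite energies); any analysis sensitive to it is
sensitive to unobservable structure and should be treated with
suspicion.

## The joint distribution

The Boltzmann weight of a full conformer sequence is

```
w(s_1..s_n) = exp{ [ Σ_j G(s_j, j) + Σ_pairs ( δG(s_{j+1} s_j; j+1,j)
                                             + δG(s_j s_{j+1}; j,j+1) ) ] / RT }
```

— each residue's intrinsic energy counted once and each adjacent dimer
contributing its two *directional* couplings. The package defines the
model by **exhaustive enumeration** of all `4^n` sequences (n ≤ 3, so at
most 64 terms, computed in log space). A transfer-matrix chain could be
written down, but the printed form of that chain places the intrinsic
energies both inside the conditional-probability matrices and in the end
vector, which double-counts them relative to the explicit conformer
weights above; enumeration is exact, internally consistent and cheap, so
it is the authoritative formulation here. Residue marginals are computed
as exact sums over the joint distribution.

Two structural facts follow directly and are enforced by property tests:

- **IPH limit.** With all δG = 0 the joint distribution factorizes into
  the product of single-residue fractions, to machine precision.
- **Gauge freedom.** The distribution depends on the two directional
  couplings of a dimer only through their sum
  `δG{ji}_LK = δG_LK,ji + δG_KL,ij`. The directional split is pure
  bookkeeping. Consequently the fitter parameterizes the *combined* sums
  and reports directions as half each; `scan_uncertainty(mode =
  "directional")` exposes the flatness of the split explicitly.

## Fitting protocol

`fit_nni()` minimizes the unweighted sum of squared residuals between
calculated and observed residue-state mole fractions (the source tables
carry no per-state uncertainties, so weighting would be invented). The
protocol is staged:

- **Stage 1** frees only the pPII↔β cross couplings of each adjacent
  dimer, in both directions — the dominant interaction channel.
- **Stage 2** additionally frees couplings between the turn classes and
  pPII/β. Same-state pPII–pPII and β–β couplings are never fitted: the
  observed anti-correlation between pPII and β propensities identifies
  only the cross channel, and freeing same-state terms adds pure gauge
  directions against the normalized marginals.

For pentapeptides (`fit_nni_penta()`), the 1–2 dimer couplings are fixed
at the corresponding tetrapeptide (GxyG) values; the 2–3 dimer couplings
are fitted, together with an upstream adjustment on the 1–2 dimer
representing the influence of the central residue on its first neighbor.
In a strictly nearest-neighbor world that adjustment would be zero; its
fitted magnitude is a diagnostic for second-neighbor effects the model
does not represent.

The optimizer is bounded L-BFGS-B inside ±10 kJ/mol with a multistart
scheme (default 16 starts: zero, the previous stage's optimum carried
forward — which also guarantees the stage-2 objective never exceeds
stage 1 — and random starts in ±5 kJ/mol under a fixed seed). The
surfaces are low-dimensional but can be flat; multistarts are cheap
insurance, and replicate simulation studies in the test-suite use 4
starts after verifying the stage-1 surface yields identical optima.

**Identifiability is the central caveat.** A two-residue peptide offers
six independent observations; stage 2 frees ten combined couplings. The
fit then reproduces the observed marginals essentially exactly (which is
the point: the model is a *representation* of the table, and the
interesting quantities are the dominant couplings), but individual
turn-class couplings can be poorly determined. `scan_uncertainty()`
profiles any combined coupling by pinning it on a grid and re-minimizing
the rest; the reported interval is where χ² stays within `threshold`
(default 1.0 — a package convention, the source analysis states none) of
its minimum, and intervals wider than 2.5 kJ/mol (thermal energy) are
flagged *flat*. The significance convention for reported couplings is
|δG| > 1.25 kJ/mol, half the thermal energy.

## Entropy

`entropy_iph()` is the additive four-class Shannon entropy of the
single-residue propensities; `entropy_nni()` is the Shannon entropy of
the joint conformer distribution. The reported quantity is
`T·(S_NNI − S_IPH)` in kJ/mol at the stated temperature: negative when
couplings narrow the ensemble. Two cautions, both surfaced in the
package's outputs and tests:

- The entropies are over the four coarse classes only — basin
  substructure is ignored — so absolute values are not meaningful; only
  differences are.
- The sign is not fixed a priori. Couplings that *equipartition* a
  skewed ensemble raise the joint entropy; the guarantee
  `S_NNI ≤ S_IPH` holds only against the factorized reference with the
  *same marginals* (the mutual-information inequality), which is the
  relevant comparison for fitted models whose marginals match the
  observations.

## The Gaussian-basin / Karplus module

A residue's Ramachandran density is a weighted superposition of
axis-aligned two-dimensional Gaussians, wrapped periodically at ±180°
(`basin_set()`). Ensemble-averaged couplings are Karplus curves averaged
over that density (`predict_coupling()`), on a rectangular periodic grid
with a default 2° step — converged to well under 0.01 Hz for halfwidths
≥ 5°, and evaluated exactly in the delta limit for basins much narrower
than the grid. The five default Karplus parameterizations (four
φ-dependent ³J couplings and the ψ-dependent ¹J(N,Cα)) are shipped as an
editable table (`karplus_default()`), because predicted absolute
couplings shift with the chosen coefficients; every fit object carries
the set it used.

`fit_basins()` estimates basin weights from observed couplings. Because
the prediction is *linear* in the weights, the weights-only stage is
solved exactly as an equality/bound-constrained least-squares problem on
the probability simplex (a convex QP with a unique solution) rather than
by a logistic reparameterization — boundary solutions (zero weights) are
common in real tables and a logistic map cannot reach them. A ridge of
1e-4 toward the initial weights keeps the QP well-posed when fewer
coupling types than basins are observed; its contribution to the
objective is O(1e-8). The position stage varies basin centers within
±30° of their initial values (L-BFGS-B, inner weight-QP at every trial
geometry), optionally freezing ψ. Observations below the minimum of
their Karplus curve are flagged `below_minimum`: no conformational
average can reach them and they contribute an irreducible residual —
a known failure mode of empirical Karplus curves near their minima.

Goodness of fit is reported as reduced χ²
(`reduced_chi_square()`), with the degrees of freedom
`N_obs − N_free`; when a stage frees more parameters than there are
observations the reduced χ² is reported as `NA` rather than something
invented.

## The synthetic generator: what it emulates, and what it does not

`synthetic_scenario()` fixes a seed, a system size (2 or 3 guest
residues), an intrinsic propensity preset, a coupling magnitude and
noise levels. The presets mirror the three propensity archetypes of the
experimental tables: `alanine-like` (0.80/0.10/0.05/0.05,
pPII-dominated), `valine-like` (0.20/0.65/0.10/0.05, β-dominated) and
`aspartate-like` (0.30/0.30/0.30/0.10, turn-rich). `make_truth()` draws
directional pPII↔β cross couplings uniformly within
±`coupling_magnitude` (default 2 kJ/mol, so combined dimer couplings
span ±4 kJ/mol — the range reported for real residue pairs, which
reaches and exceeds thermal energy). `observe_fractions()` adds
truncated Gaussian noise to the exact marginals and renormalizes onto
the simplex (default SD 0.02, a typical scatter for fitted mole
fractions; the source analyses state no error model).
`observe_couplings()` adds Gaussian noise (default 0.2 Hz for ³J-scale
couplings) to predicted couplings.

What passing the synthetic suite shows: the estimator chain is correct
and unbiased — noiseless observations return the generated combined
couplings to ±0.1 kJ/mol, and across noisy replicates the mean signed
error stays below 0.3 kJ/mol. What it does **not** show: that
*individual* noisy estimates are precise. A Fisher-information
calculation at the fit's own design (eight observed fractions, stage-1
two-parameter fit) bounds the per-coupling standard deviation at
mole-fraction noise of 0.02 to roughly 0.7–0.9 kJ/mol even for
favorable, balanced propensity profiles; pPII-dominated profiles are
worse. Individual couplings recovered from single noisy tables therefore
scatter by ±1–2 kJ/mol — which is precisely why the flat-χ² uncertainty
scan exists and why the significance convention is a half thermal
energy. The generator also does not emulate: basin-position shifts
(excluded from the model by design), second-nearest-neighbor couplings
(their absence is what the pentapeptide upstream adjustment diagnoses),
temperature dependence of propensities, or raw NMR observables.

## Numerical choices, in one place

| Choice | Default | Why |
|---|---|---|
| Gas constant | 8.314 J mol⁻¹ K⁻¹ | standard value used throughout |
| Temperature | 300 K | the reference temperature for energies/entropies; configurable |
| `eps_floor` | 1e-4 | finite energies for unobserved classes |
| Fit bounds | ±10 kJ/mol | generous envelope around the observed 0–4 kJ/mol range |
| Multistarts | 16 in ±5 kJ/mol, fixed seed | flat/multimodal surfaces |
| χ² scan threshold | min + 1.0 | interval convention; not stated by the source analysis |
| Flat flag | interval > 2.5 kJ/mol | thermal-energy benchmark |
| Significance | combined couplings > 1.25 kJ/mol | half thermal energy |
| Quadrature | 2° periodic grid, wrap ±360° | < 0.01 Hz error for σ ≥ 5° |
| Weight QP ridge | 1e-4 toward initial weights | positive-definite QP under few observations |

Test problem sizes were chosen to keep the default suite fast while
still exercising every claim: enumeration oracles run 100 random
systems of 16–64 conformers; parameter-recovery studies run 10 noiseless
and 100 noisy tetrapeptide replicates (4 optimizer starts each);
coupling-weight recovery runs 50 replicates against a single cached
basin geometry.

## A worked example

```{r example, eval = FALSE}
tab <- example_fraction_table()

intr <- bind_rows(
  intrinsic_energies(filter(tab, peptide == "GAG")[, 2:4]),
  intrinsic_energies(filter(tab, peptide == "GFG")[, 2:4]) |>
    mutate(residue = 2)
)

fit <- fit_nni(
  filter(tab, peptide == "GAFG")[, c("residue", "state", "fraction")],
  intr, stages = 2
)
tidy(fit)          # combined couplings + significance calls
glance(fit)        # chi-square per stage
autoplot(fit)      # observed vs fitted marginals

entropy_gibbs_difference(intr, fit$params)
scan_uncertainty(fit, 1, "pPII", "beta", grid = seq(-2, 6, 0.5))
```

## Known limitations

- Chains are limited to two or three guest residues; no extrapolation to
  long peptides (the persistence of coupled conformational stretches is
  an open question the model cannot answer).
- Only the combined directional sums are identifiable; any directional
  decomposition in the output is a convention.
- Stage-2 fits are over-parameterized relative to a single peptide's
  observations; turn-class couplings should always be read together with
  their flat-χ² intervals.
- Entropies are four-class entropies; basin substructure and continuous
  (φ,ψ) entropy are out of scope.
- The Gaussian basins are axis-aligned (no φ–ψ correlation term) and
  basin halfwidths are not fitted.
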