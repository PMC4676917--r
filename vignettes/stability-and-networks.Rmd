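---
title: "Cold denaturation thermodynamics and contact-persistence networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cold denaturation thermodynamics and contact-persistence networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coldcurve)
```

## The two-state stability curve

A two-state protein in equilibrium between a folded and an unfolded state
has an unfolding free energy ΔG(T). With a temperature-independent
heat-capacity change of unfolding ΔCp — a good approximation over the
0–80 °C window for small globular proteins, where ΔCp is dominated by
hydrophobic hydration — ΔG takes the Gibbs–Helmholtz form

$$\Delta G(T) = \Delta H \left(1 - \frac{T}{T_m}\right) +
\Delta C_p \left[(T - T_m) - T \ln\frac{T}{T_m}\right],$$

anchored at the heat-denaturation midpoint $T_m$ where $\Delta G(T_m)=0$
and $\Delta H$ is the van't Hoff unfolding enthalpy. Because ΔCp > 0 the
curve is concave (dome-shaped): it has a single interior maximum at the
temperature of maximal stability, which follows in closed form from
$d\Delta G/dT = 0$,

$$T_s = T_m \exp\!\left(-\frac{\Delta H}{\Delta C_p\, T_m}\right),$$

and, when the dome is narrow enough, a second zero $T_c < T_s$: the
cold-denaturation midpoint. The folded population at any temperature is
$f = K/(1+K)$ with $K = \exp(\Delta G / RT)$ the folded/unfolded ratio
($R = 1.9872\times10^{-3}$ kcal mol⁻¹ K⁻¹; all energies in kcal). $f$
equals 0.5 exactly at both midpoints and peaks between them.

Conventions worth stating explicitly:

* ΔG is the free energy of **unfolding**: positive when the folded state
  is favoured.
* Temperatures are kelvin internally; every user-facing value is Celsius
  (conversion constant 273.15).
* `stability_report()` reports the folded percentage **at $T_s$** — the
  best the protein ever does. For a marginally stable protein this number
  is strikingly low (61 % for wild-type Yfh1), which is the scientifically
  interesting observation; an alternative convention (a fixed 25 °C
  readout) reproduces published folded-percentage tables for such proteins
  less well, which is why the $T_s$ convention is the default.

### Numerical choices

$T_c$ is found by bracketed root finding (Brent via `stats::uniroot`, then
bisection polish) on $[200\,\mathrm{K}, T_s]$, to a **function** tolerance
of $10^{-9}$ kcal mol⁻¹. An unbracketed Newton iteration is deliberately
avoided — the curve is nearly flat around $T_s$, where Newton steps can be
thrown far outside the physical range. Below 200 K the constant-ΔCp
extrapolation has no physical meaning, so a curve whose cold zero would
fall there is reported as having *no cold transition in range* (a distinct
condition from invalid parameters), and `stability_report()` converts it
to an `NA` cold midpoint plus a warning rather than an error, so batch
runs continue.

```{r}
stability_report(stability_params(19.2, 2.24, 33.6, celsius = TRUE), "Wt")
```

## Fitting CD thermograms

The observable is the ellipticity at 222 nm, which tracks helicity and
hence the folded population. The signal model mixes two **linear**
baselines by the folded fraction:

$$\theta(T) = f(T)\,(a_F + b_F T) + (1 - f(T))\,(a_U + b_U T).$$

Design choices:

* **One shared unfolded baseline.** A thermogram with both cold and heat
  transitions visits the unfolded state at both ends of the temperature
  axis. Fitting separate cold- and heat-unfolded baselines would add two
  parameters that nothing in a single-wavelength trace can distinguish;
  sharing one line keeps the seven-parameter model identifiable.
* **Direct signal fitting.** The model is fitted to θ(T) directly rather
  than to pointwise-derived ΔG values, which would require committing to
  baselines *before* the fit and propagating their error nonlinearly.
* **$T_c$ is never a free parameter.** It is always recomputed from the
  fitted (ΔH, ΔCp, $T_m$) through the stability curve, so the reported
  cold midpoint is exactly the one the fitted thermodynamics implies.
* **Bounded local least squares.** Levenberg–Marquardt (`minpack.lm`) with
  bounds ΔH ∈ (1, 200) kcal mol⁻¹, ΔCp ∈ (0.1, 10) kcal K⁻¹ mol⁻¹,
  $T_m$ ∈ (0, 110) °C, one fallback restart from a +10 % perturbed start,
  and no global search: with two visible transitions the residual surface
  is benign. Unweighted by default; a per-point σ column, when present in
  the input file, enters as 1/σ weights. Parameter standard errors come
  from the local curvature at the optimum. Non-convergence yields a
  diagnosable `converged = FALSE` result, not an exception; a constant
  trace is rejected as unidentifiable outright.

The starting point matters more than the optimizer. Transition-detection
by smoothed derivatives proved erratic on shallow melts at realistic
noise, so `initial_guess()` instead runs a coarse profile search: for each
candidate ($T_m$, ΔH, ΔCp) on a small fixed grid, $f(T)$ is fixed and the
four baseline coefficients solve by ordinary linear least squares; the
lowest-residual candidate seeds the nonlinear fit. A trace that is
statistically a straight line falls back to fixed defaults
(ΔH = 25 kcal mol⁻¹, ΔCp = 2 kcal K⁻¹ mol⁻¹) with a `weak_signal` flag.

### What the synthetic thermograms emulate — and what they do not

`generate_thermogram()` produces the model signal on a 0–80 °C grid
(default 1 °C steps, matching a typical CD temperature ramp) plus additive
Gaussian noise, with default baselines folded (−10, +0.01) and unfolded
(−3, +0.02) mdeg — a plausible 222 nm helicity loss, chosen once as
fixtures. Real CD melts additionally contain slow-drift artefacts,
possible irreversibility at the hot end, and baseline curvature; passing
recovery tests on the generator therefore demonstrates the estimator's
correctness and precision under the stated noise model, not robustness to
every instrumental pathology.

A consequence worth knowing: for a *shallow* melt such as wild-type Yfh1
(maximal folded fraction ≈ 0.61), the information content of a single
trace limits how well $T_m$ can be recovered. At noise of 2 % of the
signal span, the Fisher-information standard error of $T_m$ for the
wild-type parameter set is ≈ 1.9 °C — so scatter of that order in refitted
$T_m$ values is a property of the data, not of the optimizer. Steep melts
(the mutant-like parameter sets) are recovered several-fold more tightly,
and noise-free traces are recovered to optimizer tolerance. Replicate
counts used in the test suite (20–50 synthetic traces per truth set) keep
the whole suite inside a couple of minutes on one CPU.

## Persistence networks from trajectories

The network half of the package answers: *which charge-bearing residues
spend an appreciable fraction of a trajectory close to each other in
space?* Clusters of like charges held loosely together on the surface
are candidate sites of electrostatic frustration — in yeast frataxin such
a cluster of acidic residues on adjacent β-strands behaves as a gate for
water entry and an early driver of cold denaturation.

The pipeline:

1. **Charge selection.** A residue (position in the ungapped reference
   sequence) is kept iff its alignment column carries D/E/K/R in *at
   least one* aligned orthologue — the reference itself or any other row.
   This deliberately includes positions where only a distant orthologue
   is charged, so cross-species comparisons see the same node set.
   Histidine is not counted as charged: at the experimental pH of 7.5 its
   imidazole is predominantly neutral. Columns where the reference has a
   gap have no reference numbering and are skipped.
2. **Distances.** For each selected pair and frame, the minimum distance
   over side-chain heavy atoms (Cα for glycine), in nm. Side chains, not
   backbones, are what approach each other in a salt bridge or a
   like-charge repulsion, hence the atom set.
3. **Persistence.** $p_{ij}$ = (number of frames with $d_{ij} <$
   threshold) / (number of frames) — an exact count, strict inequality at
   the boundary. Frame order is irrelevant by construction.
4. **Filter.** An edge is retained iff the pair is *beyond* the threshold
   for **not more than 99 %** of the trajectory, i.e. $p_{ij} \ge 0.01$
   with the default threshold of 0.6 nm. The complement phrasing matters
   at the boundary: a pair below threshold in exactly 10 of 1000 frames
   is beyond it in exactly 99 % — not *more than* 99 % — and is kept.
   Isolated nodes stay in the graph, flagged, so the node set remains the
   full charge selection.
5. **Clusters.** Connected components of the subgraph induced by acidic
   nodes, ordered by size then summed persistence. With an optional
   per-residue secondary-structure annotation, each cluster is flagged if
   it spans more than one element — a cluster confined to a single helix
   cannot strain the tertiary fold the way an inter-strand cluster can.

Trajectory input is a multi-model PDB (or a precomputed long-format
distance CSV); serialization is GraphML (lossless round trip through the
package's reader), edge-list CSV and DOT.

### The trajectory generator as an oracle

`generate_trajectory()` places alanine-like residues 3 nm apart and, in
exactly `round(persistence × n_frames)` seed-chosen frames per planted
edge, translates the higher-numbered residue to 0.55 nm from its partner;
everything else stays ≥ 0.8 nm apart. The margins (0.55 vs 0.8 nm) flank
the 0.6 nm threshold so widely that floating-point geometry cannot flip a
classification, making planted persistences *exact* and network recovery
an equality test rather than a statistical one. Edges sharing a moving
residue receive disjoint frame sets; a planted pattern that cannot be
realised (a residue owing more contact frames than the trajectory has, or
needing two simultaneous distant partners) raises an explicit
infeasible-geometry error, and a brute-force verification of the realised
contact counts backs the construction. The generator emulates *contact
patterns only* — there is no force field, no excluded volume, no
dynamics — so network-recovery tests validate the counting and filtering
machinery, not anything about real MD ensembles.

## Scope and limitations

* Two-state, monomeric, constant-ΔCp thermodynamics only: no three-state
  intermediates, oligomer-coupled unfolding, temperature-dependent ΔCp or
  pressure axis.
* Single-wavelength CD fitting; no spectral decomposition or global
  multi-wavelength fits.
* The network module consumes trajectories; it does not run or configure
  MD, and it deliberately reports geometry-based persistence, not
  electrostatic energies.
* The 0.6 nm / 99 % defaults are the field-standard operating point for
  side-chain contact persistence; both are exposed as parameters and the
  filter is monotone in each (raising the threshold never lowers a
  persistence; raising the persistence floor never adds an edge).
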