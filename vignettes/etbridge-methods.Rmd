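---
title: "Models and methods in etbridge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in etbridge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(etbridge)
```

etbridge characterises an electron-transfer (ET) complex between a small
redox protein (a cytochrome-like acceptor) and a larger partner enzyme from
solution NMR, activity, redox and scattering data, and ranks candidate
docking poses of the complex by their electron-tunneling coupling. This
vignette records the models, the defaults, and the design decisions; every
number shown here is produced by the package's own tests or the bundled
acceptance script.

## Chemical-shift-perturbation interface mapping

`compute_csp()` compares amide cross-peak positions of the free protein with
its partner-saturated state. The generalized shift difference weights the
proton axis five-fold relative to nitrogen,

$$\Delta\delta = \sqrt{\Delta\delta_H^2 + (\Delta\delta_N / 5)^2},$$

implemented as division of the ^15^N difference by `hn_weight = 5` inside
the root. The equivalent convention multiplies the ^1^H axis by 5; the two
differ only by a global factor that cancels in SD-relative classification.
The weight is a parameter.

Residues whose bound-state peak vanishes are carried as `broadened_out`,
never dropped: disappearance beyond the detection limit is itself binding
evidence in slow exchange. The intensity ratio `I_free / I_bound`
accompanies each residue because complex formation slows tumbling and
broadens every line, with extra broadening at the contact surface.

`classify_csp()` bins observed residues against the plain standard deviation
of the combined shifts (a median-absolute-deviation option exists but is off
by default, since the reference analysis used the plain SD, which lands near
0.1 ppm for typical amide perturbation sets). `call_interface()` then:

1. groups `above_sd` and `broadened` residues into runs bridging gaps of up
   to `contiguity_window = 3` residues (a contact patch is contiguous on the
   sequence at helix-turn granularity);
2. demotes runs whose observed members show no intensity-ratio elevation
   over the ensemble mean (`ratio_margin = 1.2`) to *allosteric
   candidates* — a large shift without extra broadening indicates a
   conformational response transmitted from the interface, not contact;
3. prunes individual run members that are neither broadened, nor strongly
   shifted (≥ 2 SD), nor intensity-elevated: isolated noise exceedances
   merged into a genuine run by the contiguity window would otherwise
   inflate the called set;
4. optionally demotes runs that are buried (median relative side-chain SASA
   below `sasa_threshold = 0.15`) when a structure is supplied.

Automated demotion approximates, but cannot reproduce, expert judgment;
both sets are always reported so a user can move a window between them.

## Binding, redox and pH-activity fits

**Morrison isotherm.** When the dissociation constant is comparable to the
protein concentration, ligand depletion makes the hyperbolic isotherm
invalid; the quadratic-root (tight-binding) form is used:

$$\Delta I_{obs} = \Delta I_{max}\,
  \frac{nP_t + L_t + K_d - \sqrt{(nP_t + L_t + K_d)^2 - 4nP_tL_t}}{2nP_t}.$$

`fit_morrison()` estimates `Kd` (internally on a log scale, keeping it
positive) and `dImax`; the site number `n` is fixed at 1 by default because
saturation at a ~1:1 molar ratio indicates a single site — estimating `n`
is opt-in. The discriminant is clamped at zero as a numerical guard.

**Nernst.** One-electron centres titrate as
$f_{red}(E) = 1/(1 + 10^{(E - E_m)/s})$ with $s = \ln(10)RT/F$
(59.16 mV at 298.15 K, the default temperature since no in-cell temperature
is stated for the redox titrations). Only `Em` is fitted.

**pH-activity with an acidic shoulder.** The enzyme's activity follows the
classic two-pKa bell
$\Phi = 1/(1 + 10^{pK_{acid} - pH} + 10^{pH - pK_{alk}})$ attributed to
essential catalytic groups (reference values 8.5 and 10.5). With the
cytochrome acceptor an extra shoulder appears on the acidic side; it is
modelled as a component tied to protonation of a histidine-like site on the
acceptor, $\theta_{sh} = 1/(1 + 10^{pH - pK_{sh}})$. The published analyses
of such curves do not print a functional form, so the composition is a
pluggable interpretation: the default multiplies the bell amplitude,
$A = (A_{base} + A_{sh}\theta_{sh})\,\Phi$ (protonation modulates the
productivity of the same catalytic cycle); an additive variant
$A = A_{base}\Phi + A_{sh}\theta_{sh}$ is provided. With $A_{sh}=0$ both
reduce to the plain bell.

Numerical choices for this fit deserve note. The three equilibria are
parametrised as `pKa_acid` plus strictly positive offsets
(`pKa_sh = pKa_acid - d_sh`, `pKa_alk = pKa_acid + d_alk`), which enforces
their ordering and prevents the optimizer from swapping the shoulder and
alkaline limbs. Offsets are bounded by the measured pH window: a shoulder
located outside the data cannot be identified and would otherwise drift to
absorb baseline noise. Optimization uses `minpack.lm::nls.lm` directly
(the `nls`-object wrapper rejects the near-degenerate Jacobian a weak
shoulder legitimately produces) with a small multi-start over shoulder
placements; among candidates whose residual sums are within 5% of the
minimum, an interior solution is preferred over one pinned at the window
bound, which marks the degenerate valley where the shoulder has left the
data. Shoulder support is decided by two conditions together: an F-test of
the full model against the plain bell, and a bootstrap interval for
`A_sh` excluding zero — `A_sh` alone is degenerate with the bell amplitude
when `pKa_sh` crowds `pKa_acid`, so interval coverage by itself is not
evidence.

All fits report seeded residual-bootstrap intervals (default 500
resamples) rather than asymptotic covariances, which are unreliable at the
small point counts these titrations have.

## Pseudocontact shifts

For a nucleus at distance $r$ from a paramagnetic centre with direction
cosines $(l, m, n)$ in the principal frame of the magnetic susceptibility
tensor:

$$\delta^{pc} = \frac{1}{24\pi r^3}\left[(2\chi_{zz} - \chi_{xx} -
\chi_{yy})(3n^2 - 1) + 3(\chi_{xx} - \chi_{yy})(l^2 - m^2)\right],$$

algebraically identical to the axial/rhombic form
$\frac{1}{12\pi r^3}[\Delta\chi_{ax}(3n^2-1) +
\tfrac{3}{2}\Delta\chi_{rh}(l^2-m^2)]$. Both are implemented and their
equality on random inputs is pinned to machine precision by a test, which
fixes the algebra against typographical ambiguity in transcribed sources.
Units follow the tensor; `pcs_ppm()` covers the common convention of
anisotropies in $10^{-32}\,\mathrm{m^3}$ with distances in Angstrom.
`pcs_field()` evaluates the shift over a structure and, given two tensors,
returns their per-nucleus difference — the splitting pattern produced by a
fluxional axial ligand exchanging the tensor between two states. No tensor
values are fitted or assumed: the module is exercised on synthetic tensors,
since no numeric tensor is available for the reference system.

## The Pathways tunneling calculator

The empirical tunneling-pathway model assigns each step between atoms a
decay factor:

| step | decay | default |
|---|---|---|
| covalent bond | $\epsilon_C$ | 0.6 |
| hydrogen bond | $\epsilon_C^2\,e^{-\beta(R - R_{HB})}$ | $\beta = 1.7\,\mathrm{\AA^{-1}}$, $R_{HB} = 2.8\,\mathrm{\AA}$ |
| through-space | $\tfrac{1}{2}\epsilon_C\,e^{-\beta(R - R_{TS})}$ | $R_{TS} = 1.4\,\mathrm{\AA}$ |

with detection cutoffs 1.9 Å for covalent pairs (2.2 Å with sulfur or a
metal; Cu-ligand 2.6 Å and Fe-ligand 2.4 Å coordination bonds count as
covalent so metal centres join the bonded graph), 3.5 Å donor-acceptor
heavy-atom distance for hydrogen bonds (no angle criterion, because docked
models carry unreliable or no hydrogens — hydrogens are excluded from the
graph by default), and 6.0 Å for through-space jumps. All decays are capped
at $\epsilon_C$. These values follow the canonical parameterization of the
model; every one is exposed in `pathway_params()`.

The donor-to-acceptor coupling is the maximum over paths of the product of
step decays, $T_{DA} = \max_\pi \prod_{e \in \pi} \epsilon_e$, a relative
(dimensionless) coupling with no absolute prefactor — couplings of
$10^{-7}$–$10^{-5}$ correspond to bridges of roughly 15–25 covalent-bond
steps. `best_path()` maximizes the product as a shortest path under edge
weights $-\ln\epsilon > 0$, with ties broken by the lexicographically
smallest node sequence so results are deterministic; `top_k_paths()`
enumerates alternatives (Yen's algorithm via igraph). Correctness is
established against an exhaustive simple-path enumeration oracle on 200
seeded graphs of up to 10 nodes, plus closed-form chains
($T_{DA} = 0.6^k$) and an edge-monotonicity property suite. Donor and
acceptor atom sets attach to virtual super-nodes through unit-decay edges,
so multi-atom centres (a metal site, a heme macrocycle with its
propionates) terminate paths at whichever member atom is reached first.

## Pose ranking and restraint generation

`score_poses()` evaluates $T_{DA}$ for every pose of a docking ensemble and
sorts by it; poses with disconnected donor/acceptor score zero and sort
last, and per-pose failures are recorded without aborting the run. When an
external docking score is available it is carried along but never overrides
the coupling: tunneling efficiency is the primary selection criterion, the
external score a secondary diagnostic.

`contacts_vs_csp()` checks a pose's intermolecular residue contacts
(heavy-atom distance ≤ 5 Å; the cutoff is a parameter since no published
value exists) against the CSP-called interface, reporting precision and
recall plus any contacts inside flagged allosteric windows.

`generate_airs()` converts the CSP interface call into ambiguous
interaction restraints in the information-driven docking convention:
active residues are the surface-exposed interface residues (buried ones are
excluded with a warning, via the Shrake-Rupley SASA filter), passive
residues are surface neighbours within 6.5 Å of an active, and each active
residue is restrained to the OR-ed partner set with effective distance
bounds 0–2 Å. `extract_unambiguous_restraints()` measures named atom pairs
in a selected pose (metal-to-propionate, interface side-chain pairs) and
emits unambiguous records with symmetric ±1 Å bounds by default. Both
serialize to CNS/HADDOCK `assign` statements via `write_restraints()`.

The package does not run docking. The second modelling stage is emulated at
desk scale by `check_restraints()`: the unambiguous restraints extracted
from the best pose filter the ensemble down to poses sharing its binding
geometry, which strictly reduces the ligand-position spread
(`pose_spread()`, measured after receptor superposition on atoms common to
all poses). Engine-side protocol settings belong to the docking engine and
are out of scope.

## Structure-ensemble and scattering descriptors

Superposition is the SVD solution of the orthogonal Procrustes problem with
the reflection branch excluded (`superpose()`), cross-checked against a
rotation-grid-search oracle. `ensemble_stats()` superposes all models on
the core backbone (two passes: onto the first model, then onto the mean),
and reports both RMSD conventions — average RMSD to the mean structure
(default) and average over all model pairs — because "ensemble RMSD" is
used for either in the literature; backbone selection defaults to
N, CA, C, O with CA-only traces handled automatically. The maximum extent
is reported per model and as the maximum over models (the most extended
conformer sets the ensemble's size). `pr_from_coords()` histograms all
heavy-atom pair distances (normalized to integrate to 1) with
`Dmax` the largest distance; both are rigid-motion invariant by
construction and by test.

`guinier_fit()` fits $\ln I$ against $q^2$ over a low-angle window whose
upper limit is iterated so that $q_{max}R_g \le 1.3$, the standard validity
limit for globular scatterers; `kratky()` produces the dimensionless curve
$(qR_g)^2 I/I_0$, which for an ideal Guinier-law scatterer peaks at
$\sqrt{3}$ with value $3/e$ (an analytic fixed point used as a test).
`sasa()` is Shrake-Rupley sphere sampling with a deterministic
golden-spiral point set (960 points, probe 1.4 Å) and a documented van der
Waals radius table; `group_sasa()` reports a group's area in context
against the extracted group alone, quantifying e.g. heme solvent exposure.
`sequence_mass()` uses average residue masses plus one water with optional
N-terminal (signal-peptide) truncation; `isoelectric_point()` bisects the
Henderson-Hasselbalch net charge under the EMBOSS pKa table (other tables
can be passed, and published pI values move by ±0.2 between tables).

## Synthetic data: what it emulates, and what it does not

All generators are pure functions of their arguments and a seed (the
caller's RNG state is untouched), and each returns its ground truth
alongside the data.

* `make_peaklists()` plants a direct-contact interface into two-state
  slow-exchange peak lists: per-residue displacement scales
  (defaults H 0.2 ppm, N 1.0 ppm), a broadened-beyond-detection fraction
  (0.3), a global bound-state intensity attenuation (0.6) with extra
  attenuation at the interface (×0.4), referencing noise of 0.02 ppm, and
  optional allosteric residues that shift but keep interface-free intensity
  behaviour. These scales mirror a mid-size complex saturating a 153-residue
  partner; what they do *not* emulate is peak overlap, assignment error, or
  exchange-regime lineshape effects — recovery statistics on this generator
  therefore bound algorithmic, not spectroscopic, performance.
* `make_titration()` draws Gaussian noise around the exact forward models.
  Recovery studies use noise at which the measured feature is clearly
  resolved, matching the reference data: 3% of the signal change for
  binding, 2% of the reduced fraction for redox, and 0.02 activity units
  for pH curves (signal-to-noise ≈ 15 on the shoulder component — at
  several-fold larger noise the shoulder is physically unresolvable and its
  pKa undefined, which the identifiability flag reports).
* `make_ensemble()` builds a CA-trace ensemble of 153 residues: a compact
  seeded self-avoiding core (residues 24–132) shared across 20 models with
  0.3 Å per-coordinate jitter — chosen so the core RMSD-to-mean sits near
  0.5 Å, the hallmark of a well-defined NMR core — and per-model 3.8 Å-step
  random-walk tails for the disordered histidine-rich termini. The random
  tails reproduce the low-core/high-termini RMSD profile and a
  model-variable maximum extent, but not the specific compaction of real
  disordered chains, so the ensemble's absolute Dmax is not a reproduction
  of any measured value.
* `make_saxs()` produces a Guinier-Porod profile exact in the Guinier
  region with a continuous $q^{-4}$ crossover, plus relative noise.
* `make_toy_complex()` embeds donor-bridge-acceptor chains with exact link
  distances and returns the intended molecular graph for oracle comparison;
  chemistry realism is not a goal, graph realism is.

## Problem sizes

The test-suite and acceptance-script study sizes are: 200 random graphs
(≤ 10 nodes) for the path oracle, 50 planted-interface simulations for
recovery statistics, 50–100 replicates per titration model for bias, 20
noisy profiles for Guinier recovery, 20-model ensembles for structure
statistics, and 3–6-pose ensembles for the ranking and restraint
round-trips. These sizes give stable means (the recovery statistics move by
well under their tolerance across seed streams) while keeping a full run in
tens of seconds.

## Known limitations

* The interface caller reproduces rule-based demotion only; expert
  judgments that split a run between contact and allosteric assignment must
  be applied by moving windows between the two reported sets.
* $T_{DA}$ is relative: no reorganization energy, packing density or
  absolute rate is computed, and couplings from differently parameterized
  implementations agree only up to their parameter choices.
* The pH shoulder's composition with the bell (multiplicative vs additive)
  is an interpretation; both are available and the choice matters only for
  amplitudes, not the fitted pKa values, in the regimes tested.
* NMR-STAR reading covers the assigned-chemical-shift loop of v3 entries,
  not full depositions; mmCIF writing emits a minimal `atom_site` loop.
* SASA uses a fixed radius table and no hydrogens; relative (fractional)
  values are robust to this, absolute areas less so.
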