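---
title: "Models and methods behind ythbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ythbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ythbind)
```

`ythbind` quantifies how a YTH reader domain recognises
N6-methyladenosine (m⁶A) in single-stranded RNA, through four analysis
chains — chemical-shift-perturbation (CSP) mapping, scaffold-independent
sequence-preference analysis (SIA), one-site ITC fitting and
NMR-ensemble statistics — plus a synthetic-data layer that generates
inputs with the statistical structure each chain assumes. This vignette
explains the models, the tunable parameters and the design choices; it is
the package's methods reference.

## Chemical-shift perturbation mapping

A two-state binding event moves each amide resonance from its free to its
bound position. The combined perturbation of a residue is

$$\Delta\delta = \sqrt{\delta_{HN}^2 + (\delta_N / 6.51)^2},$$

the Euclidean shift change with the ¹⁵N axis compressed by 6.51 so that
both dimensions contribute on a comparable ppm scale
(`combined_csp()`).

**Peak tracking.** Titration spectra are unassigned beyond the free
state, so each free-state peak is chained to its nearest neighbour in the
next point, within a rectangular search radius (default 0.05 ppm ¹H,
0.4 ppm ¹⁵N — chosen as a few line widths; no community standard exists,
so it is a visible, configurable parameter of `track_peaks()`). If two
candidates fall inside the radius the smaller combined distance wins and
the trajectory is flagged ambiguous. A chain that breaks — the
intermediate-exchange phenotype, where a peak broadens beyond detection —
marks the residue *untracked*.

**The 0.3 ppm cap.** Untracked residues clearly perturb but their
magnitude is unknowable from the endpoint spectra; they enter all
downstream sums at a fixed cap (default 0.3 ppm, `cap_value`), a value at
the upper end of typical combined perturbations. Prolines and residues
unassigned in either state are a *status*, excluded from sums entirely —
they are not given a sentinel number, because a numeric placeholder would
silently bias position scores.

The profile is computed free-state versus final titration point (1:1
complex), not cumulatively per step: intermediate points serve tracking
only.

## Scaffold-independent sequence-preference analysis

Each hexamer position is probed by titrating the four substitution
oligos and summing each variant's per-residue perturbations (capped
values included, unassigned residues contributing zero). Within a
position the four sums are normalised to the largest (`score_position()`),
so exactly one variant scores 1 except under exact ties. The *modified*
protocol fixes the winning nucleotide into the scaffold before the next
position is assayed, in the order 4, 3, 2, 6, 1; position 5 is never
assayed and is always reported `N`. `run_sia()` verifies that each
panel's scaffold carries all previously fixed winners and assembles the
IUPAC consensus.

**Winner margin.** How much a nucleotide must dominate before the
position is called specific is a judgement call the protocol leaves open.
We call a winner only when the runner-up's normalised score falls below
$1 - \tau$ with $\tau = 0.2$ by default (`margin`): smaller margins
over-call noisy panels, larger ones under-call genuine preferences. With
20% multiplicative noise on the perturbations, a 3× preference is called
correctly in ≥95% of replicates (see the acceptance tests), while
uniform panels normalise to ≈1 everywhere and yield `N`.

Two further choices: all residues enter the sums (an optional `min_csp`
floor is off by default — the protocol sums perturbations without a
threshold), and capped residues are *included* in the sums, since the cap
exists precisely so that strongly perturbed but untrackable residues
still count. Sub-stoichiometric panels (e.g. a position titrated only to
a 1:0.6 ratio) are scored as-is, with the ratio kept as provenance on the
panel.

## One-site ITC model and fitting

For a single-site equilibrium with association constant $K$, enthalpy
$\Delta H$ and stoichiometry $N$, the cumulative heat content of the cell
after injection $i$ is

$$Q_i = \frac{N M_i \Delta H V_0}{2}\left[ 1 + \frac{X_i}{N M_i} +
\frac{1}{N K M_i} - \sqrt{\left(1 + \frac{X_i}{N M_i} +
\frac{1}{N K M_i}\right)^2 - \frac{4 X_i}{N M_i}} \right],$$

where $M_i$ and $X_i$ are the dilution-corrected total macromolecule and
titrant concentrations. We adopt the perfusion-cell convention
throughout: with cumulative injected volume $v_i$,

$$M_i = M_0 \frac{1 - v_i/2V_0}{1 + v_i/2V_0}, \qquad
X_i = X_s \frac{v_i/V_0}{1 + v_i/2V_0},$$

and the observed heat of injection $i$ is
$\Delta Q_i = Q_i - Q_{i-1} + (dV_i/V_0)\,(Q_i + Q_{i-1})/2$, the last
term being the mean-value correction for heat carried out with the
displaced volume. What matters most is that the simulator and the fitter
share one convention — mixing conventions induces percent-level parameter
bias; this package uses exactly this one on both sides. The cell volume
defaults to 1.4 ml (a typical perfusion cell) and is configurable; heats
are handled in µcal, thermodynamics reported in kcal·mol⁻¹ and
cal·mol⁻¹·K⁻¹ with R = 1.98720 cal·mol⁻¹·K⁻¹.

`fit_one_site()` minimises χ² with Levenberg–Marquardt (`minpack.lm`),
parameterising $\log K$ to keep the association constant positive.
Starting values come from the isotherm shape: $\Delta H$ from the
early-injection plateau of the normalised heats, $N$ from the molar ratio
at half-height, and $K$ from the width of the transition through the
empirical relation $c \approx 4 / \Delta r$ between the c-value
($c = N K M_0$) and the ratio width of the sigmoid's fall. Fits outside
$c \in [1, 1000]$ warn that parameters are weakly determined — below
$c=1$ the isotherm is featureless, above 1000 the transition is sharper
than the injection grid. The entropy is derived from the identity
$\Delta G = -RT\ln K = \Delta H - T\Delta S$, which holds exactly for
every returned fit and is asserted in the tests. The first injection can
be excluded (`exclude_first`), the common practice for real thermograms;
it is off by default because simulated first injections are unbiased.
`fold_change()` reports the ratio of two dissociation constants with
relative uncertainties combined in quadrature.

## Ensemble statistics, restraints and contacts

**Superposition.** RMSD-to-mean statistics require a reference frame; we
superpose all models onto an *iteratively refined mean*: fit every model
to the current mean of the selected atoms by optimal least-squares
rotation (Kabsch, via SVD), recompute the mean, repeat until the mean
moves less than 10⁻⁶ Å. The rotation is computed on the structured
selection and applied to all atoms, so different atom classes can then be
measured on one common frame. The iteration never increases the total
squared deviation of the selection, and the result is invariant under
rigid motion of the input — both are tested properties.

**Atom classes.** Backbone means N, CA, C for protein (carbonyl O
excluded) and P, O5′, C5′, C4′, C3′, O3′ for RNA; heavy means everything
but hydrogen. These sets are conventional but not universal, so they are
documented here and the selection object is configurable.

**Restraints.** Upper-limit distance restraints are classified by the
residue separation of same-chain pairs — intraresidual ($|i-j|=0$),
sequential ($|i-j|=1$), medium range ($1<|i-j|<5$), long range
($|i-j|\ge5$) — with cross-chain pairs intermolecular and
hydrogen-bond-flagged restraints counted as their own category; the six
categories always partition the input. CYANA `.upl` files number all
chains in one sequence, so chain identity is recovered from caller-
supplied residue ranges; a minimal NMR-STAR `_Gen_dist_constraint`
reader covers deposited restraint files.

**Contacts.** Hydrogen bonds are donor–acceptor pairs (N/O with an
attached hydrogen, N/O acceptor) with distance ≤ 3.5 Å and
donor–H–acceptor angle ≥ 120°; hydrophobic contacts are carbon–carbon
pairs ≤ 4.5 Å. These defaults are standard geometric criteria, not
values taken from any specific structure, and are parameters of
`find_contacts()`. NMR bundles carry hydrogens; for hydrogen-free models
a distance-only fallback exists but must be enabled explicitly, because
distance-only hydrogen bonds over-report. N6-methyladenosine appears
under several component codes in deposited files (`6MZ`, `6MA`, `MA6`);
all are normalised to an internal `M6A`.

## The synthetic-data layer

The generators produce inputs with the statistical structure the
analysis stages assume — they emulate phenotypes, not physics:

* **Titrations** (`simulate_titration()`) place a 30-residue construct's
  free shifts uniformly in realistic amide ranges (¹H 7–10, ¹⁵N 105–130
  ppm), with half the residues responding by up to 0.2 ppm (¹H) / 1.2 ppm
  (¹⁵N), and drive the bound fraction through the exact two-state mass
  balance `fraction_bound()`. Fast exchange moves one population-averaged
  peak; slow exchange trades free-position intensity $1-f_b$ for
  bound-position intensity $f_b$, peaks vanishing below an intensity
  cutoff; intermediate exchange drops designated residues whenever $f_b$
  lies in a window (default 0.25–0.75), producing exactly the
  "could not be followed" phenotype downstream. Full Bloch–McConnell
  lineshape simulation is deliberately out of scope: the pipeline only
  consumes peak positions and presence.

* **SIA panels** (`simulate_sia_panels()`) scale a common per-residue
  response pattern by per-nucleotide preference multipliers and chain the
  panels per the fixing rule. The default starting scaffold is a neutral
  poly-U hexamer — the scaffold is always an explicit argument, since the
  analysis is only interpretable when the assayed scaffold is stated.

* **Isotherms** (`simulate_itc()`) add i.i.d. Gaussian noise to the
  forward model. The synthetic study titrations use ΔH = −10 kcal/mol
  (methylated, Kd 0.1 µM) and −5 kcal/mol (unmethylated, Kd 5 µM):
  both reactions are exothermic, and these magnitudes are typical for
  protein–RNA association; only the dissociation constants, schedules
  and the sign of ΔH are constrained by the study being emulated.

* **Ensembles** (`perturb_ensemble()`) scatter a base structure (an
  idealised helical backbone from `synthetic_ensemble_base()`) with
  isotropic Gaussian displacement of sd σ per coordinate, optionally
  behind random rigid-body motions. The expected RMSD-to-mean is
  $\sqrt{3\sigma^2(1 - 1/M)}$ for $M$ models, which the generator
  reproduces within Monte-Carlo error.

Every generator is a pure function of its parameters and a seed, drawn
from a private RNG stream that leaves the caller's `.Random.seed`
untouched.

**What passing tests do and do not show.** The synthetic layer captures
two-state thermodynamics, exchange-regime phenomenology and isotropic
coordinate scatter. It does not model correlated noise, baseline drift or
integration error in thermograms, spectral overlap beyond what the
tracking radius resolves, assignment errors, or anisotropic /
correlated structural variation. Recovery of planted parameters therefore
validates the *computational* chain — formulas, tracking, normalisation,
fitting, superposition — not robustness to every pathology of real data.

## Problem sizes and numerical choices

The validation suite uses 30-residue constructs with ~11-point
titrations, 45-injection isotherms, 100-replicate consensus-recovery and
noisy-fit studies, and 50-replicate ensemble-scatter studies over
20-model, 15-residue ensembles — sizes at which every quantity of
interest is already stable to well within the asserted tolerances.
Noiseless ITC round trips recover parameters to <0.1% across
$c \in [1, 1000]$; the square-root discriminants in `one_site_heats()`
and `fraction_bound()` are clamped at zero to absorb rounding at the
stoichiometric boundary; superposition convergence is declared at an RMS
mean shift below 10⁻⁶ Å (typically 2–3 iterations); collinear
superposition selections are rejected rather than silently resolved.

## Known limitations

* Peak tracking is positional only; it will follow a wrong peak through a
  genuine crossing that stays inside the search radius (flagged
  ambiguous, not resolved).
* The ITC module fits a single-site model only; multi-site or competitive
  schemes are out of scope, as is baseline integration of raw power
  traces.
* Restraint handling counts and classifies; it does not recompute
  violation energies.
* The contact report is criteria-dependent by nature; membership of a
  pair near the cutoffs should be read with the thresholds in mind.
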