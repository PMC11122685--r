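---
title: "Quantifying active-site competence: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying active-site competence: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polsite)
```

## The scientific question

High-fidelity DNA polymerases only catalyse phosphoryl transfer when the
active site is geometrically poised: the primer 3'-OH, the incoming dNTP's
alpha-phosphate, the catalytic aspartates and the two Mg2+ ions must sit
within narrow distance windows, and reaching that arrangement requires a
collective open-to-closed motion of the Fingers subdomain. Point mutations
far from the catalytic residues can abolish activity by destabilising this
arrangement rather than by removing chemistry. `polsite` implements the
quantitative toolkit used to make that argument from simulation ensembles
and binding experiments:

- subdomain-resolved RMSD and RMSF profiles, and mutant-minus-wild-type
  RMSF differences;
- dynamic cross-correlation matrices (DCCM) and their difference maps;
- normal modes, both elastic-network (ANM) on a structure and PCA on an
  ensemble, with per-mode contribution fractions and mode–displacement
  overlaps (to label, e.g., "breathing" vs "rocking" motions against
  user-supplied reference displacement vectors);
- extraction of catalytic distances, k-means clustering in the (d1, d2)
  plane, and occupancy of a "competence box";
- residue-pairwise non-bonded energy decomposition (EDA);
- single-site titration calorimetry fitting and the thermodynamic
  conversions between Kd, ΔG and ΔΔG.

Here d1 is the primer O3′ to dNTP Pα distance and d2 the catalytic
aspartate to primer O3′ distance; the competence box defaults to
d1 ∈ [3.0, 3.8] Å, d2 ∈ [2.8, 3.5] Å (closed intervals on both axes).

Production MD trajectories for such systems are rarely deposited, so the
package treats synthetic-data generation as a first-class module: every
analysis stage can be exercised on ensembles with exactly known ground
truth, which turns the whole pipeline into a parameter-recovery experiment.

## Synthetic ensembles and what they do (and do not) emulate

### Elastic-network ensembles

`gen_enm_ensemble()` samples conformations from the Boltzmann distribution
of an anisotropic elastic-network model: displacements are drawn from a
multivariate Gaussian with covariance $k_B T \, H^{+}$, where $H$ is the
3N×3N ANM Hessian (uniform spring constant γ, contact cutoff 15 Å — the
standard Cα-ANM defaults) and $H^{+}$ its pseudo-inverse over internal
modes. The six rigid-body modes are excluded by eigenvalue rank after
checking that no more than six eigenvalues are numerically zero; more than
six indicates a disconnected contact graph and is an error naming the
components, not a warning.

Because the exact covariance is attached to the ensemble, closed-form
predictions exist for everything downstream: the per-residue RMSF is the
square root of the trace of each atom's 3×3 covariance block
(`enm_model_rmsf()`), the DCCM converges to the model-implied correlation,
and ensemble PCA must recover the soft ANM subspace (we require a top-5
RMSIP ≥ 0.9 at 20,000 frames in the acceptance suite, and observe ≈ 0.97
to 0.999).

What this emulates well: harmonic fluctuation statistics, subdomain
correlation structure, the spectral composition of collective motion. What
it does not emulate: anharmonicity, barrier crossings, solvent friction,
and amplitude scales of real force fields. A passing recovery test
therefore validates the *estimators*, not any claim about a particular
protein's dynamics.

### Two-state catalytic-distance trajectories

`gen_two_state_distances()` draws each frame from a bivariate Gaussian
mixture in (d1, d2): a competent state with occupancy `p_competent` and an
incompetent state. Negative draws are rejected and resampled (distances
are positive); with state means ≥ 2.8 Å and standard deviations ≤ 0.5 Å
the rejection probability is negligible, so the mode locations are not
materially biased.

The default parameterisation encodes the study regime for this enzyme
family: the competent state centred at d1 = 3.5 Å and the incompetent
state at d1 = 4.3 Å, with competent occupancy 0.40 for the wild-type-like
system and 0.12 for the mutant-like system (chosen once, below the < 15%
bound that characterises the mutant regime). The within-state standard
deviations (0.10 Å competent, 0.25 Å incompetent, correlation 0.3) were
fixed once as realistic widths for an MD distance coordinate: tight enough
that the competent state sits essentially inside the competence box, wide
enough that the incompetent state leaks a fraction of a percent into it,
as real distance clouds do.

### Toy charged topologies

`gen_toy_topology()` builds point-charge residues with chained bonds and
plausible Lennard-Jones parameters from a residue-level spec (net charge,
atom count, centre). `eda_demo_residues()` ships the canonical test
system: a +1 arginine-like residue in ~3 Å contact with a −4 dCTP-like
ligand plus distant spectator residues, the regime in which one charged
contact dominates the ligand's stabilisation ranking.

### Titration isotherms

`gen_itc_isotherm()` produces per-injection heats from the same
single-site model the fitter uses (see below) plus additive Gaussian
noise, under the published titration geometry defaults: 19 injections
(0.4 µL then 18 × 2 µL) of 200 µM ligand into 5 µM macromolecule at
310.15 K.

## Method details and numerical choices

**Superposition.** `kabsch()` is the SVD formulation with the
determinant-sign correction, so the rotation is always proper; weighted
fits are supported and near-degenerate (collinear) point sets are flagged
but still produce a proper rotation. The independent oracle in the test
suite is Horn's quaternion method; agreement is required to 1e-8 Å on
random clouds.

**Representative atoms.** All subdomain-level metrics (RMSD, RMSF, DCCM,
modes) use one representative atom per residue — Cα for amino acids, C1′
for nucleotides, falling back to the first atom of a residue for minimal
synthetic systems. Backbone-level dynamics is what these metrics are meant
to summarise; an atom-level choice would mix side-chain noise into them.

**Fit masks.** Trajectory metrics fit on a configurable mask and measure
on others without refitting (fit-on-core, measure-everywhere). The
pipeline defaults to fitting on the first (Palm-like) mask, the least
mobile region around the catalytic core.

**RMSF reference.** Profiles are computed about the *converged iterative
mean structure* (realign, re-mean, repeat until the mean moves < 1e-6 Å;
error after 100 iterations), not about frame 1, which removes
reference-frame bias. For isotropic jitter of amplitude σ this yields the
σ√3 closed form up to the small variance absorbed by the 6 fitted
rigid-body degrees of freedom (a relative effect of about 3/(3N), which is
why the closed-form test uses 100 atoms).

**DCCM.** Computed on mean-aligned displacements; atoms with zero
displacement variance produce NA rows/columns plus a warning rather than
silent zeros. `align = FALSE` is available for ensembles that are already
aligned — re-fitting constructed motions (e.g. two atoms translating in
lockstep) would distort exactly the correlations being tested. Difference
maps are taken mutant − wild type with per-block (subdomain-pair) means
reported, since single-matrix elements are too noisy to support claims
about inter-subdomain coupling.

**Normal modes.** ANM contribution fractions use inverse-eigenvalue
(variance) weights, `(1/λ_k)/Σ(1/λ)`; PCA fractions use `λ_k/Σλ`. Both
mode flavours are provided because trajectory-level "mode" analyses in the
literature are sometimes structure-based and sometimes ensemble-based; the
`kind` field records which was used. Breathing/rocking-style labels are
assigned only via `mode_overlap()` against user-supplied reference
displacement vectors — the package never hard-codes a biological label for
a mode.

**k-means.** `kmeans_2d()` seeds with k-means++ and delegates the Lloyd
iterations to `stats::kmeans(algorithm = "Lloyd")`, taking the best of
`n_init` restarts by within-cluster sum of squares; all randomness is
funnelled through one seed (default 853). Distances are clustered
unscaled: both axes are Å, so standardisation would distort the geometry.
Clusters are relabelled by ascending d1 centroid so cluster identities are
reproducible. If `k` is not given it is chosen by mean silhouette width
over k = 2..6 (on a 5,000-point subsample for large F). Because "fraction
of snapshots in the box" and "fraction of snapshots in clusters whose
centroid is in the box" answer subtly different questions, `box_occupancy()`
reports both when a clustering is supplied.

**Energy decomposition.** Pairwise Coulomb with k = 332.0636
kcal·Å/(mol·e²) in vacuum, no distance cutoff, no Ewald; Lennard-Jones
with Lorentz–Berthelot combining; 1-2 and 1-3 bonded pairs excluded and
1-4 pairs scaled by 1/1.2 (electrostatic) and 1/2.0 (LJ), the Amber-family
convention matching the force fields such systems are simulated with.
Profiles report per-residue means ± SEM (sd/√F) over frames, computed
against a reference group (ligand or mutation site); intra-reference
energies are excluded by construction. Internally all energies are signed;
the ranking layer additionally reports the magnitude of attractive totals
as `stabilization` because stabilisation energies are conventionally
quoted as positive numbers.

**ITC.** The single-site (Wiseman) model solves the binding quadratic
exactly (smaller root) after each injection, under a perfusion dilution
model: each injection displaces fraction v/V0 of the well-mixed cell
contents, and the per-injection heat credits only newly formed complex in
the cell, `ΔH·V0·(nΘ_i M_i − nΘ_{i−1} M_{i−1}(1 − v_i/V0))`. This
bookkeeping makes the tight-binding mass balance exact: as Kd → 0 with
excess syringe ligand, the heats sum to n·M0·V0·ΔH. Fitting is
Levenberg–Marquardt on (n, log Kd, ΔH) — the log scale keeps Kd positive —
with the 0.4-µL priming injection down-weighted to zero, standard errors
from the Jacobian, and ΔG derived from the fitted Kd at the isotherm
temperature (310.15 K for all replication-grade conversions; 1 M standard
state). Two diagnostic behaviours are deliberate: an essentially flat
isotherm returns ΔH ≈ 0 with Kd flagged unidentifiable rather than an
arbitrary number, and a c-value (n·M0/Kd) outside [1, 1000] attaches a
warning. In the low-c regime n trades off against ΔH and is practically
unidentifiable, so `fix_n = TRUE` (used by the pipeline, where the
generator's n = 1 is known) is the standard shallow-isotherm practice.

**Structure I/O.** Multi-model PDB is the canonical interchange format; a
whitespace XYZ dialect is accepted for synthetic ensembles. Parsing is
deliberately strict: malformed ATOM records error with the line number,
MODEL blocks must agree on atom count, and writing refuses coordinates
that would not fit the fixed 8.3 field instead of truncating. First
alternate locations are kept and insertion codes are treated as distinct
residues — deterministic behaviour on real crystallographic files without
modelling crystallographic detail. Residue numbering is 1-based and
selection ranges are inclusive at both ends.

## The pipeline and its designed contrasts

`run_pipeline()` executes the full graph — ENM ensembles for a
wild-type-like and a mutant-like system, subdomain RMSD/RMSF, DCCM and its
difference, ANM and PCA modes, two-state distances with clustering and
box occupancy, EDA, ITC fits, cross-system comparison — deterministically
from one seed, writing per-stage CSVs, a JSON summary and a
self-documenting run log. The synthetic pair differs in exactly the ways
the analyses are supposed to detect: higher effective sampling temperature
(larger fluctuations), competent occupancy 0.40 vs 0.12, a discharged
reference residue in the EDA system (arginine-to-alanine-like), and Kd
55 nM vs 37 µM. A correct implementation must recover each contrast with
the right sign; identical bundles must compare to exactly zero.

Problem sizes were chosen so the whole distribution (tests plus acceptance
script) runs in a few minutes: 150,000 frames for distance statistics
(matching the combined-trajectory scale of such studies), 20,000 frames ×
20 residues for the statistical-physics consistency checks, 60–300 frames
for pipeline-level trajectory metrics, 100 fits for the noisy ITC recovery
study. Each test states its own size; enlarging them only tightens the
sampling tolerances.

## Known limitations

- Harmonic synthetic ensembles cannot probe anharmonic or activated
  dynamics; recovery tests validate estimators, not biology.
- The EDA convention (vacuum, no cutoff) is one defensible choice among
  several; absolute energies are convention-dependent even though rankings
  are robust.
- The ITC model is strictly single-site; competitive or multi-site
  binding, and baseline integration of raw power traces, are out of scope.
- mmCIF, compressed trajectory formats, symmetry expansion and
  occupancy-weighted models are not supported.
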