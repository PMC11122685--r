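# polsite

Tools for asking whether a DNA polymerase active site is catalytically
poised — and how a mutation changes the answer.

High-fidelity polymerases only catalyse phosphoryl transfer when the primer
3′-OH, the incoming dNTP's α-phosphate, the catalytic aspartates and the two
Mg²⁺ ions sit within narrow distance windows, an arrangement reached through
a collective closing of the Fingers subdomain. Mutations far from the
chemistry can kill activity by destabilising this geometry. `polsite`
implements the analysis chain used to quantify that mechanism from
conformational ensembles and binding experiments, for structural biologists
and simulators who have (or can generate) such ensembles:

- **Structure I/O** — strict multi-model PDB and XYZ trajectory reading and
  writing, YAML subdomain masks, toy force-field topologies.
- **Superposition metrics** — Kabsch fits, per-subdomain RMSD series,
  iteratively-referenced RMSF profiles and mutant-minus-WT differences,
  hinge rotation angles, atom-pair distances.
- **Correlation and modes** — dynamic cross-correlation matrices (DCCM)
  with difference maps and subdomain-block summaries; elastic-network (ANM)
  and ensemble-PCA normal modes with contribution fractions, mode overlap
  and RMSIP.
- **Competence clustering** — catalytic-distance extraction, seeded
  k-means++ clustering in the (d1, d2) plane, competence-box occupancy and
  threshold fractions. d1 is the primer O3′–Pα distance, d2 the catalytic
  aspartate–O3′ distance; the box defaults to d1 ∈ [3.0, 3.8] Å,
  d2 ∈ [2.8, 3.5] Å.
- **Energy decomposition** — residue-pairwise Coulomb + Lennard-Jones
  interaction profiles with SEM error bars and stabiliser ranking
  (k = 332.0636 kcal·Å/(mol·e²), Amber-style 1-4 scaling).
- **Binding thermodynamics** — single-site (Wiseman) isotherm simulation
  and Levenberg–Marquardt fitting, ΔG = RT·ln(Kd), fold changes and ΔΔG.
- **Synthetic data** — seeded generators for every input class (ENM
  ensembles with exactly known covariance, two-state distance trajectories
  with known occupancies, charged toy topologies, noisy isotherms), so each
  stage is testable against ground truth.
- **Pipeline** — `run_pipeline()` drives the whole graph for a WT/mutant
  pair from one config and seed, writing CSVs, a JSON summary and a run
  log; `inst/cli/polsite.R` is a thin command-line front end.

Everything user-facing takes and returns tibbles, composes with the pipe,
and has `tidy()`/`glance()`/`autoplot()` methods where a fitted object is
involved.

## Worked example

Binding thermodynamics from measured dissociation constants (55 nM
wild type, 37 µM mutant, 37 °C):

```r
library(polsite)

delta_g_from_kd(55e-9)    # -10.30 kcal/mol
delta_g_from_kd(37e-6)    # -6.29 kcal/mol
fc <- affinity_fold_change(kd_mutant = 37e-6, kd_wt = 55e-9)
#> fold = 672.7, ddG = 4.01 kcal/mol
```

The mutant binds the nucleotide ~670-fold more weakly, a ~4 kcal/mol loss —
far more than one hydrogen bond, pointing at a disrupted interaction
network rather than a single lost contact.

Competence statistics on a synthetic two-state distance trajectory
(150,000 frames, wild-type-like regime, competent state at d1 = 3.5 Å with
occupancy 0.40):

```r
wt <- gen_two_state_distances(two_state_defaults("wt"),
                              n_frames = 150000, seed = 853)
cl <- kmeans_2d(wt, k = 2, seed = 853)
box_occupancy(wt, competence_box(), cl)
#> # A tibble: 1 × 5
#>   occupancy n_inside n_frames occupancy_by_cluster clusters_inside
#>       <dbl>    <int>    <int>                <dbl> <list>
#> 1     0.399    59893   150000                0.413 <int [1]>
```

0.399 of frames fall inside the competence box (the generator truth is
0.40); counting instead by clusters-whose-centroid-is-in-the-box gives
0.413 — both counts are reported because they answer slightly different
questions. `autoplot(cl)` draws the clustered (d1, d2) scatter with the
box overlay.

Fitting a noisy synthetic isotherm generated at the published titration
geometry (19 injections of 0.4 + 18 × 2 µL, 200 µM ligand into 5 µM
complex):

```r
iso <- gen_itc_isotherm(itc_truth(kd = 55e-9, dh = -12, noise_sd = 0.05),
                        seed = 853)
fit_isotherm(iso)
#> <binding_fit> single-site isotherm fit
#>   n = 1.010, Kd = 4.97e-08 M, dH = -12.02 kcal/mol, dG = -10.365 kcal/mol
#>   c-value = 102, RSS = 0.0307
```

The fit recovers the generating parameters (n = 1, Kd = 55 nM,
ΔH = −12 kcal/mol) within the noise; `tidy()` gives the coefficient table
with standard errors, `glance()` the one-row summary, `autoplot()` the
molar-ratio plot with the fitted curve.

The full WT-vs-mutant analysis graph:

```r
res <- run_pipeline(default_pipeline_config(seed = 853), out_dir = "out")
res$summary$contrast
# occupancy difference, Kd fold change, ddG, mean |ΔRMSF|
```

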