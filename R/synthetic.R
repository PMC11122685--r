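# Seeded generators for every input class the pipeline consumes:
# elastic-network ensembles with known covariance, two-state catalytic
# distance trajectories with known occupancies, toy charged topologies, and
# noisy titration isotherms with known (n, Kd, dH). Each is a pure function
# of (parameters, seed), so downstream recovery tests have exact ground
# truth.

#' Sample a conformational ensemble from an elastic-network model
#'
#' Displacements about the reference structure are drawn from the
#' multivariate Gaussian with covariance `kB * T * H^+`, where `H` is the
#' anisotropic-network Hessian at the given cutoff and spring constant and
#' `H^+` its pseudo-inverse over the internal modes (the 6 rigid-body zero
#' modes are excluded by eigenvalue rank). The exact model covariance is
#' attached, making the ensemble a ground-truth fixture for RMSF, DCCM and
#' PCA consistency checks.
#'
#' @param reference N x 3 reference coordinates (Angstrom), N >= 3,
#'   connected at `cutoff`.
#' @param n_frames Number of frames to draw.
#' @param seed RNG seed.
#' @param cutoff Contact cutoff, Angstrom (default 15).
#' @param gamma Spring constant, kcal/mol/Angstrom^2 (default 1).
#' @param temperature Kelvin; `0` returns the reference repeated.
#' @param atoms Optional atom metadata tibble; defaults to one C-alpha per
#'   residue on chain A.
#' @return A [conf_ensemble()] with attributes `model_covariance`
#'   (3N x 3N, Angstrom^2) and `reference`.
#' @export
gen_enm_ensemble <- function(reference, n_frames, seed, cutoff = 15,
                             gamma = 1, temperature = 300, atoms = NULL) {
  ref <- as_coord_matrix(reference, "reference")
  n <- nrow(ref)
  stopifnot_scalar_num(n_frames, "n_frames", positive = TRUE)
  stopifnot_scalar_num(temperature, "temperature")
  if (temperature < 0) abort("`temperature` must be >= 0.")

  h <- anm_hessian(ref, cutoff, gamma)
  eig <- eigen(h, symmetric = TRUE)
  vals <- rev(eig$values)
  vecs <- eig$vectors[, rev(seq_len(3 * n)), drop = FALSE]
  thr <- 1e-8 * max(vals)
  if (sum(vals < thr) > 6L) {
    comp <- enm_components(ref, cutoff)
    abort(sprintf(
      "Reference structure disconnected at cutoff %.1f A (%d components, sizes %s).",
      cutoff, max(comp), paste(tabulate(comp), collapse = ", ")))
  }
  keep <- 7:(3 * n)
  lam <- vals[keep]
  v <- vecs[, keep, drop = FALSE]
  kbt <- .kB * temperature
  cov_model <- v %*% (t(v) * (kbt / lam))

  coords <- array(0, dim = c(n_frames, n, 3L))
  if (temperature > 0) {
    disp <- with_seed(seed, {
      z <- matrix(rnorm(n_frames * length(lam)), n_frames)
      z %*% (t(v) * sqrt(kbt / lam))
    })
  } else {
    disp <- matrix(0, n_frames, 3 * n)
  }
  for (f in seq_len(n_frames)) {
    coords[f, , ] <- ref + matrix(disp[f, ], ncol = 3L, byrow = TRUE)
  }
  if (is.null(atoms)) {
    atoms <- tibble(serial = seq_len(n), name = "CA", resname = "ALA",
                    chain = "A", resno = seq_len(n), icode = "",
                    element = "C")
  }
  ens <- conf_ensemble(atoms, coords)
  attr(ens, "model_covariance") <- cov_model
  attr(ens, "reference") <- ref
  ens
}

#' Model RMSF implied by an ENM ensemble's exact covariance
#'
#' Square root of the trace of each atom's 3 x 3 covariance block; the
#' closed-form value that sampled RMSF profiles converge to.
#'
#' @param ensemble An ensemble from [gen_enm_ensemble()].
#' @return Numeric vector, one RMSF (Angstrom) per atom.
#' @export
enm_model_rmsf <- function(ensemble) {
  cv <- attr(ensemble, "model_covariance")
  if (is.null(cv)) abort("Ensemble carries no model covariance.")
  n <- n_atoms(ensemble)
  vapply(seq_len(n), function(i) {
    ii <- (3 * i - 2):(3 * i)
    sqrt(sum(diag(cv[ii, ii])))
  }, numeric(1))
}

#' Two-state catalytic-distance model
#'
#' Parameters of a bivariate two-state mixture in (d1, d2) space, where d1
#' is the primer O3' to dNTP alpha-phosphate distance and d2 the catalytic
#' aspartate to primer O3' distance. State A is the catalytically competent
#' state, state B the incompetent one. Defaults encode the wild-type-like
#' and mutant-like regimes: the competent state sits at d1 = 3.5 Angstrom
#' and the incompetent state at d1 = 4.3 Angstrom, with competent occupancy
#' 0.40 (wild type) or 0.12 (mutant).
#'
#' @param p_competent Occupancy of state A, in `[0, 1]`.
#' @param mean_a,mean_b Length-2 state means `(d1, d2)`, Angstrom.
#' @param cov_a,cov_b 2 x 2 state covariances (symmetric positive definite),
#'   Angstrom^2.
#' @return A `two_state_model` parameter list.
#' @export
two_state_model <- function(p_competent,
                            mean_a = c(3.5, 3.15),
                            mean_b = c(4.3, 4.0),
                            cov_a = matrix(c(0.01, 0.003, 0.003, 0.01), 2),
                            cov_b = matrix(c(0.0625, 0.019, 0.019, 0.0625), 2)) {
  if (p_competent < 0 || p_competent > 1) {
    abort("`p_competent` must lie in [0, 1].")
  }
  check_spd <- function(s, nm) {
    if (!isTRUE(all.equal(s, t(s))) || any(eigen(s, symmetric = TRUE,
                                                 only.values = TRUE)$values <= 0)) {
      abort(sprintf("`%s` must be symmetric positive definite.", nm))
    }
  }
  check_spd(cov_a, "cov_a"); check_spd(cov_b, "cov_b")
  structure(list(p_competent = p_competent, mean_a = mean_a, mean_b = mean_b,
                 cov_a = cov_a, cov_b = cov_b),
            class = "two_state_model")
}

#' @rdname two_state_model
#' @param system `"wt"` or `"mutant"`: the two default parameterisations.
#' @export
two_state_defaults <- function(system = c("wt", "mutant")) {
  system <- match.arg(system)
  two_state_model(p_competent = if (system == "wt") 0.40 else 0.12)
}

#' Draw a two-state (d1, d2) distance trajectory
#'
#' Each frame is drawn from state A with probability `p_competent`, else
#' from state B, as a bivariate Gaussian; draws with a non-positive
#' coordinate are rejected and resampled (distances are positive).
#'
#' @param model A [two_state_model()].
#' @param n_frames Number of frames.
#' @param seed RNG seed.
#' @return Tibble `frame`, `state` (`"A"`/`"B"`), `d1`, `d2` (Angstrom).
#' @export
gen_two_state_distances <- function(model, n_frames, seed) {
  stopifnot(inherits(model, "two_state_model"))
  stopifnot_scalar_num(n_frames, "n_frames", positive = TRUE)
  with_seed(seed, {
    st <- rbinom(n_frames, 1L, model$p_competent) == 1L
    draw <- function(k, mu, sg) {
      if (k == 0L) return(matrix(numeric(0), 0, 2))
      x <- MASS::mvrnorm(k, mu, sg)
      x <- matrix(x, ncol = 2)
      bad <- which(x[, 1] <= 0 | x[, 2] <= 0)
      while (length(bad) > 0L) {
        x[bad, ] <- matrix(MASS::mvrnorm(length(bad), mu, sg), ncol = 2)
        bad <- which(x[, 1] <= 0 | x[, 2] <= 0)
      }
      x
    }
    out <- matrix(NA_real_, n_frames, 2)
    out[st, ] <- draw(sum(st), model$mean_a, model$cov_a)
    out[!st, ] <- draw(sum(!st), model$mean_b, model$cov_b)
    tibble(frame = seq_len(n_frames), state = ifelse(st, "A", "B"),
           d1 = out[, 1], d2 = out[, 2])
  })
}

#' Generate a toy charged topology with coordinates
#'
#' Builds a minimal system of point-charge residues for exercising the
#' energy-decomposition module: each residue gets `n_atoms` atoms placed
#' around its centre, its net charge split evenly across them, and
#' LJ parameters jittered around physically plausible values. Bonds chain
#' the atoms within each residue.
#'
#' @param residues Tibble/data frame with one row per residue: columns
#'   `resname`, `net_charge`, `n_atoms`, `x`, `y`, `z` (residue centre,
#'   Angstrom).
#' @param seed RNG seed (placement jitter and LJ parameters).
#' @return List with `topology` ([toy_topology()]) and `coords` (N x 3).
#' @export
gen_toy_topology <- function(residues, seed) {
  residues <- as_tibble(residues)
  need <- c("resname", "net_charge", "n_atoms", "x", "y", "z")
  if (!all(need %in% names(residues))) {
    abort(sprintf("`residues` needs columns: %s.", paste(need, collapse = ", ")))
  }
  if (any(residues$n_atoms < 1L)) abort("Each residue needs >= 1 atom.")
  with_seed(seed, {
    offsets <- rbind(c(0, 0, 0), c(0.9, 0, 0), c(0, 0.9, 0), c(0, 0, 0.9),
                     c(-0.9, 0, 0), c(0, -0.9, 0), c(0, 0, -0.9),
                     c(0.7, 0.7, 0))
    coords <- NULL; charge <- NULL; sigma <- NULL; eps <- NULL
    resid <- NULL; bonds <- NULL
    serial <- 0L
    for (r in seq_len(nrow(residues))) {
      na <- residues$n_atoms[r]
      if (na > nrow(offsets)) abort("At most 8 atoms per toy residue.")
      cen <- as.numeric(residues[r, c("x", "y", "z")])
      jit <- matrix(rnorm(3 * na, sd = 0.05), na, 3)
      coords <- rbind(coords, sweep(offsets[seq_len(na), , drop = FALSE] + jit,
                                    2, cen, `+`))
      charge <- c(charge, rep(residues$net_charge[r] / na, na))
      sigma <- c(sigma, runif(na, 3.0, 3.6))
      eps <- c(eps, runif(na, 0.05, 0.20))
      resid <- c(resid, rep(r, na))
      if (na > 1L) {
        bonds <- rbind(bonds, cbind(serial + seq_len(na - 1L),
                                    serial + seq_len(na - 1L) + 1L))
      }
      serial <- serial + na
    }
    if (is.null(bonds)) bonds <- matrix(integer(0), ncol = 2L)
    topo <- toy_topology(charge, sigma, eps, resid, bonds,
                         resname = residues$resname)
    if (abs(sum(topo$charge) - sum(residues$net_charge)) > 1e-9) {
      abort("Internal error: charges do not sum to the specified totals.")
    }
    list(topology = topo, coords = coords)
  })
}

#' Default toy system for energy-decomposition demonstrations
#'
#' A +1 arginine-like reference residue in close contact (~3 Angstrom) with
#' a -4 dCTP-like ligand, surrounded by more distant spectator residues of
#' small mixed charge; the regime in which the reference residue dominates
#' the ligand's stabilisation.
#'
#' @return A residue-spec tibble for [gen_toy_topology()].
#' @export
eda_demo_residues <- function() {
  tibble(
    resname = c("ARG", "DCP", "ASP", "LYS", "GLY", "SER"),
    net_charge = c(+1, -4, -1, +1, 0, 0),
    n_atoms = c(4L, 8L, 4L, 4L, 3L, 3L),
    x = c(0, 4.8, 8, -8, 10, -10),
    y = c(0, 1.2, 6, 7, -8, -6),
    z = c(0, 0.5, -5, 5, 6, -7)
  )
}

#' Ground-truth parameters for a synthetic titration isotherm
#'
#' Defaults follow the printed titration geometry for this system: 19
#' injections (0.4 uL then 18 x 2 uL) of 200 uM ligand into 5 uM
#' macromolecule at 37 C.
#'
#' @param n Stoichiometry (sites per macromolecule).
#' @param kd Dissociation constant, molar.
#' @param dh Binding enthalpy, kcal/mol.
#' @param cell_conc Cell macromolecule concentration, molar.
#' @param syringe_conc Syringe ligand concentration, molar.
#' @param injection_vol Per-injection volumes, uL.
#' @param cell_volume Cell volume, uL.
#' @param noise_sd Gaussian heat noise, ucal.
#' @param temperature Kelvin.
#' @return An `itc_truth` parameter list.
#' @export
itc_truth <- function(n = 1, kd = 55e-9, dh = -10,
                      cell_conc = 5e-6, syringe_conc = 200e-6,
                      injection_vol = c(0.4, rep(2, 18)),
                      cell_volume = 200, noise_sd = 0,
                      temperature = 310.15) {
  stopifnot_scalar_num(kd, "kd", positive = TRUE)
  stopifnot_scalar_num(cell_conc, "cell_conc", positive = TRUE)
  stopifnot_scalar_num(syringe_conc, "syringe_conc", positive = TRUE)
  stopifnot_scalar_num(cell_volume, "cell_volume", positive = TRUE)
  if (any(injection_vol <= 0)) abort("Injection volumes must be > 0.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  structure(list(n = n, kd = kd, dh = dh, cell_conc = cell_conc,
                 syringe_conc = syringe_conc, injection_vol = injection_vol,
                 cell_volume = cell_volume, noise_sd = noise_sd,
                 temperature = temperature),
            class = "itc_truth")
}

#' Generate a noisy single-site titration isotherm
#'
#' Per-injection heats from the single-site (Wiseman) model under perfusion
#' dilution, plus additive Gaussian noise. A syringe concentration of at
#' most 5x the cell concentration triggers a warning (the resulting fit is
#' poorly determined), not an error.
#'
#' @param truth An [itc_truth()].
#' @param seed RNG seed (ignored when `noise_sd = 0`).
#' @return A [binding_isotherm()].
#' @export
gen_itc_isotherm <- function(truth, seed = 1L) {
  stopifnot(inherits(truth, "itc_truth"))
  if (truth$syringe_conc <= 5 * truth$cell_conc) {
    warn("Syringe concentration <= 5x cell concentration: fit will be poorly determined.")
  }
  q <- wiseman_heats(truth$n, truth$kd, truth$dh, truth$injection_vol,
                     truth$cell_volume, truth$cell_conc, truth$syringe_conc)
  if (truth$noise_sd > 0) {
    q <- q + with_seed(seed, rnorm(length(q), sd = truth$noise_sd))
  }
  binding_isotherm(injection_vol = truth$injection_vol,
                   cell_volume = truth$cell_volume,
                   cell_conc = truth$cell_conc,
                   syringe_conc = truth$syringe_conc,
                   heats = q, temperature = truth$temperature)
}
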