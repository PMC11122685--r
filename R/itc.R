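# Single-site ITC: the Wiseman isotherm model under perfusion dilution,
# nonlinear least-squares fitting, and the thermodynamic conversions
# (delta G from Kd, fold changes, ddG).

#' Standard-state binding free energy from a dissociation constant
#'
#' `dG = R T ln(Kd / 1 M)` with `R = 1.98720425e-3` kcal/(mol K); negative
#' for sub-molar Kd. The 1 M standard state is implicit.
#'
#' @param kd Dissociation constant(s), molar, > 0.
#' @param temperature Kelvin, > 0 (default 310.15, i.e. 37 C).
#' @return Free energy in kcal/mol.
#' @examples
#' delta_g_from_kd(55e-9)    # tight binder, about -10.3 kcal/mol
#' @export
delta_g_from_kd <- function(kd, temperature = 310.15) {
  if (any(!is.finite(kd)) || any(kd <= 0)) abort("`kd` must be > 0 (molar).")
  stopifnot_scalar_num(temperature, "temperature", positive = TRUE)
  .kB * temperature * log(kd)
}

#' Affinity fold change and binding free-energy difference
#'
#' @param kd_mutant,kd_wt Dissociation constants, molar.
#' @param temperature Kelvin.
#' @return List with `fold` (`kd_mutant / kd_wt`) and `ddg`
#'   (kcal/mol, positive when the mutant binds more weakly).
#' @export
affinity_fold_change <- function(kd_mutant, kd_wt, temperature = 310.15) {
  stopifnot_scalar_num(kd_mutant, "kd_mutant", positive = TRUE)
  stopifnot_scalar_num(kd_wt, "kd_wt", positive = TRUE)
  list(fold = kd_mutant / kd_wt,
       ddg = delta_g_from_kd(kd_mutant, temperature) -
         delta_g_from_kd(kd_wt, temperature))
}

#' Titration isotherm container
#'
#' @param injection_vol Per-injection volumes, uL.
#' @param cell_volume Cell volume, uL.
#' @param cell_conc Initial cell macromolecule concentration, molar.
#' @param syringe_conc Syringe ligand concentration, molar.
#' @param heats Per-injection integrated heats, ucal.
#' @param temperature Kelvin.
#' @return A `binding_isotherm`.
#' @export
binding_isotherm <- function(injection_vol, cell_volume, cell_conc,
                             syringe_conc, heats, temperature = 310.15) {
  if (any(injection_vol <= 0) || cell_volume <= 0 || cell_conc <= 0 ||
      syringe_conc <= 0) {
    abort("Volumes and concentrations must be > 0.")
  }
  if (length(heats) != length(injection_vol)) {
    abort("`heats` must have one value per injection.")
  }
  if (any(!is.finite(heats))) abort("Heats must be finite.")
  structure(list(injection_vol = as.numeric(injection_vol),
                 cell_volume = cell_volume, cell_conc = cell_conc,
                 syringe_conc = syringe_conc, heats = as.numeric(heats),
                 temperature = temperature),
            class = "binding_isotherm")
}

#' @export
print.binding_isotherm <- function(x, ...) {
  cat(sprintf(
    "<binding_isotherm> %d injections; cell %.2g M in %.0f uL; syringe %.2g M; T = %.2f K\n",
    length(x$heats), x$cell_conc, x$cell_volume, x$syringe_conc,
    x$temperature))
  invisible(x)
}

#' Tidy an isotherm into an injection table
#'
#' @param x A `binding_isotherm`.
#' @param ... Unused.
#' @return Tibble `injection`, `volume_uL`, `molar_ratio`, `heat_ucal`.
#' @method tidy binding_isotherm
#' @export
tidy.binding_isotherm <- function(x, ...) {
  conc <- itc_concentrations(x$injection_vol, x$cell_volume, x$cell_conc,
                             x$syringe_conc)
  tibble(injection = seq_along(x$heats), volume_uL = x$injection_vol,
         molar_ratio = conc$xt / conc$mt, heat_ucal = x$heats)
}

# Cell concentrations after each injection under perfusion displacement:
# a fraction v_i/V0 of the (well-mixed) cell contents is expelled per
# injection; the cell volume stays constant.
itc_concentrations <- function(injection_vol, cell_volume, cell_conc,
                               syringe_conc) {
  k <- length(injection_vol)
  mt <- numeric(k); xt <- numeric(k)
  m <- cell_conc; x <- 0
  for (i in seq_len(k)) {
    f <- injection_vol[i] / cell_volume
    if (f >= 1) abort("Injection volume must be smaller than the cell volume.")
    m <- m * (1 - f)
    x <- x * (1 - f) + syringe_conc * f
    mt[i] <- m; xt[i] <- x
  }
  list(mt = mt, xt = xt)
}

#' Predicted per-injection heats of the single-site Wiseman model
#'
#' After each injection, the bound fraction solves the one-site quadratic
#' `theta^2 - theta (1 + Xt/(n Mt) + Kd/(n Mt)) + Xt/(n Mt) = 0` (smaller
#' root). The heat of injection i is the enthalpy of newly formed complex in
#' the cell, `dH * V0 * (n theta_i Mt_i - n theta_{i-1} Mt_{i-1} (1 - v_i/V0))`,
#' i.e. complex expelled by perfusion displacement does not absorb heat on
#' later injections. Concentrations are diluted per injection as in
#' [itc_concentrations()].
#'
#' @param n Stoichiometry.
#' @param kd Dissociation constant, molar.
#' @param dh Binding enthalpy, kcal/mol.
#' @param injection_vol Injection volumes, uL.
#' @param cell_volume Cell volume, uL.
#' @param cell_conc Initial macromolecule concentration, molar.
#' @param syringe_conc Syringe ligand concentration, molar.
#' @return Per-injection heats, ucal.
#' @export
wiseman_heats <- function(n, kd, dh, injection_vol, cell_volume, cell_conc,
                          syringe_conc) {
  conc <- itc_concentrations(injection_vol, cell_volume, cell_conc,
                             syringe_conc)
  k <- length(injection_vol)
  v0_l <- cell_volume * 1e-6
  bound_prev <- 0    # molar concentration of complex in the cell
  q <- numeric(k)
  for (i in seq_len(k)) {
    mt <- conc$mt[i]; xt <- conc$xt[i]
    b <- 1 + xt / (n * mt) + kd / (n * mt)
    disc <- b^2 - 4 * xt / (n * mt)
    if (disc < 0) abort("Internal error: negative discriminant in binding quadratic.")
    theta <- (b - sqrt(disc)) / 2
    bound <- n * theta * mt
    carried <- bound_prev * (1 - injection_vol[i] / cell_volume)
    q[i] <- dh * v0_l * (bound - carried) * 1e9   # kcal -> ucal
    bound_prev <- bound
  }
  q
}

#' Fit the single-site model to a titration isotherm
#'
#' Nonlinear least squares (Levenberg-Marquardt) of [wiseman_heats()]
#' against the measured heats, with the first (priming) injection
#' down-weighted to zero as is standard practice. Kd is fitted on the log
#' scale to stay positive. Standard errors come from the Jacobian at the
#' optimum; `dg` is computed from the fitted Kd at the isotherm temperature.
#' A c-value (`n * Mt / Kd`) outside `[1, 1000]` attaches a warning to the
#' fit, as does an essentially flat isotherm (Kd unidentifiable).
#'
#' In the low-c regime the stoichiometry is practically unidentifiable and
#' trades off against the enthalpy; `fix_n = TRUE` holds it at its starting
#' value (default 1), the standard practice for shallow isotherms.
#'
#' @param isotherm A [binding_isotherm()].
#' @param start Optional named list of starting values (`n`, `kd`, `dh`).
#' @param fix_n Hold the stoichiometry fixed instead of fitting it.
#' @return A `binding_fit`: `n`, `kd` (M), `dh` (kcal/mol), `dg` (kcal/mol),
#'   `rss`, `se` (named vector), `c_value`, `warnings`, plus the data and
#'   fitted heats. Has [tidy()], [glance()] and [autoplot()] methods.
#' @export
fit_isotherm <- function(isotherm, start = NULL, fix_n = FALSE) {
  stopifnot(inherits(isotherm, "binding_isotherm"))
  q <- isotherm$heats
  if (length(q) < 6L) abort("Need at least 6 injections to fit.")
  w <- c(0, rep(1, length(q) - 1L))   # drop the priming injection

  flat <- max(abs(q[-1])) < 1e-9
  if (flat) {
    fitq <- rep(0, length(q))
    return(structure(
      list(n = 1, kd = NA_real_, dh = 0,
           dg = NA_real_, rss = sum(w * q^2),
           se = c(n = NA_real_, kd = NA_real_, dh = NA_real_),
           c_value = NA_real_,
           warnings = "All heats are ~0: dH ~ 0 and Kd is unidentifiable.",
           temperature = isotherm$temperature,
           fitted = fitq, isotherm = isotherm),
      class = "binding_fit"))
  }

  if (is.null(start)) {
    # crude dH guess: total heat / total macromolecule enthalpy capacity
    tot <- sum(q)
    cap <- isotherm$cell_conc * isotherm$cell_volume * 1e-6 * 1e9
    start <- list(n = 1, kd = isotherm$cell_conc / 5, dh = tot / cap)
    if (abs(start$dh) < 1e-6) start$dh <- sign(tot + 1e-30)
  }

  n_fixed <- start$n
  resid_fn <- function(p) {
    n_cur <- if (fix_n) n_fixed else p[["n"]]
    pred <- wiseman_heats(n_cur, exp(p[["log_kd"]]), p[["dh"]],
                          isotherm$injection_vol, isotherm$cell_volume,
                          isotherm$cell_conc, isotherm$syringe_conc)
    sqrt(w) * (q - pred)
  }
  p0 <- if (fix_n) {
    c(log_kd = log(start$kd), dh = start$dh)
  } else {
    c(n = start$n, log_kd = log(start$kd), dh = start$dh)
  }
  fit <- minpack.lm::nls.lm(
    par = p0, fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 1000, maxfev = 5000,
                                         ftol = 1e-14, ptol = 1e-14))
  if (fit$info %in% c(0, 5, 9)) {
    abort(sprintf(
      "Isotherm fit did not converge (%s). Last iterate: n=%.3g kd=%.3g dh=%.3g.",
      fit$message, if (fix_n) n_fixed else fit$par[["n"]],
      exp(fit$par[["log_kd"]]), fit$par[["dh"]]))
  }
  p <- fit$par
  n_hat <- if (fix_n) n_fixed else p[["n"]]
  kd_hat <- exp(p[["log_kd"]]); dh_hat <- p[["dh"]]
  pred <- wiseman_heats(n_hat, kd_hat, dh_hat, isotherm$injection_vol,
                        isotherm$cell_volume, isotherm$cell_conc,
                        isotherm$syringe_conc)
  rss <- sum(w * (q - pred)^2)

  # delta-method SEs from the J'J at the optimum (log-kd back-transformed)
  npar <- length(p0)
  se_par <- rep(NA_real_, npar)
  dof <- sum(w > 0) - npar
  if (dof > 0) {
    cv <- try(solve(fit$hessian) * rss / dof, silent = TRUE)
    if (!inherits(cv, "try-error")) se_par <- sqrt(pmax(diag(cv), 0))
  }
  if (fix_n) {
    se <- c(n = NA_real_, kd = se_par[1] * kd_hat, dh = se_par[2])
  } else {
    se <- c(n = se_par[1], kd = se_par[2] * kd_hat, dh = se_par[3])
  }

  warnings <- character(0)
  c_value <- n_hat * isotherm$cell_conc / kd_hat
  if (c_value < 1 || c_value > 1000) {
    warnings <- c(warnings, sprintf(
      "c-value %.3g outside [1, 1000]: parameters may be poorly determined.",
      c_value))
  }
  structure(
    list(n = n_hat, kd = kd_hat, dh = dh_hat,
         dg = delta_g_from_kd(kd_hat, isotherm$temperature),
         rss = rss, se = se, c_value = c_value, warnings = warnings,
         temperature = isotherm$temperature,
         fitted = pred, isotherm = isotherm),
    class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat("<binding_fit> single-site isotherm fit\n")
  if (is.na(x$kd)) {
    cat("  Kd unidentifiable (flat isotherm); dH ~ 0\n")
  } else {
    cat(sprintf("  n = %.3f, Kd = %.3g M, dH = %.2f kcal/mol, dG = %.3f kcal/mol\n",
                x$n, x$kd, x$dh, x$dg))
    cat(sprintf("  c-value = %.3g, RSS = %.3g\n", x$c_value, x$rss))
  }
  for (wn in x$warnings) cat("  warning:", wn, "\n")
  invisible(x)
}

#' Tidy / glance methods for single-site binding fits
#'
#' @param x A `binding_fit`.
#' @param ... Unused.
#' @return `tidy()`: tibble `term`, `estimate`, `std.error`. `glance()`:
#'   one-row tibble with `kd`, `dg`, `n`, `dh`, `rss`, `c_value`,
#'   `n_injections`, `temperature`.
#' @method tidy binding_fit
#' @export
tidy.binding_fit <- function(x, ...) {
  tibble(term = c("n", "kd", "dh"),
         estimate = c(x$n, x$kd, x$dh),
         std.error = unname(x$se))
}

#' @rdname tidy.binding_fit
#' @method glance binding_fit
#' @export
glance.binding_fit <- function(x, ...) {
  tibble(kd = x$kd, dg = x$dg, n = x$n, dh = x$dh, rss = x$rss,
         c_value = x$c_value,
         n_injections = length(x$isotherm$heats),
         temperature = x$temperature)
}
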