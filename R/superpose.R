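# Least-squares superposition and the trajectory metrics built on it:
# per-subdomain RMSD series, iteratively-aligned RMSF profiles, RMSF
# differences, hinge rotation angles, and atom-pair distances.

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimising the (weighted) RMSD
#' between two paired point sets. Reflections are excluded by the usual sign
#' correction on the smallest singular value, so `det(rotation) = +1` always.
#' Near-degenerate (collinear/coplanar-to-machine-precision) inputs are
#' flagged but still return a proper rotation.
#'
#' @param mobile,target N x 3 coordinate matrices (N >= 3), paired by row.
#' @param weights Optional non-negative per-atom weights (not all zero).
#' @return A `superposition`: list with `rotation` (3 x 3), `translation`
#'   (length 3), `rmsd` (Angstrom, weighted), `degenerate` flag. Apply with
#'   [apply_superposition()]: `aligned = mobile %*% rotation + translation`.
#' @examples
#' a <- matrix(rnorm(30), 10, 3)
#' kabsch(a, a)$rmsd
#' @export
kabsch <- function(mobile, target, weights = NULL) {
  mobile <- as_coord_matrix(mobile, "mobile")
  target <- as_coord_matrix(target, "target")
  n <- nrow(mobile)
  if (n < 3L) abort("Superposition needs at least 3 points.")
  if (nrow(target) != n) abort("`mobile` and `target` must have equal rows.")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) <= 0) {
    abort("`weights` must be non-negative with positive sum.")
  }
  w <- weights / sum(weights)

  cm_m <- colSums(mobile * w)
  cm_t <- colSums(target * w)
  a <- sweep(mobile, 2, cm_m)
  b <- sweep(target, 2, cm_t)
  h <- t(a * w) %*% b
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  s <- diag(c(1, 1, d))
  rot <- sv$u %*% s %*% t(sv$v)
  degenerate <- sv$d[2] <= 1e-10 * max(sv$d[1], .Machine$double.eps)

  aligned <- a %*% rot
  rmsd <- sqrt(sum(w * rowSums((aligned - b)^2)))
  structure(
    list(rotation = rot, translation = as.numeric(cm_t - cm_m %*% rot),
         rmsd = rmsd, degenerate = degenerate),
    class = "superposition"
  )
}

#' @rdname kabsch
#' @param coords Coordinates to transform (N x 3).
#' @param sp A `superposition` from [kabsch()].
#' @export
apply_superposition <- function(coords, sp) {
  stopifnot(inherits(sp, "superposition"))
  sweep(as_coord_matrix(coords) %*% sp$rotation, 2, sp$translation, `+`)
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd = %.4f A%s\n", x$rmsd,
              if (x$degenerate) " (degenerate point set)" else ""))
  invisible(x)
}

# RMSD between paired coordinate sets without fitting.
plain_rmsd <- function(a, b) {
  sqrt(mean(rowSums((a - b)^2)))
}

#' Per-frame, per-subdomain RMSD series
#'
#' Each frame is superposed onto the reference using the representative
#' atoms of `fit_mask` (no per-subdomain refit); the RMSD is then reported
#' for the representative atoms of each mask in `calc_masks`. This mirrors
#' the usual fit-on-core, measure-everywhere trajectory convention.
#'
#' @param ensemble A [conf_ensemble()].
#' @param reference Reference coordinates: an N x 3 matrix over the full
#'   atom set, a single-frame ensemble, or a frame index into `ensemble`
#'   (default 1).
#' @param fit_mask Mask (or indices) used for the superposition.
#' @param calc_masks Named list of masks to report RMSD for; a single mask is
#'   accepted.
#' @return Tibble with columns `frame`, `subdomain`, `rmsd` (Angstrom).
#' @export
rmsd_series <- function(ensemble, reference = 1L, fit_mask,
                        calc_masks = NULL) {
  stopifnot(inherits(ensemble, "conf_ensemble"))
  ref <- if (is.numeric(reference) && length(reference) == 1L) {
    frame_coords(ensemble, as.integer(reference))
  } else {
    as_coord_matrix(reference, "reference")
  }
  if (nrow(ref) != n_atoms(ensemble)) {
    abort("`reference` must cover the full atom set of the ensemble.")
  }
  if (is.null(calc_masks)) calc_masks <- list(all = fit_mask)
  if (inherits(calc_masks, "subdomain_mask")) {
    calc_masks <- setNames(list(calc_masks), calc_masks$name)
  }
  if (is.null(names(calc_masks))) {
    names(calc_masks) <- vapply(calc_masks, function(m) {
      if (inherits(m, "subdomain_mask")) m$name else "mask"
    }, character(1))
  }
  fit_idx <- representative_atoms(ensemble, fit_mask)
  if (length(fit_idx) == 0L) abort("Empty fit mask.")
  calc_idx <- lapply(calc_masks, function(m) {
    ci <- representative_atoms(ensemble, m)
    if (length(ci) == 0L) abort("Empty calc mask.")
    ci
  })

  out <- vector("list", n_frames(ensemble))
  for (f in seq_len(n_frames(ensemble))) {
    m <- frame_coords(ensemble, f)
    sp <- kabsch(m[fit_idx, , drop = FALSE], ref[fit_idx, , drop = FALSE])
    aligned <- apply_superposition(m, sp)
    out[[f]] <- tibble(
      frame = f,
      subdomain = names(calc_idx),
      rmsd = unname(vapply(calc_idx, function(ci) {
        plain_rmsd(aligned[ci, , drop = FALSE], ref[ci, , drop = FALSE])
      }, numeric(1)))
    )
  }
  dplyr::bind_rows(out)
}

# Iteratively superpose all frames onto their mean structure (fit on the
# representative atoms of fit_mask) until the mean moves < tol. Returns the
# aligned F x N x 3 array with the converged mean as attribute.
align_to_mean <- function(ensemble, fit_mask = NULL, tol = 1e-6,
                          max_iter = 100L) {
  fit_idx <- representative_atoms(ensemble, fit_mask)
  coords <- ensemble$coords
  nf <- dim(coords)[1]
  mean_s <- frame_coords(ensemble, 1L)
  for (it in seq_len(max_iter)) {
    for (f in seq_len(nf)) {
      m <- coords[f, , ]
      sp <- kabsch(m[fit_idx, , drop = FALSE], mean_s[fit_idx, , drop = FALSE])
      coords[f, , ] <- apply_superposition(m, sp)
    }
    new_mean <- apply(coords, c(2, 3), mean)
    shift <- plain_rmsd(new_mean, mean_s)
    mean_s <- new_mean
    if (shift < tol) {
      attr(coords, "mean_structure") <- mean_s
      attr(coords, "iterations") <- it
      return(coords)
    }
  }
  abort(sprintf(
    "Mean-structure alignment did not converge in %d iterations (last shift %.2e A).",
    max_iter, shift))
}

#' Per-residue RMSF profile
#'
#' Frames are iteratively aligned to their mean structure (fitting on the
#' representative atoms of `fit_mask`) until the mean structure moves by less
#' than `tol`; the RMSF of each residue's representative atom (C-alpha /
#' C1') about its mean position is then reported.
#'
#' @inheritParams rmsd_series
#' @param calc_mask Mask over which the profile is reported (default: all).
#' @param tol Convergence threshold on the mean-structure shift (Angstrom).
#' @param max_iter Maximum alignment iterations.
#' @return Tibble with columns `chain`, `resno`, `atom`, `rmsf` (Angstrom).
#' @export
rmsf_profile <- function(ensemble, fit_mask = NULL, calc_mask = NULL,
                         tol = 1e-6, max_iter = 100L) {
  stopifnot(inherits(ensemble, "conf_ensemble"))
  if (n_frames(ensemble) < 2L) abort("RMSF needs at least 2 frames.")
  aligned <- align_to_mean(ensemble, fit_mask, tol, max_iter)
  mean_s <- attr(aligned, "mean_structure")
  idx <- representative_atoms(ensemble, calc_mask)
  at <- ensemble$atoms[idx, , drop = FALSE]
  rmsf <- vapply(idx, function(i) {
    d <- sweep(aligned[, i, , drop = TRUE], 2, mean_s[i, ])
    sqrt(mean(rowSums(d^2)))
  }, numeric(1))
  tibble(chain = at$chain, resno = at$resno, atom = trimws(at$name),
         rmsf = rmsf)
}

#' Difference between two RMSF profiles (a - b)
#'
#' Profiles are joined on `(chain, resno)`; residues present in only one
#' profile are dropped from the difference and reported in the
#' `"missing"` attribute.
#'
#' @param a,b RMSF profiles from [rmsf_profile()].
#' @return Tibble `chain`, `resno`, `rmsf_a`, `rmsf_b`, `delta_rmsf`.
#' @export
delta_rmsf <- function(a, b) {
  need <- c("chain", "resno", "rmsf")
  if (!all(need %in% names(a)) || !all(need %in% names(b))) {
    abort("Inputs must be RMSF profiles with chain/resno/rmsf columns.")
  }
  j <- dplyr::inner_join(
    dplyr::select(a, "chain", "resno", rmsf_a = "rmsf"),
    dplyr::select(b, "chain", "resno", rmsf_b = "rmsf"),
    by = c("chain", "resno")
  )
  if (nrow(j) == 0L) abort("RMSF profiles share no residues.")
  miss_a <- dplyr::anti_join(a, b, by = c("chain", "resno"))
  miss_b <- dplyr::anti_join(b, a, by = c("chain", "resno"))
  out <- dplyr::mutate(j, delta_rmsf = .data$rmsf_a - .data$rmsf_b)
  attr(out, "missing") <- list(only_in_a = miss_a, only_in_b = miss_b)
  out
}

#' Hinge rotation angle of a subdomain between two conformations
#'
#' The two conformations are first superposed on `fit_mask` (typically the
#' Palm core); a second Kabsch fit restricted to `domain_mask` then yields
#' the residual rotation `R` of the subdomain, reported as the unsigned
#' geodesic angle `acos((tr(R) - 1) / 2)` in degrees. If `toward` (an
#' active-site reference point, length-3) is given, the sign of the
#' projection of the domain-centroid displacement onto the direction from
#' the domain centroid to that point is reported separately as `direction`
#' (+1 toward, -1 away).
#'
#' @param conf_a,conf_b Single conformations (N x 3 matrices or one-frame
#'   ensembles) over the same atom set.
#' @param fit_mask Mask for the global superposition.
#' @param domain_mask Mask of the rotating subdomain (>= 3 atoms).
#' @param toward Optional length-3 reference point (Angstrom).
#' @return List with `angle_deg` in `[0, 180]`, `direction` (+1/-1/NA), and
#'   the domain-fit `rmsd`.
#' @export
domain_rotation_angle <- function(conf_a, conf_b, fit_mask, domain_mask,
                                  toward = NULL) {
  a <- as_coord_matrix(conf_a, "conf_a")
  b <- as_coord_matrix(conf_b, "conf_b")
  if (!all(dim(a) == dim(b))) abort("Conformations must share an atom set.")
  fit_idx <- mask_indices(fit_mask)
  dom_idx <- mask_indices(domain_mask)
  if (length(dom_idx) < 3L) abort("Domain mask needs at least 3 atoms.")

  sp_global <- kabsch(b[fit_idx, , drop = FALSE], a[fit_idx, , drop = FALSE])
  b_al <- apply_superposition(b, sp_global)
  sp_dom <- kabsch(a[dom_idx, , drop = FALSE], b_al[dom_idx, , drop = FALSE])
  tr <- sum(diag(sp_dom$rotation))
  angle <- acos(max(-1, min(1, (tr - 1) / 2))) * 180 / pi

  direction <- NA_real_
  if (!is.null(toward)) {
    cen_a <- colMeans(a[dom_idx, , drop = FALSE])
    cen_b <- colMeans(b_al[dom_idx, , drop = FALSE])
    to_site <- toward - cen_a
    nrm <- sqrt(sum(to_site^2))
    if (nrm > 0) direction <- sign(sum((cen_b - cen_a) * to_site / nrm))
  }
  list(angle_deg = angle, direction = direction, rmsd = sp_dom$rmsd)
}

# Parse an atom spec: either list(chain=, resno=, name=) or "chain:resno:name"
# (chain optional: "resno:name" or "chain:resno:name").
parse_atom_spec <- function(spec) {
  if (is.list(spec)) return(spec)
  parts <- strsplit(as.character(spec), ":", fixed = TRUE)[[1]]
  if (length(parts) == 3L) {
    list(chain = parts[1], resno = as.integer(parts[2]), name = parts[3])
  } else if (length(parts) == 2L) {
    list(chain = NULL, resno = as.integer(parts[1]), name = parts[2])
  } else {
    abort(sprintf("Cannot parse atom spec '%s' (use 'chain:resno:name').", spec))
  }
}

resolve_atom_spec <- function(ensemble, spec) {
  s <- parse_atom_spec(spec)
  idx <- select_atoms(ensemble, chain = s$chain, resno = s$resno,
                      name = s$name)
  if (length(idx) == 0L) {
    cand <- select_atoms(ensemble, chain = s$chain, resno = s$resno)
    nms <- trimws(ensemble$atoms$name[cand])
    abort(sprintf(
      "Atom spec %s:%s:%s matches no atom. Atoms at that residue: %s.",
      s$chain %||% "*", s$resno, s$name,
      if (length(nms)) paste(nms, collapse = ", ") else "none"))
  }
  if (length(idx) > 1L) {
    at <- ensemble$atoms[idx, ]
    abort(sprintf(
      "Atom spec %s:%s:%s is ambiguous; candidates: %s.",
      s$chain %||% "*", s$resno, s$name,
      paste(sprintf("%s:%d:%s", at$chain, at$resno, trimws(at$name)),
            collapse = "; ")))
  }
  idx
}

#' Distance between two named atoms in a conformation
#'
#' @param conf A single conformation (one-frame [conf_ensemble()]).
#' @param spec1,spec2 Atom specs: `"chain:resno:name"` strings or lists with
#'   `chain`, `resno`, `name`. Each must resolve to exactly one atom.
#' @return Distance in Angstrom.
#' @export
atom_pair_distance <- function(conf, spec1, spec2) {
  stopifnot(inherits(conf, "conf_ensemble"))
  i <- resolve_atom_spec(conf, spec1)
  j <- resolve_atom_spec(conf, spec2)
  m <- frame_coords(conf, 1L)
  sqrt(sum((m[i, ] - m[j, ])^2))
}
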