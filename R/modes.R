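# Dynamic cross-correlation matrices and normal modes: anisotropic
# elastic-network (ANM) modes of a single structure and PCA modes of an
# ensemble, with mode contribution fractions and mode-displacement overlap.

# 3N x 3N ANM Hessian. Off-diagonal super-element for a contact pair (i,j):
# -gamma * (d_ij d_ij^T) / |d_ij|^2; diagonal super-elements are minus the
# row sums, so rigid-body motions are exact zero modes.
anm_hessian <- function(coords, cutoff = 15, gamma = 1) {
  coords <- as_coord_matrix(coords)
  n <- nrow(coords)
  h <- matrix(0, 3 * n, 3 * n)
  dmat <- as.matrix(dist(coords))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (dmat[i, j] > cutoff || dmat[i, j] == 0) next
      d <- coords[j, ] - coords[i, ]
      blk <- -gamma * tcrossprod(d) / sum(d^2)
      ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
      h[ii, jj] <- blk
      h[jj, ii] <- blk
      h[ii, ii] <- h[ii, ii] - blk
      h[jj, jj] <- h[jj, jj] - blk
    }
  }
  h
}

# Contact-graph connectivity check; returns component membership.
enm_components <- function(coords, cutoff) {
  dmat <- as.matrix(dist(as_coord_matrix(coords)))
  g <- igraph::graph_from_adjacency_matrix(dmat <= cutoff & dmat > 0,
                                           mode = "undirected")
  igraph::components(g)$membership
}

#' Anisotropic elastic-network (ANM) normal modes
#'
#' Builds the 3N x 3N elastic-network Hessian over the representative atoms
#' of `mask`, eigendecomposes it, removes exactly the 6 rigid-body zero
#' modes (by eigenvalue rank, after verifying that no more than 6
#' eigenvalues are numerically zero), and reports the remaining modes in
#' order of increasing eigenvalue. The contribution fraction of mode k is
#' its share of the thermal fluctuation variance,
#' `(1/lambda_k) / sum_m (1/lambda_m)` over retained modes.
#'
#' @param coords Reference coordinates: N x 3 matrix or single-frame
#'   [conf_ensemble()].
#' @param mask Optional mask restricting the network (ensemble input only).
#' @param cutoff Contact cutoff in Angstrom (default 15, standard
#'   C-alpha ANM practice).
#' @param gamma Uniform spring constant (arbitrary units; contribution
#'   fractions are scale-free).
#' @return A `mode_set`: `vectors` (3M x K, columns orthonormal, mode 1 =
#'   softest), `values` (eigenvalues, force-constant units), `fractions`,
#'   `kind = "ENM"`.
#' @export
anm_modes <- function(coords, mask = NULL, cutoff = 15, gamma = 1) {
  if (inherits(coords, "conf_ensemble")) {
    idx <- representative_atoms(coords, mask)
    coords <- frame_coords(coords, 1L)[idx, , drop = FALSE]
  } else {
    coords <- as_coord_matrix(coords)
  }
  n <- nrow(coords)
  if (n < 3L) abort("ANM needs at least 3 atoms.")
  h <- anm_hessian(coords, cutoff, gamma)
  eig <- eigen(h, symmetric = TRUE)
  vals <- rev(eig$values)            # ascending
  vecs <- eig$vectors[, rev(seq_len(3 * n)), drop = FALSE]
  thr <- 1e-8 * max(vals)
  nzero <- sum(vals < thr)
  if (nzero > 6L) {
    comp <- enm_components(coords, cutoff)
    abort(sprintf(
      "Structure is disconnected at cutoff %.1f A: %d components (sizes %s); %d near-zero modes.",
      cutoff, max(comp), paste(tabulate(comp), collapse = ", "), nzero))
  }
  keep <- (6L + 1L):(3L * n)
  vals <- vals[keep]
  vecs <- vecs[, keep, drop = FALSE]
  inv <- 1 / vals
  structure(
    list(vectors = vecs, values = vals, fractions = inv / sum(inv),
         kind = "ENM", n_atoms = n, cutoff = cutoff, gamma = gamma),
    class = "mode_set"
  )
}

#' Principal-component (PCA) modes of a conformational ensemble
#'
#' Frames are aligned to their mean structure, the 3M x 3M covariance of the
#' representative-atom coordinates is eigendecomposed, and modes are
#' reported in order of decreasing variance. Contribution fraction of mode k
#' is `lambda_k / sum(lambda)`.
#'
#' @param ensemble A [conf_ensemble()] with F >= 2 frames.
#' @param mask Optional mask restricting the atoms.
#' @param fit_mask Mask used for the alignment (default: `mask`).
#' @return A `mode_set` with `kind = "PCA"`, eigenvalues in Angstrom^2.
#' @export
pca_modes <- function(ensemble, mask = NULL, fit_mask = mask) {
  stopifnot(inherits(ensemble, "conf_ensemble"))
  if (n_frames(ensemble) < 2L) abort("PCA needs at least 2 frames.")
  aligned <- align_to_mean(ensemble, fit_mask)
  idx <- representative_atoms(ensemble, mask)
  nf <- dim(aligned)[1]
  # rows: frames; cols interleaved (x1,y1,z1,x2,...) to match mode vectors
  x <- matrix(NA_real_, nf, 3 * length(idx))
  for (f in seq_len(nf)) x[f, ] <- as.numeric(t(aligned[f, idx, ]))
  cv <- stats::cov(x)
  eig <- eigen(cv, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  structure(
    list(vectors = eig$vectors, values = vals,
         fractions = vals / sum(vals), kind = "PCA",
         n_atoms = length(idx)),
    class = "mode_set"
  )
}

#' @export
print.mode_set <- function(x, ...) {
  k <- min(10L, length(x$values))
  ord <- order(x$fractions, decreasing = TRUE)[seq_len(k)]
  cat(sprintf("<mode_set> %s, %d atoms, %d retained modes\n",
              x$kind, x$n_atoms, length(x$values)))
  cat("  top modes (fraction of fluctuation variance):\n")
  for (i in ord) {
    cat(sprintf("    mode %d: %.1f%%\n", i, 100 * x$fractions[i]))
  }
  invisible(x)
}

#' Tidy a mode set into a tibble of mode summaries
#'
#' @param x A `mode_set`.
#' @param ... Unused.
#' @return Tibble `mode`, `value`, `fraction`, `kind`.
#' @method tidy mode_set
#' @export
tidy.mode_set <- function(x, ...) {
  tibble(mode = seq_along(x$values), value = x$values,
         fraction = x$fractions, kind = x$kind)
}

#' Overlap between a mode and a displacement vector
#'
#' Absolute cosine of the angle between the two 3M-dimensional vectors;
#' 1 means the mode points exactly along the displacement (e.g. a reference
#' open-to-closed difference vector), 0 means orthogonal.
#'
#' @param mode,displacement Numeric vectors of equal length, nonzero.
#' @return Scalar in `[0, 1]`.
#' @export
mode_overlap <- function(mode, displacement) {
  mode <- as.numeric(mode); displacement <- as.numeric(displacement)
  if (length(mode) != length(displacement)) {
    abort("Vectors must have equal dimension.")
  }
  nm <- sqrt(sum(mode^2)); nd <- sqrt(sum(displacement^2))
  if (nm == 0 || nd == 0) abort("Zero vector supplied to mode_overlap().")
  abs(sum(mode * displacement)) / (nm * nd)
}

#' Root mean square inner product between two mode subspaces
#'
#' @param a,b `mode_set` objects over the same atoms.
#' @param n_modes Number of leading modes from each set (by contribution).
#' @return RMSIP in `[0, 1]`.
#' @export
rmsip <- function(a, b, n_modes = 5L) {
  ka <- order(a$fractions, decreasing = TRUE)[seq_len(n_modes)]
  kb <- order(b$fractions, decreasing = TRUE)[seq_len(n_modes)]
  va <- a$vectors[, ka, drop = FALSE]
  vb <- b$vectors[, kb, drop = FALSE]
  sqrt(sum((t(va) %*% vb)^2) / n_modes)
}

#' Dynamic cross-correlation matrix (DCCM)
#'
#' Frames are aligned to their mean structure (fit on `fit_mask`), and for
#' each pair of representative atoms the normalised covariance of the
#' displacement vectors about their means is computed:
#' `C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>)`. +1 is fully
#' correlated motion, -1 fully anticorrelated. Atoms with zero displacement
#' variance get `NA` rows/columns and a warning.
#'
#' @param ensemble A [conf_ensemble()] with F >= 2 frames.
#' @param mask Optional mask restricting the matrix.
#' @param fit_mask Mask for the alignment (default `mask`).
#' @param align Superpose frames onto their mean first (default). Set to
#'   `FALSE` for ensembles that are already aligned, where removing net
#'   translation/rotation again would distort constructed motions.
#' @return A `dccm` object: M x M matrix with a `keys` attribute
#'   (`chain:resno` labels).
#' @export
dccm <- function(ensemble, mask = NULL, fit_mask = mask, align = TRUE) {
  stopifnot(inherits(ensemble, "conf_ensemble"))
  if (n_frames(ensemble) < 2L) abort("DCCM needs at least 2 frames.")
  aligned <- if (align) align_to_mean(ensemble, fit_mask) else ensemble$coords
  idx <- representative_atoms(ensemble, mask)
  nf <- dim(aligned)[1]
  m <- length(idx)
  dx <- aligned[, idx, , drop = FALSE]
  mu <- apply(dx, c(2, 3), mean)
  for (f in seq_len(nf)) dx[f, , ] <- dx[f, , ] - mu
  # <dr_i . dr_j> = sum over xyz of time-covariance
  flat <- matrix(NA_real_, nf, 3 * m)
  for (f in seq_len(nf)) flat[f, ] <- as.numeric(t(dx[f, , ]))
  cv <- crossprod(flat) / nf
  inner <- matrix(0, m, m)
  for (d in 1:3) {
    sel <- seq(d, 3 * m, by = 3)
    inner <- inner + cv[sel, sel]
  }
  v <- diag(inner)
  zero_var <- v <= 0
  denom <- sqrt(outer(v, v))
  cc <- inner / denom
  if (any(zero_var)) {
    warn(sprintf("%d atom(s) with zero displacement variance; rows set to NA.",
                 sum(zero_var)))
    cc[zero_var, ] <- NA_real_
    cc[, zero_var] <- NA_real_
  }
  diag(cc)[!zero_var] <- 1
  at <- ensemble$atoms[idx, ]
  structure(cc, keys = paste0(at$chain, ":", at$resno), class = "dccm")
}

#' @export
print.dccm <- function(x, ...) {
  cat(sprintf("<dccm> %d x %d residues; range [%.3f, %.3f]\n",
              nrow(x), ncol(x), min(x, na.rm = TRUE), max(x, na.rm = TRUE)))
  invisible(x)
}

#' Difference between two cross-correlation matrices (a - b)
#'
#' The canonical use is mutant minus wild type, with the wild type as the
#' reference. When `blocks` (a named list of masks resolved to the same
#' residue keys, or of key subsets) is given, per-block-pair mean
#' differences are reported, supporting statements about e.g. increased
#' Fingers-Palm anticorrelation.
#'
#' @param a,b `dccm` objects with identical residue keys.
#' @param blocks Optional named list; each element a character vector of
#'   residue keys (`"chain:resno"`) or a `subdomain_mask` resolved against
#'   the same ensemble layout.
#' @param ensemble Ensemble used to resolve `subdomain_mask` blocks.
#' @return A list with `matrix` (M x M difference, class `dccm_diff`) and
#'   `blocks` (tibble `block_a`, `block_b`, `mean_diff`), or just the matrix
#'   when `blocks` is `NULL`.
#' @export
dccm_difference <- function(a, b, blocks = NULL, ensemble = NULL) {
  ka <- attr(a, "keys"); kb <- attr(b, "keys")
  if (is.null(ka) || is.null(kb) || !identical(ka, kb)) {
    abort("DCCM residue keys differ; matrices are not comparable.")
  }
  d <- unclass(a) - unclass(b)
  attr(d, "keys") <- ka
  class(d) <- "dccm_diff"
  if (is.null(blocks)) return(d)

  block_keys <- lapply(blocks, function(bl) {
    if (inherits(bl, "subdomain_mask")) {
      if (is.null(ensemble)) {
        abort("Resolving mask blocks needs `ensemble`.")
      }
      idx <- representative_atoms(ensemble, bl)
      at <- ensemble$atoms[idx, ]
      paste0(at$chain, ":", at$resno)
    } else {
      as.character(bl)
    }
  })
  combos <- expand.grid(block_a = names(block_keys),
                        block_b = names(block_keys),
                        stringsAsFactors = FALSE)
  combos <- combos[combos$block_a <= combos$block_b, , drop = FALSE]
  combos$mean_diff <- mapply(function(na_, nb_) {
    ia <- which(ka %in% block_keys[[na_]])
    ib <- which(ka %in% block_keys[[nb_]])
    mean(d[ia, ib], na.rm = TRUE)
  }, combos$block_a, combos$block_b)
  list(matrix = d, blocks = as_tibble(combos))
}
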