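#' Conformational ensemble container
#'
#' A `conf_ensemble` bundles frame-invariant atom metadata with an
#' F x N x 3 coordinate array (Angstrom). It is the universal trajectory
#' object consumed by every metric in the package: a single crystal/cryo-EM
#' model is an ensemble with one frame, an MD-like trajectory has many.
#'
#' @param atoms A data frame with one row per atom and columns `serial`,
#'   `name`, `resname`, `chain`, `resno`, `icode`, `element`. Missing
#'   optional columns are filled with defaults.
#' @param coords Either an N x 3 matrix (one frame) or an F x N x 3 array.
#' @return A `conf_ensemble` object.
#' @examples
#' atoms <- tibble::tibble(serial = 1:2, name = "CA", resname = "ALA",
#'                         chain = "A", resno = 1:2, element = "C")
#' ens <- conf_ensemble(atoms, matrix(rnorm(6), 2, 3))
#' n_frames(ens)
#' @export
conf_ensemble <- function(atoms, coords) {
  atoms <- as_tibble(as.data.frame(atoms, stringsAsFactors = FALSE))
  if (nrow(atoms) == 0L) abort("`atoms` must contain at least one atom.")
  if (!"serial" %in% names(atoms)) atoms$serial <- seq_len(nrow(atoms))
  if (!"name" %in% names(atoms)) abort("`atoms` needs a `name` column.")
  if (!"resname" %in% names(atoms)) atoms$resname <- "UNK"
  if (!"chain" %in% names(atoms)) atoms$chain <- "A"
  if (!"resno" %in% names(atoms)) atoms$resno <- seq_len(nrow(atoms))
  if (!"icode" %in% names(atoms)) atoms$icode <- ""
  if (!"element" %in% names(atoms)) {
    atoms$element <- toupper(substr(trimws(atoms$name), 1L, 1L))
  }
  atoms$serial <- as.integer(atoms$serial)
  atoms$resno <- as.integer(atoms$resno)
  if (anyDuplicated(atoms$serial)) {
    abort("Atom serial numbers must be unique within a frame.")
  }

  if (is.matrix(coords)) {
    coords <- array(coords, dim = c(1L, nrow(coords), ncol(coords)))
  }
  if (!is.array(coords) || length(dim(coords)) != 3L || dim(coords)[3] != 3L) {
    abort("`coords` must be an N x 3 matrix or an F x N x 3 array.")
  }
  if (dim(coords)[2] != nrow(atoms)) {
    abort(sprintf("Coordinate array has %d atoms but metadata has %d.",
                  dim(coords)[2], nrow(atoms)))
  }
  if (dim(coords)[1] < 1L) abort("An ensemble needs at least one frame.")
  if (!all(is.finite(coords))) abort("All coordinates must be finite.")
  storage.mode(coords) <- "double"

  structure(
    list(atoms = atoms, coords = coords,
         frame_index = seq_len(dim(coords)[1])),
    class = "conf_ensemble"
  )
}

#' @rdname conf_ensemble
#' @param x A `conf_ensemble`.
#' @export
n_frames <- function(x) {
  stopifnot(inherits(x, "conf_ensemble"))
  dim(x$coords)[1]
}

#' @rdname conf_ensemble
#' @export
n_atoms <- function(x) {
  stopifnot(inherits(x, "conf_ensemble"))
  dim(x$coords)[2]
}

#' Extract one frame as an N x 3 coordinate matrix
#'
#' @param x A `conf_ensemble`.
#' @param i Frame index (1-based).
#' @return An N x 3 numeric matrix in Angstrom.
#' @export
frame_coords <- function(x, i = 1L) {
  stopifnot(inherits(x, "conf_ensemble"))
  if (i < 1L || i > n_frames(x)) {
    abort(sprintf("Frame index %d out of range [1, %d].", i, n_frames(x)))
  }
  m <- x$coords[i, , , drop = FALSE]
  dim(m) <- dim(x$coords)[2:3]
  m
}

#' Extract a sub-ensemble restricted to a set of atoms
#'
#' @param x A `conf_ensemble`.
#' @param idx Integer atom indices (or a `subdomain_mask`).
#' @return A `conf_ensemble` over the selected atoms, frames preserved.
#' @export
subset_atoms <- function(x, idx) {
  stopifnot(inherits(x, "conf_ensemble"))
  idx <- mask_indices(idx)
  if (length(idx) == 0L) abort("Empty atom selection.")
  if (any(idx < 1L | idx > n_atoms(x))) abort("Atom index out of range.")
  conf_ensemble(x$atoms[idx, , drop = FALSE],
                x$coords[, idx, , drop = FALSE])
}

#' @export
print.conf_ensemble <- function(x, ...) {
  cat(sprintf("<conf_ensemble> %d frame(s) x %d atoms\n",
              n_frames(x), n_atoms(x)))
  chains <- unique(x$atoms$chain)
  cat(sprintf("  chains: %s; residues: %d\n",
              paste(chains, collapse = ", "),
              nrow(unique(x$atoms[c("chain", "resno", "icode")]))))
  invisible(x)
}

# Residue-level key used throughout (insertion codes distinct residues).
residue_key <- function(atoms) {
  paste(atoms$chain, atoms$resno, atoms$icode, sep = "|")
}

#' Representative-atom indices within a selection
#'
#' Subdomain-level metrics (RMSD, RMSF, DCCM, normal modes) operate on one
#' representative atom per residue: C-alpha for amino acids, C1' for
#' nucleotides. Selections containing neither (e.g. minimal synthetic
#' systems) fall back to the first atom of each residue.
#'
#' @param ensemble A `conf_ensemble`.
#' @param idx Atom indices or a `subdomain_mask` (default: all atoms).
#' @return Integer vector of atom indices, one per residue in the selection.
#' @export
representative_atoms <- function(ensemble, idx = NULL) {
  stopifnot(inherits(ensemble, "conf_ensemble"))
  idx <- if (is.null(idx)) seq_len(n_atoms(ensemble)) else mask_indices(idx)
  at <- ensemble$atoms[idx, , drop = FALSE]
  nm <- trimws(at$name)
  key <- residue_key(at)
  rep_of <- function(k) {
    sub <- which(key == k)
    hit <- sub[nm[sub] %in% c("CA", "C1'")]
    if (length(hit) > 0L) hit[1L] else sub[1L]
  }
  picked <- vapply(unique(key), rep_of, integer(1))
  sort(idx[picked])
}
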