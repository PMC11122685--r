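# Internal helpers shared across modules.

# Boltzmann/gas constant in kcal/(mol K); the single energy-unit convention
# used by the elastic-network sampler and the thermodynamic conversions.
.kB <- 1.98720425e-3

# Coulomb prefactor in kcal * Angstrom / (mol * e^2), vacuum.
.coulomb_k <- 332.0636

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random number stream. Every generator in the package funnels through this,
# which is what makes them pure functions of (parameters, seed).
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

stopifnot_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0.", name))
  }
  invisible(x)
}

# Coerce an N x 3 coordinate input (matrix, data frame, or single-frame
# ensemble) to a plain numeric matrix.
as_coord_matrix <- function(x, arg = "coords") {
  if (inherits(x, "conf_ensemble")) {
    if (n_frames(x) != 1L) {
      abort(sprintf("`%s`: expected a single conformation, got %d frames.",
                    arg, n_frames(x)))
    }
    return(frame_coords(x, 1L))
  }
  m <- as.matrix(x)
  if (ncol(m) != 3L || !is.numeric(m)) {
    abort(sprintf("`%s` must be an N x 3 numeric matrix.", arg))
  }
  storage.mode(m) <- "double"
  m
}
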