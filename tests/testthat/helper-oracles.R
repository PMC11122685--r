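# Independent reference implementations used as oracles. Each is written
# from a different formulation than the code it checks (quaternion
# superposition vs SVD, explicit double loops vs vectorised sums, numeric
# differentiation vs analytic Hessian, bisection vs quadratic formula).

# Horn's quaternion method for optimal superposition RMSD.
quaternion_rmsd <- function(mobile, target) {
  a <- scale(mobile, scale = FALSE)
  b <- scale(target, scale = FALSE)
  m <- t(a) %*% b
  sxx <- m[1, 1]; sxy <- m[1, 2]; sxz <- m[1, 3]
  syx <- m[2, 1]; syy <- m[2, 2]; syz <- m[2, 3]
  szx <- m[3, 1]; szy <- m[3, 2]; szz <- m[3, 3]
  k <- matrix(c(
    sxx + syy + szz, syz - szy,       szx - sxz,       sxy - syx,
    syz - szy,       sxx - syy - szz, sxy + syx,       szx + sxz,
    szx - sxz,       sxy + syx,       -sxx + syy - szz, syz + szy,
    sxy - syx,       szx + sxz,       syz + szy,       -sxx - syy + szz
  ), 4, 4, byrow = TRUE)
  lam <- max(eigen(k, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(a^2) + sum(b^2) - 2 * lam) / nrow(a)
  sqrt(max(msd, 0))
}

# Brute-force DCCM from pre-aligned coordinates (F x N x 3 array).
bruteforce_dccm <- function(aligned) {
  nf <- dim(aligned)[1]; n <- dim(aligned)[2]
  mu <- apply(aligned, c(2, 3), mean)
  cc <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      s <- 0; vi <- 0; vj <- 0
      for (f in seq_len(nf)) {
        di <- aligned[f, i, ] - mu[i, ]
        dj <- aligned[f, j, ] - mu[j, ]
        s <- s + sum(di * dj)
        vi <- vi + sum(di * di)
        vj <- vj + sum(dj * dj)
      }
      cc[i, j] <- s / sqrt(vi * vj)
    }
  }
  cc
}

# ENM potential energy: 0.5 * gamma * sum over contacts of the change in
# pair distance squared (contacts fixed at the reference geometry).
enm_potential <- function(x, ref, cutoff, gamma) {
  n <- nrow(ref)
  e <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d0 <- sqrt(sum((ref[i, ] - ref[j, ])^2))
      if (d0 > cutoff || d0 == 0) next
      d <- sqrt(sum((x[i, ] - x[j, ])^2))
      e <- e + 0.5 * gamma * (d - d0)^2
    }
  }
  e
}

# Central-difference Hessian of the ENM potential at the reference.
fd_enm_hessian <- function(ref, cutoff, gamma, h = 1e-5) {
  n3 <- 3 * nrow(ref)
  hes <- matrix(NA_real_, n3, n3)
  perturb <- function(k, delta) {
    x <- ref
    at <- ceiling(k / 3); dm <- (k - 1) %% 3 + 1
    x[at, dm] <- x[at, dm] + delta
    x
  }
  for (a in seq_len(n3)) {
    for (b in a:n3) {
      xpp <- perturb(a, h); xpp <- {
        at <- ceiling(b / 3); dm <- (b - 1) %% 3 + 1
        xpp[at, dm] <- xpp[at, dm] + h; xpp
      }
      xpm <- perturb(a, h); xpm <- {
        at <- ceiling(b / 3); dm <- (b - 1) %% 3 + 1
        xpm[at, dm] <- xpm[at, dm] - h; xpm
      }
      xmp <- perturb(a, -h); xmp <- {
        at <- ceiling(b / 3); dm <- (b - 1) %% 3 + 1
        xmp[at, dm] <- xmp[at, dm] + h; xmp
      }
      xmm <- perturb(a, -h); xmm <- {
        at <- ceiling(b / 3); dm <- (b - 1) %% 3 + 1
        xmm[at, dm] <- xmm[at, dm] - h; xmm
      }
      v <- (enm_potential(xpp, ref, cutoff, gamma) -
              enm_potential(xpm, ref, cutoff, gamma) -
              enm_potential(xmp, ref, cutoff, gamma) +
              enm_potential(xmm, ref, cutoff, gamma)) / (4 * h^2)
      hes[a, b] <- v; hes[b, a] <- v
    }
  }
  hes
}

# Breadth-first bond-graph distance, independent of igraph.
bfs_separation <- function(bonds, n_atoms, from, to, cap = 5L) {
  adj <- vector("list", n_atoms)
  if (nrow(bonds) > 0L) {
    for (r in seq_len(nrow(bonds))) {
      i <- bonds[r, 1]; j <- bonds[r, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  dist <- rep(Inf, n_atoms)
  dist[from] <- 0
  frontier <- from
  d <- 0
  while (length(frontier) > 0L && d < cap) {
    d <- d + 1
    nxt <- unique(unlist(adj[frontier]))
    nxt <- nxt[is.infinite(dist[nxt])]
    dist[nxt] <- d
    frontier <- nxt
  }
  dist[to]
}

# Independent residue-group non-bonded energy with Amber-style exclusions.
bruteforce_eda <- function(topology, coords, group_a, group_b) {
  coul <- 0; vdw <- 0
  n <- length(topology$charge)
  for (i in group_a) {
    seps <- bfs_separation(topology$bonds, n, i, group_b)
    for (bi in seq_along(group_b)) {
      j <- group_b[bi]
      sep <- seps[bi]
      if (sep <= 2) next
      fc <- if (sep == 3) 1 / 1.2 else 1
      fv <- if (sep == 3) 1 / 2.0 else 1
      r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      coul <- coul + fc * 332.0636 * topology$charge[i] * topology$charge[j] / r
      sg <- (topology$sigma[i] + topology$sigma[j]) / 2
      ep <- sqrt(topology$epsilon[i] * topology$epsilon[j])
      vdw <- vdw + fv * 4 * ep * ((sg / r)^12 - (sg / r)^6)
    }
  }
  c(coulomb = coul, vdw = vdw)
}

# Solve the one-site binding polynomial for free ligand by bisection, then
# bound complex; an alternative route to the quadratic smaller root.
bisect_bound <- function(n, kd, mt, xt, tol = 1e-15) {
  f <- function(xfree) {
    bound <- n * mt * xfree / (kd + xfree)
    xfree + bound - xt
  }
  lo <- 0; hi <- xt
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  xfree <- (lo + hi) / 2
  n * mt * xfree / (kd + xfree)
}

# Heats via the bisection route under the same perfusion dilution model.
bisect_wiseman <- function(n, kd, dh, injection_vol, cell_volume, cell_conc,
                           syringe_conc) {
  k <- length(injection_vol)
  m <- cell_conc; x <- 0
  bound_prev <- 0
  q <- numeric(k)
  for (i in seq_len(k)) {
    fdil <- injection_vol[i] / cell_volume
    m <- m * (1 - fdil)
    x <- x * (1 - fdil) + syringe_conc * fdil
    bound <- bisect_bound(n, kd, m, x)
    q[i] <- dh * cell_volume * 1e-6 *
      (bound - bound_prev * (1 - fdil)) * 1e9
    bound_prev <- bound
  }
  q
}

# Shared fixtures -----------------------------------------------------------

helix_coords <- function(n, radius = 2.3, rise = 1.5, turn_deg = 100) {
  t <- seq_len(n)
  cbind(radius * cos(t * turn_deg * pi / 180),
        radius * sin(t * turn_deg * pi / 180),
        rise * t)
}

random_ensemble <- function(n_frames, n_atoms, seed, sd = 1) {
  set.seed(seed)
  atoms <- tibble::tibble(serial = seq_len(n_atoms), name = "CA",
                          resname = "ALA", chain = "A",
                          resno = seq_len(n_atoms), element = "C")
  base <- matrix(runif(n_atoms * 3, -5, 5), n_atoms, 3)
  coords <- array(NA_real_, dim = c(n_frames, n_atoms, 3))
  for (f in seq_len(n_frames)) {
    coords[f, , ] <- base + matrix(rnorm(n_atoms * 3, sd = sd), n_atoms, 3)
  }
  polsite::conf_ensemble(atoms, coords)
}

rotation_about_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

rotation_about_axis <- function(axis, deg) {
  axis <- axis / sqrt(sum(axis^2))
  th <- deg * pi / 180
  k <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(th) * k + (1 - cos(th)) * (k %*% k)
}
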