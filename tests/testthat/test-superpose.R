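test_that("kabsch recovers identity and constructed rigid transforms", {
  set.seed(1)
  a <- matrix(rnorm(30), 10, 3)
  sp <- kabsch(a, a)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-12)
  expect_lt(sp$rmsd, 1e-12)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)

  rz <- rotation_about_z(90)
  b <- a %*% rz + matrix(c(1, -2, 5), 10, 3, byrow = TRUE)
  sp2 <- kabsch(a, b)
  expect_lt(sp2$rmsd, 1e-9)
  ang <- acos((sum(diag(sp2$rotation)) - 1) / 2) * 180 / pi
  expect_equal(ang, 90, tolerance = 1e-9)
  expect_equal(apply_superposition(a, sp2), b, tolerance = 1e-9)
})

test_that("kabsch refuses tiny inputs, flags degeneracy, stays proper", {
  expect_error(kabsch(matrix(0, 2, 3), matrix(0, 2, 3)), "at least 3")
  line <- cbind(1:5, 0, 0)
  set.seed(2)
  sp <- kabsch(line, line %*% rotation_about_z(40))
  expect_true(sp$degenerate)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
})

test_that("kabsch RMSD matches the quaternion oracle on random clouds", {
  set.seed(99)
  for (i in 1:25) {
    a <- matrix(rnorm(30), 10, 3)
    b <- matrix(rnorm(30), 10, 3)
    expect_lt(abs(kabsch(a, b)$rmsd - quaternion_rmsd(a, b)), 1e-8)
  }
})

test_that("weighted superposition ignores zero-weight outliers", {
  set.seed(4)
  a <- matrix(rnorm(24), 8, 3)
  b <- a %*% rotation_about_z(25)
  a_out <- rbind(a, c(100, 100, 100))
  b_out <- rbind(b, c(-50, 0, 0))
  w <- c(rep(1, 8), 0)
  expect_lt(kabsch(a_out, b_out, weights = w)$rmsd, 1e-9)
})

test_that("rmsd_series is zero for self-reference and removes rigid offsets", {
  ens <- random_ensemble(1, 10, seed = 11)
  coords <- array(NA_real_, dim = c(5, 10, 3))
  for (f in 1:5) coords[f, , ] <- frame_coords(ens, 1)
  stacked <- conf_ensemble(ens$atoms, coords)
  mask <- subdomain_mask("all", 1:10)
  rs <- rmsd_series(stacked, reference = frame_coords(ens, 1),
                    fit_mask = mask, calc_masks = list(all = mask))
  expect_true(all(rs$rmsd < 1e-12))

  coords[3, , ] <- coords[3, , ] + 1   # translate frame 3 by (1,1,1)
  shifted <- conf_ensemble(ens$atoms, coords)
  rs2 <- rmsd_series(shifted, reference = frame_coords(ens, 1),
                     fit_mask = mask, calc_masks = list(all = mask))
  expect_true(all(rs2$rmsd < 1e-12))
})

test_that("rmsd_series equals a brute-force per-frame kabsch loop", {
  ens <- random_ensemble(6, 12, seed = 21, sd = 0.7)
  ref <- frame_coords(ens, 1)
  fit_idx <- 1:8
  calc_idx <- 9:12
  rs <- rmsd_series(ens, reference = ref,
                    fit_mask = subdomain_mask("core", fit_idx),
                    calc_masks = list(tail = subdomain_mask("tail", calc_idx)))
  for (f in 1:6) {
    m <- frame_coords(ens, f)
    sp <- kabsch(m[fit_idx, ], ref[fit_idx, ])
    al <- apply_superposition(m, sp)
    expect_equal(unname(rs$rmsd[rs$frame == f]),
                 sqrt(mean(rowSums((al[calc_idx, ] - ref[calc_idx, ])^2))),
                 tolerance = 1e-10)
  }
})

test_that("rmsf is zero for constant ensembles and sqrt(3)*sigma for isotropic jitter", {
  ens0 <- random_ensemble(1, 8, seed = 31)
  coords <- array(NA_real_, dim = c(5, 8, 3))
  for (f in 1:5) coords[f, , ] <- frame_coords(ens0, 1)
  expect_true(all(rmsf_profile(conf_ensemble(ens0$atoms, coords))$rmsf < 1e-12))

  # enough atoms that absorbing 6 rigid DOFs into the fit (6 of 3N
  # variance components) shifts the RMSF by well under the tolerance
  sigma <- 0.25
  n_at <- 100
  set.seed(77)
  base <- helix_coords(n_at) * 4
  jit <- array(rnorm(10000 * n_at * 3, sd = sigma),
               dim = c(10000, n_at, 3))
  for (f in 1:10000) jit[f, , ] <- jit[f, , ] + base
  atoms <- tibble::tibble(serial = 1:n_at, name = "CA", resname = "ALA",
                          chain = "A", resno = 1:n_at, element = "C")
  prof <- rmsf_profile(conf_ensemble(atoms, jit))
  expect_equal(mean(prof$rmsf), sigma * sqrt(3), tolerance = 0.03)
})

test_that("rmsf matches a brute-force two-pass computation on aligned frames", {
  ens <- random_ensemble(40, 6, seed = 41, sd = 0.3)
  prof <- rmsf_profile(ens)
  aligned <- polsite:::align_to_mean(ens, NULL)
  mu <- attr(aligned, "mean_structure")
  brute <- vapply(1:6, function(i) {
    sqrt(mean(rowSums(sweep(aligned[, i, ], 2, mu[i, ])^2)))
  }, numeric(1))
  expect_equal(prof$rmsf, brute, tolerance = 1e-10)
})

test_that("delta_rmsf differences, reports missing keys, and is antisymmetric", {
  a <- tibble::tibble(chain = "A", resno = 1:5, atom = "CA",
                      rmsf = c(1, 2, 3, 4, 5))
  b <- tibble::tibble(chain = "A", resno = 3:7, atom = "CA",
                      rmsf = c(1, 1, 1, 1, 1))
  d <- delta_rmsf(a, b)
  expect_equal(d$resno, 3:5)
  expect_equal(d$delta_rmsf, c(2, 3, 4))
  expect_equal(nrow(attr(d, "missing")$only_in_a), 2L)
  d2 <- delta_rmsf(b, a)
  expect_equal(d2$delta_rmsf, -d$delta_rmsf)
  expect_equal(delta_rmsf(a, a)$delta_rmsf, rep(0, 5))
  c_tbl <- tibble::tibble(chain = "B", resno = 1:3, rmsf = 1:3)
  expect_error(delta_rmsf(a, c_tbl), "no residues")
})

test_that("domain rotation angle recovers constructed hinge rotations monotonically", {
  set.seed(51)
  coords <- helix_coords(20)
  fit_idx <- 1:10; dom_idx <- 11:20
  hinge <- colMeans(coords[10:11, ])
  axis <- c(0, 0, 1)
  rotate_domain <- function(deg) {
    out <- coords
    r <- rotation_about_axis(axis, deg)
    out[dom_idx, ] <- sweep(sweep(coords[dom_idx, ], 2, hinge) %*% t(r),
                            2, hinge, `+`)
    out
  }
  expect_equal(domain_rotation_angle(coords, coords, fit_idx,
                                     dom_idx)$angle_deg, 0, tolerance = 1e-6)
  r30 <- domain_rotation_angle(coords, rotate_domain(30), fit_idx, dom_idx)
  expect_equal(r30$angle_deg, 30, tolerance = 1e-6)
  sweep_deg <- c(10, 50, 90, 130, 170)
  got <- vapply(sweep_deg, function(d) {
    domain_rotation_angle(coords, rotate_domain(d), fit_idx, dom_idx)$angle_deg
  }, numeric(1))
  expect_equal(got, sweep_deg, tolerance = 1e-6)
  expect_true(all(diff(got) > 0))
})

test_that("atom pair distances resolve specs and are rigid-motion invariant", {
  atoms <- tibble::tibble(serial = 1:3, name = c("O3'", "PA", "MG"),
                          resname = c("DC", "DCP", "MG"), chain = "A",
                          resno = 1:3, element = c("O", "P", "MG"))
  conf <- conf_ensemble(atoms, rbind(c(0, 0, 0), c(3, 4, 0), c(1, 1, 1)))
  expect_equal(atom_pair_distance(conf, "A:1:O3'", "A:2:PA"), 5)
  expect_equal(atom_pair_distance(conf, "A:1:O3'", "A:1:O3'"), 0)
  expect_error(atom_pair_distance(conf, "A:1:OXT", "A:2:PA"), "O3'")

  r <- rotation_about_axis(c(1, 2, 0.5), 66)
  moved <- conf_ensemble(atoms, frame_coords(conf, 1) %*% t(r) +
                           matrix(c(3, -1, 2), 3, 3, byrow = TRUE))
  expect_equal(atom_pair_distance(moved, "A:1:O3'", "A:2:PA"), 5,
               tolerance = 1e-10)
})
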