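test_that("dccm pins constructed correlated and anticorrelated motion", {
  # atoms 1 and 2 translate identically; atom 3 jitters independently in z
  set.seed(61)
  nf <- 200
  coords <- array(0, dim = c(nf, 3, 3))
  drift <- rnorm(nf)
  for (f in 1:nf) {
    coords[f, 1, ] <- c(0, 0, 0) + c(drift[f], 0, 0)
    coords[f, 2, ] <- c(5, 0, 0) + c(drift[f], 0, 0)
    coords[f, 3, ] <- c(0, 5, 0) + c(0, 0, rnorm(1))
  }
  atoms <- tibble::tibble(serial = 1:3, name = "CA", resname = "ALA",
                          chain = "A", resno = 1:3, element = "C")
  ens <- conf_ensemble(atoms, coords)
  # skip alignment effects: use a fixed fit on all atoms of a rigid frame
  cc <- dccm(ens, align = FALSE)
  expect_equal(unclass(cc)[1, 2], 1, tolerance = 1e-9)

  coords2 <- coords
  for (f in 1:nf) coords2[f, 2, ] <- c(5, 0, 0) - c(drift[f], 0, 0)
  cc2 <- dccm(conf_ensemble(atoms, coords2), align = FALSE)
  expect_equal(unclass(cc2)[1, 2], -1, tolerance = 1e-9)
})

test_that("dccm equals the brute-force double loop and stays in [-1, 1]", {
  ens <- random_ensemble(30, 8, seed = 71, sd = 0.4)
  cc <- dccm(ens)
  aligned <- polsite:::align_to_mean(ens, NULL)
  brute <- bruteforce_dccm(aligned)
  expect_lt(max(abs(unclass(cc) - brute)), 1e-10)
  expect_true(all(unclass(cc) >= -1 - 1e-12 & unclass(cc) <= 1 + 1e-12))
  expect_equal(unname(diag(unclass(cc))), rep(1, 8), tolerance = 1e-9)
  expect_equal(unclass(cc), t(unclass(cc)), tolerance = 1e-12)
})

test_that("dccm difference is zero on identity, antisymmetric, and detects designed blocks", {
  ens <- random_ensemble(25, 6, seed = 81, sd = 0.3)
  cc <- dccm(ens)
  d0 <- dccm_difference(cc, cc)
  expect_true(all(abs(d0) < 1e-14))

  ens2 <- random_ensemble(25, 6, seed = 82, sd = 0.3)
  cc2 <- dccm(ens2)
  expect_equal(unclass(dccm_difference(cc, cc2)),
               -unclass(dccm_difference(cc2, cc)), ignore_attr = TRUE)

  # designed contrast: "wt" has anticorrelated halves, "mut" independent
  set.seed(83)
  nf <- 400
  mk <- function(anti) {
    coords <- array(0, dim = c(nf, 6, 3))
    base <- helix_coords(6) * 3
    for (f in 1:nf) {
      a <- rnorm(1, sd = 0.5)
      b <- if (anti) -a else rnorm(1, sd = 0.5)
      coords[f, , ] <- base + 0.05 * array(rnorm(18), dim = c(6, 3))
      coords[f, 1:3, 1] <- coords[f, 1:3, 1] + a
      coords[f, 4:6, 1] <- coords[f, 4:6, 1] + b
    }
    atoms <- tibble::tibble(serial = 1:6, name = "CA", resname = "ALA",
                            chain = "A", resno = 1:6, element = "C")
    dccm(conf_ensemble(atoms, coords), align = FALSE)
  }
  wt <- mk(anti = TRUE); mut <- mk(anti = FALSE)
  res <- dccm_difference(mut, wt,
                         blocks = list(half1 = c("A:1", "A:2", "A:3"),
                                       half2 = c("A:4", "A:5", "A:6")))
  cross <- res$blocks$mean_diff[res$blocks$block_a == "half1" &
                                  res$blocks$block_b == "half2"]
  expect_gt(cross, 0.3)   # mut minus wt loses the anticorrelation
  other <- dccm(random_ensemble(25, 8, seed = 84, sd = 0.3))
  expect_error(dccm_difference(cc, other), "keys differ")
})

test_that("ANM yields exactly 6 zero modes and the 2-body analytic solution", {
  ms <- anm_modes(helix_coords(10), cutoff = 15, gamma = 1)
  # retained spectrum strictly positive, 6 modes removed
  expect_equal(length(ms$values), 24L)
  expect_true(all(ms$values > 1e-8 * max(ms$values)))
  expect_equal(sum(ms$fractions), 1)

  # two particles, one spring, gamma = 1: single internal mode, eigenvalue
  # 2*gamma, eigenvector the symmetric stretch along the bond
  h <- polsite:::anm_hessian(rbind(c(0, 0, 0), c(2, 0, 0)), cutoff = 5,
                             gamma = 1)
  eig <- eigen(h, symmetric = TRUE)
  # a linear 2-atom system has 5 rigid modes, 1 internal mode
  expect_equal(sort(eig$values)[5], 0, tolerance = 1e-12)
  expect_equal(max(eig$values), 2, tolerance = 1e-12)
  stretch <- eig$vectors[, which.max(eig$values)]
  expect_equal(abs(stretch), c(1, 0, 0, 1, 0, 0) / sqrt(2), tolerance = 1e-9)

  h3 <- polsite:::anm_hessian(rbind(c(0, 0, 0), c(3, 0, 0)), cutoff = 5,
                              gamma = 2.5)
  expect_equal(max(eigen(h3, only.values = TRUE)$values), 5, tolerance = 1e-12)
})

test_that("ANM Hessian matches finite differences of the network potential", {
  ref <- helix_coords(5)
  h <- polsite:::anm_hessian(ref, cutoff = 8, gamma = 1.3)
  fd <- fd_enm_hessian(ref, cutoff = 8, gamma = 1.3)
  expect_lt(max(abs(h - fd)), 1e-6)
})

test_that("ANM spectrum is invariant under rigid rotation of the input", {
  ref <- helix_coords(9)
  r <- rotation_about_axis(c(1, 1, 2), 37)
  v1 <- anm_modes(ref)$values
  v2 <- anm_modes(ref %*% t(r) + 5)$values
  expect_equal(v1, v2, tolerance = 1e-9)
})

test_that("degenerate eigenvalues of a symmetric network get equal fractions", {
  # equilateral triangle: the two in-plane E modes are degenerate
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  ms <- anm_modes(tri, cutoff = 2, gamma = 1)
  expect_equal(length(ms$values), 3L)
  dup <- which(abs(diff(ms$values)) < 1e-9)
  expect_length(dup, 1L)
  expect_equal(ms$fractions[dup], ms$fractions[dup + 1], tolerance = 1e-12)
})

test_that("PCA recovers a 1-D oscillation and matches brute-force covariance", {
  nf <- 50
  base <- helix_coords(5) * 4
  coords <- array(0, dim = c(nf, 5, 3))
  amp <- sin(seq(0, 6 * pi, length.out = nf))
  for (f in 1:nf) {
    coords[f, , ] <- base
    coords[f, , 1] <- coords[f, , 1] + amp[f]   # all atoms oscillate in x
  }
  atoms <- tibble::tibble(serial = 1:5, name = "CA", resname = "ALA",
                          chain = "A", resno = 1:5, element = "C")
  # common x-translation is removed by fitting, so add marker motion on one
  # atom only to keep an internal mode
  coords[, 3, 1] <- coords[, 3, 1] + amp
  ms <- pca_modes(conf_ensemble(atoms, coords))
  expect_gt(ms$fractions[1], 0.99)

  ens <- random_ensemble(40, 4, seed = 91, sd = 0.2)
  aligned <- polsite:::align_to_mean(ens, NULL)
  x <- matrix(NA_real_, 40, 12)
  for (f in 1:40) x[f, ] <- as.numeric(t(aligned[f, , ]))
  brute_cov <- crossprod(sweep(x, 2, colMeans(x))) / (40 - 1)
  ms2 <- pca_modes(ens)
  expect_equal(sum(ms2$values), sum(diag(brute_cov)), tolerance = 1e-9)
  expect_equal(sort(ms2$values, decreasing = TRUE),
               sort(pmax(eigen(brute_cov, only.values = TRUE)$values, 0),
                    decreasing = TRUE), tolerance = 1e-9)
})

test_that("mode overlap is a cosine with the Bessel bound over an orthonormal set", {
  v <- c(1, 2, 3) / sqrt(14)
  expect_equal(mode_overlap(v, 2 * v), 1)
  expect_equal(mode_overlap(c(1, 0), c(0, 1)), 0)
  expect_error(mode_overlap(c(0, 0), c(1, 0)), "Zero vector")

  ms <- anm_modes(helix_coords(8))
  set.seed(5)
  u <- rnorm(24); u <- u / sqrt(sum(u^2))
  tot <- sum(vapply(seq_len(ncol(ms$vectors)), function(k) {
    mode_overlap(ms$vectors[, k], u)^2
  }, numeric(1)))
  expect_lte(tot, 1 + 1e-9)
})

test_that("PCA of an ENM ensemble spans the soft ANM subspace", {
  # smaller-scale counterpart of the acceptance check
  ref <- helix_coords(10)
  ens <- gen_enm_ensemble(ref, n_frames = 4000, seed = 13)
  expect_gt(rmsip(anm_modes(ref), pca_modes(ens), n_modes = 5), 0.85)
})
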