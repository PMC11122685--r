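active_site_ensemble <- function(nf, seed) {
  # 4 named atoms; O3'-PA distance drifts, others rigid
  set.seed(seed)
  atoms <- tibble::tibble(serial = 1:4,
                          name = c("O3'", "PA", "OD1", "MG"),
                          resname = c("DC", "DCP", "ASP", "MG"),
                          chain = "A", resno = 1:4,
                          element = c("O", "P", "O", "MG"))
  coords <- array(0, dim = c(nf, 4, 3))
  for (f in 1:nf) {
    coords[f, 1, ] <- c(0, 0, 0)
    coords[f, 2, ] <- c(3.5 + 0.3 * sin(f), 0, 0)
    coords[f, 3, ] <- c(0, 3.1, 0)
    coords[f, 4, ] <- c(1.8, 1.8, 1.0)
  }
  conf_ensemble(atoms, coords)
}

test_that("extract_distances matches per-frame atom_pair_distance and rigid invariance", {
  ens <- active_site_ensemble(10, seed = 1)
  specs <- list(distance_spec("d1", "A:1:O3'", "A:2:PA"),
                distance_spec("d2", "A:3:OD1", "A:1:O3'"))
  tb <- extract_distances(ens, specs)
  expect_named(tb, c("frame", "d1", "d2"))
  for (f in c(1, 5, 10)) {
    one <- subset_atoms(ens, 1:4)
    conf <- conf_ensemble(ens$atoms, frame_coords(ens, f))
    expect_equal(tb$d1[f], atom_pair_distance(conf, "A:1:O3'", "A:2:PA"),
                 tolerance = 1e-12)
  }
  expect_equal(tb$d2, rep(3.1, 10), tolerance = 1e-12)

  r <- rotation_about_axis(c(2, 1, 1), 53)
  coords <- ens$coords
  for (f in 1:10) coords[f, , ] <- frame_coords(ens, f) %*% t(r) + 7
  moved <- conf_ensemble(ens$atoms, coords)
  expect_equal(extract_distances(moved, specs)$d1, tb$d1, tolerance = 1e-10)
})

test_that("a static ensemble yields constant distances and missing atoms are named", {
  ens <- active_site_ensemble(1, seed = 2)
  coords <- array(NA_real_, dim = c(3, 4, 3))
  for (f in 1:3) coords[f, , ] <- frame_coords(ens, 1)
  stat <- conf_ensemble(ens$atoms, coords)
  tb <- extract_distances(stat, list(distance_spec("d2", "A:3:OD1", "A:1:O3'")))
  expect_equal(diff(range(tb$d2)), 0)
  expect_error(
    extract_distances(ens, list(distance_spec("dx", "A:9:XX", "A:1:O3'"))),
    "matches no atom")
})

test_that("kmeans_2d handles the degenerate extremes", {
  set.seed(3)
  pts <- matrix(rnorm(60), 30, 2)
  one <- kmeans_2d(pts, k = 1, seed = 1)
  expect_equal(unlist(one$centroids[1, c("d1", "d2")]), colMeans(pts),
               ignore_attr = TRUE, tolerance = 1e-12)
  all_k <- kmeans_2d(pts, k = 30, seed = 1)
  expect_lt(all_k$tot_withinss, 1e-20)
  expect_error(kmeans_2d(matrix(c(1, 1, 1, 1), 2, 2), k = 2), "distinct")
})

test_that("kmeans_2d recovers well-separated blobs and their mixing fractions", {
  set.seed(4)
  nf <- 10000
  lab <- runif(nf) < 0.3
  pts <- cbind(ifelse(lab, rnorm(nf, 3.4, 0.1), rnorm(nf, 4.4, 0.2)),
               ifelse(lab, rnorm(nf, 3.1, 0.1), rnorm(nf, 4.0, 0.2)))
  cl <- kmeans_2d(pts, k = 2, seed = 99)
  expect_equal(cl$centroids$d1, c(3.4, 4.4), tolerance = 0.01)
  expect_equal(cl$centroids$occupancy[1], mean(lab), tolerance = 0.01)
  # determinism
  cl2 <- kmeans_2d(pts, k = 2, seed = 99)
  expect_identical(cl$assignment, cl2$assignment)
})

test_that("silhouette-based k selection finds two clusters in a two-blob field", {
  set.seed(5)
  nf <- 2000
  lab <- runif(nf) < 0.4
  pts <- cbind(ifelse(lab, rnorm(nf, 3.4, 0.08), rnorm(nf, 4.5, 0.15)),
               ifelse(lab, rnorm(nf, 3.1, 0.08), rnorm(nf, 4.1, 0.15)))
  cl <- kmeans_2d(pts, k = NULL, seed = 7)
  expect_equal(cl$k, 2L)
})

test_that("Lloyd iterations never increase the within-cluster sum of squares", {
  set.seed(6)
  pts <- rbind(matrix(rnorm(400, 0, 1), ncol = 2),
               matrix(rnorm(400, 4, 1), ncol = 2))
  init <- pts[c(1, 2, 3), ]
  wss <- vapply(1:8, function(it) {
    suppressWarnings(
      stats::kmeans(pts, centers = init, algorithm = "Lloyd",
                    iter.max = it)$tot.withinss)
  }, numeric(1))
  expect_true(all(diff(wss) <= 1e-9))
})

test_that("box occupancy counts closed-box membership and is monotone in the box", {
  series <- tibble::tibble(d1 = c(3.0, 3.4, 3.8, 4.2),
                           d2 = c(2.8, 3.0, 3.5, 3.6))
  box <- competence_box()
  occ <- box_occupancy(series, box)
  expect_equal(occ$occupancy, 0.75)   # boundary points are inside
  all_in <- box_occupancy(tibble::tibble(d1 = rep(3.4, 5), d2 = rep(3.0, 5)),
                          box)
  expect_equal(all_in$occupancy, 1)
  none <- box_occupancy(series, competence_box(10, 11, 10, 11))
  expect_equal(none$occupancy, 0)

  bigger <- box_occupancy(series, competence_box(2.9, 4.3, 2.7, 3.7))
  expect_gte(bigger$occupancy, occ$occupancy)
  expect_error(competence_box(3.8, 3.0, 2.8, 3.5), "low < high")
})

test_that("cluster-membership occupancy reports centroids inside the box", {
  set.seed(8)
  nf <- 5000
  lab <- runif(nf) < 0.35
  series <- tibble::tibble(
    d1 = ifelse(lab, rnorm(nf, 3.4, 0.1), rnorm(nf, 4.4, 0.2)),
    d2 = ifelse(lab, rnorm(nf, 3.1, 0.1), rnorm(nf, 4.0, 0.2)))
  cl <- kmeans_2d(series, k = 2, seed = 11)
  occ <- box_occupancy(series, competence_box(), cl)
  expect_equal(occ$clusters_inside[[1]], 1L)
  expect_equal(occ$occupancy_by_cluster, mean(lab), tolerance = 0.02)
  expect_equal(occ$occupancy, occ$occupancy_by_cluster, tolerance = 0.03)
})

test_that("threshold fractions use strict inequalities and sum to one", {
  expect_equal(
    as.numeric(threshold_fractions(tibble::tibble(d1 = rep(3.5, 4)))),
    c(1, 0, 0))
  expect_equal(
    as.numeric(threshold_fractions(tibble::tibble(d1 = rep(3.9, 4)))),
    c(0, 1, 0))
  expect_equal(
    as.numeric(threshold_fractions(tibble::tibble(d1 = c(3.8, 4.0)))),
    c(0, 1, 0))   # boundary values are intermediate under strict inequalities

  m <- two_state_defaults("mutant")
  d <- gen_two_state_distances(m, 50000, seed = 17)
  fr <- threshold_fractions(d)
  expect_equal(fr$f_competent + fr$f_intermediate + fr$f_incompetent, 1)
  # state A (sd 0.10 around 3.5) is essentially all competent; state B
  # contributes P(d1 < 3.8 | B) ~ 2.3%
  expected <- 0.12 * 0.9987 + 0.88 * pnorm((3.8 - 4.3) / 0.25)
  ci <- 3 * sqrt(expected * (1 - expected) / 50000)
  expect_lt(abs(fr$f_competent - expected), ci + 0.002)
  expect_error(threshold_fractions(d, competent_max = 4.2,
                                   incompetent_min = 4.0), "<=")
})

test_that("the generate-cluster-occupancy pipeline recovers both regimes", {
  wt <- gen_two_state_distances(two_state_defaults("wt"), 150000, seed = 21)
  cl_wt <- kmeans_2d(wt, k = 2, seed = 853)
  occ_wt <- box_occupancy(wt, competence_box(), cl_wt)
  expect_gt(occ_wt$occupancy, 0.35)
  expect_lt(abs(occ_wt$occupancy - 0.40), 0.02)

  mut <- gen_two_state_distances(two_state_defaults("mutant"), 150000,
                                 seed = 22)
  occ_mut <- box_occupancy(mut, competence_box())
  expect_lt(occ_mut$occupancy, 0.15)
  expect_lt(abs(occ_mut$occupancy - 0.12), 0.02)
})
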